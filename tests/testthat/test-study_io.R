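test_that("synapse and neuron tables round-trip through CSV", {
  syn <- toy_synapses(c("acetylcholine", "gaba", "glutamate"))
  neu <- tibble::tibble(neuron_id = "n1", hemilineage = "hlA",
                        cell_type = "t1", side = "right", dataset = "sim",
                        homolog_id = NA_character_)
  sp <- withr::local_tempfile(fileext = ".csv")
  np <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(syn, sp)
  readr::write_csv(neu, np)
  tb <- read_tables(sp, np, dialect = "fafb")
  expect_equal(nrow(tb$synapses), 3)
  expect_equal(tb$synapses$pred_label, syn$pred_label)
  expect_equal(tb$neurons$neuron_id, "n1")
  expect_equal(tb$dialect, "fafb")
})

test_that("label vocabulary is normalized case-insensitively via aliases", {
  expect_equal(normalize_transmitters(c("ACh", "GABA", "Glut", "5-HT", "OA", "DA")),
               c("acetylcholine", "gaba", "glutamate", "serotonin",
                 "octopamine", "dopamine"))
  syn <- toy_synapses("acetylcholine")
  syn$pred_label <- "ACh"
  expect_equal(validate_synapse_table(syn)$pred_label, "acetylcholine")
  syn$pred_label <- "histamine"
  expect_error(validate_synapse_table(syn), "histamine")
})

test_that("schema violations raise errors naming the offender", {
  syn <- toy_synapses("gaba")
  expect_error(validate_synapse_table(syn[setdiff(names(syn), "neuron_id")]),
               "neuron_id")
  syn2 <- rbind(syn, syn) # duplicate synapse_id
  expect_error(validate_synapse_table(syn2), "unique")
  expect_error(validate_neuron_table(tibble::tibble(x = 1)), "neuron_id")
})

test_that("score vectors are simplex-normalized and checked against labels", {
  syn <- toy_synapses(c("gaba", "acetylcholine"))
  scores <- matrix(0, 2, 6, dimnames = list(NULL, paste0("score_", labs)))
  scores[1, ] <- c(8, 1, 1, 0, 0, 0)   # argmax gaba
  scores[2, ] <- c(1, 6, 1, 1, 1, 0)   # argmax acetylcholine
  syn <- cbind(syn, as.data.frame(scores))
  v <- validate_synapse_table(syn)
  expect_equal(unname(rowSums(as.matrix(v[paste0("score_", labs)]))), c(1, 1))
  expect_equal(v$score_gaba[1], 0.8)

  # zero-sum score row is rejected
  syn$score_gaba[1] <- 0; syn$score_acetylcholine[1] <- 0
  syn$score_glutamate[1] <- 0
  expect_error(validate_synapse_table(syn), "sum to zero")

  # label contradicting the argmax is rejected
  syn2 <- cbind(toy_synapses(c("dopamine", "acetylcholine")),
                as.data.frame(scores))
  expect_error(validate_synapse_table(syn2), "argmax")
})

test_that("homolog links are symmetrized and conflicts rejected", {
  neu <- tibble::tibble(neuron_id = c("a", "b"), homolog_id = c("b", NA))
  v <- validate_neuron_table(neu)
  expect_equal(v$homolog_id, c("b", "a"))
  bad <- tibble::tibble(neuron_id = c("a", "b", "c"),
                        homolog_id = c("b", "c", "b"))
  expect_error(validate_neuron_table(bad), "asymmetric")
})

test_that("neuron-call output is written deterministically and round-trips", {
  syn <- toy_synapses(c(rep("acetylcholine", 70), rep("gaba", 30)))
  calls <- suppressMessages(
    call_neurons(syn, filter_policy(min_presynapses = 30),
                 diag_confusion(0.9)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_neuron_calls(calls, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back)[1:6],
               c("neuron_id", "top_nt", "conf_nt", "margin", "confidence",
                 "n_synapses_used"))
  expect_equal(back$conf_nt, calls$conf_nt)
  expect_equal(back$confidence, calls$confidence, tolerance = 1e-12)

  # empty call set -> header-only file
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_neuron_calls(calls[0, ], p2)
  expect_equal(nrow(readr::read_csv(p2, show_col_types = FALSE)), 0)

  # two identical runs produce byte-identical files
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_neuron_calls(suppressMessages(
    call_neurons(syn, filter_policy(min_presynapses = 30),
                 diag_confusion(0.9))), p3)
  expect_identical(readLines(path), readLines(p3))
})

test_that("the pipeline is a pure function of tables, config and seed", {
  cfg <- sim_config(seed = 7, n_hemilineages = 2, m_true = c(1, 2),
                    n_neurons = 8, synapse_median = 80)
  st <- simulate_study(cfg)
  rc <- run_config(policy = filter_policy(min_presynapses = 30),
                   confusion_synapse = diag_confusion(0.9),
                   confusion_neuron = diag_confusion(0.9, level = "neuron"),
                   min_neurons = 5, seed = 3)
  r1 <- suppressMessages(run_pipeline(st$synapses, st$neurons, rc))
  r2 <- suppressMessages(run_pipeline(st$synapses, st$neurons, rc))
  expect_equal(r1$neuron_calls, r2$neuron_calls)
  expect_equal(r1$bayes, r2$bayes)

  # stricter presynapse floor yields at least as many uncertain calls
  rc30 <- run_config(policy = filter_policy(min_presynapses = 30),
                     confusion_synapse = diag_confusion(0.9))
  rc100 <- run_config(policy = filter_policy(min_presynapses = 100),
                      confusion_synapse = diag_confusion(0.9))
  u30 <- sum(suppressMessages(
    run_pipeline(st$synapses, st$neurons, rc30))$neuron_calls$conf_nt == "uncertain")
  u100 <- sum(suppressMessages(
    run_pipeline(st$synapses, st$neurons, rc100))$neuron_calls$conf_nt == "uncertain")
  expect_gte(u100, u30)
})
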