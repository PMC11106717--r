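test_that("filtering applies strict/inclusive bounds and ledgers removals", {
  res <- suppressMessages(filter_synapses(filter_fixture(), filter_policy()))
  expect_equal(nrow(res$synapses), 7)
  rep <- stats::setNames(res$report$removed, res$report$rule)
  expect_equal(unname(rep["detection_score"]), 1) # score == 50 removed: strict >
  expect_equal(unname(rep["compartment"]), 1)
  expect_equal(unname(rep["dist_soma"]), 1)
  expect_equal(unname(rep["dist_primary_dendrite"]), 0)
  expect_equal(unname(rep["retained"]), 7)

  # boundary values on the inclusive distance rules survive
  tb <- toy_synapses("gaba")
  tb$dist_soma_um <- 15; tb$dist_primary_dendrite_um <- 0.1
  expect_equal(nrow(suppressMessages(filter_synapses(tb))$synapses), 1)

  # rows lacking optional columns pass those checks unless strict
  tb2 <- toy_synapses("gaba")[c("synapse_id", "neuron_id", "pred_label",
                                "detection_score")]
  expect_equal(nrow(suppressMessages(filter_synapses(tb2))$synapses), 1)
  expect_equal(nrow(suppressMessages(
    filter_synapses(tb2, filter_policy(strict = TRUE)))$synapses), 0)
})

test_that("vote fractions count labels on the simplex, order-invariantly", {
  v <- vote_fractions(c(rep("acetylcholine", 60), rep("gaba", 40)))
  expect_equal(unname(v[c("gaba", "acetylcholine")]), c(0.4, 0.6))
  expect_equal(sum(v), 1)
  expect_equal(unname(vote_fractions(rep("dopamine", 5))["dopamine"]), 1)
  set.seed(5)
  lab <- sample(labs, 200, replace = TRUE)
  expect_equal(vote_fractions(lab), vote_fractions(sample(lab)))
  expect_error(vote_fractions(character(0)), "zero synapses")
})

test_that("neuron calls apply the margin, count and tie rules", {
  pol <- filter_policy(min_presynapses = 100)
  mk <- function(n1, n2) c(rep("acetylcholine", n1), rep("gaba", n2))
  expect_equal(neuron_call(mk(52, 48), pol)$winner, "uncertain") # margin 0.04
  expect_equal(neuron_call(mk(60, 40), pol)$winner, "acetylcholine")
  expect_equal(neuron_call(mk(60, 40), pol)$margin, 0.2)
  expect_equal(neuron_call(mk(60, 39), pol)$winner, "uncertain") # n = 99
  expect_equal(neuron_call(mk(50, 50), pol)$winner, "uncertain") # exact tie
})

test_that("neuron confidence equals the confusion-row average", {
  # row: 0.95 on the diagonal, 0.02 for GABA, remainder spread elsewhere
  M <- diag(6) * 0.95 + (1 - diag(6)) * 0.01
  M[2, ] <- c(0.02, 0.95, rep(0.03 / 4, 4)) # C[acetylcholine, gaba] = 0.02
  C <- confusion_matrix(M)
  expect_equal(neuron_confidence("acetylcholine",
                                 rep("acetylcholine", 10), C), 0.95)
  expect_equal(neuron_confidence("acetylcholine",
                                 c(rep("acetylcholine", 3), "gaba"), C),
               (3 * 0.95 + 0.02) / 4)
  expect_equal(neuron_confidence("gaba", rep("gaba", 4),
                                 identity_confusion()), 1)
  expect_error(neuron_confidence("uncertain", "gaba", C), "uncertain")
})

test_that("confidence matches a brute-force oracle and the vote identity", {
  set.seed(33)
  for (i in 1:1000) {
    C <- random_confusion(level = "synapse")
    n <- sample(1:40, 1)
    lab <- sample(labs, n, replace = TRUE)
    win <- sample(labs, 1)
    got <- neuron_confidence(win, lab, C)
    # oracle: explicit per-synapse loop
    oracle <- 0
    for (s in lab) oracle <- oracle + unclass(C)[win, s]
    expect_equal(got, oracle / n, tolerance = 1e-12)
    # algebraic identity c(n) = sum_y p_n(y) C[winner, y]
    expect_equal(got, sum(vote_fractions(lab) * unclass(C)[win, ]),
                 tolerance = 1e-12)
  }
})

test_that("call_neurons produces both unfiltered and filtered votes", {
  # neuron whose call flips once low-quality synapses are filtered out:
  # 60 ACh on the axon, 90 GABA on the soma (all above detection threshold)
  syn <- dplyr::bind_rows(
    toy_synapses(rep("acetylcholine", 60)),
    {
      tb <- toy_synapses(rep("gaba", 90))
      tb$synapse_id <- paste0("g", tb$synapse_id)
      tb$compartment <- "soma"
      tb
    })
  calls <- suppressMessages(
    call_neurons(syn, filter_policy(min_presynapses = 30),
                 diag_confusion(0.9)))
  expect_equal(calls$top_nt, "gaba")
  expect_equal(calls$conf_nt, "acetylcholine")
  expect_equal(calls$n_synapses_used, 60L)
  expect_equal(calls$confidence, 0.9)
  expect_equal(calls$p_acetylcholine, 1)

  # filtering then voting is invariant to row order
  calls2 <- suppressMessages(
    call_neurons(syn[sample(nrow(syn)), ], filter_policy(min_presynapses = 30),
                 diag_confusion(0.9)))
  expect_equal(calls2$conf_nt, calls$conf_nt)
  expect_equal(calls2$margin, calls$margin)
})

test_that("cell-type calls take the mode, flag conflicts and break ties", {
  calls <- tibble::tibble(
    neuron_id = paste0("n", 1:7),
    conf_nt = c("acetylcholine", "acetylcholine", "gaba",
                "acetylcholine", "acetylcholine",
                "acetylcholine", "gaba"),
    confidence = c(0.9, 0.8, 0.5, 0.9, 0.9, 0.9, 0.6))
  neurons <- tibble::tibble(neuron_id = paste0("n", 1:7),
                            cell_type = c("A", "A", "A", "B", "B", "C", "C"))
  ct <- celltype_calls(calls, neurons)
  ct <- ct[order(ct$cell_type), ]
  expect_equal(ct$winner, c("acetylcholine", "acetylcholine", "uncertain"))
  expect_equal(ct$conflicted, c(TRUE, FALSE, TRUE))

  # all-uncertain type: uncertain winner, not conflicted
  calls$conf_nt <- "uncertain"
  ct2 <- celltype_calls(calls, neurons)
  expect_true(all(ct2$winner == "uncertain"))
  expect_true(all(!ct2$conflicted))
})
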