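# Truncated-normal sampling and CDF by inverse transform. Used only for
# detection-score mixtures; bounds are the dialect's score range.
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.ptnorm <- function(x, mean, sd, lo, hi) {
  (stats::pnorm(x, mean, sd) - stats::pnorm(lo, mean, sd)) /
    (stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd))
}

#' Detection-score mixture parameters
#'
#' Two truncated normals on the dialect's score range: one for valid
#' presynapses, one for false detections. The default means were solved
#' (once, from the truncated-normal CDF) so that the dialect's standard
#' threshold removes 13% of valid and 60% of false detections -- the
#' calibration anchors of the real detection pipeline. Parameters live in
#' the config so the calibration is transparent and overridable.
#'
#' @param dialect `"fafb"` (range 0-250, threshold 50) or `"hemibrain"`
#'   (range 0-1, threshold 0.5).
#' @return A list with `valid` and `false` component parameters plus the
#'   range.
#' @export
detection_mixture <- function(dialect = c("fafb", "hemibrain")) {
  dialect <- match.arg(dialect)
  if (dialect == "fafb") {
    list(valid = list(mean = 98.07219, sd = 45),
         false = list(mean = 30.13987, sd = 40),
         lo = 0, hi = 250)
  } else {
    list(valid = list(mean = 0.7086578, sd = 0.18),
         false = list(mean = 0.4591968, sd = 0.16),
         lo = 0, hi = 1)
  }
}

#' Configuration of a synthetic classifier-output study
#'
#' Parameterizes the generative model the downstream analysis assumes:
#' hemilineages composed of 1-3 true transmitters, neurons obeying Dale's
#' law, per-synapse predictions drawn i.i.d. from the confusion-matrix row
#' of the neuron's true transmitter, false-detection contamination with a
#' detection-score mixture, and heavy-tailed synapse counts per neuron.
#'
#' @param seed Integer RNG seed (mandatory; all randomness flows from it).
#' @param n_hemilineages Number of hemilineages to generate.
#' @param m_true Transmitter count per hemilineage: a single value in 1..3
#'   or a vector recycled over hemilineages.
#' @param n_neurons Neurons per hemilineage (single value or vector).
#' @param proportions Neuron shares of each of the `m_true` transmitters
#'   within a hemilineage (default: balanced). A list per hemilineage or a
#'   single numeric vector.
#' @param first_born_deviant If `TRUE`, one neuron per hemilineage gets a
#'   transmitter outside the hemilineage's set (the "stray first-born"
#'   pattern).
#' @param synapse_median,synapse_sdlog Lognormal synapse-count law per
#'   neuron, parameterized by its median (default 202, the FAFB filtered
#'   median) and log-scale SD (default 0.8, a heavy right tail).
#' @param C_syn Synapse-level confusion matrix used to sample predictions
#'   (default: diagonal 0.9, off-diagonal 0.02).
#' @param false_detection_rate Fraction of detected presynapses that are
#'   erroneous (default 0.32).
#' @param contamination One of `"uniform"` (false detections carry labels
#'   uniform over the six classes) or `"octopamine_skewed"` (false
#'   detections attracted to octopamine).
#' @param compartment_props Named compartment shares (default: axon 0.76,
#'   dendrite 0.19, soma 0.02, primary_dendrite 0.02, cell_body_fiber 0.01).
#' @param mixture Detection-score mixture (default [detection_mixture()]
#'   for the dialect).
#' @param dialect Detection-score dialect.
#' @param homolog_pairs If `TRUE`, each neuron gets a mirror homolog on the
#'   other hemisphere with independently resampled synapses.
#' @return A list with class `"nt_sim_config"`.
#' @export
sim_config <- function(seed,
                       n_hemilineages = 10L,
                       m_true = 1L,
                       n_neurons = 30L,
                       proportions = NULL,
                       first_born_deviant = FALSE,
                       synapse_median = 202,
                       synapse_sdlog = 0.8,
                       C_syn = NULL,
                       false_detection_rate = 0.32,
                       contamination = c("uniform", "octopamine_skewed"),
                       compartment_props = c(axon = 0.76, dendrite = 0.19,
                                             soma = 0.02,
                                             primary_dendrite = 0.02,
                                             cell_body_fiber = 0.01),
                       mixture = NULL,
                       dialect = c("fafb", "hemibrain"),
                       homolog_pairs = FALSE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  dialect <- match.arg(dialect)
  contamination <- match.arg(contamination)
  if (is.null(C_syn)) {
    C_syn <- confusion_matrix(diag(6) * 0.9 + (1 - diag(6)) * 0.02,
                              level = "synapse")
  }
  if (is.null(mixture)) mixture <- detection_mixture(dialect)
  if (false_detection_rate < 0 || false_detection_rate >= 1) {
    stop("false_detection_rate must be in [0, 1)", call. = FALSE)
  }
  if (abs(sum(compartment_props) - 1) > 1e-8) {
    stop("compartment_props must sum to 1", call. = FALSE)
  }
  m_true <- rep_len(as.integer(m_true), n_hemilineages)
  if (any(m_true < 1 | m_true > 3)) {
    stop("m_true must be in 1..3", call. = FALSE)
  }
  n_neurons <- rep_len(as.integer(n_neurons), n_hemilineages)
  if (any(m_true > n_neurons)) {
    stop("m_true cannot exceed n_neurons", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_hemilineages = as.integer(n_hemilineages),
                 m_true = m_true, n_neurons = n_neurons,
                 proportions = proportions,
                 first_born_deviant = first_born_deviant,
                 synapse_median = synapse_median, synapse_sdlog = synapse_sdlog,
                 C_syn = C_syn, false_detection_rate = false_detection_rate,
                 contamination = contamination,
                 compartment_props = compartment_props,
                 mixture = mixture, dialect = dialect,
                 homolog_pairs = homolog_pairs),
            class = "nt_sim_config")
}

#' Sample per-synapse predicted labels for a neuron
#'
#' i.i.d. categorical draws from the confusion-matrix row of the neuron's
#' true transmitter -- the sampling assumption underlying the whole
#' downstream probability model.
#'
#' @param true_label The neuron's true transmitter.
#' @param n Number of presynapses.
#' @param C_syn Synapse-level `nt_confusion` matrix.
#' @return Character vector of `n` predicted labels.
#' @export
sample_synapse_labels <- function(true_label, n, C_syn) {
  .check_labels(true_label)
  sample(transmitter_labels(), n, replace = TRUE,
         prob = unclass(C_syn)[true_label, ])
}

#' Sample detection scores for valid and false presynapses
#'
#' Valid presynapses draw from the high-score truncated normal, false
#' detections from the low-score one (see [detection_mixture()]).
#'
#' @param valid Logical vector: is each presynapse a true detection?
#' @param mixture A [detection_mixture()] parameter list.
#' @return Numeric scores, one per input flag.
#' @export
sample_detection_scores <- function(valid, mixture = detection_mixture()) {
  out <- numeric(length(valid))
  nv <- sum(valid)
  out[valid] <- .rtnorm(nv, mixture$valid$mean, mixture$valid$sd,
                        mixture$lo, mixture$hi)
  out[!valid] <- .rtnorm(length(valid) - nv, mixture$false$mean,
                         mixture$false$sd, mixture$lo, mixture$hi)
  out
}

# contamination label distribution
.contamination_probs <- function(kind) {
  if (kind == "uniform") {
    rep(1 / 6, 6)
  } else { # octopamine_skewed: false detections over-attracted to octopamine
    p <- rep(0.57 / 5, 6)
    p[match("octopamine", transmitter_labels())] <- 0.43
    p
  }
}

#' Simulate a full synthetic study
#'
#' Generates hemilineages, neurons and per-synapse classifier outputs with
#' the statistical structure the analysis pipeline assumes, in
#' schema-conformant tables that pass [validate_synapse_table()] /
#' [validate_neuron_table()]. Valid presynapse labels follow the neuron's
#' confusion-matrix row; false detections (a configurable share of all
#' detected rows) carry contamination labels and low detection scores.
#' Compartments and distance fields are sampled so that every filter rule
#' removes a small realistic share of rows.
#'
#' @param config An [sim_config()] object.
#' @return A list: `synapses`, `neurons` (validated tibbles) and `truth`
#'   (per-neuron true transmitters, per-synapse validity flags,
#'   per-hemilineage transmitter sets), plus the echoed `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "nt_sim_config"))
  set.seed(config$seed)
  labs <- transmitter_labels()
  comp_names <- names(config$compartment_props)
  contam_p <- .contamination_probs(config$contamination)
  meanlog <- log(config$synapse_median)

  neuron_rows <- list(); syn_rows <- list(); truth_rows <- list()
  hl_rows <- list()
  syn_counter <- 0L

  make_neuron_synapses <- function(nid, true_nt) {
    n_valid <- max(1L, round(stats::rlnorm(1, meanlog, config$synapse_sdlog)))
    r <- config$false_detection_rate
    n_false <- if (r > 0) stats::rpois(1, n_valid * r / (1 - r)) else 0L
    n_tot <- n_valid + n_false
    valid <- rep(c(TRUE, FALSE), c(n_valid, n_false))
    lab <- character(n_tot)
    lab[valid] <- sample_synapse_labels(true_nt, n_valid, config$C_syn)
    if (n_false > 0) {
      lab[!valid] <- sample(labs, n_false, replace = TRUE, prob = contam_p)
    }
    ids <- syn_counter + seq_len(n_tot)
    syn_counter <<- syn_counter + n_tot
    tibble::tibble(
      synapse_id = sprintf("s%08d", ids),
      neuron_id = nid,
      pred_label = lab,
      detection_score = sample_detection_scores(valid, config$mixture),
      compartment = sample(comp_names, n_tot, replace = TRUE,
                           prob = config$compartment_props),
      dist_soma_um = stats::rgamma(n_tot, shape = 4, scale = 20),
      dist_primary_dendrite_um = stats::rgamma(n_tot, shape = 2, scale = 2),
      .valid = valid)
  }

  for (h in seq_len(config$n_hemilineages)) {
    hid <- sprintf("hl%03d", h)
    m <- config$m_true[h]
    nn <- config$n_neurons[h]
    nts <- sample(labs, m)
    props <- config$proportions
    if (is.list(props)) props <- props[[h]]
    if (is.null(props)) props <- rep(1 / m, m)
    if (length(props) != m || abs(sum(props) - 1) > 1e-8) {
      stop("proportions must have length m_true and sum to 1", call. = FALSE)
    }
    # deterministic rounding of shares into neuron counts
    cnt <- diff(c(0, round(cumsum(props) * nn)))
    true_nt <- rep(nts, cnt)
    if (config$first_born_deviant) {
      true_nt[1] <- sample(setdiff(labs, nts), 1)
    }
    sides <- if (config$homolog_pairs) c("right", "left") else "right"
    for (side in sides) {
      tag <- if (side == "right") "r" else "l"
      nids <- sprintf("%s_%s_n%03d", hid, tag, seq_len(nn))
      homolog <- if (config$homolog_pairs) {
        sprintf("%s_%s_n%03d", hid, if (tag == "r") "l" else "r", seq_len(nn))
      } else NA_character_
      neuron_rows[[length(neuron_rows) + 1]] <- tibble::tibble(
        neuron_id = nids, hemilineage = hid,
        cell_type = sprintf("%s_t%03d", hid, seq_len(nn)),
        side = side, dataset = "sim", homolog_id = homolog)
      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        neuron_id = nids, true_nt = true_nt)
      for (i in seq_len(nn)) {
        syn_rows[[length(syn_rows) + 1]] <-
          make_neuron_synapses(nids[i], true_nt[i])
      }
    }
    hl_rows[[length(hl_rows) + 1]] <- tibble::tibble(
      hemilineage = hid, m_true = m,
      transmitters = paste(sort(nts), collapse = ";"))
  }

  synapses <- dplyr::bind_rows(syn_rows)
  syn_truth <- synapses[c("synapse_id", ".valid")]
  names(syn_truth) <- c("synapse_id", "valid")
  synapses$.valid <- NULL
  neurons <- dplyr::bind_rows(neuron_rows)
  list(synapses = validate_synapse_table(synapses),
       neurons = validate_neuron_table(neurons),
       truth = list(neurons = dplyr::bind_rows(truth_rows),
                    synapses = syn_truth,
                    hemilineages = dplyr::bind_rows(hl_rows)),
       config = config)
}
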