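#' Base-6 Shannon entropy of a distribution over the six transmitters
#'
#' Normalized so that a degenerate distribution scores 0 and the uniform
#' distribution over the six classes scores 1; `0 * log 0` is taken as 0.
#'
#' @param p Numeric vector of 6 probabilities (re-normalized if needed).
#' @return Scalar entropy in `[0, 1]`.
#' @export
entropy6 <- function(p) {
  if (length(p) != 6 || any(p < 0) || any(!is.finite(p))) {
    stop("p must be 6 finite non-negative values", call. = FALSE)
  }
  s <- sum(p)
  if (s <= 0) stop("p has zero total mass", call. = FALSE)
  p <- p / s
  nz <- p > 0
  # + 0 normalizes the IEEE -0 that arises for degenerate distributions
  -sum(p[nz] * log(p[nz], base = 6)) + 0
}

#' Neuron-level entropy of a hemilineage
#'
#' Base-6 Shannon entropy of the empirical distribution of neuron-level
#' winning transmitters within a hemilineage. Zero means every member
#' neuron got the same call; one means all six transmitters are equally
#' common. `"uncertain"` calls are excluded (they are not part of the
#' six-class label space); their count is reported via attribute
#' `"n_excluded"`.
#'
#' @param winners Character vector of neuron-level calls.
#' @return Scalar entropy in `[0, 1]`.
#' @export
neuron_level_entropy <- function(winners) {
  .check_labels(winners, allow_uncertain = TRUE)
  usable <- winners[!is.na(winners) & winners != "uncertain"]
  if (length(usable) == 0) {
    stop("no neurons with a non-uncertain call; entropy undefined",
         call. = FALSE)
  }
  p <- as.vector(table(factor(usable, levels = transmitter_labels())))
  structure(entropy6(p / length(usable)),
            n_excluded = length(winners) - length(usable))
}

#' Synapse-level entropy of one neuron
#'
#' Base-6 entropy of the per-synapse predicted-label frequencies of a
#' single neuron: zero for homogeneous predictions, one when all six
#' classes are equally frequent among its presynapses.
#'
#' @param labels Per-synapse predicted labels of one neuron.
#' @return Scalar entropy in `[0, 1]`.
#' @export
neuron_synapse_entropy <- function(labels) {
  if (length(labels) == 0) {
    stop("no synapses; entropy undefined", call. = FALSE)
  }
  .check_labels(labels)
  p <- as.vector(table(factor(labels, levels = transmitter_labels())))
  entropy6(p / length(labels))
}

#' Mean synapse-level entropy of a hemilineage
#'
#' Unweighted mean of the per-neuron synapse entropies over member
#' neurons, so duplicating a neuron leaves it unchanged.
#'
#' @param per_neuron_entropies Numeric vector of per-neuron synapse
#'   entropies (from [neuron_synapse_entropy()]).
#' @return Scalar entropy in `[0, 1]`.
#' @export
hemilineage_synapse_entropy <- function(per_neuron_entropies) {
  if (length(per_neuron_entropies) == 0) {
    stop("no neurons; entropy undefined", call. = FALSE)
  }
  mean(per_neuron_entropies)
}

#' Entropy diagnostics for every hemilineage
#'
#' Joins neuron calls and filtered synapses to hemilineage membership and
#' computes, per hemilineage, the neuron-level entropy of winning calls and
#' the mean per-neuron synapse entropy. Eligibility follows the strict
#' population rule: more than `min_neurons` member neurons, each counted
#' neuron having more than `min_presynapses` presynapses; neurons below the
#' presynapse floor are not counted.
#'
#' @param calls Neuron-call tibble (uses `conf_nt` and `n_synapses_used`).
#' @param synapses Filtered synapse table (for per-neuron label frequencies).
#' @param neurons Neuron table with a `hemilineage` column.
#' @param min_neurons,min_presynapses Strict eligibility thresholds
#'   (defaults: more than 10 neurons, more than 30 presynapses each).
#' @return A tibble: hemilineage, n_neurons, n_uncertain, H_neuron,
#'   H_synapse_mean, eligible.
#' @export
hemilineage_entropy <- function(calls, synapses, neurons,
                                min_neurons = 10L, min_presynapses = 30L) {
  if (!"hemilineage" %in% names(neurons)) {
    stop("neuron table has no hemilineage column", call. = FALSE)
  }
  df <- dplyr::inner_join(calls,
                          neurons[c("neuron_id", "hemilineage")],
                          by = "neuron_id") |>
    dplyr::filter(!is.na(.data$hemilineage),
                  .data$n_synapses_used > min_presynapses)
  syn_h <- synapses |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(H_syn = neuron_synapse_entropy(.data$pred_label),
                     .groups = "drop")
  df <- dplyr::left_join(df, syn_h, by = "neuron_id")
  df |>
    dplyr::group_by(.data$hemilineage) |>
    dplyr::summarise(
      n_neurons = dplyr::n(),
      n_uncertain = sum(.data$conf_nt == "uncertain"),
      H_neuron = if (any(.data$conf_nt != "uncertain"))
        as.numeric(neuron_level_entropy(.data$conf_nt)) else NA_real_,
      H_synapse_mean = hemilineage_synapse_entropy(.data$H_syn),
      .groups = "drop") |>
    dplyr::mutate(eligible = .data$n_neurons > min_neurons)
}

#' Quartile-based entropy quadrants across hemilineages
#'
#' Computes the empirical 25th and 75th percentiles of the neuron-level and
#' mean synapse-level entropies over hemilineages (linear interpolation
#' between order statistics, i.e. `stats::quantile()` type 7, so boundaries
#' are reproducible) and labels each hemilineage by where it falls:
#'
#' * `neuron_segregated` -- `H_neuron >= q75(H_neuron)` and
#'   `H_synapse_mean <= q25(H_synapse_mean)`: transmitters segregate cleanly
#'   between neurons while individual neurons look unimodal.
#' * `synapse_multimodal` -- `H_synapse_mean >= q75`: multimodality already
#'   within single neurons' synapses.
#' * `homogeneous` -- both entropies at or below their q25.
#' * `intermediate` -- everything else.
#'
#' Labels are assigned in the order above (first match wins).
#'
#' @param entropies Tibble from [hemilineage_entropy()]; only eligible rows
#'   with finite entropies are used for the quartiles.
#' @return A list: `quartiles` (named vector q25/q75 of both entropies) and
#'   `table` (the input with a `quadrant` column).
#' @export
entropy_quadrants <- function(entropies) {
  use <- entropies$eligible & is.finite(entropies$H_neuron) &
    is.finite(entropies$H_synapse_mean)
  if (sum(use) < 4) {
    stop("need at least 4 eligible hemilineages for quartiles", call. = FALSE)
  }
  qN <- stats::quantile(entropies$H_neuron[use], c(0.25, 0.75),
                        type = 7, names = FALSE)
  qS <- stats::quantile(entropies$H_synapse_mean[use], c(0.25, 0.75),
                        type = 7, names = FALSE)
  quad <- function(hn, hs) {
    if (!is.finite(hn) || !is.finite(hs)) return(NA_character_)
    if (hn >= qN[2] && hs <= qS[1]) return("neuron_segregated")
    if (hs >= qS[2]) return("synapse_multimodal")
    if (hn <= qN[1] && hs <= qS[1]) return("homogeneous")
    "intermediate"
  }
  entropies$quadrant <- mapply(quad, entropies$H_neuron,
                               entropies$H_synapse_mean)
  list(quartiles = c(q25_H_neuron = qN[1], q75_H_neuron = qN[2],
                     q25_H_synapse = qS[1], q75_H_synapse = qS[2]),
       table = entropies)
}
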