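#' Agreement matrix between matched homolog calls
#'
#' Counts each homolog pair's (call_a, call_b) combination on a 7x7 grid
#' (six transmitters plus `"uncertain"`), together with a row-normalized
#' view (rows with no pairs stay zero).
#'
#' @param pairs Tibble of homolog pairs: `neuron_a`, `neuron_b`, and
#'   optionally `relation` (`left_right` or `cross_dataset`).
#' @param calls Neuron-call tibble; the `conf_nt` column is compared.
#' @return A list: `counts` (7x7 integer matrix), `row_normalized`,
#'   `n_pairs`.
#' @export
pair_agreement_matrix <- function(pairs, calls) {
  lv <- c(transmitter_labels(), "uncertain")
  a <- calls$conf_nt[match(pairs$neuron_a, calls$neuron_id)]
  b <- calls$conf_nt[match(pairs$neuron_b, calls$neuron_id)]
  miss <- is.na(a) | is.na(b)
  if (any(miss)) {
    ids <- unique(c(pairs$neuron_a[is.na(a)], pairs$neuron_b[is.na(b)]))
    stop("no call for neuron id(s): ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(a, levels = lv), factor(b, levels = lv))
  counts <- unclass(counts)
  dimnames(counts) <- list(call_a = lv, call_b = lv)
  rs <- rowSums(counts)
  norm <- counts / ifelse(rs > 0, rs, 1)
  list(counts = counts, row_normalized = norm, n_pairs = nrow(pairs))
}

#' Kullback-Leibler divergence between two six-class distributions
#'
#' `KL(p || q)` in nats. Classes where `p` is zero contribute nothing; if
#' `q` lacks support on a class where `p` has mass, both distributions are
#' mixed with a small uniform pseudo-mass so the divergence stays finite,
#' and the result is flagged via attribute `"smoothed"`.
#'
#' @param p,q Numeric vectors of 6 probabilities (re-normalized if needed).
#' @param pseudo Pseudo-mass per class used when smoothing is required.
#' @return Non-negative scalar, attribute `"smoothed"` logical.
#' @export
kl_divergence <- function(p, q, pseudo = 1e-6) {
  stopifnot(length(p) == 6, length(q) == 6)
  p <- p / sum(p); q <- q / sum(q)
  smoothed <- FALSE
  if (any(p > 0 & q == 0)) {
    smoothed <- TRUE
    p <- (p + pseudo) / (1 + 6 * pseudo)
    q <- (q + pseudo) / (1 + 6 * pseudo)
  }
  nz <- p > 0
  structure(sum(p[nz] * log(p[nz] / q[nz])), smoothed = smoothed)
}

#' @rdname kl_divergence
#' @details `kl_symmetric()` is the symmetrized variant
#'   `(KL(p||q) + KL(q||p)) / 2`, the default reported in pair tables since
#'   homolog pairs have no privileged direction.
#' @export
kl_symmetric <- function(p, q, pseudo = 1e-6) {
  a <- kl_divergence(p, q, pseudo)
  b <- kl_divergence(q, p, pseudo)
  structure((as.numeric(a) + as.numeric(b)) / 2,
            smoothed = attr(a, "smoothed") || attr(b, "smoothed"))
}

#' Six-class prediction distribution of one neuron
#'
#' The neuron's synapse-level transmitter distribution used for similarity
#' scoring: the mean of the per-synapse score vectors when score columns
#' are present, otherwise the per-synapse label frequencies with a
#' pseudo-count of 1 per class.
#'
#' @param synapses Synapse table rows of one neuron.
#' @return Named numeric vector of 6 probabilities.
#' @export
neuron_score_distribution <- function(synapses) {
  if (nrow(synapses) == 0) stop("neuron has no synapses", call. = FALSE)
  if (all(.score_cols() %in% names(synapses))) {
    p <- colMeans(as.matrix(synapses[.score_cols()]))
    names(p) <- transmitter_labels()
    return(p / sum(p))
  }
  n <- table(factor(synapses$pred_label, levels = transmitter_labels()))
  p <- (as.vector(n) + 1) / (nrow(synapses) + 6)
  stats::setNames(p, transmitter_labels())
}

#' Per-pair homolog consistency table
#'
#' One row per homolog pair with both members' calls, a match flag,
#' confidences, and KL similarity of their synapse-level prediction
#' distributions (directed `KL(a||b)` and symmetrized).
#'
#' @inheritParams pair_agreement_matrix
#' @param synapses Filtered synapse table (for prediction distributions).
#' @return A tibble: neuron_a, neuron_b, relation, call_a, call_b, match,
#'   confidence_a, confidence_b, kl, kl_sym.
#' @export
pair_consistency <- function(pairs, calls, synapses) {
  if (!"relation" %in% names(pairs)) pairs$relation <- "left_right"
  ia <- match(pairs$neuron_a, calls$neuron_id)
  ib <- match(pairs$neuron_b, calls$neuron_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("no call for neuron id(s): ",
         paste(utils::head(c(pairs$neuron_a[is.na(ia)],
                             pairs$neuron_b[is.na(ib)]), 10), collapse = ", "),
         call. = FALSE)
  }
  dist_of <- function(id) {
    neuron_score_distribution(synapses[synapses$neuron_id == id, , drop = FALSE])
  }
  kls <- t(mapply(function(a, b) {
    pa <- dist_of(a); pb <- dist_of(b)
    c(kl = as.numeric(kl_divergence(pa, pb)),
      kl_sym = as.numeric(kl_symmetric(pa, pb)))
  }, pairs$neuron_a, pairs$neuron_b))
  tibble::tibble(
    neuron_a = pairs$neuron_a, neuron_b = pairs$neuron_b,
    relation = pairs$relation,
    call_a = calls$conf_nt[ia], call_b = calls$conf_nt[ib],
    match = calls$conf_nt[ia] == calls$conf_nt[ib],
    confidence_a = calls$confidence[ia], confidence_b = calls$confidence[ib],
    kl = kls[, "kl"], kl_sym = kls[, "kl_sym"])
}

#' Match/mismatch summary per homolog relation
#'
#' Counts matched and conflicting pairs per relation and summarizes the
#' pair-mean confidence within each group (conflicting homolog pairs are
#' expected to have systematically lower confidence). The counts are also
#' formatted as a `"matches:mismatches"` string.
#'
#' @param pair_table Output of [pair_consistency()].
#' @return A tibble: relation, n_match, n_mismatch, ratio, mean/sd
#'   confidence per group.
#' @export
mismatch_summary <- function(pair_table) {
  pair_table$pair_conf <- rowMeans(
    cbind(pair_table$confidence_a, pair_table$confidence_b), na.rm = TRUE)
  out <- pair_table |>
    dplyr::group_by(.data$relation) |>
    dplyr::summarise(
      n_match = sum(.data$match),
      n_mismatch = sum(!.data$match),
      ratio = paste0(sum(.data$match), ":", sum(!.data$match)),
      mean_conf_match = mean(.data$pair_conf[.data$match]),
      sd_conf_match = stats::sd(.data$pair_conf[.data$match]),
      mean_conf_mismatch = mean(.data$pair_conf[!.data$match]),
      sd_conf_mismatch = stats::sd(.data$pair_conf[!.data$match]),
      .groups = "drop")
  if (any(out$n_mismatch == 0)) {
    message("mismatch_summary: some relation(s) have no mismatched pairs")
  }
  out
}
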