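#' Presynapse filter policy
#'
#' Encodes the quality filters applied to automatically detected
#' presynapses before voting. Detected presynapses are kept when the
#' detection score is strictly above the threshold ("above" is exclusive),
#' the compartment is axonic or dendritic, and the site is at least 15 um
#' from the soma and at least 0.1 um from the primary dendrite (inclusive
#' bounds). Neurons need at least `min_presynapses` surviving presynapses
#' for a call; rows lacking an optional compartment/distance column pass
#' those specific checks unless `strict = TRUE`.
#'
#' @param detection_threshold Detection-score cutoff; defaults to 50 for the
#'   FAFB cleft-score dialect and 0.5 for the HemiBrain confidence dialect.
#' @param allowed_compartments Compartments retained (default axon, dendrite).
#' @param min_dist_soma_um Minimum distance from the cell body, micrometers.
#' @param min_dist_primary_dendrite_um Minimum distance from the primary
#'   dendrite, micrometers.
#' @param min_presynapses Minimum surviving presynapses per neuron for a
#'   non-uncertain call (default 100; use 30 for test-set-style voting).
#' @param strict If `TRUE`, rows missing optional filter columns are removed
#'   rather than passed.
#' @param dialect Convenience switch setting the default threshold.
#' @return A list with class `"nt_filter_policy"`.
#' @export
filter_policy <- function(detection_threshold = NULL,
                          allowed_compartments = c("axon", "dendrite"),
                          min_dist_soma_um = 15,
                          min_dist_primary_dendrite_um = 0.1,
                          min_presynapses = 100L,
                          strict = FALSE,
                          dialect = c("fafb", "hemibrain")) {
  dialect <- match.arg(dialect)
  if (is.null(detection_threshold)) {
    detection_threshold <- if (dialect == "fafb") 50 else 0.5
  }
  vals <- c(detection_threshold, min_dist_soma_um,
            min_dist_primary_dendrite_um, min_presynapses)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("policy thresholds must be finite and non-negative", call. = FALSE)
  }
  structure(list(detection_threshold = detection_threshold,
                 allowed_compartments = allowed_compartments,
                 min_dist_soma_um = min_dist_soma_um,
                 min_dist_primary_dendrite_um = min_dist_primary_dendrite_um,
                 min_presynapses = as.integer(min_presynapses),
                 strict = strict, dialect = dialect),
            class = "nt_filter_policy")
}

#' Filter presynapses by detection score, compartment and distance
#'
#' Applies the policy rules in sequence and reports how many rows each rule
#' removed (each row is attributed to the first rule it violates). An empty
#' result is allowed.
#'
#' @param synapses A validated synapse table.
#' @param policy A [filter_policy()].
#' @return A list: `synapses` (surviving rows) and `report`, a tibble of
#'   per-rule removal counts.
#' @export
filter_synapses <- function(synapses, policy = filter_policy()) {
  n0 <- nrow(synapses)
  pass_opt <- function(col, test) {
    if (!col %in% names(synapses)) {
      rep(!policy$strict, n0)
    } else {
      ok <- test(synapses[[col]])
      ok[is.na(ok)] <- !policy$strict
      ok
    }
  }
  keep_score <- synapses$detection_score > policy$detection_threshold
  keep_comp <- pass_opt("compartment",
                        function(x) x %in% policy$allowed_compartments)
  keep_soma <- pass_opt("dist_soma_um",
                        function(x) x >= policy$min_dist_soma_um)
  keep_pd <- pass_opt("dist_primary_dendrite_um",
                      function(x) x >= policy$min_dist_primary_dendrite_um)
  rules <- list(detection_score = keep_score, compartment = keep_comp,
                dist_soma = keep_soma, dist_primary_dendrite = keep_pd)
  # attribute each removed row to the first rule it violates
  alive <- rep(TRUE, n0)
  removed <- integer(length(rules))
  names(removed) <- names(rules)
  for (i in seq_along(rules)) {
    hit <- alive & !rules[[i]]
    removed[i] <- sum(hit)
    alive <- alive & rules[[i]]
  }
  report <- tibble::tibble(rule = names(removed),
                           removed = unname(removed))
  report <- dplyr::bind_rows(report,
                             tibble::tibble(rule = "retained",
                                            removed = sum(alive)))
  message("filter_synapses: ", n0, " rows in, ", sum(alive), " retained (",
          paste(sprintf("%s=%d", names(removed), removed), collapse = ", "), ")")
  list(synapses = synapses[alive, , drop = FALSE], report = report)
}

#' Empirical vote fractions of one neuron's presynapse predictions
#'
#' The fraction of a neuron's presynapses predicted as each transmitter:
#' a point on the 6-simplex, in canonical label order. Order of rows is
#' irrelevant.
#'
#' @param labels Character vector of per-synapse predicted labels.
#' @return Named numeric vector of length 6 summing to 1.
#' @export
vote_fractions <- function(labels) {
  if (length(labels) == 0) {
    stop("vote fractions are undefined for zero synapses", call. = FALSE)
  }
  .check_labels(labels)
  tab <- table(factor(labels, levels = transmitter_labels()))
  as.vector(tab / length(labels)) |> stats::setNames(transmitter_labels())
}

#' Majority-vote transmitter call for one neuron
#'
#' Winner is the argmax vote fraction; the call is `"uncertain"` when the
#' margin between the top and second vote fractions is below 0.10 (ten
#' percentage points of presynapse share), when fewer than
#' `policy$min_presynapses` presynapses survive filtering, or on an exact
#' tie.
#'
#' @param labels Per-synapse predicted labels of one neuron (post filtering).
#' @param policy A [filter_policy()] supplying `min_presynapses`.
#' @return A list: `winner`, `margin`, `fractions`, `n_synapses_used`.
#' @export
neuron_call <- function(labels, policy = filter_policy()) {
  n <- length(labels)
  if (n == 0) {
    return(list(winner = "uncertain", margin = NA_real_,
                fractions = stats::setNames(rep(NA_real_, 6), transmitter_labels()),
                n_synapses_used = 0L))
  }
  p <- vote_fractions(labels)
  ord <- order(p, decreasing = TRUE)
  margin <- p[ord[1]] - p[ord[2]]
  winner <- names(p)[ord[1]]
  if (margin < 0.10 - 1e-12 || n < policy$min_presynapses || margin == 0) {
    winner <- "uncertain"
  }
  list(winner = winner, margin = unname(margin), fractions = p,
       n_synapses_used = n)
}

#' Confusion-weighted confidence of a neuron-level call
#'
#' The mean confusion-matrix entry, in the winning transmitter's row, over
#' the neuron's per-synapse predictions: synapses predicted as the winner
#' contribute the row's diagonal entry, synapses predicted otherwise
#' contribute the corresponding misclassification probability. Bounded by
#' the row's min and max entries.
#'
#' @param winner The neuron's winning transmitter (not `"uncertain"`).
#' @param labels Per-synapse predicted labels used for the vote.
#' @param C A synapse-level `nt_confusion` matrix.
#' @return Scalar confidence in `[0, 1]`.
#' @export
neuron_confidence <- function(winner, labels, C) {
  if (identical(winner, "uncertain") || is.na(winner)) {
    stop("confidence is undefined for an uncertain call", call. = FALSE)
  }
  .check_labels(winner)
  .check_labels(labels)
  if (length(labels) == 0) stop("no synapses", call. = FALSE)
  mean(unclass(C)[winner, labels])
}

#' Neuron-level calls for a whole synapse table
#'
#' Produces one row per neuron with both the unfiltered-vote call
#' (`top_nt`: detection threshold only, no compartment/distance filtering,
#' no minimum count) and the fully filtered call (`conf_nt`), the filtered
#' vote margin and fractions, the confusion-weighted confidence (when a
#' synapse-level matrix is supplied), and the surviving synapse count.
#'
#' @param synapses A validated synapse table.
#' @param policy A [filter_policy()].
#' @param confusion Optional synapse-level `nt_confusion` matrix for
#'   confidence scores.
#' @return A tibble of neuron calls; attribute `"filter_report"` carries the
#'   per-rule removal counts.
#' @export
call_neurons <- function(synapses, policy = filter_policy(), confusion = NULL) {
  # unfiltered votes: detection threshold only
  thr_only <- filter_policy(detection_threshold = policy$detection_threshold,
                            allowed_compartments = c("axon", "dendrite", "soma",
                                                     "primary_dendrite",
                                                     "cell_body_fiber", "unknown"),
                            min_dist_soma_um = 0,
                            min_dist_primary_dendrite_um = 0,
                            min_presynapses = 1L,
                            dialect = policy$dialect)
  unf <- suppressMessages(filter_synapses(synapses, thr_only)$synapses)
  flt <- filter_synapses(synapses, policy)
  top <- unf |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(top_nt = neuron_call(.data$pred_label, thr_only)$winner,
                     .groups = "drop")
  ids <- unique(synapses$neuron_id)
  labs_by_id <- split(flt$synapses$pred_label, flt$synapses$neuron_id)
  conf_rows <- lapply(ids, function(id) {
    labs <- labs_by_id[[id]] %||% character(0)
    cl <- neuron_call(labs, policy)
    conf <- NA_real_
    if (!is.null(confusion) && cl$winner != "uncertain") {
      conf <- neuron_confidence(cl$winner, labs, confusion)
    }
    tibble::tibble(neuron_id = id, conf_nt = cl$winner, margin = cl$margin,
                   confidence = conf, n_synapses_used = cl$n_synapses_used,
                   !!!stats::setNames(as.list(cl$fractions),
                                      paste0("p_", names(cl$fractions))))
  })
  calls <- dplyr::bind_rows(conf_rows) |>
    dplyr::left_join(top, by = "neuron_id") |>
    dplyr::relocate("top_nt", .after = "neuron_id")
  calls$top_nt[is.na(calls$top_nt)] <- "uncertain"
  attr(calls, "filter_report") <- flt$report
  calls
}

#' Cell-type-level transmitter calls
#'
#' The modal neuron-level call per cell type, with `"uncertain"` members
#' excluded from the mode. A modal tie yields `"uncertain"`; a type is
#' flagged conflicted when two or more distinct non-uncertain calls occur
#' among its members.
#'
#' @param calls A neuron-call tibble (from [call_neurons()]); the `conf_nt`
#'   column is used.
#' @param neurons A validated neuron table with a `cell_type` column.
#' @return A tibble: cell_type, winner, conflicted, mean_confidence,
#'   n_neurons, n_uncertain.
#' @export
celltype_calls <- function(calls, neurons) {
  if (!"cell_type" %in% names(neurons)) {
    stop("neuron table has no cell_type column", call. = FALSE)
  }
  df <- dplyr::inner_join(calls, neurons[c("neuron_id", "cell_type")],
                          by = "neuron_id")
  df |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      winner = {
        nt <- .data$conf_nt[.data$conf_nt != "uncertain"]
        if (length(nt) == 0) "uncertain" else {
          tab <- sort(table(nt), decreasing = TRUE)
          if (length(tab) > 1 && tab[1] == tab[2]) "uncertain" else names(tab)[1]
        }
      },
      conflicted = dplyr::n_distinct(.data$conf_nt[.data$conf_nt != "uncertain"]) >= 2,
      mean_confidence = mean(.data$confidence, na.rm = TRUE),
      n_neurons = dplyr::n(),
      n_uncertain = sum(.data$conf_nt == "uncertain"),
      .groups = "drop")
}
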