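#' Validate a per-synapse prediction table
#'
#' The synapse table is the raw input of the pipeline: one row per
#' automatically detected presynapse, with either a predicted label, a
#' six-class score vector, or both. Validation normalizes the label
#' vocabulary (see [normalize_transmitters()]), projects score vectors onto
#' the simplex, and checks that labels agree with score argmaxes.
#'
#' Required columns: `synapse_id`, `neuron_id`, `detection_score`, and at
#' least one of `pred_label` / the six `score_<label>` columns. Optional:
#' `compartment` (axon, dendrite, soma, primary_dendrite, cell_body_fiber,
#' unknown), `dist_soma_um`, `dist_primary_dendrite_um`.
#'
#' @param synapses A data frame of per-synapse rows.
#' @return A validated tibble with normalized labels and simplex scores.
#' @export
validate_synapse_table <- function(synapses) {
  synapses <- tibble::as_tibble(synapses)
  required <- c("synapse_id", "neuron_id", "detection_score")
  missing <- setdiff(required, names(synapses))
  if (length(missing) > 0) {
    stop("synapse table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_label <- "pred_label" %in% names(synapses)
  has_scores <- all(.score_cols() %in% names(synapses))
  if (!has_label && !has_scores) {
    stop("synapse table needs either pred_label or all six score_<label> columns",
         call. = FALSE)
  }
  if (anyDuplicated(synapses$synapse_id)) {
    stop("synapse_id values must be unique", call. = FALSE)
  }
  if (any(!is.finite(synapses$detection_score))) {
    stop("detection_score must be finite", call. = FALSE)
  }
  if (has_label) {
    synapses$pred_label <- normalize_transmitters(synapses$pred_label)
  }
  if (has_scores) {
    S <- as.matrix(synapses[.score_cols()])
    if (any(!is.finite(S)) || any(S < 0)) {
      stop("score columns must be finite and non-negative", call. = FALSE)
    }
    tot <- rowSums(S)
    if (any(tot <= 0)) {
      stop("score vector(s) sum to zero for synapse_id: ",
           paste(utils::head(synapses$synapse_id[tot <= 0], 5), collapse = ", "),
           call. = FALSE)
    }
    S <- S / tot
    synapses[.score_cols()] <- as.data.frame(S)
    argmax <- transmitter_labels()[max.col(S, ties.method = "first")]
    if (!has_label) {
      synapses$pred_label <- argmax
    } else {
      # label must match the argmax score (first-in-canonical-order on ties)
      mism <- which(synapses$pred_label != argmax)
      # tolerate ties where the stated label attains the max
      if (length(mism) > 0) {
        stated <- S[cbind(mism, match(synapses$pred_label[mism],
                                      transmitter_labels()))]
        top <- apply(S[mism, , drop = FALSE], 1, max)
        off <- mism[stated < top - 1e-12]
        if (length(off) > 0) {
          stop("pred_label disagrees with score argmax for synapse_id: ",
               paste(utils::head(synapses$synapse_id[off], 5), collapse = ", "),
               call. = FALSE)
        }
      }
    }
  }
  if ("compartment" %in% names(synapses)) {
    comp_ok <- c("axon", "dendrite", "soma", "primary_dendrite",
                 "cell_body_fiber", "unknown")
    synapses$compartment <- tolower(as.character(synapses$compartment))
    bad <- setdiff(unique(synapses$compartment), c(comp_ok, NA))
    if (length(bad) > 0) {
      stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  for (col in c("dist_soma_um", "dist_primary_dendrite_um")) {
    if (col %in% names(synapses) &&
        any(synapses[[col]] < 0, na.rm = TRUE)) {
      stop(col, " must be non-negative", call. = FALSE)
    }
  }
  synapses
}

#' Validate a neuron metadata table
#'
#' One row per neuron: `neuron_id` (unique, required), and optional
#' `hemilineage`, `cell_type`, `side` (left/right/unknown), `dataset`,
#' `homolog_id`. Homolog links are symmetrized: if a lists b, b is made to
#' list a, and conflicting asymmetric links are an error.
#'
#' @param neurons A data frame of neuron metadata.
#' @return A validated tibble.
#' @export
validate_neuron_table <- function(neurons) {
  neurons <- tibble::as_tibble(neurons)
  if (!"neuron_id" %in% names(neurons)) {
    stop("neuron table is missing required column(s): neuron_id", call. = FALSE)
  }
  if (anyDuplicated(neurons$neuron_id)) {
    stop("neuron_id values must be unique", call. = FALSE)
  }
  if ("side" %in% names(neurons)) {
    neurons$side <- tolower(as.character(neurons$side))
    bad <- setdiff(unique(neurons$side), c("left", "right", "unknown", NA))
    if (length(bad) > 0) {
      stop("side must be left, right or unknown; got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if ("homolog_id" %in% names(neurons)) {
    h <- neurons$homolog_id
    linked <- which(!is.na(h))
    for (i in linked) {
      j <- match(h[i], neurons$neuron_id)
      if (is.na(j)) next # partner outside table is allowed
      back <- neurons$homolog_id[j]
      if (is.na(back)) {
        neurons$homolog_id[j] <- neurons$neuron_id[i]
      } else if (back != neurons$neuron_id[i]) {
        stop("asymmetric homolog link: ", neurons$neuron_id[i], " -> ", h[i],
             " but ", h[i], " -> ", back, call. = FALSE)
      }
    }
  }
  neurons
}

#' Read synapse and neuron tables from disk
#'
#' CSV (UTF-8, header row) is the interchange format; Feather/Arrow files
#' (as released for the real datasets) are read when the `arrow` package is
#' available and the file extension is `.feather` or `.arrow`. The
#' `dialect` records which detection-score convention the table uses:
#' `"fafb"` cleft scores (roughly 0-200+) or `"hemibrain"` confidences
#' (0-1); it sets the default detection threshold downstream.
#'
#' @param synapse_path,neuron_path File paths.
#' @param dialect `"fafb"` or `"hemibrain"`.
#' @return A list with validated `synapses` and `neurons` tibbles and the
#'   `dialect` tag.
#' @export
read_tables <- function(synapse_path, neuron_path, dialect = c("fafb", "hemibrain")) {
  dialect <- match.arg(dialect)
  list(synapses = validate_synapse_table(.read_any(synapse_path)),
       neurons = validate_neuron_table(.read_any(neuron_path)),
       dialect = dialect)
}

.read_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(feather|arrow)$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Feather files requires the arrow package", call. = FALSE)
    }
    return(tibble::as_tibble(arrow::read_feather(path)))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write neuron-level calls (and other reports) to CSV
#'
#' Writes with a deterministic column order. The per-neuron table carries
#' both the unfiltered-vote call (`top_nt`, detection threshold only) and
#' the fully filtered call (`conf_nt`), plus margin, confidence, synapse
#' count and the six vote-fraction columns.
#'
#' @param calls A tibble of neuron calls (from [call_neurons()]).
#' @param path Output path (`.csv`, or `.feather` with arrow installed).
#' @return `path`, invisibly.
#' @export
write_neuron_calls <- function(calls, path) {
  lead <- c("neuron_id", "top_nt", "conf_nt", "margin", "confidence",
            "n_synapses_used")
  cols <- c(intersect(lead, names(calls)),
            sort(setdiff(names(calls), lead)))
  .write_any(calls[cols], path)
}

.write_any <- function(df, path) {
  if (grepl("\\.(feather|arrow)$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("writing Feather files requires the arrow package", call. = FALSE)
    }
    arrow::write_feather(df, path)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Assemble a full pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated object so a run
#' is a pure function of (tables, config). The seed governs any stochastic
#' stage and is echoed into outputs.
#'
#' @param dialect Detection-score dialect, `"fafb"` (cleft score, default
#'   threshold 50) or `"hemibrain"` (confidence, threshold 0.5).
#' @param policy A [filter_policy()]; defaults to the dialect's policy.
#' @param confusion_synapse,confusion_neuron `nt_confusion` matrices at
#'   synapse and neuron level; synapse level is needed for confidence
#'   scores, neuron level for the Bayes analysis.
#' @param prior A [smoothing_prior()] for the Bayes stage (default
#'   `lambda = 16`, `epsilon = 1e-3`).
#' @param min_neurons,min_presynapses_entropy Hemilineage eligibility for
#'   the entropy stage (strict: more than 10 neurons, each with more than
#'   30 presynapses).
#' @param seed Integer RNG seed recorded in every output.
#' @return A list with class `"nt_run_config"`.
#' @export
run_config <- function(dialect = c("fafb", "hemibrain"),
                       policy = NULL,
                       confusion_synapse = NULL,
                       confusion_neuron = NULL,
                       prior = smoothing_prior(16, 1e-3),
                       min_neurons = 10L,
                       min_presynapses_entropy = 30L,
                       seed = 1L) {
  dialect <- match.arg(dialect)
  if (is.null(policy)) policy <- filter_policy(dialect = dialect)
  stopifnot(inherits(policy, "nt_filter_policy"), inherits(prior, "nt_prior"))
  if (!is.null(confusion_synapse)) stopifnot(inherits(confusion_synapse, "nt_confusion"))
  if (!is.null(confusion_neuron)) stopifnot(inherits(confusion_neuron, "nt_confusion"))
  structure(list(dialect = dialect, policy = policy,
                 confusion_synapse = confusion_synapse,
                 confusion_neuron = confusion_neuron,
                 prior = prior,
                 min_neurons = as.integer(min_neurons),
                 min_presynapses_entropy = as.integer(min_presynapses_entropy),
                 seed = as.integer(seed)),
            class = "nt_run_config")
}
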