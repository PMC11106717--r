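#' Run the full annotation pipeline on a study
#'
#' Chains the stages filter -> vote -> confidence -> cell-type mode ->
#' entropy -> Bayes -> homolog consistency, logging each filter's removal
#' counts, and returns all stage outputs in one report bundle. The run is a
#' pure function of (tables, config): the config seed is set before any
#' stochastic step and echoed into the bundle.
#'
#' Stages whose required inputs are absent are skipped gracefully: cell-type
#' calls need a `cell_type` column, entropy and Bayes need `hemilineage`
#' (Bayes also needs a neuron-level confusion matrix), and consistency needs
#' `homolog_id` links.
#'
#' @param synapses A validated synapse table.
#' @param neurons A validated neuron table.
#' @param config A [run_config()].
#' @return A list of class `"nt_report"`: `neuron_calls`, `filter_report`,
#'   `celltype_calls`, `entropy`, `quadrants`, `bayes`, `pairs`,
#'   `mismatches`, `config`.
#' @export
run_pipeline <- function(synapses, neurons, config = run_config()) {
  stopifnot(inherits(config, "nt_run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  synapses <- stage("validate", validate_synapse_table(synapses))
  neurons <- stage("validate", validate_neuron_table(neurons))

  calls <- stage("aggregate",
                 call_neurons(synapses, config$policy, config$confusion_synapse))
  message("run_pipeline: ", nrow(calls), " neurons called; ",
          sum(calls$conf_nt == "uncertain"), " uncertain")

  ct <- NULL
  if ("cell_type" %in% names(neurons)) {
    ct <- stage("celltype", celltype_calls(calls, neurons))
  }

  flt <- stage("filter", filter_synapses(synapses, config$policy))
  ent <- NULL; quad <- NULL
  if ("hemilineage" %in% names(neurons)) {
    ent <- stage("entropy",
                 hemilineage_entropy(calls, flt$synapses, neurons,
                                     min_neurons = config$min_neurons,
                                     min_presynapses = config$min_presynapses_entropy))
    if (sum(ent$eligible & is.finite(ent$H_neuron)) >= 4) {
      quad <- stage("entropy", entropy_quadrants(ent))
    }
  }

  bayes <- NULL
  if ("hemilineage" %in% names(neurons) && !is.null(config$confusion_neuron)) {
    bayes <- stage("bayes",
                   analyze_hemilineages(calls, neurons, config$confusion_neuron,
                                        prior = config$prior))
  }

  pairs_tbl <- NULL; mm <- NULL
  if ("homolog_id" %in% names(neurons) && any(!is.na(neurons$homolog_id))) {
    linked <- neurons[!is.na(neurons$homolog_id), c("neuron_id", "homolog_id")]
    # each unordered pair once
    linked <- linked[linked$neuron_id < linked$homolog_id, ]
    pairs <- tibble::tibble(neuron_a = linked$neuron_id,
                            neuron_b = linked$homolog_id,
                            relation = "left_right")
    pairs_tbl <- stage("consistency",
                       pair_consistency(pairs, calls, flt$synapses))
    mm <- stage("consistency", mismatch_summary(pairs_tbl))
  }

  structure(list(neuron_calls = calls,
                 filter_report = attr(calls, "filter_report"),
                 celltype_calls = ct,
                 entropy = ent, quadrants = quad,
                 bayes = bayes,
                 pairs = pairs_tbl, mismatches = mm,
                 config = config),
            class = "nt_report")
}
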