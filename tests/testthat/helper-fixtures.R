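# Shared fixtures: small constructed tables and matrices built in code.

labs <- transmitter_labels()

# diagonal-dominant confusion matrix (diag d, off-diagonal uniform)
diag_confusion <- function(d = 0.9, level = "synapse") {
  confusion_matrix(diag(6) * d + (1 - diag(6)) * (1 - d) / 5, level = level)
}

uniform_confusion <- function(level = "neuron") {
  confusion_matrix(matrix(1 / 6, 6, 6), level = level)
}

identity_confusion <- function(level = "neuron") {
  confusion_matrix(diag(6), level = level)
}

# random row-stochastic matrix (rows drawn from a flat Dirichlet)
random_confusion <- function(level = "neuron") {
  m <- matrix(stats::rexp(36), 6, 6)
  confusion_matrix(m / rowSums(m), level = level)
}

# minimal valid synapse table: one neuron, given labels
toy_synapses <- function(labels, neuron_id = "n1", detection_score = 100,
                         compartment = "axon") {
  tibble::tibble(
    synapse_id = sprintf("%s_s%04d", neuron_id, seq_along(labels)),
    neuron_id = neuron_id,
    pred_label = labels,
    detection_score = detection_score,
    compartment = compartment,
    dist_soma_um = 50,
    dist_primary_dendrite_um = 5)
}

# the 10-row fixture exercising each filter rule: 7 clean rows and one
# violation of each of detection score (exactly at threshold), compartment,
# and soma distance
filter_fixture <- function() {
  tb <- toy_synapses(rep("acetylcholine", 10))
  tb$detection_score[1] <- 50        # exactly at threshold -> removed (strict >)
  tb$compartment[2] <- "soma"        # disallowed compartment
  tb$dist_soma_um[3] <- 10           # below the 15 um floor
  tb
}
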