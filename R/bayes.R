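# log-sum-exp over a numeric vector; -Inf inputs handled exactly
.lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf (or contains +Inf/NaN upstream)
  m + log(sum(exp(x - m)))
}

#' Log marginal likelihood of observed winners given m true transmitters
#'
#' The probability of observing the neuron-level winning transmitters
#' `yhat_1..yhat_n` of a hemilineage under the hypothesis that the
#' hemilineage truly expresses `m` distinct transmitters, with a flat prior
#' over which size-`m` subset and which member of the subset each neuron
#' uses:
#' \deqn{p(\hat y | m) = \binom{6}{m}^{-1} \sum_{S \in P_m}
#'   \prod_j \frac{1}{m} \sum_{y \in S} C[y, \hat y_j].}
#' Accumulated entirely in natural-log space (per-subset log terms combined
#' by log-sum-exp) so hemilineages with hundreds of neurons do not
#' underflow; `-Inf` is a valid return (impossible data under the model).
#'
#' @param winners Character vector of neuron-level winning transmitters
#'   (no `"uncertain"` entries; drop them first).
#' @param C_eff Row-stochastic effective confusion matrix at neuron level,
#'   typically [expected_confusion()] output.
#' @param m Hypothesized number of true transmitters, 1..6.
#' @return Scalar log probability.
#' @export
log_marginal_likelihood <- function(winners, C_eff, m) {
  if (length(m) != 1 || !m %in% 1:6) {
    stop("m must be an integer in 1..6", call. = FALSE)
  }
  .check_labels(winners)
  if (length(winners) == 0) stop("no winners supplied", call. = FALSE)
  counts <- as.vector(table(factor(winners, levels = transmitter_labels())))
  Cm <- unclass(C_eff)
  subsets <- utils::combn(6, m)
  logterms <- apply(subsets, 2, function(S) {
    w <- colSums(Cm[S, , drop = FALSE]) / m # P(yhat | S) per predicted class
    lw <- ifelse(w > 0, log(w), -Inf)
    contrib <- counts * lw
    contrib[counts == 0] <- 0 # 0 * -Inf := 0
    sum(contrib)
  })
  .lse(logterms) - log(choose(6, m))
}

#' Pairwise Bayes factor between two transmitter-count hypotheses
#'
#' `K_{m1,m2} = p(yhat | m1) / p(yhat | m2)`, computed from the log
#' marginals. `+Inf` when only the denominator is impossible; if both
#' hypotheses assign zero probability the comparison is undefined and an
#' error is raised.
#'
#' @inheritParams log_marginal_likelihood
#' @param m1,m2 Hypothesized transmitter counts to compare.
#' @return Positive scalar (possibly `Inf`).
#' @export
pairwise_bayes_factor <- function(winners, C_eff, m1, m2) {
  l1 <- log_marginal_likelihood(winners, C_eff, m1)
  l2 <- log_marginal_likelihood(winners, C_eff, m2)
  if (!is.finite(l1) && !is.finite(l2)) {
    stop("both marginal likelihoods are zero; Bayes factor undefined",
         call. = FALSE)
  }
  if (!is.finite(l2)) return(Inf)
  exp(l1 - l2)
}

#' One-versus-rest Bayes factor for a transmitter count
#'
#' `K_{m,not-m} = p(yhat | m) / sum_{n != m} p(yhat | n)` with the five
#' competing counts summed unweighted (implicit uniform model prior);
#' computed stably from log marginals via log-sum-exp.
#'
#' @inheritParams log_marginal_likelihood
#' @param log_marginals Optional precomputed vector of the six log
#'   marginals (index = m); supplied by [analyze_hemilineage()] to avoid
#'   recomputation.
#' @return Positive scalar (possibly `Inf`).
#' @export
one_vs_rest <- function(winners, C_eff, m, log_marginals = NULL) {
  if (is.null(log_marginals)) {
    log_marginals <- vapply(1:6, function(k)
      log_marginal_likelihood(winners, C_eff, k), numeric(1))
  }
  num <- log_marginals[m]
  den <- .lse(log_marginals[-m])
  if (!is.finite(den)) {
    if (is.finite(num)) return(Inf)
    stop("all marginal likelihoods are zero; Bayes factor undefined",
         call. = FALSE)
  }
  exp(num - den)
}

#' Classify Bayes-factor evidence strength
#'
#' Jeffreys-style classes with inclusive thresholds: decisive at
#' `K >= 10^2`, strong at `10^{3/2}`, good at `10^1`, substantial at
#' `10^{1/2}`, otherwise none.
#'
#' @param K Non-negative Bayes factor(s); vectorized.
#' @return Character vector of evidence classes.
#' @export
classify_evidence <- function(K) {
  if (any(is.na(K)) || any(K < 0)) {
    stop("K must be non-negative", call. = FALSE)
  }
  cut_pts <- c(10^0.5, 10, 10^1.5, 100)
  lab <- c("none", "substantial", "good", "strong", "decisive")
  lab[findInterval(K, cut_pts) + 1L]
}

#' Frequency-ranked transmitters of a hemilineage
#'
#' Labels sorted by descending frequency among non-uncertain neuron-level
#' winners; ties broken by canonical label order and flagged.
#'
#' @param winners Character vector of neuron-level calls.
#' @return A tibble: transmitter, n, frequency; attribute `"tied"` marks
#'   whether any adjacent ranks are tied.
#' @export
rank_transmitters <- function(winners) {
  .check_labels(winners, allow_uncertain = TRUE)
  usable <- winners[!is.na(winners) & winners != "uncertain"]
  if (length(usable) == 0) {
    stop("no non-uncertain winners to rank", call. = FALSE)
  }
  tab <- table(factor(usable, levels = transmitter_labels()))
  tab <- tab[tab > 0]
  ord <- order(-as.vector(tab), match(names(tab), transmitter_labels()))
  out <- tibble::tibble(transmitter = names(tab)[ord],
                        n = as.integer(tab[ord]),
                        frequency = as.integer(tab[ord]) / length(usable))
  attr(out, "tied") <- anyDuplicated(out$n) > 0
  out
}

#' Full Bayes-factor analysis of one hemilineage
#'
#' Marginalizes the neuron-level confusion matrix over the smoothing prior,
#' computes the six log marginal likelihoods of the observed winners, all
#' pairwise Bayes factors, the six one-versus-rest factors, the best
#' supported transmitter count and its evidence class, and the
#' frequency-ranked transmitter list. `"uncertain"` winners are dropped
#' before inference and counted.
#'
#' @param winners Neuron-level calls of the hemilineage (may include
#'   `"uncertain"`).
#' @param C Neuron-level `nt_confusion` matrix (test-set estimate).
#' @param prior A [smoothing_prior()]; default `lambda = 16`,
#'   `epsilon = 1e-3`.
#' @param marginalize If `FALSE`, use `C` directly instead of its prior
#'   expectation.
#' @return A list of class `"nt_bayes"`: `log_marginal` (length 6),
#'   `K_pairwise` (6x6), `K_one_vs_rest` (length 6), `best_m`, `evidence`,
#'   `ranked`, `n_used`, `n_uncertain`, `prior`.
#' @export
analyze_hemilineage <- function(winners, C, prior = smoothing_prior(16, 1e-3),
                                marginalize = TRUE) {
  .check_labels(winners, allow_uncertain = TRUE)
  usable <- winners[!is.na(winners) & winners != "uncertain"]
  if (length(usable) == 0) {
    stop("hemilineage has no usable (non-uncertain) neuron calls",
         call. = FALSE)
  }
  C_eff <- if (marginalize) expected_confusion(C, prior) else C
  lm <- vapply(1:6, function(m)
    log_marginal_likelihood(usable, C_eff, m), numeric(1))
  Kp <- outer(lm, lm, function(a, b) exp(a - b))
  dimnames(Kp) <- list(m1 = 1:6, m2 = 1:6)
  Kovr <- vapply(1:6, function(m)
    one_vs_rest(usable, C_eff, m, log_marginals = lm), numeric(1))
  best_m <- which.max(Kovr)
  structure(list(log_marginal = lm, K_pairwise = Kp, K_one_vs_rest = Kovr,
                 best_m = best_m,
                 evidence = classify_evidence(Kovr[best_m]),
                 ranked = rank_transmitters(usable),
                 n_used = length(usable),
                 n_uncertain = length(winners) - length(usable),
                 prior = prior),
            class = "nt_bayes")
}

#' Bayes-factor analysis of every hemilineage in a study
#'
#' Applies [analyze_hemilineage()] to the neuron calls of each hemilineage
#' and returns one summary row per hemilineage in report-CSV shape.
#'
#' @param calls Neuron-call tibble (uses `conf_nt`).
#' @param neurons Neuron table with a `hemilineage` column.
#' @param C Neuron-level `nt_confusion` matrix.
#' @inheritParams analyze_hemilineage
#' @return A tibble: hemilineage, n_neurons, n_uncertain, logp_m1..logp_m6,
#'   K_1vr..K_6vr, best_m, evidence, ranked_transmitters, lambda, epsilon.
#' @export
analyze_hemilineages <- function(calls, neurons, C,
                                 prior = smoothing_prior(16, 1e-3),
                                 marginalize = TRUE) {
  if (!"hemilineage" %in% names(neurons)) {
    stop("neuron table has no hemilineage column", call. = FALSE)
  }
  df <- dplyr::inner_join(calls, neurons[c("neuron_id", "hemilineage")],
                          by = "neuron_id") |>
    dplyr::filter(!is.na(.data$hemilineage))
  hls <- split(df$conf_nt, df$hemilineage)
  # expected confusion is hemilineage-independent; compute once
  C_eff <- if (marginalize) expected_confusion(C, prior) else C
  rows <- lapply(names(hls), function(h) {
    if (all(hls[[h]] == "uncertain")) {
      message("analyze_hemilineages: skipping ", h,
              " (no non-uncertain neuron calls)")
      return(NULL)
    }
    res <- analyze_hemilineage(hls[[h]], C_eff, prior, marginalize = FALSE)
    tibble::tibble(
      hemilineage = h,
      n_neurons = res$n_used, n_uncertain = res$n_uncertain,
      !!!stats::setNames(as.list(res$log_marginal), paste0("logp_m", 1:6)),
      !!!stats::setNames(as.list(res$K_one_vs_rest), paste0("K_", 1:6, "vr")),
      best_m = res$best_m, evidence = res$evidence,
      ranked_transmitters = paste(res$ranked$transmitter, collapse = ";"),
      lambda = prior$lambda_rate, epsilon = prior$epsilon)
  })
  dplyr::bind_rows(rows)
}
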