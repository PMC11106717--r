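#' Construct and validate a transmitter confusion matrix
#'
#' A confusion matrix `C` is the row-stochastic error model of the upstream
#' classifier: `C[y, yhat]` is the probability that a unit (presynapse or
#' whole neuron, depending on `level`) with true transmitter `y` is predicted
#' as `yhat`, estimated on a held-out labeled test set. It powers both the
#' neuron confidence score and the hemilineage Bayes-factor model.
#'
#' @param C 6x6 numeric matrix, rows = true label, columns = predicted label,
#'   in canonical label order (see [transmitter_labels()]). Unlabeled
#'   matrices are assumed to already be in canonical order.
#' @param level `"synapse"` or `"neuron"`; which unit the error rates refer to.
#' @param tol Tolerance for the row-sum check.
#' @return The matrix with canonical dimnames and a `level` attribute,
#'   classed `"nt_confusion"`.
#' @export
#' @examples
#' confusion_matrix(diag(6), level = "neuron")
confusion_matrix <- function(C, level = c("synapse", "neuron"), tol = 1e-9) {
  level <- match.arg(level)
  C <- as.matrix(C)
  labs <- transmitter_labels()
  if (!all(dim(C) == c(6, 6))) stop("confusion matrix must be 6x6", call. = FALSE)
  if (!is.null(rownames(C)) && !is.null(colnames(C))) {
    idx <- match(labs, normalize_transmitters(rownames(C)))
    jdx <- match(labs, normalize_transmitters(colnames(C)))
    if (!anyNA(idx) && !anyNA(jdx)) C <- C[idx, jdx, drop = FALSE]
  }
  dimnames(C) <- list(true = labs, predicted = labs)
  if (any(!is.finite(C)) || any(C < 0) || any(C > 1)) {
    stop("confusion matrix entries must be finite and in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(C)
  if (any(abs(rs - 1) > tol)) {
    stop("confusion matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  structure(C, level = level, class = c("nt_confusion", "matrix", "array"))
}

#' Estimate a confusion matrix from test-set counts with additive smoothing
#'
#' Row-normalizes a 6x6 count matrix `N` (rows = true label, columns =
#' predicted label) with an optional integer pseudo-count `beta` added to
#' every cell: `C[y, yhat] = (N[y, yhat] + beta) / (sum_yhat N[y, yhat] + 6 beta)`.
#' `beta = 0` is plain count normalization; as `beta` grows every row tends
#' to the uniform 1/6 distribution.
#'
#' @param counts 6x6 non-negative integer matrix of test-set counts.
#' @param beta Non-negative integer smoothing pseudo-count.
#' @param level Passed to [confusion_matrix()].
#' @return An `nt_confusion` matrix.
#' @export
estimate_confusion <- function(counts, beta = 0, level = c("synapse", "neuron")) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(6, 6))) stop("counts must be 6x6", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(beta) != 1 || beta < 0 || beta != round(beta)) {
    stop("beta must be a single non-negative integer", call. = FALSE)
  }
  rs <- rowSums(counts)
  if (beta == 0 && any(rs == 0)) {
    stop("zero count row for true label(s) ",
         paste(transmitter_labels()[rs == 0], collapse = ", "),
         " with beta = 0", call. = FALSE)
  }
  C <- (counts + beta) / (rs + 6 * beta)
  confusion_matrix(C, level = match.arg(level))
}

#' Additively smooth a confusion matrix
#'
#' Applies the count-normalized smoothing
#' `C~[y, yhat] = (C[y, yhat] + alpha) / (1 + 6 alpha)`. `alpha = 0` returns
#' `C` unchanged; `alpha -> Inf` drives every entry to 1/6. Row sums are
#' preserved exactly: each row sum maps to `(1 + 6 alpha) / (1 + 6 alpha) = 1`.
#'
#' @param C An `nt_confusion` matrix (or plain row-stochastic 6x6 matrix).
#' @param alpha Non-negative smoothing parameter.
#' @return An `nt_confusion` matrix.
#' @export
smooth_confusion <- function(C, alpha) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha < 0) {
    stop("alpha must be a single non-negative finite number", call. = FALSE)
  }
  level <- attr(C, "level") %||% "synapse"
  confusion_matrix((unclass(C) + alpha) / (1 + 6 * alpha), level = level)
}

#' Exponential smoothing prior
#'
#' The prior over the smoothing parameter alpha used when marginalizing the
#' confusion matrix: a shifted exponential
#' `p(alpha) = lambda * exp(-lambda * (alpha - epsilon))` on
#' `[epsilon, Inf)`, zero below `epsilon`. Mass concentrates just above the
#' observed matrix (`alpha = epsilon`) and decays for heavier smoothing;
#' alpha below epsilon is excluded because it would leave zero
#' misclassification probabilities, an artifact of the finite test set.
#'
#' @param lambda_rate Positive rate parameter; larger values trust the
#'   observed matrix more.
#' @param epsilon Small positive offset, `0 < epsilon < 0.1` (default 1e-3).
#' @return A list with class `"nt_prior"`.
#' @export
smoothing_prior <- function(lambda_rate, epsilon = 1e-3) {
  if (length(lambda_rate) != 1 || !is.finite(lambda_rate) || lambda_rate <= 0) {
    stop("lambda_rate must be a single positive finite number", call. = FALSE)
  }
  if (length(epsilon) != 1 || !is.finite(epsilon) || epsilon <= 0 || epsilon >= 0.1) {
    stop("epsilon must satisfy 0 < epsilon < 0.1", call. = FALSE)
  }
  structure(list(lambda_rate = lambda_rate, epsilon = epsilon),
            class = "nt_prior")
}

# internal: E[1 / (1 + 6 alpha)] under the shifted-exponential prior.
#
# The smoothed matrix obeys the identity
#   C~(alpha) = 1/6 + (C - 1/6) / (1 + 6 alpha),
# so the entrywise expectation of C~ reduces to this single scalar integral.
# Substituting u = exp(-lambda (alpha - eps)) maps [eps, Inf) to (0, 1] and
# absorbs the exponential tail exactly:
#   E[1/(1+6 alpha)] = int_0^1 du / (1 + 6 eps - 6 log(u) / lambda).
.expected_shrink <- function(lambda, epsilon, abs.tol = 1e-10) {
  f <- function(u) 1 / (1 + 6 * epsilon - 6 * log(u) / lambda)
  q <- stats::integrate(f, 0, 1, abs.tol = abs.tol, rel.tol = 1e-10,
                        subdivisions = 500L, stop.on.error = FALSE)
  if (q$message != "OK" && q$abs.error > 1e-8) {
    stop("quadrature did not converge: ", q$message,
         " (abs.error = ", format(q$abs.error), ")", call. = FALSE)
  }
  q$value
}

#' Prior-marginalized (expected) confusion matrix
#'
#' Entrywise expectation of the smoothed confusion matrix under the
#' exponential prior on the smoothing parameter alpha:
#' `E[C~] = 1/6 + (C - 1/6) * E[1/(1 + 6 alpha)]`, where the scalar
#' expectation is evaluated by adaptive quadrature (absolute tolerance
#' below 1e-8) after an exact exponential-tail substitution. For
#' `lambda -> Inf` the result approaches the epsilon-smoothed matrix; for
#' `lambda -> 0` it approaches uniform 1/6.
#'
#' @param C An `nt_confusion` matrix.
#' @param prior An [smoothing_prior()] object.
#' @return An `nt_confusion` matrix of expected entries.
#' @export
expected_confusion <- function(C, prior) {
  stopifnot(inherits(prior, "nt_prior"))
  g <- .expected_shrink(prior$lambda_rate, prior$epsilon)
  level <- attr(C, "level") %||% "synapse"
  confusion_matrix(1 / 6 + (unclass(C) - 1 / 6) * g, level = level)
}

#' Expected average accuracy under the smoothing prior
#'
#' Mean diagonal of [expected_confusion()]; a single interpretable scalar
#' summarizing how much residual trust the prior places in the test-set
#' accuracy. Always in `[1/6, 1]`; equal to 1/6 for a uniform matrix.
#'
#' @inheritParams expected_confusion
#' @return Scalar expected accuracy.
#' @export
expected_accuracy <- function(C, prior) {
  mean(diag(expected_confusion(C, prior)))
}

#' Solve for the prior rate that yields a target expected accuracy
#'
#' Expected accuracy is monotonically increasing in the rate `lambda`
#' whenever the observed mean diagonal exceeds chance (1/6), ranging from
#' 1/6 (`lambda -> 0`) up to the epsilon-smoothed observed accuracy
#' (`lambda -> Inf`). This inverts that map by bisection on `log(lambda)`.
#'
#' @param C An `nt_confusion` matrix.
#' @param target_accuracy Desired expected accuracy, strictly between 1/6
#'   and the epsilon-smoothed observed accuracy.
#' @param epsilon Prior offset (see [smoothing_prior()]).
#' @param tol Accuracy tolerance on the solution.
#' @return The rate `lambda` such that
#'   `expected_accuracy(C, smoothing_prior(lambda, epsilon))` equals
#'   `target_accuracy` within `tol`.
#' @export
solve_lambda_for_accuracy <- function(C, target_accuracy, epsilon = 1e-3,
                                      tol = 1e-6) {
  cbar <- mean(diag(C))
  amax <- 1 / 6 + (cbar - 1 / 6) / (1 + 6 * epsilon) # lambda -> Inf limit
  if (target_accuracy <= 1 / 6 || target_accuracy >= amax) {
    stop("target accuracy must lie strictly in (", format(1 / 6), ", ",
         format(amax), ") for this matrix and epsilon", call. = FALSE)
  }
  f <- function(loglam) {
    expected_accuracy(C, smoothing_prior(exp(loglam), epsilon)) - target_accuracy
  }
  lo <- log(1e-8); hi <- log(1e8)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  lam <- exp(root$root)
  if (abs(f(log(lam))) > tol) {
    stop("bisection failed to reach tolerance", call. = FALSE)
  }
  lam
}

#' Read / write a confusion matrix as labeled CSV
#'
#' 6x6 CSV with a header row of predicted labels and a first column of true
#' labels, in canonical order.
#'
#' @param path File path.
#' @param level Unit of the error rates (see [confusion_matrix()]).
#' @return `read_confusion_csv()` returns an `nt_confusion` matrix;
#'   `write_confusion_csv()` returns `path` invisibly.
#' @export
read_confusion_csv <- function(path, level = c("synapse", "neuron")) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  idx <- match(transmitter_labels(), normalize_transmitters(rownames(m)))
  jdx <- match(transmitter_labels(), normalize_transmitters(colnames(m)))
  if (anyNA(idx) || anyNA(jdx)) {
    stop("confusion CSV must label all six transmitters on both axes",
         call. = FALSE)
  }
  confusion_matrix(m[idx, jdx], level = match.arg(level))
}

#' @rdname read_confusion_csv
#' @param C An `nt_confusion` matrix to write.
#' @export
write_confusion_csv <- function(C, path) {
  utils::write.csv(as.data.frame(unclass(C)), path)
  invisible(path)
}

#' @importFrom rlang %||%
NULL
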