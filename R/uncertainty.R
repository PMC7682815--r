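#' Monte Carlo Dropout posterior samples
#'
#' Runs `n_mc` stochastic forward passes with dropout active at inference
#' time (all other stochastic layers off, batch normalization on running
#' statistics), at the rates the network was trained with. Each pass yields
#' a softmax class distribution per record; the spread across passes
#' measures the model's predictive uncertainty, which the Information
#' Entropy and Top Difference estimators condense into rejection scores.
#'
#' @param classifier A `trained_classifier` containing at least one dropout
#'   layer.
#' @param x An `encoded_batch` / `ragged_batch`.
#' @param n_mc Number of dropout-perturbed passes (default 50).
#' @param seed Integer seed; results are reproducible under it.
#' @return An object of class `mc_posterior`: array `samples` of shape
#'   (n_mc, n_records, C), the class order, and the per-record MC mean
#'   (`mean`) and standard deviation (`sd`) matrices, both n_records x C.
#' @export
mc_dropout_predict <- function(classifier, x, n_mc = 50, seed = 1L) {
  if (n_mc < 2) abort("n_mc must be >= 2")
  types <- vapply(classifier$model$layers, function(l) l$type, character(1))
  if (!any(types == "dropout")) {
    abort("Monte Carlo Dropout requires a model with at least one dropout layer")
  }
  X <- as_model_input(x)
  check_input_shape(classifier$model, X)
  n <- if (is.list(X) && !is.array(X)) length(X) else dim(X)[1]
  C <- length(classifier$classes)
  samples <- array(0, c(n_mc, n, C))
  set.seed(seed)
  for (s in seq_len(n_mc)) {
    for (start in seq(1, n, by = 256)) {
      idx <- start:min(start + 255, n)
      fw <- nn_forward(classifier$model, slice_batch(X, idx), mode = "mc")
      samples[s, idx, ] <- nn_softmax(fw$out)
    }
  }
  mean_p <- apply(samples, c(2, 3), mean)
  sd_p <- apply(samples, c(2, 3), sd)
  colnames(mean_p) <- colnames(sd_p) <- classifier$classes
  structure(list(samples = samples, classes = classifier$classes,
                 n_mc = n_mc, mean = mean_p, sd = sd_p,
                 ids = if (!is.null(x$ids)) x$ids else as.character(seq_len(n))),
            class = "mc_posterior")
}

#' @export
print.mc_posterior <- function(x, ...) {
  cat("<mc_posterior> ", dim(x$samples)[2], " records x ", length(x$classes),
      " classes, N_mc = ", x$n_mc, "\n", sep = "")
  invisible(x)
}

#' Information Entropy of the Monte Carlo mean distribution
#'
#' `H = -sum_k mean_p_k * log2(mean_p_k + eps)`, the Shannon entropy in bits
#' of each record's MC-mean class distribution; `eps` guards the logarithm.
#' H is near 0 for a confident point-mass prediction and `log2(C)` for a
#' uniform one; high entropy flags uncertain or non-functional input.
#'
#' @param posterior An `mc_posterior` (or a bare probability matrix whose
#'   rows are mean class distributions).
#' @param eps Numerical stability constant added inside the logarithm.
#' @return Numeric vector of entropies, one per record.
#' @export
information_entropy <- function(posterior, eps = 1e-12) {
  p <- if (inherits(posterior, "mc_posterior")) posterior$mean else posterior
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  -rowSums(p * log2(p + eps))
}

#' Top Difference uncertainty score
#'
#' For each record, let k1 and k2 be the two classes with the largest MC
#' mean probabilities. The score is
#' `D = mean_k1 - c*sd_k1 - (mean_k2 + c*sd_k2)`:
#' the gap between the two top classes after shrinking the leader and
#' inflating the runner-up by `c` MC standard deviations. Confident
#' predictions give D near 1; D < 0 flags uncertainty.
#'
#' @param posterior An `mc_posterior`.
#' @param c Standard-deviation weighting constant (default 0.6).
#' @return Numeric vector of D scores, one per record.
#' @export
top_difference <- function(posterior, c = 0.6) {
  if (length(posterior$classes) < 2) abort("Top Difference requires C >= 2")
  m <- posterior$mean
  s <- posterior$sd
  vapply(seq_len(nrow(m)), function(i) {
    ord <- order(m[i, ], decreasing = TRUE)
    k1 <- ord[1]; k2 <- ord[2]
    m[i, k1] - c * s[i, k1] - (m[i, k2] + c * s[i, k2])
  }, numeric(1))
}

#' Per-record uncertainty score table
#'
#' @param posterior An `mc_posterior`.
#' @param c Top Difference constant.
#' @param eps Entropy stability constant.
#' @return A tibble with columns `id`, `predicted` (class of the maximal MC
#'   mean), `entropy` (H, bits) and `top_difference` (D).
#' @export
uncertainty_scores <- function(posterior, c = 0.6, eps = 1e-12) {
  tibble::tibble(
    id = posterior$ids,
    predicted = posterior$classes[max.col(posterior$mean, ties.method = "first")],
    entropy = information_entropy(posterior, eps),
    top_difference = top_difference(posterior, c)
  )
}

#' @export
tidy.mc_posterior <- function(x, ...) uncertainty_scores(x, ...)

#' Accept/reject decision from an uncertainty score
#'
#' The entropy estimator rejects a record when `H > threshold` with default
#' threshold `(1/3) * log2(C)` (one third of the maximal entropy); the top
#' difference estimator rejects when `D < threshold` with default threshold
#' 0. Both thresholds are overridable.
#'
#' @param scores Numeric vector: H values for `estimator = "entropy"`,
#'   D values for `estimator = "topdiff"`. A tibble from
#'   [uncertainty_scores()] is also accepted.
#' @param n_classes Number of classes C (entropy default threshold).
#' @param estimator `"entropy"` or `"topdiff"`.
#' @param threshold Optional override of the decision threshold.
#' @return Character vector of `"accept"` / `"reject"`.
#' @export
rejection_decision <- function(scores, n_classes,
                               estimator = c("entropy", "topdiff"),
                               threshold = NULL) {
  estimator <- match.arg(estimator)
  if (is.data.frame(scores)) {
    scores <- if (estimator == "entropy") scores$entropy else scores$top_difference
  }
  if (estimator == "entropy") {
    if (is.null(threshold)) threshold <- log2(n_classes) / 3
    ifelse(scores > threshold, "reject", "accept")
  } else {
    if (is.null(threshold)) threshold <- 0
    ifelse(scores < threshold, "reject", "accept")
  }
}
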