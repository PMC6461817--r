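#' Two-sample Student t test (equal variances)
#'
#' Two-tailed pooled-variance t test between two groups of log2 ratios.
#' The equal-variance form is the default throughout the pipeline; set
#' `var_equal = FALSE` for the Welch variant.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 finite values.
#' @param var_equal Use the pooled-variance (Student) statistic. Default TRUE.
#' @return A list with `t` (the statistic) and `p` (two-tailed p-value).
#' @examples
#' students_t_test(c(0, 0, 1), c(1, 1, 2))
#' @export
students_t_test <- function(group_a, group_b, var_equal = TRUE) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (sum(is.finite(group_a)) < 2L || sum(is.finite(group_b)) < 2L)
    stop("each group needs at least 2 finite values")
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (stats::var(group_a) + stats::var(group_b) == 0)
    stop("degenerate input: zero pooled variance")
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Storey q-values
#'
#' Multiple-testing correction with an estimated proportion of true null
#' hypotheses (pi0). pi0 is estimated on a lambda grid (0.05 to 0.90,
#' step 0.05) with a cubic smoother evaluated at the largest lambda; with
#' fewer than 100 tests pi0 falls back to 1, in which case the q-values
#' coincide with Benjamini-Hochberg adjusted p-values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param pi0 Optional fixed pi0 overriding the estimate (e.g. 1 for BH).
#' @return A list with `p_values`, `q_values` (same order), and
#'   `pi0_estimate`.
#' @references Storey JD, Tibshirani R (2003) PNAS 100:9440-9445.
#' @export
storey_qvalues <- function(p_values, pi0 = NULL) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.90, by = 0.05)
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 0), 1)
      if (pi0 <= 0) pi0 <- 1  # degenerate estimate: be conservative
    }
  }
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # running minimum of pi0 * m * p / rank, from largest p downwards
  q <- pi0 * m * p[o] / (m:1L)
  q <- cummin(pmin(q, 1))[ro]
  list(p_values = p, q_values = q, pi0_estimate = pi0)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values. Constant input (zero rank
#' variance) yields `NA`, the "undefined" sentinel that downstream mean-z
#' computations exclude.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Fisher z-transformation with clipping
#'
#' z = atanh(rho) after clipping rho into \[-0.99, 0.99\], so perfectly
#' correlated pairs map to a finite score (|z| <= atanh(0.99) ~ 2.6467)
#' rather than infinity.
#'
#' @param rho Correlation value(s) in \[-1, 1\]; `NA` passes through.
#' @return z score(s).
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) stop("|rho| must not exceed 1")
  atanh(pmin(pmax(rho, -0.99), 0.99))
}

#' Effect-size cutoff from a normal null
#'
#' The two-sided normal quantile scaled by the null standard deviation:
#' `qnorm(1 - alpha/2) * sd`. Used to convert an empirical null SD into
#' an effect-size cutoff (e.g. SD 0.158 at alpha 0.05 gives 0.31; SD
#' 0.428 at alpha 0.10 gives 0.70).
#'
#' @param sd Nonnegative null standard deviation.
#' @param alpha Two-sided tail probability in (0, 1).
#' @return A list with `cutoff` (raw) and `cutoff_2dp` (rounded for
#'   reporting).
#' @export
normal_threshold <- function(sd, alpha) {
  if (sd < 0) stop("sd must be nonnegative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  cutoff <- stats::qnorm(1 - alpha / 2) * sd
  list(cutoff = cutoff, cutoff_2dp = round(cutoff, 2))
}

#' Two-tailed normal tail probability of an observed statistic
#'
#' p = 2 * (1 - Phi(|observed - mean| / sd)) under a normal null summary.
#'
#' @param observed Observed statistic.
#' @param null A [null_summary()] (or any list with `mean` and `sd`).
#' @return Two-tailed p-value.
#' @export
normal_tail_p <- function(observed, null) {
  if (null$sd <= 0) stop("null sd must be positive")
  2 * stats::pnorm(abs(observed - null$mean) / null$sd, lower.tail = FALSE)
}

#' Summary of a resampling null distribution
#'
#' @param samples Numeric vector of null draws, or NULL when only the
#'   moments are known.
#' @param mean,sd Moments; computed from `samples` when given.
#' @param n_iterations Number of draws; defaults to `length(samples)`.
#' @param keep_samples Retain the draws in the object (for audit).
#' @return An object of class `null_summary`.
#' @export
null_summary <- function(samples = NULL, mean = NULL, sd = NULL,
                         n_iterations = NULL, keep_samples = FALSE) {
  if (!is.null(samples)) {
    samples <- samples[is.finite(samples)]
    mean <- base::mean(samples)
    sd <- stats::sd(samples)
    if (is.null(n_iterations)) n_iterations <- length(samples)
  }
  if (is.null(mean) || is.null(sd)) stop("need samples or explicit moments")
  if (sd < 0) stop("sd must be nonnegative")
  structure(
    list(n_iterations = n_iterations, mean = mean, sd = sd,
         samples = if (keep_samples) samples else NULL),
    class = "null_summary"
  )
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("null summary: %s iterations, mean %.4g, sd %.4g\n",
              x$n_iterations, x$mean, x$sd))
  invisible(x)
}

#' Fisher exact over-representation test with enrichment factor
#'
#' One-sided hypergeometric tail for over-representation of a term in a
#' selection relative to a background, plus the ratio of proportions as
#' the enrichment factor.
#'
#' @param selection_size,selection_in_term Counts in the selection.
#' @param background_size,background_in_term Counts in the background.
#' @return A list with `enrichment_factor` (NA when the term is absent
#'   from the background) and `p`.
#' @export
fisher_exact_enrichment <- function(selection_size, selection_in_term,
                                    background_size, background_in_term) {
  stopifnot(selection_in_term <= selection_size,
            selection_size <= background_size,
            selection_in_term <= background_in_term,
            background_in_term <= background_size)
  ef <- if (background_in_term == 0) NA_real_ else
    (selection_in_term / selection_size) /
      (background_in_term / background_size)
  p <- stats::phyper(selection_in_term - 1L, background_in_term,
                     background_size - background_in_term, selection_size,
                     lower.tail = FALSE)
  list(enrichment_factor = ef, p = p)
}

#' Tukey biweight location estimate
#'
#' Iteratively reweighted robust average. Weights are
#' `(1 - u^2)^2` for `|u| < 1` with `u = (x - t) / (c * (MAD + eps))`,
#' re-centred until the estimate moves less than `tol`. With tuning
#' constant c = 5 roughly the central 5 MADs of the data carry weight,
#' so isolated outliers contribute nothing.
#'
#' @param values Numeric vector with at least one finite value.
#' @param c Tuning constant (default 5).
#' @param eps Stabilizer added to the MAD (default 1e-4).
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 50).
#' @return The location estimate.
#' @export
tukey_biweight_location <- function(values, c = 5, eps = 1e-4,
                                    tol = 1e-6, max_iter = 50L) {
  x <- values[is.finite(values)]
  if (length(x) == 0L) stop("no finite values")
  if (length(x) == 1L) return(x)
  t0 <- stats::median(x)
  for (i in seq_len(max_iter)) {
    s <- stats::mad(x, center = t0) + eps
    u <- (x - t0) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(t0)
    t1 <- sum(w * x) / sum(w)
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}
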