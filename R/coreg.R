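# Batch mean-z engine.
#
# vals: k x N matrix of distinct representative subunit rows.
# idx:  iters x s integer matrix of column indices (one resampled subset
#       per row). Returns one mean z per subset: Spearman rho for every
#       unordered row pair over the subset, Fisher z with +/-0.99
#       clipping, averaged; undefined pairs (zero rank variance) are
#       excluded from the average.
#
# Ranks are computed for all subsets at once by comparison counts
# ((#less + #less-or-equal + 1)/2 gives average ranks), and the Pearson
# correlation of the centred ranks via rowSums. This is what makes
# 10^4-iteration per-complex nulls tractable.
mean_z_batch <- function(vals, idx) {
  k <- nrow(vals)
  iters <- nrow(idx)
  s <- ncol(idx)
  ranked <- vector("list", k)
  for (r in seq_len(k)) {
    X <- matrix(vals[r, t(idx)], iters, s, byrow = TRUE)
    R <- matrix(0, iters, s)
    for (j in seq_len(s)) {
      less <- rowSums(X < X[, j])
      leq <- rowSums(X <= X[, j])
      R[, j] <- (less + leq + 1) / 2
    }
    ranked[[r]] <- R - rowMeans(R)
  }
  ss <- lapply(ranked, function(R) rowSums(R^2))
  zsum <- numeric(iters)
  cnt <- integer(iters)
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      den <- sqrt(ss[[a]] * ss[[b]])
      rho <- ifelse(den > 0, rowSums(ranked[[a]] * ranked[[b]]) / den,
                    NA_real_)
      z <- atanh(pmin(pmax(rho, -0.99), 0.99))
      ok <- is.finite(z)
      zsum[ok] <- zsum[ok] + z[ok]
      cnt[ok] <- cnt[ok] + 1L
    }
  }
  ifelse(cnt > 0L, zsum / cnt, NA_real_)
}

# deterministic per-complex RNG stream seed, kept below 2^31
derive_stream_seed <- function(seed, complex_id) {
  s <- ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((s + (as.numeric(complex_id) * 10007) %% 1048573) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Mean z score (assembly score) of a complex on a sample subset
#'
#' For every unordered pair of distinct representative subunit rows, the
#' Spearman correlation over the given samples is Fisher z-transformed
#' (clipped at +/-0.99) and the z scores are averaged. Pairs with
#' undefined correlation (a constant vector) are excluded and counted.
#' Pairs arising from one protein group representing several subunits do
#' not occur, because pairs are formed over distinct rows (no
#' self-pairs).
#'
#' @param qm `quant_matrix`.
#' @param mapped_complex One row of a mapped-complex data.frame.
#' @param sample_subset Character or integer vector of >= 3 samples.
#' @return List with `mean_z` (NA when every pair is undefined),
#'   `pair_z` (data.frame: pair, rho, z), and `n_excluded_pairs`.
#' @export
complex_mean_z <- function(qm, mapped_complex, sample_subset) {
  rows <- mapped_complex$rows[[1]]
  if (length(rows) < 2L) stop("complex needs >=2 distinct quantified rows")
  if (length(sample_subset) < 3L) stop("sample subset needs >=3 samples")
  vals <- qm$values[rows, sample_subset, drop = FALSE]
  pairs <- utils::combn(rows, 2L)
  rho <- apply(pairs, 2, function(pr)
    spearman_rho(vals[pr[1], ], vals[pr[2], ]))
  z <- fisher_z(rho)
  pair_z <- data.frame(
    complex_id = mapped_complex$complex_id,
    pair = apply(apply(pairs, 2, sort), 2, paste, collapse = "|"),
    rho = rho, z = z, stringsAsFactors = FALSE)
  ok <- is.finite(z)
  list(mean_z = if (any(ok)) mean(z[ok]) else NA_real_,
       pair_z = pair_z,
       n_excluded_pairs = sum(!ok))
}

#' Resampling null of mean z score differences for one complex
#'
#' Per iteration, two disjoint subsets of `subset_size` samples are drawn
#' without replacement from the pooled samples as conditions A and B, and
#' the difference of the complex's mean z scores between them is
#' recorded. The draws are reproducible: the RNG stream is derived
#' deterministically from `(seed, complex_id)`.
#'
#' @param qm `quant_matrix`.
#' @param mapped_complex One mapped-complex row.
#' @param pooled_samples Samples to resample from (>= 2 * subset_size).
#' @param subset_size Samples per condition (default 8).
#' @param iterations Number of resampling iterations (default 10000).
#' @param seed Master seed.
#' @param keep_samples Retain the null draws in the summary.
#' @return A [null_summary()] of the mean z score differences.
#' @export
null_mean_z_differences <- function(qm, mapped_complex, pooled_samples,
                                    subset_size = 8L, iterations = 10000L,
                                    seed = 1L, keep_samples = FALSE) {
  if (iterations < 1L) stop("iterations must be >= 1")
  n_pool <- length(pooled_samples)
  if (n_pool < 2L * subset_size)
    stop("need at least ", 2L * subset_size, " pooled samples")
  rows <- mapped_complex$rows[[1]]
  vals <- qm$values[rows, pooled_samples, drop = FALSE]
  idx <- with_seed(derive_stream_seed(seed, mapped_complex$complex_id), {
    t(vapply(seq_len(iterations),
             function(i) sample.int(n_pool, 2L * subset_size),
             integer(2L * subset_size)))
  })
  za <- mean_z_batch(vals, idx[, seq_len(subset_size), drop = FALSE])
  zb <- mean_z_batch(vals, idx[, subset_size + seq_len(subset_size),
                               drop = FALSE])
  null_summary(samples = za - zb, n_iterations = iterations,
               keep_samples = keep_samples)
}

#' Differential co-regulation test for a set of complexes
#'
#' For each complex (which should already have passed the PPI-coverage
#' filter), the observed statistic is the difference of mean z scores
#' between the two comparison groups. Its significance comes from the
#' per-complex resampling null: `p_normal` is the two-tailed tail
#' probability under a normal with mean 0 and the null's empirical SD
#' (finer resolution than 1/iterations), and `p_empirical` is
#' `(1 + #(|null| >= |observed|)) / (1 + iterations)`. Storey q-values
#' are computed over the `p_normal` vector. A complex is `up` when
#' q < `q_cutoff` and the observed difference exceeds the effect-size
#' cutoff, which by default is derived from the pooled SD of all null
#' draws at two-sided p < 0.1 (see [derive_coreg_cutoff()]); pass
#' `cutoff` to fix it (e.g. 0.7).
#'
#' @param qm Normalized, exclusion-applied `quant_matrix`.
#' @param mapped PPI-coverage-filtered, deduplicated mapped complexes.
#' @param design Sample design.
#' @param comparison Two group labels (effect = first minus second).
#' @param iterations Resampling iterations per complex (default 10000).
#' @param seed Master seed; per-complex streams are derived from it.
#' @param q_cutoff Significance cutoff (default 0.05).
#' @param cutoff Optional fixed effect-size cutoff on the mean z
#'   difference.
#' @param subset_size Samples per resampled condition; defaults to the
#'   comparison group size and must equal it.
#' @param keep_null Retain per-complex null draws (audit; memory-heavy).
#' @return data.frame with per-group mean z, `observed_difference`, null
#'   moments, `p_normal`, `p_empirical`, `q`, `status`; the applied
#'   cutoff and the derived-cutoff detail are attached as attributes.
#' @export
test_complex_coregulation <- function(qm, mapped, design, comparison,
                                      iterations = 10000L, seed = 1L,
                                      q_cutoff = 0.05, cutoff = NULL,
                                      subset_size = NULL, keep_null = FALSE) {
  cols <- comparison_columns(design, comparison, colnames(qm$values))
  sizes <- lengths(cols)
  if (is.null(subset_size)) subset_size <- sizes[[1]]
  if (any(sizes != subset_size))
    stop("comparison group sizes (", paste(sizes, collapse = ", "),
         ") must equal subset_size (", subset_size,
         "): the null must match the design")
  pooled <- colnames(qm$values)

  n <- nrow(mapped)
  mz_a <- mz_b <- null_mean <- null_sd <- p_emp <- numeric(n)
  n_pairs <- integer(n)
  nulls <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- mapped[i, ]
    a <- complex_mean_z(qm, cx, cols[[1]])
    b <- complex_mean_z(qm, cx, cols[[2]])
    mz_a[i] <- a$mean_z
    mz_b[i] <- b$mean_z
    n_pairs[i] <- nrow(a$pair_z)
    ns <- null_mean_z_differences(qm, cx, pooled, subset_size = subset_size,
                                  iterations = iterations, seed = seed,
                                  keep_samples = TRUE)
    null_mean[i] <- ns$mean
    null_sd[i] <- ns$sd
    obs <- a$mean_z - b$mean_z
    p_emp[i] <- (1 + sum(abs(ns$samples) >= abs(obs), na.rm = TRUE)) /
      (1 + length(ns$samples))
    nulls[[i]] <- if (keep_null) ns else
      null_summary(mean = ns$mean, sd = ns$sd, n_iterations = ns$n_iterations)
  }
  observed <- mz_a - mz_b
  p_normal <- vapply(seq_len(n), function(i)
    normal_tail_p(observed[i], list(mean = 0, sd = null_sd[i])), 0)
  q <- storey_qvalues(p_normal)
  derived <- derive_coreg_cutoff(nulls, alpha = 0.10)
  if (is.null(cutoff)) cutoff <- derived$cutoff
  out <- data.frame(complex_id = mapped$complex_id, name = mapped$name,
                    k = mapped$k, n = mapped$n,
                    ppi_coverage = mapped$ppi_coverage,
                    n_pairs = n_pairs,
                    comparison = paste(comparison, collapse = "_vs_"),
                    stringsAsFactors = FALSE)
  out[[paste0("mean_z_", comparison[1])]] <- mz_a
  out[[paste0("mean_z_", comparison[2])]] <- mz_b
  out$observed_difference <- observed
  out$null_mean <- null_mean
  out$null_sd <- null_sd
  out$p_normal <- p_normal
  out$p_empirical <- p_emp
  out$q <- q$q_values
  out$status <- assign_status(out$q, out$observed_difference, q_cutoff,
                              cutoff)
  attr(out, "cutoff") <- cutoff
  attr(out, "derived_cutoff") <- derived
  attr(out, "pi0_estimate") <- q$pi0_estimate
  if (keep_null) attr(out, "nulls") <- nulls
  out
}

#' Effect-size cutoff from the pooled co-regulation null
#'
#' Pools the null mean z score differences across all complexes and
#' converts the pooled SD into a cutoff exceeded with two-sided
#' probability `alpha` under a normal null (the paper-style usage: pooled
#' SD 0.428 at alpha 0.10 gives 0.70). The pooled SD is computed exactly
#' from per-complex moments, equal to the SD of the concatenated draws.
#'
#' @param null_summaries List of [null_summary()] objects (>= 1).
#' @param alpha Two-sided tail probability (default 0.10).
#' @return List with `pooled_sd`, `cutoff`, `cutoff_2dp`.
#' @export
derive_coreg_cutoff <- function(null_summaries, alpha = 0.10) {
  if (length(null_summaries) == 0L) stop("need at least one null summary")
  n_i <- vapply(null_summaries, function(s)
    if (!is.null(s$samples)) length(s$samples) else s$n_iterations, 0)
  m_i <- vapply(null_summaries, `[[`, 0, "mean")
  sd_i <- vapply(null_summaries, `[[`, 0, "sd")
  N <- sum(n_i)
  grand_mean <- sum(n_i * m_i) / N
  total_ss <- sum(sd_i^2 * (n_i - 1) + n_i * m_i^2)
  pooled_sd <- sqrt((total_ss - N * grand_mean^2) / (N - 1))
  th <- normal_threshold(pooled_sd, alpha)
  list(pooled_sd = pooled_sd, cutoff = th$cutoff,
       cutoff_2dp = th$cutoff_2dp)
}
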