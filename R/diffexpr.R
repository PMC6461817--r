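# Row-wise pooled-variance t statistics; shared by the protein- and
# complex-level tests. Rows with zero pooled variance get p = 1 (warned,
# never dropped).
row_t_test <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  p <- 2 * stats::pt(abs(t), df = na + nb - 2, lower.tail = FALSE)
  degen <- !is.finite(t)
  if (any(degen)) {
    warning(sum(degen), " row(s) with zero pooled variance: p set to 1")
    t[degen] <- 0
    p[degen] <- 1
  }
  list(mean_a = ma, mean_b = mb, t = t, p = p)
}

assign_status <- function(q, effect, q_cutoff, effect_cutoff) {
  ifelse(q < q_cutoff & effect > effect_cutoff, "up",
         ifelse(q < q_cutoff & effect < -effect_cutoff, "down", "ns"))
}

comparison_columns <- function(design, comparison, samples) {
  stopifnot(length(comparison) == 2L)
  d <- design_samples(design, include_excluded = FALSE)
  d <- d[d$sample_id %in% samples, , drop = FALSE]
  cols <- lapply(comparison, function(g) d$sample_id[d$group == g])
  if (any(lengths(cols) < 2L))
    stop("comparison groups need >=2 analyzed samples: ",
         paste(comparison, collapse = " vs "))
  names(cols) <- comparison
  cols
}

#' Protein-level differential expression
#'
#' Two-tailed pooled-variance t test per protein group between the two
#' groups of `comparison` (effect = mean of the first minus mean of the
#' second, in log2 units), with Storey q-values over the comparison's
#' p-vector. A protein is `up` when q < `q_cutoff` and log2FC >
#' `fc_cutoff`, `down` symmetrically, otherwise `ns`.
#'
#' @param qm Normalized, complete-case, exclusion-applied `quant_matrix`.
#' @param design Sample design.
#' @param comparison Character vector of two group labels, e.g.
#'   `c("LG", "N")`.
#' @param q_cutoff,fc_cutoff Significance and effect-size cutoffs
#'   (defaults 0.05 and 0.5).
#' @return data.frame with one row per protein group: means, `log2fc`,
#'   `t`, `p`, `q`, `status`.
#' @export
test_proteins <- function(qm, design, comparison, q_cutoff = 0.05,
                          fc_cutoff = 0.5) {
  cols <- comparison_columns(design, comparison, colnames(qm$values))
  tt <- row_t_test(qm$values[, cols[[1]], drop = FALSE],
                   qm$values[, cols[[2]], drop = FALSE])
  q <- storey_qvalues(tt$p)
  out <- data.frame(protein_group_id = qm$protein_groups$group_id,
                    accessions = vapply(qm$protein_groups$accessions,
                                        paste, "", collapse = ";"),
                    comparison = paste(comparison, collapse = "_vs_"),
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", comparison[1])]] <- tt$mean_a
  out[[paste0("mean_", comparison[2])]] <- tt$mean_b
  out$log2fc <- tt$mean_a - tt$mean_b
  out$t <- tt$t
  out$p <- tt$p
  out$q <- q$q_values
  out$status <- assign_status(out$q, out$log2fc, q_cutoff, fc_cutoff)
  attr(out, "pi0_estimate") <- q$pi0_estimate
  out
}

#' Per-sample mean profile of a complex
#'
#' The unweighted arithmetic mean of the representative subunit rows of
#' one mapped complex, per sample.
#'
#' @param qm `quant_matrix`.
#' @param mapped_complex One row of a mapped-complex data.frame.
#' @return Named numeric vector (one value per sample).
#' @export
complex_mean_profile <- function(qm, mapped_complex) {
  rows <- mapped_complex$rows[[1]]
  missing <- setdiff(rows, rownames(qm$values))
  if (length(missing))
    stop("subunit row(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  colMeans(qm$values[rows, , drop = FALSE])
}

complex_profile_matrix <- function(qm, mapped) {
  profs <- t(vapply(seq_len(nrow(mapped)),
                    function(i) complex_mean_profile(qm, mapped[i, ]),
                    numeric(ncol(qm$values))))
  rownames(profs) <- as.character(mapped$complex_id)
  profs
}

#' Complex-level differential expression
#'
#' Per-sample subunit mean profiles are compared between the two groups
#' with the pooled-variance t test; Storey q-values are computed over all
#' tested complexes. The effect-size cutoff defaults to the one derived
#' from the observed distribution of mean differences (see
#' [derive_expression_cutoff()]); pass `cutoff` to fix it (e.g. 0.31).
#'
#' @param qm Normalized `quant_matrix`.
#' @param mapped Filtered, deduplicated mapped complexes.
#' @param design Sample design.
#' @param comparison Two group labels.
#' @param q_cutoff Significance cutoff (default 0.05).
#' @param cutoff Optional fixed effect-size cutoff in log2 units.
#' @param alpha Tail probability used when deriving the cutoff (0.05).
#' @param robust_sd Use the MAD-based SD when deriving the cutoff.
#' @return data.frame: complex id/name, k, n, coverages, per-group means,
#'   `mean_difference`, `t`, `p`, `q`, `status`, plus the applied cutoff
#'   in the `cutoff` attribute.
#' @export
test_complexes <- function(qm, mapped, design, comparison, q_cutoff = 0.05,
                           cutoff = NULL, alpha = 0.05, robust_sd = TRUE) {
  cols <- comparison_columns(design, comparison, colnames(qm$values))
  profs <- complex_profile_matrix(qm, mapped)
  tt <- row_t_test(profs[, cols[[1]], drop = FALSE],
                   profs[, cols[[2]], drop = FALSE])
  diffs <- tt$mean_a - tt$mean_b
  derived <- if (is.null(cutoff))
    derive_expression_cutoff(diffs, alpha = alpha, robust = robust_sd)
  if (is.null(cutoff)) cutoff <- derived$cutoff
  q <- storey_qvalues(tt$p)
  out <- data.frame(complex_id = mapped$complex_id, name = mapped$name,
                    k = mapped$k, n = mapped$n,
                    subunit_coverage = mapped$subunit_coverage,
                    comparison = paste(comparison, collapse = "_vs_"),
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", comparison[1])]] <- tt$mean_a
  out[[paste0("mean_", comparison[2])]] <- tt$mean_b
  out$mean_difference <- diffs
  out$t <- tt$t
  out$p <- tt$p
  out$q <- q$q_values
  out$status <- assign_status(out$q, out$mean_difference, q_cutoff, cutoff)
  attr(out, "cutoff") <- cutoff
  attr(out, "derived_cutoff") <- derived
  attr(out, "pi0_estimate") <- q$pi0_estimate
  out
}

#' Derive the complex-expression effect-size cutoff
#'
#' Fits a normal scale to the observed complex mean differences and
#' returns the value exceeded with two-sided probability `alpha` under
#' that null: `qnorm(1 - alpha/2) * SD`. The SD is estimated robustly
#' (MAD scaled to the normal SD) by default so genuinely changed
#' complexes do not inflate it; set `robust = FALSE` for the plain SD.
#'
#' @param mean_differences Numeric vector (>= 10 values) of observed
#'   complex mean differences.
#' @param alpha Two-sided tail probability (default 0.05).
#' @param robust Use MAD-based SD (default TRUE).
#' @return List with `sd`, `cutoff` (raw) and `cutoff_2dp`.
#' @export
derive_expression_cutoff <- function(mean_differences, alpha = 0.05,
                                     robust = TRUE) {
  x <- mean_differences[is.finite(mean_differences)]
  if (length(x) < 10L) stop("need at least 10 mean differences")
  s <- if (robust) stats::mad(x) else stats::sd(x)
  th <- normal_threshold(s, alpha)
  list(sd = s, cutoff = th$cutoff, cutoff_2dp = th$cutoff_2dp)
}
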