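# Simulation-based operating characteristics of the pipeline, computed
# on synthetic data with known planted truth. These back the package's
# validation claims and the analysis scripts; they run the same exported
# stage functions as a real analysis.

# shared scaffolding: generate a scenario, push it through ingest ->
# ratios -> normalize -> complete cases -> exclusions -> mapping
prepare_scenario <- function(cat, data) {
  design <- read_design(data$design)
  raw <- suppressMessages(ingest_protein_groups(data$protein_groups_table,
                                                design))
  qm <- apply_sample_exclusions(
    filter_complete_cases(normalize_samples(compute_log2_ratios(raw, design))),
    design)
  mapped <- map_quantified_proteins(cat$catalog, qm$protein_groups, qm$values)
  list(qm = qm, design = design, mapped = mapped)
}

#' Type-I error of the co-regulation test on null data
#'
#' Generates a dataset with no planted effects (independent noise within
#' every complex), runs the differential co-regulation test for one
#' comparison, and reports the fraction of complexes with normal-fit
#' p < `alpha`. On exchangeable noise this should sit near `alpha`.
#'
#' @param n_complexes Number of null complexes (default 400).
#' @param subunit_size_range Complex sizes (default c(3, 4)).
#' @param iterations Resampling iterations per complex (default 2000).
#' @param comparison Two group labels (default c("LG", "N")).
#' @param seed RNG seed.
#' @param alpha Nominal level (default 0.05).
#' @return List with `rate`, `n_complexes`, `alpha`, and the result table.
#' @export
validate_coreg_type1 <- function(n_complexes = 400L,
                                 subunit_size_range = c(3L, 4L),
                                 iterations = 2000L,
                                 comparison = c("LG", "N"), seed = 1L,
                                 alpha = 0.05) {
  cat <- generate_catalog(n_complexes, subunit_size_range,
                          n_background_proteins = 100L, seed = seed)
  truth <- synthetic_truth(noise_sd = 0.3, seed = seed)
  data <- generate_quant_matrix(cat, truth, seed = seed)
  sc <- prepare_scenario(cat, data)
  eligible <- filter_complexes(deduplicate_complexes(
    filter_complexes(sc$mapped)), min_ppi_coverage = 0.5)
  res <- test_complex_coregulation(sc$qm, eligible, sc$design, comparison,
                                   iterations = iterations, seed = seed)
  list(rate = mean(res$p_normal < alpha), n_complexes = nrow(res),
       alpha = alpha, result = res)
}

#' Recovery of planted effects in a mixed scenario
#'
#' Builds a mixed dataset: `n_coreg` complexes of `coreg_subunits`
#' subunits with a planted latent factor giving within-group Pearson
#' correlation `target_rho` in one group and none in the other,
#' `n_expr` complexes with a complex-wide expression shift of
#' `expr_shift` log2 units in the same group, and `n_null` unaffected
#' complexes. Runs the complex expression and co-regulation tests for
#' that comparison and reports the fraction of planted complexes
#' recovered.
#'
#' @param n_coreg,n_expr,n_null Complex counts (defaults 50/50/200; planted
#'   complexes are a minority, as in real complex catalogs).
#' @param coreg_subunits Subunits per co-regulation-planted complex (6).
#' @param target_rho Planted within-group Pearson correlation (0.85).
#' @param expr_shift Planted complex-wide shift in log2 units (0.6).
#' @param group Group carrying the planted effects (default "LG");
#'   tested against "N".
#' @param iterations Resampling iterations (default 2000).
#' @param seed RNG seed.
#' @return List with `coreg_power` (fraction of planted co-regulation
#'   complexes at q < 0.05), `coreg_power_status` (also beyond the
#'   effect-size cutoff), `expression_power` (fraction of planted
#'   expression complexes with status != ns), `coreg_false_hits`,
#'   `expression_false_hits`, and the two result tables.
#' @export
validate_recovery <- function(n_coreg = 50L, n_expr = 50L, n_null = 200L,
                              coreg_subunits = 6L, target_rho = 0.85,
                              expr_shift = 0.6, group = "LG",
                              iterations = 2000L, seed = 1L) {
  n_total <- n_coreg + n_expr + n_null
  cat <- generate_catalog(n_total, c(coreg_subunits, coreg_subunits),
                          n_background_proteins = 200L, seed = seed)
  coreg_ids <- seq_len(n_coreg)
  expr_ids <- n_coreg + seq_len(n_expr)
  truth <- synthetic_truth(
    de_complexes = data.frame(complex_id = expr_ids, group = group,
                              shift = expr_shift),
    coreg_complexes = data.frame(
      complex_id = coreg_ids, group = group,
      lambda = lambda_for_correlation(target_rho, 0.3)),
    noise_sd = 0.3, seed = seed)
  data <- generate_quant_matrix(cat, truth, seed = seed)
  sc <- prepare_scenario(cat, data)
  expr_set <- deduplicate_complexes(filter_complexes(sc$mapped))
  coreg_set <- filter_complexes(expr_set, min_ppi_coverage = 0.5)
  comparison <- c(group, "N")
  expr_res <- test_complexes(sc$qm, expr_set, sc$design, comparison)
  coreg_res <- test_complex_coregulation(sc$qm, coreg_set, sc$design,
                                         comparison,
                                         iterations = iterations,
                                         seed = seed)
  planted_coreg <- coreg_res$complex_id %in% coreg_ids
  planted_expr <- expr_res$complex_id %in% expr_ids
  list(
    coreg_power = mean(coreg_res$q[planted_coreg] < 0.05),
    coreg_power_status = mean(coreg_res$status[planted_coreg] == "up"),
    expression_power = mean(expr_res$status[planted_expr] == "up"),
    coreg_false_hits = sum(coreg_res$status[!planted_coreg] != "ns"),
    expression_false_hits = sum(expr_res$status[!planted_expr &
                                !(expr_res$complex_id %in% coreg_ids)] != "ns"),
    expression = expr_res, coreg = coreg_res)
}
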