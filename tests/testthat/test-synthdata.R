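test_that("injected duplicate complexes are removed exactly by deduplication", {
  cat <- generate_catalog(10, c(3, 4), duplication_cases = 3, seed = 31)
  expect_equal(nrow(cat$catalog), 13)
  pg <- data.frame(group_id = cat$proteins, stringsAsFactors = FALSE)
  pg$accessions <- as.list(cat$proteins)
  mapped <- map_quantified_proteins(cat$catalog, pg)
  dedup <- deduplicate_complexes(mapped)
  expect_equal(nrow(mapped) - nrow(dedup), 3)
  expect_false(any(cat$duplicate_ids %in% dedup$complex_id))
  # kept originals have the higher subunit coverage
  expect_true(all(dedup$subunit_coverage[dedup$complex_id %in% 1:3] == 1))
})

test_that("empty catalogs are valid and seeded generation is byte-identical", {
  dir0 <- withr::local_tempdir()
  empty <- generate_catalog(0, c(3, 4), n_background_proteins = 5,
                            seed = 1, dir = dir0)
  expect_equal(nrow(empty$catalog), 0)
  parsed <- parse_complex_catalog(file.path(dir0, "complexes.tsv"))
  expect_equal(nrow(parsed), 0)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_fixtures(d1, "mixed", seed = 5)
  f2 <- write_fixtures(d2, "mixed", seed = 5)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = paste("file", nm))
  d3 <- withr::local_tempdir()
  f3 <- write_fixtures(d3, "mixed", seed = 6)
  expect_false(identical(readLines(f1[["protein_groups"]]),
                         readLines(f3[["protein_groups"]])))
})

test_that("truth manifests round-trip losslessly", {
  truth <- synthetic_truth(
    de_proteins = data.frame(accession = c("P00001", "P00002"),
                             group = "LG", shift = c(1, -0.5),
                             stringsAsFactors = FALSE),
    de_complexes = data.frame(complex_id = 3L, group = "HG", shift = 0.6),
    coreg_complexes = data.frame(complex_id = c(1L, 2L), group = "LG",
                                 lambda = 0.7),
    noise_sd = 0.25, missing_rate = 0.05, seed = 99L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$de_proteins, truth$de_proteins)
  expect_equal(back$de_complexes, truth$de_complexes)
  expect_equal(back$coreg_complexes, truth$coreg_complexes)
  expect_equal(back$noise_sd, truth$noise_sd)
  expect_equal(back$missing_rate, truth$missing_rate)
  expect_error(synthetic_truth(coreg_complexes = data.frame(
    complex_id = 1L, group = "LG", lambda = -1)), "nonnegative")
})

test_that("design marks the configured exclusions and group sizes", {
  sc <- build_scenario("null_only", seed = 1)
  d <- sc$data$design
  expect_equal(sum(d$is_internal_standard), 3)
  expect_equal(sum(!d$is_internal_standard & !d$excluded), 24)
  for (g in c("N", "LG", "HG"))
    expect_equal(sum(d$group == g & !d$excluded), 8)
  # truth manifest of the null scenario is empty
  expect_equal(nrow(sc$data$truth$de_proteins), 0)
  expect_equal(nrow(sc$data$truth$coreg_complexes), 0)
  expect_error(build_scenario("not_a_scenario"), "null_only")
})

test_that("latent-factor loadings produce the closed-form correlation at large n", {
  lam <- lambda_for_correlation(0.85, 0.3)
  expect_equal(lam^2 / (lam^2 + 0.3^2), 0.85, tolerance = 1e-12)

  cat <- generate_catalog(4, c(6, 6), n_background_proteins = 200, seed = 32)
  truth <- synthetic_truth(
    coreg_complexes = data.frame(complex_id = 1:2, group = "LG",
                                 lambda = lam),
    noise_sd = 0.3, seed = 32)
  data <- generate_quant_matrix(cat, truth, n_per_group = 200L,
                                n_excluded_per_group = 0L, n_sets = 1L,
                                seed = 32, n_decoy_rows = 0L)
  design <- data$design
  lg <- design$sample_id[design$group == "LG"]
  tab <- data$protein_groups_table
  subs <- cat$catalog$subunits[[1]]
  # remove the per-sample loading offsets (constant within a column)
  # before correlating, as ratio normalization does in the pipeline
  all_logs <- log2(as.matrix(tab[, design$sample_id]))
  all_logs <- sweep(all_logs, 2, apply(all_logs, 2, median))
  logs <- all_logs[match(subs, tab[["Majority protein IDs"]]), lg]
  C <- cor(t(logs))
  mean_rho <- mean(C[upper.tri(C)])
  expect_equal(mean_rho, 0.85, tolerance = 0.06)
  # Spearman attenuation follows the bivariate-normal closed form
  S <- cor(t(logs), method = "spearman")
  expect_equal(mean(S[upper.tri(S)]), spearman_from_pearson(0.85),
               tolerance = 0.06)
  # no planted correlation in the N group
  nn <- design$sample_id[design$group == "N"]
  logs_n <- all_logs[match(subs, tab[["Majority protein IDs"]]), nn]
  Cn <- cor(t(logs_n))
  expect_lt(abs(mean(Cn[upper.tri(Cn)])), 0.12)
})

test_that("paper-scale scenario matches the study's shape", {
  sc <- build_scenario("paper_scale", seed = 2)
  expect_equal(sum(sc$data$protein_groups_table$Reverse != "+"), 3642)
  expect_equal(sum(!sc$data$design$is_internal_standard), 27)
  expect_equal(nrow(sc$cat$catalog), 500)
})

test_that("missingness is injected at the requested rate and propagates", {
  cat <- generate_catalog(10, c(3, 4), n_background_proteins = 500, seed = 33)
  truth <- synthetic_truth(noise_sd = 0.3, missing_rate = 0.1, seed = 33)
  data <- generate_quant_matrix(cat, truth, seed = 33)
  design <- read_design(data$design)
  raw <- suppressMessages(ingest_protein_groups(data$protein_groups_table,
                                                design))
  smp <- design$sample_id[!design$is_internal_standard]
  rate <- mean(is.na(raw$values[, smp]))
  expect_lt(abs(rate - 0.1), 0.02)
  qm <- filter_complete_cases(compute_log2_ratios(raw, design))
  direct <- sum(rowSums(is.na(raw$values[, smp])) == 0)
  expect_equal(nrow(qm$values), direct)
  # survival scale matches the binomial expectation
  expect_equal(nrow(qm$values) / nrow(raw$values), 0.9^27, tolerance = 0.05)
})
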