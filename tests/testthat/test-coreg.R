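test_that("complex mean z equals brute-force enumeration over all pairs", {
  vals <- noise_matrix(6, 12, seed = 21)
  qm <- make_qm(vals)
  subset <- paste0("s", 1:8)
  for (k in c(2, 4, 6)) {
    rows <- paste0("r", 1:k)
    res <- complex_mean_z(qm, make_mapped(rows), subset)
    # independent oracle: enumerate all pairs with the scalar primitives
    zs <- c()
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      zs <- c(zs, fisher_z(spearman_rho(vals[rows[i], 1:8],
                                        vals[rows[j], 1:8])))
    }
    expect_equal(res$mean_z, mean(zs), tolerance = 1e-12)
    expect_equal(nrow(res$pair_z), k * (k - 1) / 2)
    expect_equal(sort(res$pair_z$z), sort(zs), tolerance = 1e-12)
  }
  # 2-subunit complex: mean z is the single pair's z
  res <- complex_mean_z(qm, make_mapped(c("r1", "r2")), subset)
  expect_equal(res$mean_z, res$pair_z$z[1])
})

test_that("constant subunits yield undefined pairs that are excluded and counted", {
  vals <- noise_matrix(3, 8, seed = 22)
  vals[2, ] <- 5
  qm <- make_qm(vals)
  res <- complex_mean_z(qm, make_mapped(paste0("r", 1:3)), paste0("s", 1:8))
  expect_equal(res$n_excluded_pairs, 2)
  expect_equal(res$mean_z,
               fisher_z(spearman_rho(vals[1, ], vals[3, ])))
  vals[3, ] <- 2
  res <- complex_mean_z(make_qm(vals), make_mapped(paste0("r", 2:3)),
                        paste0("s", 1:8))
  expect_true(is.na(res$mean_z))
})

test_that("the batch rank engine agrees with the scalar path on random subsets", {
  vals <- noise_matrix(5, 24, seed = 23)
  qm <- make_qm(vals)
  mc <- make_mapped(paste0("r", 1:5))
  withr::with_seed(24, {
    idx <- t(replicate(40, sample.int(24, 8)))
  })
  batch <- plexdiff:::mean_z_batch(vals, idx)
  scalar <- vapply(seq_len(nrow(idx)), function(i)
    complex_mean_z(qm, mc, paste0("s", idx[i, ]))$mean_z, 0)
  expect_equal(batch, scalar, tolerance = 1e-12)
  # ties are ranked identically too
  vals_t <- round(vals, 1)
  batch_t <- plexdiff:::mean_z_batch(vals_t, idx)
  scalar_t <- vapply(seq_len(nrow(idx)), function(i)
    complex_mean_z(make_qm(vals_t), mc, paste0("s", idx[i, ]))$mean_z, 0)
  expect_equal(batch_t, scalar_t, tolerance = 1e-12)
})

test_that("mean z is invariant under monotone per-sample transforms of all rows", {
  vals <- noise_matrix(4, 10, seed = 25)
  mc <- make_mapped(paste0("r", 1:4))
  sub <- paste0("s", 1:10)
  z0 <- complex_mean_z(make_qm(vals), mc, sub)$mean_z
  expect_equal(complex_mean_z(make_qm(vals^3 + vals), mc, sub)$mean_z, z0)
  expect_equal(complex_mean_z(make_qm(exp(vals)), mc, sub)$mean_z, z0)
})

test_that("resampling null is reproducible, centred, and guarded", {
  vals <- noise_matrix(4, 24, seed = 26)
  qm <- make_qm(vals)
  mc <- make_mapped(paste0("r", 1:4))
  n1 <- null_mean_z_differences(qm, mc, colnames(vals), iterations = 500,
                                seed = 7, keep_samples = TRUE)
  n2 <- null_mean_z_differences(qm, mc, colnames(vals), iterations = 500,
                                seed = 7, keep_samples = TRUE)
  expect_identical(n1$samples, n2$samples)
  n3 <- null_mean_z_differences(qm, mc, colnames(vals), iterations = 500,
                                seed = 8, keep_samples = TRUE)
  expect_false(identical(n1$samples, n3$samples))
  # CLT bound on the null mean
  expect_lt(abs(n1$mean), 4 * n1$sd / sqrt(n1$n_iterations))
  expect_error(null_mean_z_differences(qm, mc, colnames(vals),
                                       iterations = 0), "iterations")
  expect_error(null_mean_z_differences(qm, mc, paste0("s", 1:10)),
               "at least 16")
})

test_that("co-regulation test is antisymmetric in the comparison order", {
  design <- make_design(8, 8)
  vals <- noise_matrix(8, 16, seed = 27)
  colnames(vals) <- design$sample_id[-1]
  qm <- make_qm(vals)
  mapped <- rbind(make_mapped(paste0("r", 1:4), 1),
                  make_mapped(paste0("r", 5:8), 2))
  a <- test_complex_coregulation(qm, mapped, design, c("LG", "N"),
                                 iterations = 300, seed = 5)
  b <- test_complex_coregulation(qm, mapped, design, c("N", "LG"),
                                 iterations = 300, seed = 5)
  expect_equal(b$observed_difference, -a$observed_difference)
  expect_equal(b$p_normal, a$p_normal)
  expect_error(
    test_complex_coregulation(qm, mapped, design, c("LG", "N"),
                              iterations = 100, subset_size = 5),
    "must equal subset_size")
})

test_that("co-regulation is decoupled from expression shifts", {
  design <- make_design(8, 8)
  vals <- noise_matrix(4, 16, seed = 28)
  colnames(vals) <- design$sample_id[-1]
  mapped <- make_mapped(paste0("r", 1:4))
  lg <- design$sample_id[design$group == "LG"]
  shifted <- vals
  shifted[, lg] <- shifted[, lg] + 2  # strong expression change
  a <- test_complex_coregulation(make_qm(vals), mapped, design,
                                 c("LG", "N"), iterations = 200, seed = 6)
  b <- test_complex_coregulation(make_qm(shifted), mapped, design,
                                 c("LG", "N"), iterations = 200, seed = 6)
  # per-group mean z and the observed difference are rank-based within
  # groups, hence unchanged
  expect_equal(b$mean_z_LG, a$mean_z_LG)
  expect_equal(b$mean_z_N, a$mean_z_N)
  expect_equal(b$observed_difference, a$observed_difference)
  # while the expression test moves by the planted shift
  ea <- test_complexes(make_qm(vals), make_mapped(paste0("r", 1:4)),
                       design, c("LG", "N"), cutoff = 0.31)
  eb <- test_complexes(make_qm(shifted), make_mapped(paste0("r", 1:4)),
                       design, c("LG", "N"), cutoff = 0.31)
  expect_equal(eb$mean_difference, ea$mean_difference + 2, tolerance = 1e-12)
})

test_that("normal-fit and empirical p agree within a factor of 3 on simulated nulls", {
  design <- make_design(8, 8)
  withr::with_seed(29, {
    vals <- matrix(rnorm(40 * 16, 0, 0.3), 40, 16,
                   dimnames = list(paste0("r", 1:40), design$sample_id[-1]))
  })
  mapped <- do.call(rbind, lapply(1:10, function(i)
    make_mapped(paste0("r", (4 * i - 3):(4 * i)), i)))
  res <- test_complex_coregulation(make_qm(vals), mapped, design,
                                   c("LG", "N"), iterations = 2000, seed = 9)
  sel <- res$p_normal > 0.01 & res$p_normal < 0.5
  expect_true(any(sel))
  ratio <- res$p_empirical[sel] / res$p_normal[sel]
  expect_true(all(ratio > 1 / 3 & ratio < 3))
})

test_that("pooled null SD matches the concatenated draws and reproduces 0.70", {
  withr::with_seed(30, {
    draws <- list(rnorm(500, 0.02, 0.3), rnorm(800, -0.01, 0.5),
                  rnorm(300, 0, 0.4))
  })
  nulls <- lapply(draws, null_summary, keep_samples = TRUE)
  pooled <- derive_coreg_cutoff(nulls)
  expect_equal(pooled$pooled_sd, sd(unlist(draws)), tolerance = 1e-12)
  # single summary: pooled sd is its sd
  expect_equal(derive_coreg_cutoff(nulls[1])$pooled_sd, sd(draws[[1]]))
  # the published-style conversion
  th <- derive_coreg_cutoff(list(null_summary(mean = 0, sd = 0.428,
                                              n_iterations = 10000)))
  expect_equal(th$cutoff, 0.704, tolerance = 1e-3)
  expect_equal(th$cutoff_2dp, 0.70)
})
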