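#' Planted-truth manifest for synthetic data
#'
#' Records every effect planted into a synthetic dataset so recovery can
#' be checked: protein-level expression shifts, complex-wide expression
#' shifts, and within-complex co-regulation via per-sample latent factors
#' with group-specific loadings.
#'
#' @param de_proteins data.frame(`accession`, `group`, `shift`) or NULL.
#' @param de_complexes data.frame(`complex_id`, `group`, `shift`) or NULL.
#' @param coreg_complexes data.frame(`complex_id`, `group`, `lambda`) or
#'   NULL; `lambda` >= 0 is the latent-factor loading shared by all
#'   subunits of the complex in that group.
#' @param noise_sd Residual SD in log2 units (default 0.3, a typical
#'   within-group variability for TMT tissue data).
#' @param missing_rate Completely-at-random missingness fraction.
#' @param seed Seed recorded with the truth.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(de_proteins = NULL, de_complexes = NULL,
                            coreg_complexes = NULL, noise_sd = 0.3,
                            missing_rate = 0, seed = 1L) {
  empty <- function(cols) stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  if (is.null(de_proteins)) de_proteins <- empty(c("accession", "group", "shift"))
  if (is.null(de_complexes)) de_complexes <- empty(c("complex_id", "group", "shift"))
  if (is.null(coreg_complexes)) coreg_complexes <- empty(c("complex_id", "group", "lambda"))
  if (nrow(coreg_complexes) && any(coreg_complexes$lambda < 0))
    stop("latent loadings must be nonnegative")
  structure(list(de_proteins = de_proteins, de_complexes = de_complexes,
                 coreg_complexes = coreg_complexes, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = seed),
            class = "synthetic_truth")
}

#' Latent-factor loading for a target within-group correlation
#'
#' With shared factor f ~ N(0,1), loading `lambda` and residual SD
#' `sigma`, two subunits have Pearson correlation
#' lambda^2 / (lambda^2 + sigma^2); this inverts that relation.
#'
#' @param rho Target Pearson correlation in \[0, 1).
#' @param noise_sd Residual SD.
#' @return The loading lambda.
#' @export
lambda_for_correlation <- function(rho, noise_sd = 0.3) {
  stopifnot(rho >= 0, rho < 1)
  noise_sd * sqrt(rho / (1 - rho))
}

#' Expected Spearman correlation of a bivariate normal pair
#'
#' For bivariate normal data with Pearson correlation `rho`, the
#' population Spearman correlation is (6/pi) * asin(rho / 2).
#'
#' @param rho Pearson correlation.
#' @return Spearman correlation.
#' @export
spearman_from_pearson <- function(rho) (6 / pi) * asin(rho / 2)

#' Generate a synthetic complex catalog in the CORUM dialect
#'
#' Builds `n_complexes` complexes with disjoint subunit sets (sizes drawn
#' uniformly from `subunit_size_range`) plus optional background proteins
#' belonging to no complex. `duplication_cases` complexes are duplicated
#' under a new id with two extra never-quantified phantom subunits, so
#' their quantified subunit sets coincide with the originals while their
#' subunit coverage is lower — exercising the redundancy-removal rule.
#'
#' @param n_complexes Number of base complexes.
#' @param subunit_size_range Length-2 integer range of subunit counts
#'   (default c(3, 6); minimum 2).
#' @param n_background_proteins Proteins outside any complex.
#' @param duplication_cases Number of injected duplicate complexes.
#' @param seed RNG seed.
#' @param dir Optional directory: when given, `complexes.tsv` and
#'   `mapping.tsv` are written there.
#' @return List with `catalog` (parsed-form data.frame), `complex_table`
#'   and `mapping_table` (CORUM-dialect data.frames), `proteins` (all
#'   quantifiable accessions), and `duplicate_ids`.
#' @export
generate_catalog <- function(n_complexes, subunit_size_range = c(3L, 6L),
                             n_background_proteins = 0L,
                             duplication_cases = 0L, seed = 1L, dir = NULL) {
  stopifnot(subunit_size_range[1] >= 2L,
            duplication_cases <= n_complexes)
  with_seed(seed, {
    size_choices <- seq.int(subunit_size_range[1], subunit_size_range[2])
    sizes <- if (n_complexes > 0)
      size_choices[sample.int(length(size_choices), n_complexes,
                              replace = TRUE)] else integer(0)
    total <- sum(sizes) + n_background_proteins
    accs <- sprintf("P%05d", seq_len(total))
    subunits <- split(accs[seq_len(sum(sizes))],
                      rep(seq_along(sizes), sizes))
    ids <- seq_len(n_complexes)
    names <- sprintf("synthetic complex %d", ids)
    if (duplication_cases > 0L) {
      for (d in seq_len(duplication_cases)) {
        dup_id <- n_complexes + d
        phantom <- sprintf("PHANTOM%03d_%d", d, seq_len(2L))
        subunits[[length(subunits) + 1L]] <- c(subunits[[d]], phantom)
        ids <- c(ids, dup_id)
        names <- c(names, sprintf("synthetic complex %d (variant of %d)",
                                  dup_id, d))
      }
    }
    o <- order(ids)
    catalog <- data.frame(complex_id = ids[o], name = names[o],
                          stringsAsFactors = FALSE)
    catalog$subunits <- unname(subunits[o])
    complex_table <- data.frame(
      ComplexID = catalog$complex_id,
      ComplexName = catalog$name,
      check.names = FALSE, stringsAsFactors = FALSE)
    complex_table[["subunits(UniProt IDs)"]] <-
      vapply(catalog$subunits, paste, "", collapse = ";")
    mapping_table <- data.frame(
      `UniProt accession` = unlist(catalog$subunits, use.names = FALSE),
      ComplexID = rep(catalog$complex_id, lengths(catalog$subunits)),
      check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(complex_table, file.path(dir, "complexes.tsv"))
      write_tsv(mapping_table, file.path(dir, "mapping.tsv"))
    }
    list(catalog = catalog, complex_table = complex_table,
         mapping_table = mapping_table, proteins = accs,
         duplicate_ids = if (duplication_cases > 0L)
           n_complexes + seq_len(duplication_cases) else integer(0))
  })
}

#' Generate a synthetic protein-group table and sample design
#'
#' Emulates a multi-set isobaric design: `length(groups) * n_per_group`
#' samples spread over TMT sets, each set carrying one pooled
#' internal-standard channel; `n_excluded_per_group` samples per group
#' are marked excluded. The latent log2 ratio of protein p in sample s is
#'
#' `value = baseline_p + shift(p, group) + lambda(complex, group) * f_s + eps`
#'
#' with `f_s` a standard-normal per-sample factor shared by all subunits
#' of a planted complex, and `eps ~ N(0, noise_sd)`. Values are emitted
#' as reporter-style intensities (internal standard at the protein's
#' baseline intensity, samples offset by a per-sample loading error that
#' normalization must remove); missing values are injected at
#' `missing_rate` as zero intensities. A few reverse/contaminant decoy
#' rows exercise the ingest filters.
#'
#' @param cat Output of [generate_catalog()].
#' @param truth A [synthetic_truth()].
#' @param groups Group labels (default c("N", "LG", "HG")).
#' @param n_per_group Samples per group (default 9).
#' @param n_excluded_per_group Samples per group marked excluded
#'   (default 1).
#' @param n_sets Number of TMT sets (default 3).
#' @param seed RNG seed.
#' @param n_decoy_rows Flagged decoy rows to include (default 2).
#' @return List with `protein_groups_table`, `design` (data.frames) and
#'   `truth`.
#' @export
generate_quant_matrix <- function(cat, truth, groups = c("N", "LG", "HG"),
                                  n_per_group = 9L, n_excluded_per_group = 1L,
                                  n_sets = 3L, seed = 1L, n_decoy_rows = 2L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            n_per_group %% n_sets == 0L,
            n_excluded_per_group < n_per_group)
  bad <- setdiff(truth$de_proteins$accession, cat$proteins)
  if (length(bad)) stop("truth references unknown protein(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(c(truth$de_complexes$complex_id,
                   truth$coreg_complexes$complex_id),
                 cat$catalog$complex_id)
  if (length(bad)) stop("truth references unknown complex(es): ",
                        paste(bad, collapse = ", "))

  per_set <- n_per_group / n_sets
  design <- do.call(rbind, lapply(groups, function(g) {
    data.frame(sample_id = paste0(g, seq_len(n_per_group)),
               group = g,
               tmt_set = paste0("S", rep(seq_len(n_sets), each = per_set)),
               stringsAsFactors = FALSE)
  }))
  design <- design[order(design$tmt_set, design$group), ]
  design$channel <- unlist(lapply(split(design$sample_id, design$tmt_set),
                                  function(s) paste0("ch", seq_along(s) + 1L)),
                           use.names = FALSE)
  design$is_internal_standard <- FALSE
  design$excluded <- design$sample_id %in%
    unlist(lapply(groups, function(g)
      paste0(g, n_per_group - seq_len(n_excluded_per_group) + 1L)))
  is_rows <- data.frame(sample_id = paste0("IS_S", seq_len(n_sets)),
                        group = "IS",
                        tmt_set = paste0("S", seq_len(n_sets)),
                        channel = "ch1", is_internal_standard = TRUE,
                        excluded = FALSE, stringsAsFactors = FALSE)
  design <- rbind(is_rows, design)
  rownames(design) <- NULL

  accs <- cat$proteins
  m <- length(accs)
  smp <- design$sample_id[!design$is_internal_standard]
  ns <- length(smp)
  grp <- design$group[match(smp, design$sample_id)]

  with_seed(seed, {
    baseline <- stats::rnorm(m, 0, 1)
    names(baseline) <- accs
    vals <- matrix(stats::rnorm(m * ns, 0, truth$noise_sd), m, ns,
                   dimnames = list(accs, smp))
    vals <- vals + baseline
    if (nrow(truth$de_proteins))
      for (i in seq_len(nrow(truth$de_proteins))) {
        r <- truth$de_proteins[i, ]
        vals[r$accession, grp == r$group] <-
          vals[r$accession, grp == r$group] + r$shift
      }
    subunits_of <- stats::setNames(cat$catalog$subunits,
                                   as.character(cat$catalog$complex_id))
    if (nrow(truth$de_complexes))
      for (i in seq_len(nrow(truth$de_complexes))) {
        r <- truth$de_complexes[i, ]
        subs <- intersect(subunits_of[[as.character(r$complex_id)]], accs)
        vals[subs, grp == r$group] <- vals[subs, grp == r$group] + r$shift
      }
    if (nrow(truth$coreg_complexes)) {
      for (cid in unique(truth$coreg_complexes$complex_id)) {
        f <- stats::rnorm(ns)  # one latent factor per complex and sample
        rows_c <- truth$coreg_complexes[truth$coreg_complexes$complex_id == cid, ]
        subs <- intersect(subunits_of[[as.character(cid)]], accs)
        for (i in seq_len(nrow(rows_c))) {
          sel <- grp == rows_c$group[i]
          vals[subs, sel] <- vals[subs, sel] +
            rows_c$lambda[i] * matrix(f[sel], length(subs), sum(sel),
                                      byrow = TRUE)
        }
      }
    }
    # reporter-style intensities: IS at baseline, samples offset by a
    # per-sample loading error that normalization must remove
    sample_offset <- stats::rnorm(ns, 0, 0.2)
    base_int <- 2^(baseline + 20)
    intens <- base_int * 2^(sweep(vals - baseline, 2, sample_offset, `+`))
    if (truth$missing_rate > 0)
      intens[stats::runif(m * ns) < truth$missing_rate] <- 0
    tab <- data.frame(id = seq_len(m) - 1L, check.names = FALSE,
                      stringsAsFactors = FALSE)
    tab[["Majority protein IDs"]] <- accs
    tab[["Reverse"]] <- ""
    tab[["Potential contaminant"]] <- ""
    tab[["Only identified by site"]] <- ""
    for (s in is_rows$sample_id) tab[[s]] <- base_int
    for (j in seq_along(smp)) tab[[smp[j]]] <- intens[, j]
    if (n_decoy_rows > 0L) {
      decoys <- tab[seq_len(n_decoy_rows), , drop = FALSE]
      decoys$id <- m + seq_len(n_decoy_rows) - 1L
      decoys[["Majority protein IDs"]] <- paste0("REV__Q", seq_len(n_decoy_rows))
      decoys$Reverse <- "+"
      tab <- rbind(tab, decoys)
    }
    list(protein_groups_table = tab, design = design, truth = truth)
  })
}

#' Write a deterministic named fixture bundle
#'
#' Emits a complete input set (complex catalog, accession mapping,
#' protein-group table, sample design, truth manifest) for one of the
#' built-in scenarios:
#' \describe{
#'   \item{null_only}{no planted effects: type-I error checks.}
#'   \item{expression_only}{planted protein and complex-wide shifts.}
#'   \item{coreg_only}{planted within-group co-regulation (latent
#'     factors), no expression changes.}
#'   \item{mixed}{both effect kinds plus duplicate catalog entries.}
#'   \item{paper_scale}{a shape-scale emulation: 3642 protein rows,
#'     27 samples (3 excluded), ~500 complexes; no planted effects.}
#' }
#'
#' @param output_dir Directory to write into (created if needed).
#' @param scenario_name One of the scenario names above.
#' @param seed RNG seed (default 1).
#' @return Invisibly, the named list of written file paths.
#' @export
write_fixtures <- function(output_dir, scenario_name, seed = 1L) {
  sc <- build_scenario(scenario_name, seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(complexes = file.path(output_dir, "complexes.tsv"),
             mapping = file.path(output_dir, "mapping.tsv"),
             protein_groups = file.path(output_dir, "proteinGroups.tsv"),
             design = file.path(output_dir, "design.tsv"),
             truth = file.path(output_dir, "truth.yaml"))
  write_tsv(sc$cat$complex_table, paths["complexes"])
  write_tsv(sc$cat$mapping_table, paths["mapping"])
  write_tsv(sc$data$protein_groups_table, paths["protein_groups"])
  write_tsv(sc$data$design, paths["design"])
  write_truth(sc$data$truth, paths["truth"])
  invisible(paths)
}

#' Build a named synthetic scenario in memory
#'
#' Same scenarios as [write_fixtures()], returned as in-memory objects:
#' a list with `cat` (catalog bundle) and `data` (protein-group table,
#' design, truth).
#'
#' @param scenario_name Scenario name.
#' @param seed RNG seed.
#' @return List with `cat` and `data`.
#' @export
build_scenario <- function(scenario_name, seed = 1L) {
  scenarios <- c("null_only", "expression_only", "coreg_only", "mixed",
                 "paper_scale")
  if (!scenario_name %in% scenarios)
    stop("unknown scenario '", scenario_name, "'; valid: ",
         paste(scenarios, collapse = ", "))
  lam <- lambda_for_correlation(0.85, 0.3)
  switch(scenario_name,
    null_only = {
      cat <- generate_catalog(60, c(3, 4), n_background_proteins = 100,
                              seed = seed)
      truth <- synthetic_truth(noise_sd = 0.3, seed = seed)
      list(cat = cat, data = generate_quant_matrix(cat, truth, seed = seed))
    },
    expression_only = {
      cat <- generate_catalog(40, c(3, 6), n_background_proteins = 200,
                              seed = seed)
      truth <- synthetic_truth(
        de_proteins = data.frame(
          accession = sprintf("P%05d", 150 + seq_len(20)),
          group = "LG", shift = 1.0, stringsAsFactors = FALSE),
        de_complexes = data.frame(complex_id = 1:10, group = "LG",
                                  shift = 0.6),
        noise_sd = 0.3, seed = seed)
      list(cat = cat, data = generate_quant_matrix(cat, truth, seed = seed))
    },
    coreg_only = {
      cat <- generate_catalog(30, c(6, 6), n_background_proteins = 100,
                              seed = seed)
      truth <- synthetic_truth(
        coreg_complexes = data.frame(complex_id = 1:10, group = "LG",
                                     lambda = lam),
        noise_sd = 0.3, seed = seed)
      list(cat = cat, data = generate_quant_matrix(cat, truth, seed = seed))
    },
    mixed = {
      cat <- generate_catalog(60, c(3, 6), n_background_proteins = 200,
                              duplication_cases = 3, seed = seed)
      truth <- synthetic_truth(
        de_proteins = data.frame(
          accession = sprintf("P%05d", 200 + seq_len(20)),
          group = "HG", shift = 1.0, stringsAsFactors = FALSE),
        de_complexes = data.frame(complex_id = 11:20, group = "LG",
                                  shift = 0.6),
        coreg_complexes = data.frame(complex_id = 21:30, group = "LG",
                                     lambda = lam),
        noise_sd = 0.3, seed = seed)
      list(cat = cat, data = generate_quant_matrix(cat, truth, seed = seed))
    },
    paper_scale = {
      # sizes are drawn first from the seed, so a second call with the
      # same seed reproduces them and only the background count changes
      cat <- generate_catalog(500, c(2, 8), n_background_proteins = 0L,
                              seed = seed)
      n_bg <- max(0L, 3642L - length(cat$proteins))
      cat <- generate_catalog(500, c(2, 8), n_background_proteins = n_bg,
                              seed = seed)
      truth <- synthetic_truth(noise_sd = 0.3, seed = seed)
      list(cat = cat, data = generate_quant_matrix(cat, truth, seed = seed))
    }
  )
}

#' Write / read a truth manifest
#'
#' The manifest is structured text (YAML): scalar settings plus the three
#' planted-effect tables, round-tripping losslessly.
#'
#' @param truth A [synthetic_truth()].
#' @param path Output path.
#' @return `write_truth` invisibly returns `path`; `read_truth` the
#'   reconstructed `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  df2l <- function(d) lapply(seq_len(nrow(d)), function(i) as.list(d[i, ]))
  yaml::write_yaml(list(seed = truth$seed, noise_sd = truth$noise_sd,
                        missing_rate = truth$missing_rate,
                        de_proteins = df2l(truth$de_proteins),
                        de_complexes = df2l(truth$de_complexes),
                        coreg_complexes = df2l(truth$coreg_complexes)),
                   path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  y <- yaml::read_yaml(path)
  l2df <- function(l, cols) {
    if (length(l) == 0) return(NULL)
    do.call(rbind, lapply(l, function(r) as.data.frame(r[cols])))
  }
  synthetic_truth(
    de_proteins = l2df(y$de_proteins, c("accession", "group", "shift")),
    de_complexes = l2df(y$de_complexes, c("complex_id", "group", "shift")),
    coreg_complexes = l2df(y$coreg_complexes,
                           c("complex_id", "group", "lambda")),
    noise_sd = y$noise_sd, missing_rate = y$missing_rate, seed = y$seed)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
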