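#' Pipeline run configuration
#'
#' Collects paths, thresholds, resampling settings and flags for
#' [run_pipeline()]. Every report header records the seed and settings.
#'
#' @param protein_groups,design,complexes,mapping Paths to (or
#'   data.frames of) the four inputs.
#' @param annotation Optional term-annotation table (columns `term`,
#'   `complex_id`) for enrichment.
#' @param output_dir Directory for output TSVs; NULL returns results
#'   in-memory only.
#' @param comparisons List of 2-vectors of group labels; default all
#'   three pairwise prostate-study comparisons.
#' @param q_cutoff,protein_fc_cutoff Significance / protein effect
#'   cutoffs (defaults 0.05, 0.5).
#' @param complex_cutoff Complex-expression effect cutoff: "derived" or a
#'   number (the literal published value would be 0.31).
#' @param coreg_cutoff Co-regulation effect cutoff: "derived" or a number
#'   (literal published value 0.7).
#' @param iterations Resampling iterations per complex (default 10000).
#' @param min_quantified,min_subunit_coverage,min_ppi_coverage Catalog
#'   filter thresholds (defaults 2, 0.5, 0.5).
#' @param enrichment_q,enrichment_factor Enrichment cutoffs (0.05, 2).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(protein_groups, design, complexes, mapping = NULL,
                       annotation = NULL, output_dir = NULL,
                       comparisons = list(c("LG", "N"), c("HG", "N"),
                                          c("HG", "LG")),
                       q_cutoff = 0.05, protein_fc_cutoff = 0.5,
                       complex_cutoff = "derived", coreg_cutoff = "derived",
                       iterations = 10000L, min_quantified = 2L,
                       min_subunit_coverage = 0.5, min_ppi_coverage = 0.5,
                       enrichment_q = 0.05, enrichment_factor = 2,
                       seed = 1L) {
  stopifnot(q_cutoff > 0, q_cutoff < 1, iterations >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full complex-level analysis pipeline
#'
#' Ingest, ratio, normalize, complete-case filter, apply exclusions, map
#' the catalog, filter and deduplicate complexes, then per comparison:
#' protein differential expression, complex differential expression, and
#' differential co-regulation; optional term enrichment of the
#' differential complexes. Deterministic given the config (incl. seed).
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `quant` (the final quant_matrix),
#'   `design`, `mapped`, `expression_complexes`, `coreg_complexes`
#'   (mapped sets at each filter stage), `funnel` (per-stage counts),
#'   `proteins`, `complexes`, `coreg` (named lists of per-comparison
#'   result tables), `enrichment`, and `qc`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("protein_groups", "design", "complexes")) {
    x <- config[[f]]
    if (is.character(x) && !file.exists(x))
      stop("input file for '", f, "' not found: ", x)
  }
  design <- read_design(config$design)
  log_stage <- function(...) message("[plexdiff] ", ...)

  raw <- ingest_protein_groups(config$protein_groups, design)
  ratios <- compute_log2_ratios(raw, design)
  normed <- normalize_samples(ratios)
  complete <- filter_complete_cases(normed)
  log_stage(nrow(complete$values), " of ", nrow(normed$values),
            " protein groups quantified in all samples")
  qm <- apply_sample_exclusions(complete, design)
  log_stage(ncol(qm$values), " analyzed samples after exclusions")
  qc <- qc_sample_correlation(qm)

  catalog <- parse_complex_catalog(config$complexes, config$mapping)
  mapped <- map_quantified_proteins(catalog, qm$protein_groups, qm$values)
  expr_set <- deduplicate_complexes(
    filter_complexes(mapped, config$min_quantified,
                     config$min_subunit_coverage))
  coreg_set <- filter_complexes(expr_set,
                                config$min_quantified,
                                config$min_subunit_coverage,
                                config$min_ppi_coverage)
  funnel <- data.frame(
    stage = c("catalog", "quantified>=2", "subunit_coverage>=50%",
              "deduplicated", "ppi_coverage>=50%"),
    n = c(nrow(catalog),
          sum(mapped$k >= config$min_quantified),
          nrow(filter_complexes(mapped, config$min_quantified,
                                config$min_subunit_coverage)),
          nrow(expr_set), nrow(coreg_set)),
    stringsAsFactors = FALSE)
  log_stage("complex funnel: ", paste(funnel$n, collapse = " -> "))

  cplx_cut <- if (identical(config$complex_cutoff, "derived")) NULL else
    config$complex_cutoff
  coreg_cut <- if (identical(config$coreg_cutoff, "derived")) NULL else
    config$coreg_cutoff
  cmp_name <- vapply(config$comparisons, paste, "", collapse = "_vs_")
  proteins <- complexes <- coreg <- stats::setNames(
    vector("list", length(cmp_name)), cmp_name)
  for (i in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[i]]
    proteins[[i]] <- test_proteins(qm, design, cmp, config$q_cutoff,
                                   config$protein_fc_cutoff)
    complexes[[i]] <- test_complexes(qm, expr_set, design, cmp,
                                     config$q_cutoff, cutoff = cplx_cut)
    coreg[[i]] <- test_complex_coregulation(
      qm, coreg_set, design, cmp, iterations = config$iterations,
      seed = config$seed, q_cutoff = config$q_cutoff, cutoff = coreg_cut)
    log_stage(cmp_name[i], ": ", sum(proteins[[i]]$status != "ns"),
              " DE proteins, ", sum(complexes[[i]]$status != "ns"),
              " DE complexes, ", sum(coreg[[i]]$status != "ns"),
              " differentially co-regulated complexes")
  }

  enrichment <- NULL
  if (!is.null(config$annotation)) {
    ann <- read_tsv_checked(config$annotation, c("term", "complex_id"))
    enrichment <- lapply(complexes, function(res)
      enrich_terms(res$complex_id[res$status != "ns"], res$complex_id, ann,
                   config$enrichment_q, config$enrichment_factor))
  }

  result <- structure(
    list(quant = qm, design = design, mapped = mapped,
         expression_complexes = expr_set, coreg_complexes = coreg_set,
         funnel = funnel, proteins = proteins, complexes = complexes,
         coreg = coreg, enrichment = enrichment, qc = qc,
         config = config),
    class = "pipeline_result")
  if (!is.null(config$output_dir)) write_report_bundle(result)
  result
}

#' Term over-representation among selected complexes
#'
#' Fisher exact over-representation of each annotation term in a
#' selection of complexes against a background, with Storey q-values and
#' the published-style cutoffs (q and minimum enrichment factor).
#'
#' @param selection Complex ids in the selection.
#' @param background Complex ids of the tested background.
#' @param annotation data.frame with columns `term`, `complex_id`.
#' @param q_cutoff,min_enrichment Cutoffs for the `enriched` flag.
#' @return data.frame per term: counts, `enrichment_factor`, `p`, `q`,
#'   `enriched`.
#' @export
enrich_terms <- function(selection, background, annotation,
                         q_cutoff = 0.05, min_enrichment = 2) {
  stopifnot(all(selection %in% background))
  ann <- annotation[annotation$complex_id %in% background, , drop = FALSE]
  terms <- unique(ann$term)
  if (length(terms) == 0L || length(selection) == 0L)
    return(data.frame(term = character(0)))
  rows <- lapply(terms, function(tm) {
    in_term <- unique(ann$complex_id[ann$term == tm])
    fe <- fisher_exact_enrichment(length(selection),
                                  sum(selection %in% in_term),
                                  length(background), length(in_term))
    data.frame(term = tm, selection_in_term = sum(selection %in% in_term),
               background_in_term = length(in_term),
               enrichment_factor = fe$enrichment_factor, p = fe$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- storey_qvalues(out$p)$q_values
  out$enriched <- out$q < q_cutoff &
    !is.na(out$enrichment_factor) & out$enrichment_factor > min_enrichment
  out[order(out$p), , drop = FALSE]
}

#' Summary funnel / count table for a pipeline result
#'
#' Total, differential, up and down counts per analysis level and
#' comparison, in the layout of a study summary table.
#'
#' @param result A `pipeline_result`.
#' @return data.frame with one row per (analysis, comparison).
#' @export
summarize_counts <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  count_block <- function(tables, level, total) {
    do.call(rbind, lapply(names(tables), function(nm) {
      st <- tables[[nm]]$status
      data.frame(analysis = level, comparison = nm, total = total,
                 differential = sum(st != "ns"), up = sum(st == "up"),
                 down = sum(st == "down"), stringsAsFactors = FALSE)
    }))
  }
  rbind(count_block(result$proteins, "proteins", nrow(result$quant$values)),
        count_block(result$complexes, "complex_expression",
                    nrow(result$expression_complexes)),
        count_block(result$coreg, "complex_coregulation",
                    nrow(result$coreg_complexes)))
}

write_report_bundle <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# plexdiff %s | seed %s | iterations %s",
                    as.character(utils::packageVersion("plexdiff")),
                    result$config$seed, result$config$iterations)
  emit <- function(d, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(header, con)
    close(con)
    suppressWarnings(utils::write.table(
      d, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    path
  }
  for (nm in names(result$proteins))
    emit(result$proteins[[nm]], paste0("proteins_", nm))
  for (nm in names(result$complexes))
    emit(result$complexes[[nm]], paste0("complexes_", nm))
  for (nm in names(result$coreg))
    emit(result$coreg[[nm]], paste0("coreg_", nm))
  if (!is.null(result$enrichment))
    for (nm in names(result$enrichment))
      emit(result$enrichment[[nm]], paste0("enrichment_", nm))
  emit(result$funnel, "funnel")
  emit(summarize_counts(result), "summary_counts")
  emit(result$qc, "qc_sample_correlation")
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("plexdiff pipeline result\n")
  cat(sprintf("  %d protein groups x %d samples\n", nrow(x$quant$values),
              ncol(x$quant$values)))
  cat("  funnel:", paste(sprintf("%s=%d", x$funnel$stage, x$funnel$n),
                         collapse = ", "), "\n")
  print(summarize_counts(x))
  invisible(x)
}
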