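#' Container for a protein-group quantification matrix
#'
#' A light S3 wrapper holding the numeric value matrix (protein groups in
#' rows, samples in columns) and the protein-group identity table
#' (`group_id` plus the list-column `accessions`). Row order is stable
#' through every pipeline operation.
#'
#' @param values Numeric matrix with rownames = group ids, colnames =
#'   sample ids.
#' @param protein_groups data.frame with `group_id`, `accessions`.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, protein_groups) {
  stopifnot(is.matrix(values),
            !is.null(rownames(values)), !is.null(colnames(values)),
            identical(as.character(protein_groups$group_id), rownames(values)))
  structure(list(values = values, protein_groups = protein_groups),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d protein groups x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(!is.finite(x$values))))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

subset_samples <- function(qm, samples) {
  quant_matrix(qm$values[, samples, drop = FALSE], qm$protein_groups)
}

subset_rows <- function(qm, keep) {
  quant_matrix(qm$values[keep, , drop = FALSE],
               qm$protein_groups[keep, , drop = FALSE])
}

#' Read a sample design table
#'
#' Columns: `sample_id`, `group`, `tmt_set`, `channel`,
#' `is_internal_standard`, `excluded`. Validates that sample ids are
#' unique and each multiplex set has exactly one internal-standard
#' channel.
#'
#' @param path Path to a tab-separated design table, or a data.frame.
#' @return The validated design data.frame.
#' @export
read_design <- function(path) {
  d <- read_tsv_checked(path, c("sample_id", "group", "tmt_set", "channel",
                                "is_internal_standard", "excluded"))
  d$is_internal_standard <- as.logical(d$is_internal_standard)
  d$excluded <- as.logical(d$excluded)
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  n_is <- tapply(d$is_internal_standard, d$tmt_set, sum)
  if (any(n_is != 1L))
    stop("each tmt_set needs exactly one internal-standard channel")
  d
}

design_samples <- function(design, include_excluded = TRUE) {
  d <- design[!design$is_internal_standard, , drop = FALSE]
  if (!include_excluded) d <- d[!d$excluded, , drop = FALSE]
  d
}

#' Ingest a protein-group quantification table
#'
#' Reads a MaxQuant proteinGroups-style tab-separated table and removes
#' rows flagged in the `Reverse`, `Potential contaminant`, or
#' `Only identified by site` columns (a `+` marks removal). Quantity
#' columns are located by the design's sample ids (internal-standard
#' channels included). Removal counts are reported via `message()`.
#'
#' @param table Path to the TSV, or a data.frame.
#' @param design Sample design (see [read_design()]).
#' @param id_column Name of the protein-group id column (default "id";
#'   falls back to the first column when absent).
#' @param accession_column Column holding semicolon-separated accessions
#'   (default "Majority protein IDs").
#' @return A `quant_matrix` of raw quantities (zeros recoded to `NA`),
#'   with internal-standard columns still present.
#' @export
ingest_protein_groups <- function(table, design, id_column = "id",
                                  accession_column = "Majority protein IDs") {
  tab <- if (is.data.frame(table)) table else
    utils::read.delim(table, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_column %in% names(tab)) id_column <- names(tab)[1]
  if (!accession_column %in% names(tab))
    stop("missing required column: ", accession_column)
  missing_cols <- setdiff(design$sample_id, names(tab))
  if (length(missing_cols))
    stop("missing quantity column(s): ", paste(missing_cols, collapse = ", "))

  flagged <- rep(FALSE, nrow(tab))
  for (fc in c("Reverse", "Potential contaminant", "Only identified by site"))
    if (fc %in% names(tab)) flagged <- flagged | tab[[fc]] %in% "+"
  message(sum(flagged), " of ", nrow(tab),
          " protein groups removed by reverse/contaminant/site-only flags")
  tab <- tab[!flagged, , drop = FALSE]

  ids <- as.character(tab[[id_column]])
  if (anyDuplicated(ids)) stop("duplicate protein group ids")
  vals <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[!is.finite(vals) | vals <= 0] <- NA_real_  # zeros are missing, never 0
  rownames(vals) <- ids
  pg <- data.frame(group_id = ids, stringsAsFactors = FALSE)
  pg$accessions <- lapply(strsplit(as.character(tab[[accession_column]]), ";",
                                   fixed = TRUE),
                          function(s) trimws(s[nzchar(trimws(s))]))
  quant_matrix(vals, pg)
}

#' Log2 ratios against the internal standard
#'
#' Each quantity is divided by the internal-standard quantity of its
#' multiplex set and log2-transformed; the internal-standard columns are
#' then dropped. Zero or absent quantities propagate as missing.
#'
#' @param raw `quant_matrix` of raw quantities (from
#'   [ingest_protein_groups()]).
#' @param design Sample design.
#' @return A `quant_matrix` of log2 ratios over the non-standard samples.
#' @export
compute_log2_ratios <- function(raw, design) {
  vals <- raw$values
  out_samples <- design$sample_id[!design$is_internal_standard]
  out <- matrix(NA_real_, nrow(vals), length(out_samples),
                dimnames = list(rownames(vals), out_samples))
  for (set in unique(design$tmt_set)) {
    is_id <- design$sample_id[design$tmt_set == set & design$is_internal_standard]
    if (length(is_id) != 1L) stop("no internal standard for set ", set)
    cols <- design$sample_id[design$tmt_set == set & !design$is_internal_standard]
    out[, cols] <- log2(vals[, cols, drop = FALSE] / vals[, is_id])
  }
  quant_matrix(out, raw$protein_groups)
}

#' Centre each sample on its Tukey biweight location
#'
#' Subtracts the robust per-sample average of the log2 ratios, under the
#' assumption that most proteins are unchanged between samples; the
#' re-estimated location afterwards is ~0.
#'
#' @param qm `quant_matrix` of log2 ratios.
#' @return The normalized `quant_matrix`.
#' @export
normalize_samples <- function(qm) {
  vals <- qm$values
  for (j in seq_len(ncol(vals))) {
    if (!any(is.finite(vals[, j]))) stop("empty sample column: ",
                                         colnames(vals)[j])
    vals[, j] <- vals[, j] - tukey_biweight_location(vals[, j])
  }
  quant_matrix(vals, qm$protein_groups)
}

#' Keep only proteins quantified in every sample
#'
#' @param qm `quant_matrix`.
#' @return The complete-case `quant_matrix` (row order preserved).
#' @export
filter_complete_cases <- function(qm) {
  keep <- rowSums(!is.finite(qm$values)) == 0L
  subset_rows(qm, keep)
}

#' Drop samples marked as excluded in the design
#'
#' Removes the columns of excluded samples before statistics; errors when
#' an exclusion would leave any tested group with fewer than 2 samples.
#'
#' @param qm `quant_matrix`.
#' @param design Sample design with the `excluded` flag set.
#' @return The `quant_matrix` restricted to analyzed samples.
#' @export
apply_sample_exclusions <- function(qm, design) {
  d <- design_samples(design)
  unknown <- setdiff(d$sample_id[d$excluded], colnames(qm$values))
  if (length(unknown))
    stop("exclusion references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  keep <- d$sample_id[!d$excluded & d$sample_id %in% colnames(qm$values)]
  left <- table(factor(d$group[!d$excluded], levels = unique(d$group)))
  if (any(left < 2L))
    stop("exclusions leave group(s) with <2 samples: ",
         paste(names(left)[left < 2L], collapse = ", "))
  subset_samples(qm, keep)
}

#' Advisory inter-sample correlation QC
#'
#' For each sample, the median Spearman correlation with every other
#' sample on complete cases. Samples below `flag_threshold` are flagged
#' but never removed automatically; exclusions are an explicit input.
#'
#' @param qm `quant_matrix` with >= 3 samples.
#' @param flag_threshold Flag samples whose median correlation falls
#'   below this value (default 0.5).
#' @return data.frame with `sample_id`, `median_rho`, `flagged`.
#' @export
qc_sample_correlation <- function(qm, flag_threshold = 0.5) {
  vals <- qm$values[rowSums(!is.finite(qm$values)) == 0L, , drop = FALSE]
  if (ncol(vals) < 3L) stop("need at least 3 samples")
  rho <- suppressWarnings(stats::cor(vals, method = "spearman"))
  diag(rho) <- NA
  med <- apply(rho, 2, stats::median, na.rm = TRUE)
  data.frame(sample_id = colnames(vals), median_rho = unname(med),
             flagged = unname(med < flag_threshold),
             stringsAsFactors = FALSE)
}
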