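#' Parse a protein-complex catalog (CORUM download dialect)
#'
#' Reads an `allComplexes`-style tab-separated table (columns `ComplexID`,
#' `ComplexName`, `subunits(UniProt IDs)` with semicolon-separated
#' accessions) together with an accession-to-complex mapping table. The
#' subunit set of each complex is the union of both sources, with
#' duplicate accessions collapsed.
#'
#' @param complex_table Path to the complex table, or a data.frame.
#' @param accession_mapping Path to the mapping table (two required
#'   columns: UniProt accession, ComplexID), or a data.frame. Optional.
#' @return A data.frame with columns `complex_id`, `name`, and the
#'   list-column `subunits`; one row per complex, ordered by id.
#' @export
parse_complex_catalog <- function(complex_table, accession_mapping = NULL) {
  tab <- read_tsv_checked(complex_table,
                          c("ComplexID", "ComplexName", "subunits(UniProt IDs)"))
  ids <- suppressWarnings(as.integer(tab[["ComplexID"]]))
  nums <- suppressWarnings(as.numeric(tab[["ComplexID"]]))
  bad <- which(is.na(ids) | ids != nums)
  if (length(bad))
    stop("malformed complex id at line ", bad[1] + 1L, ": '",
         tab[["ComplexID"]][bad[1]], "'")
  subunits <- lapply(strsplit(as.character(tab[["subunits(UniProt IDs)"]]), ";",
                              fixed = TRUE),
                     function(s) unique(trimws(s[nzchar(trimws(s))])))
  names(subunits) <- as.character(ids)
  name_of <- stats::setNames(as.character(tab[["ComplexName"]]),
                             as.character(ids))

  if (!is.null(accession_mapping)) {
    map <- if (is.data.frame(accession_mapping)) accession_mapping else
      utils::read.delim(accession_mapping, check.names = FALSE,
                        stringsAsFactors = FALSE)
    if (ncol(map) < 2L)
      stop("mapping table needs two columns: accession, complex id")
    acc_col <- grep("accession|uniprot", names(map), ignore.case = TRUE)[1]
    id_col <- grep("complex", names(map), ignore.case = TRUE)[1]
    if (is.na(acc_col)) acc_col <- 1L
    if (is.na(id_col)) id_col <- 2L
    mids <- suppressWarnings(as.integer(map[[id_col]]))
    bad <- which(is.na(mids))
    if (length(bad))
      stop("malformed complex id in mapping at line ", bad[1] + 1L)
    for (i in seq_along(mids)) {
      key <- as.character(mids[i])
      acc <- trimws(as.character(map[[acc_col]][i]))
      subunits[[key]] <- unique(c(subunits[[key]], acc))
    }
  }

  ids_all <- sort(as.integer(names(subunits)))
  empty <- vapply(subunits, length, 0L) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " complex(es) with empty subunit set")
    ids_all <- ids_all[!ids_all %in% as.integer(names(subunits)[empty])]
  }
  key <- as.character(ids_all)
  out <- data.frame(complex_id = ids_all,
                    name = unname(ifelse(is.na(name_of[key]),
                                         paste0("complex_", key),
                                         name_of[key])),
                    stringsAsFactors = FALSE)
  out$subunits <- unname(subunits[key])
  out
}

# strip UniProt isoform suffixes ("P12345-2" -> "P12345")
strip_isoform <- function(acc) sub("-[0-9]+$", "", acc)

#' Project a complex catalog onto the quantified protein groups
#'
#' A catalog subunit counts as quantified when any accession of any
#' protein group matches it after isoform-suffix stripping. When several
#' protein groups match the same subunit, the group with the larger
#' median quantity across samples represents it (ties: lexicographically
#' smallest group id); such events are recorded in the `ambiguities`
#' attribute. One group matching several subunits of a complex counts
#' each subunit as quantified, but contributes a single row downstream so
#' no self-pair correlations arise.
#'
#' @param catalog Output of [parse_complex_catalog()].
#' @param protein_groups A data.frame with `group_id` and list-column
#'   `accessions` (as carried by a [quant_matrix()]).
#' @param values Optional numeric matrix (rows named by group id) used to
#'   resolve ambiguities by median quantity.
#' @return A data.frame of mapped complexes: `complex_id`, `name`, `n`
#'   (catalog subunits), `k` (quantified subunits), `subunit_coverage`
#'   (k/n), `ppi_coverage` (k(k-1)/2 over n(n-1)/2), and list-columns
#'   `quantified_subunits` (accessions) and `rows` (distinct
#'   representative protein-group ids).
#' @export
map_quantified_proteins <- function(catalog, protein_groups, values = NULL) {
  stopifnot(all(c("group_id", "accessions") %in% names(protein_groups)))
  acc <- strip_isoform(unlist(protein_groups$accessions, use.names = FALSE))
  gid <- rep(as.character(protein_groups$group_id),
             lengths(protein_groups$accessions))
  med <- if (!is.null(values))
    apply(values, 1, stats::median, na.rm = TRUE) else NULL

  # accession -> representative group id
  groups_of <- split(gid, acc)
  rep_of <- vapply(groups_of, function(g) {
    g <- unique(g)
    if (length(g) == 1L) return(g)
    if (!is.null(med)) {
      mg <- med[g]
      mg[is.na(mg)] <- -Inf
      g <- g[mg == max(mg)]
    }
    sort(g)[1]
  }, "")
  ambiguous <- names(groups_of)[lengths(lapply(groups_of, unique)) > 1L]

  res <- lapply(seq_len(nrow(catalog)), function(i) {
    subs <- catalog$subunits[[i]]
    n <- length(subs)
    hit <- subs[strip_isoform(subs) %in% names(rep_of)]
    k <- length(hit)
    rows <- unique(unname(rep_of[strip_isoform(hit)]))
    list(n = n, k = k,
         subunit_coverage = if (n > 0) k / n else 0,
         ppi_coverage = if (n > 1) (k * (k - 1)) / (n * (n - 1)) else 0,
         quantified_subunits = hit, rows = rows)
  })
  out <- data.frame(complex_id = catalog$complex_id,
                    name = catalog$name,
                    n = vapply(res, `[[`, 0L, "n"),
                    k = vapply(res, `[[`, 0L, "k"),
                    subunit_coverage = vapply(res, `[[`, 0, "subunit_coverage"),
                    ppi_coverage = vapply(res, `[[`, 0, "ppi_coverage"),
                    stringsAsFactors = FALSE)
  out$quantified_subunits <- lapply(res, `[[`, "quantified_subunits")
  out$rows <- lapply(res, `[[`, "rows")
  attr(out, "ambiguities") <- ambiguous
  out
}

#' Coverage filters for mapped complexes
#'
#' Keeps complexes with at least `min_quantified` quantified subunits and
#' subunit coverage at or above `min_subunit_coverage`; when
#' `min_ppi_coverage` is given, the pairwise-interaction coverage filter
#' is applied as well. Boundary values (exactly at a threshold) are kept,
#' matching removal of strictly sub-threshold complexes.
#'
#' @param mapped Output of [map_quantified_proteins()].
#' @param min_quantified Minimum quantified subunits (default 2).
#' @param min_subunit_coverage Minimum k/n (default 0.5).
#' @param min_ppi_coverage Optional minimum PPI coverage.
#' @return The filtered data.frame.
#' @export
filter_complexes <- function(mapped, min_quantified = 2L,
                             min_subunit_coverage = 0.5,
                             min_ppi_coverage = NULL) {
  stopifnot(min_subunit_coverage >= 0, min_subunit_coverage <= 1)
  keep <- mapped$k >= min_quantified &
    mapped$subunit_coverage >= min_subunit_coverage
  if (!is.null(min_ppi_coverage)) {
    stopifnot(min_ppi_coverage >= 0, min_ppi_coverage <= 1)
    keep <- keep & mapped$ppi_coverage >= min_ppi_coverage
  }
  mapped[keep, , drop = FALSE]
}

#' Remove redundant complexes sharing a quantified-subunit set
#'
#' Among complexes whose quantified subunit sets are identical, only one
#' is kept: the one with the highest subunit coverage, ties broken by the
#' smallest complex id. Output is ordered by complex id.
#'
#' @param mapped Output of [map_quantified_proteins()] (coverage fields
#'   populated).
#' @return The deduplicated data.frame.
#' @export
deduplicate_complexes <- function(mapped) {
  if (nrow(mapped) == 0L) return(mapped)
  key <- vapply(mapped$quantified_subunits,
                function(s) paste(sort(strip_isoform(s)), collapse = "|"), "")
  keep <- unlist(lapply(split(seq_len(nrow(mapped)), key), function(idx) {
    cov <- mapped$subunit_coverage[idx]
    idx <- idx[cov == max(cov)]
    idx[which.min(mapped$complex_id[idx])]
  }), use.names = FALSE)
  out <- mapped[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

read_tsv_checked <- function(x, required) {
  tab <- if (is.data.frame(x)) x else
    utils::read.delim(x, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  tab
}
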