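# in-code fixtures shared across test files

# quant_matrix from a bare matrix; accession defaults to "A<row>"
make_qm <- function(values, accessions = NULL) {
  if (is.null(rownames(values))) rownames(values) <- paste0("r", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  pg <- data.frame(group_id = rownames(values), stringsAsFactors = FALSE)
  pg$accessions <- if (is.null(accessions))
    as.list(paste0("A", seq_len(nrow(values)))) else accessions
  quant_matrix(values, pg)
}

# one-row mapped-complex data.frame over given representative rows
make_mapped <- function(rows, complex_id = 1L, n = length(rows),
                        k = length(rows)) {
  mc <- data.frame(complex_id = complex_id,
                   name = paste0("cx", complex_id), n = n, k = k,
                   subunit_coverage = k / n,
                   ppi_coverage = if (n > 1) k * (k - 1) / (n * (n - 1)) else 0,
                   stringsAsFactors = FALSE)
  mc$rows <- list(rows)
  # key the quantified set off the first row so complexes over different
  # rows are not treated as redundant by deduplicate_complexes()
  mc$quantified_subunits <- list(paste0(rows[1], "_q", seq_len(k)))
  mc
}

# minimal two-group design: n_a + n_b samples in one TMT set plus one
# internal standard
make_design <- function(n_a = 8L, n_b = 8L, groups = c("LG", "N")) {
  data.frame(
    sample_id = c("IS_S1", paste0(groups[1], seq_len(n_a)),
                  paste0(groups[2], seq_len(n_b))),
    group = c("IS", rep(groups[1], n_a), rep(groups[2], n_b)),
    tmt_set = "S1",
    channel = paste0("ch", seq_len(1L + n_a + n_b)),
    is_internal_standard = c(TRUE, rep(FALSE, n_a + n_b)),
    excluded = FALSE, stringsAsFactors = FALSE)
}

# seeded matrix of iid noise with named rows/cols
noise_matrix <- function(nrow, ncol, sd = 0.3, seed = 1) {
  withr::with_seed(seed,
    matrix(rnorm(nrow * ncol, 0, sd), nrow, ncol,
           dimnames = list(paste0("r", seq_len(nrow)),
                           paste0("s", seq_len(ncol)))))
}
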