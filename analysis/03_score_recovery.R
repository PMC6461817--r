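#!/usr/bin/env Rscript

# Step 3: score the pipeline's calls against the planted truth.
#
# Reads the truth manifest written in step 1 and the result tables from
# step 2, and reports recovery of the planted protein shifts, complex
# expression shifts, and co-regulation effects, plus false-positive
# counts among the unplanted remainder.

library(plexdiff)

fix <- file.path("results", "fixtures")
run <- file.path("results", "run")
truth <- read_truth(file.path(fix, "truth.yaml"))
read_run <- function(name)
  read.delim(file.path(run, name), check.names = FALSE, comment.char = "#")

score <- function(tab, id_col, planted_ids, hit) {
  planted <- tab[[id_col]] %in% planted_ids
  data.frame(planted_total = sum(planted),
             planted_called = sum(hit[planted]),
             unplanted_called = sum(hit[!planted]),
             unplanted_total = sum(!planted))
}

cx <- read_run("complexes_LG_vs_N.tsv")
cg <- read_run("coreg_LG_vs_N.tsv")
pr <- read_run("proteins_HG_vs_N.tsv")

out <- rbind(
  cbind(analysis = "complex_expression_LG",
        score(cx, "complex_id", truth$de_complexes$complex_id,
              cx$status == "up")),
  cbind(analysis = "complex_coregulation_LG",
        score(cg, "complex_id", truth$coreg_complexes$complex_id,
              cg$status != "ns")),
  cbind(analysis = "protein_expression_HG",
        score(within(pr, planted_key <- vapply(
                strsplit(accessions, ";", fixed = TRUE),
                function(a) if (any(a %in% truth$de_proteins$accession))
                  "planted" else "other", "")),
              "planted_key", "planted", pr$status == "up")))

write.table(out, file.path("results", "recovery.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(out)
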