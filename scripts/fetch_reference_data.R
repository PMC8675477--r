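#!/usr/bin/env Rscript
# Download the reference inputs used by the two real-data checks in
# tests/testthat/test-acceptance.R (they fail with an informative message
# when these files are absent). Requires network access; the downloaded
# files are not redistributed with the package.
#
#   Rscript scripts/fetch_reference_data.R
#
# Fetches:
#   - PDB entries 6FTI and 6ITC, reduced to CA-only traces of their SecY
#     chain (the longest polypeptide chain with > 350 residues), written to
#     inst/extdata/reference/{6fti,6itc}_secy_ca.pdb
#   - the structure-guided alignment of the SecY N- and C-half sequences
#     (journal supplementary file), to be saved manually as
#     inst/extdata/reference/secy_halves_alignment.fasta with row ids ending
#     in _N or _C marking the half each row belongs to.

suppressPackageStartupMessages(library(pseudosym))

dest <- file.path("inst", "extdata", "reference")
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

fetch_ca <- function(id, out) {
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  tmp <- tempfile(fileext = ".pdb")
  message("downloading ", url)
  utils::download.file(url, tmp, quiet = TRUE)
  traces <- read_structure(tmp, "pdb")
  lens <- vapply(traces, length, integer(1))
  cand <- traces[lens > 350]
  if (length(cand) == 0L) stop(id, ": no chain longer than 350 residues")
  tr <- cand[[which.max(vapply(cand, length, integer(1)))]]
  write_trace_pdb(tr, out)
  message("wrote ", out, " (chain ", tr$chain_id, ", ", length(tr),
          " residues)")
}

fetch_ca("6fti", file.path(dest, "6fti_secy_ca.pdb"))
fetch_ca("6itc", file.path(dest, "6itc_secy_ca.pdb"))

aln <- file.path(dest, "secy_halves_alignment.fasta")
if (!file.exists(aln))
  message("NOTE: place the N-/C-half alignment (aligned FASTA, ids suffixed ",
          "_N / _C) at ", aln,
          "; it is a journal supplementary file and cannot be fetched by URL ",
          "reliably from here.")
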