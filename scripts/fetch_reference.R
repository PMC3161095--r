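#!/usr/bin/env Rscript
# Downloads the two switchgrass chloroplast reference records (GenBank
# HQ731441 = Kanlow Lin1, HQ822121 = Summer Lin2) into
# inst/extdata/reference/ so that the reference-reproduction test block
# and analysis/07_reference.R can run. Requires network access; the
# rest of the test suite passes without it.

accs <- c("HQ731441", "HQ822121")
dir <- file.path("inst", "extdata", "reference")
dir.create(dir, showWarnings = FALSE, recursive = TRUE)
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=gb&retmode=text&id=")
for (acc in accs) {
  dest <- file.path(dir, paste0(acc, ".gb"))
  if (file.exists(dest)) {
    message(acc, " already cached")
    next
  }
  message("fetching ", acc)
  utils::download.file(paste0(base, acc), dest, quiet = TRUE)
  first <- readLines(dest, n = 1L)
  if (!grepl("^LOCUS", first)) stop("unexpected response for ", acc)
}
message("done; records in ", dir)
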