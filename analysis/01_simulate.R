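#!/usr/bin/env Rscript
# Stage 1: build the study system. A switchgrass-like plastome (139,677
# bp; LSC/IRb/SSC/IRa with region-specific GC), a derived ecotype genome
# carrying substitutions (Ti/Tv ratio ~1.1, IR copy-corrected) and
# slippage-biased indels, and two short-read pools: one from the derived
# genome (genomic, for variant confirmation) and one from the reference
# carrying 40% C-to-U editing at three planted sites (cDNA-like).
# Everything is seeded and written with full ground truth.

suppressPackageStartupMessages(library(plastcmp))
seed <- 20110824L %% 99991L
outdir <- "results/simdata"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sim <- generate_plastome(plastome_spec(seed = seed))
mut <- mutate_genome(sim, mutation_spec(seed = seed + 1L))
message(sprintf("reference %s: %d bp; derived %s: %d bp; %d planted events",
                sim$genome$id, genome_length(sim$genome),
                mut$genome$id, genome_length(mut$genome), nrow(mut$truth)))

write_fasta(sim$genome, file.path(outdir, "reference.fasta"))
write_fasta(mut$genome, file.path(outdir, "derived.fasta"))
write_gff3(sim$features, file.path(outdir, "reference.gff3"),
           seqid = sim$genome$id)
data.table::fwrite(mut$truth, file.path(outdir, "truth_variants.tsv"),
                   sep = "\t")
data.table::fwrite(sim$truth$ssrs, file.path(outdir, "truth_ssrs.tsv"),
                   sep = "\t")

st <- sim$structure
g_can <- canonicalize_rotation(sim$genome, st)
cds <- sim$features[sim$features$kind == "CDS" &
                    sim$features$end < st$irb[1], ]
picks <- cds[1:3, ]
sites <- data.frame(
  gene = picks$name,
  pos = vapply(1:3, function(i) {
    span <- substr(g_can$sequence, picks$start[i], picks$end[i])
    target <- if (picks$strand[i] == "+") "C" else "G"
    picks$start[i] + 8L +
      as.integer(regexpr(target, substr(span, 10L, nchar(span))))
  }, numeric(1)),
  change = "predicted C-to-U", strand = picks$strand)
write.table(sites, file.path(outdir, "editing_sites.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

pool <- simulate_reads(mut$genome, 42000L, 36L, error_rate = 0.002,
                       seed = seed + 2L)
write_fastq(pool$reads, file.path(outdir, "pool_derived.fastq"))
cdna <- simulate_reads(g_can, 32000L, 36L, error_rate = 0.002,
                       editing = list(sites = sites, fraction = 0.4),
                       seed = seed + 3L)
write_fastq(cdna$reads, file.path(outdir, "pool_edited.fastq"))
message(sprintf("wrote %d + %d reads and truth tables under %s",
                nrow(pool$reads), nrow(cdna$reads), outdir))
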