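#!/usr/bin/env Rscript
# Stage 6: short-read confirmation. Align the derived-genome read pool
# to the reference at <=1 mismatch, build the pileup, call variable
# positions at depth > 4, measure their overlap with the genome-pair
# variants, and verify the planted C-to-U editing sites against the
# edited (cDNA-like) pool.

suppressPackageStartupMessages(library(plastcmp))
ref <- read_genome("results/simdata/reference.fasta",
                   gff3 = "results/simdata/reference.gff3")
qry <- read_genome("results/simdata/derived.fasta")
st <- detect_quadripartite(ref$genome)
g <- canonicalize_rotation(ref$genome, st)
cmp <- compare_plastomes(ref$genome, qry$genome, ref$features)

ra <- align_reads("results/simdata/pool_derived.fastq", g)
print(ra)
pu <- build_pileup(ra, g)
print(pu)
calls <- call_pool_variants(pu, min_depth = 5L, pool = "derived")
data.table::fwrite(calls, "results/pool_calls.tsv", sep = "\t")
ov <- overlap_summary(list(derived = calls), cmp$variants,
                      genome_length(ref$genome))
message(sprintf("%d pool sites at depth>4; %d match the %d genome-pair variant positions",
                nrow(calls), ov$overlap["reference_pair", "derived"],
                nrow(cmp$variants)))
message(sprintf("inter-genome rates after shared-variation subtraction: %.3f%% SNPs, %.3f%% indels",
                ov$snp_rate_percent, ov$indel_rate_percent))
data.table::fwrite(ov$membership, "results/pool_overlap.tsv", sep = "\t")

sites <- read.delim("results/simdata/editing_sites.tsv")
ra_ed <- align_reads("results/simdata/pool_edited.fastq", g)
pu_ed <- build_pileup(ra_ed, g)
ver <- verify_editing(sites, pu_ed)
print(as.data.frame(ver))
data.table::fwrite(ver, "results/editing_verification.tsv", sep = "\t")
message(sprintf("%d of %d predicted sites supported (>=1 editing read at depth >=4)",
                sum(ver$supported), nrow(ver)))
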