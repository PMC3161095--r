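#!/usr/bin/env Rscript
# Stage 4: pairwise variant calling. Align the reference and derived
# genomes (IR-reduced so the repeat is counted once), call and classify
# every SNP and indel, summarise transitions/transversions and regional
# rates, and check the calls against the simulator's planted truth.

suppressPackageStartupMessages(library(plastcmp))
ref <- read_genome("results/simdata/reference.fasta",
                   gff3 = "results/simdata/reference.gff3")
qry <- read_genome("results/simdata/derived.fasta")
truth <- data.table::fread("results/simdata/truth_variants.tsv")

cmp <- compare_plastomes(ref$genome, qry$genome, ref$features)
print(cmp$summary)
v <- cmp$variants
data.table::fwrite(v, "results/variants.tsv", sep = "\t")
st <- cmp$structure_ref
red <- circular_genome(ref$genome$id,
                       substr(ref$genome$sequence, 1, st$ira[1] - 1L),
                       circular = FALSE)
write_vcf(v, red, "results/variants.vcf")
data.table::fwrite(cmp$summary$per_gene, "results/variant_summary.tsv",
                   sep = "\t")
large <- v[v$kind != "SNP" & v$length >= 17L, ]
data.table::fwrite(large, "results/large_indels.tsv", sep = "\t")
message(sprintf("%d large indels (>=17 bp)", nrow(large)))

hit <- mean(truth$pos %in% v$pos)
message(sprintf("planted-event recovery: %.1f%% of %d events at exact positions",
                100 * hit, nrow(truth)))
ind <- v[v$kind != "SNP", ]
message(sprintf("%d indels; %d homopolymer-associated (mean reference run %.1f bp)",
                nrow(ind), sum(ind$hp_assoc),
                mean(ind$hp_run_length[ind$hp_assoc])))
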