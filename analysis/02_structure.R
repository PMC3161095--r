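#!/usr/bin/env Rscript
# Stage 2: quadripartite architecture. Detect the inverted repeat pair
# of the simulated reference from sequence alone, confirm it matches the
# construction, and report segment lengths, per-region GC and gene
# content.

suppressPackageStartupMessages(library(plastcmp))
ref <- read_genome("results/simdata/reference.fasta",
                   gff3 = "results/simdata/reference.gff3")
st <- detect_quadripartite(ref$genome)
tab <- structure_table(st, ref$genome)
print(tab)
data.table::fwrite(tab, "results/structure.tsv", sep = "\t")

gc <- summarize_gene_content(ref$features, st)
message(sprintf("gene content: %d distinct genes, %d duplicated in the IR, %d total",
                gc$unique_genes, gc$ir_duplicated, gc$total))
dup <- ir_boundary_duplication(st, ref$features)
if (nrow(dup) > 0L) {
  message("features spanning IR junctions:")
  print(dup)
} else message("no feature spans an IR junction in this replicate")
data.table::fwrite(dup, "results/ir_boundary_duplications.tsv", sep = "\t")
message(sprintf("whole-genome GC %.2f%%", gc_fraction(ref$genome)))
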