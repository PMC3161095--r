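# Shared fixtures and independent oracles used across the test files.

random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Independent homopolymer oracle: regular-expression scan per base.
# Linear sequences only (no circular merge).
regex_ssr_oracle <- function(s, min_len) {
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    m <- gregexpr(sprintf("%s{%d,}", b, min_len), s)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    out[[b]] <- data.frame(base = b, length = len, start = as.integer(m),
                           end = as.integer(m) + len - 1L)
  }
  if (length(out) == 0L)
    return(data.frame(base = character(), length = integer(),
                      start = integer(), end = integer()))
  res <- do.call(rbind, out)
  res[order(res$start), c("base", "length", "start", "end")]
}

# A hand-built quadripartite genome from explicit segment sequences.
# The bases flanking the repeat copies are adjusted so the planted IR is
# maximal (otherwise a chance complementary base at a junction would
# legitimately extend the detected repeat by one).
toy_plastome <- function(lsc, irb, ssc) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  fix <- function(s, at, bad) {
    if (substr(s, at, at) %in% bad)
      substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), bad)[1L]
    s
  }
  lsc <- fix(lsc, nchar(lsc), comp[[substr(lsc, 1L, 1L)]])
  ssc <- fix(ssc, 1L, comp[[substr(ssc, nchar(ssc), nchar(ssc))]])
  seq <- paste0(lsc, irb, ssc, revcomp(irb))
  g <- circular_genome("toy", seq)
  st <- quadripartite(nchar(lsc), nchar(irb), nchar(ssc), genome_id = "toy")
  list(genome = g, structure = st)
}

# Small simulated plastome pair used by several files (cheap to build).
small_sim <- function(seed = 42L, mut_seed = 7L, ...) {
  spec <- plastome_spec(lsc_len = 12000L, irb_len = 2000L, ssc_len = 3000L,
                        n_cds_lsc = 8L, n_cds_ssc = 2L, n_cds_ir = 1L,
                        cds_len_range = c(300L, 600L), seed = seed, ...)
  sim <- generate_plastome(spec)
  mut <- mutate_genome(sim, mutation_spec(seed = mut_seed))
  list(sim = sim, mut = mut)
}

# Codon-pair fixture: a gap-free codon_alignment built directly.
make_codon_alignment <- function(ref_codons, qry_codons,
                                 gene = "geneX") {
  structure(list(ref_codons = ref_codons, qry_codons = qry_codons,
                 gene = rep(gene, length(ref_codons)), n_excluded = 0L),
            class = "codon_alignment")
}

# Independent NG86-style site enumeration for the dS oracle: for each
# codon, the fraction of non-stop single-base changes that preserve the
# amino acid, computed from a fresh copy of translation table 11.
enumerate_syn_sites <- function(codons) {
  code <- Biostrings::getGeneticCode("11")
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (cod in codons) {
    for (p in 1:3) {
      syn <- 0L; nonstop <- 0L
      for (b in setdiff(bases, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- b
        if (code[[mut]] == "*") next
        nonstop <- nonstop + 1L
        if (code[[mut]] == code[[cod]]) syn <- syn + 1L
      }
      if (nonstop > 0L) total <- total + syn / nonstop
    }
  }
  total
}
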