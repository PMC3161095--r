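empty_variant_list <- function() {
  v <- data.table::data.table(kind = character(), pos = integer(),
                              ref = character(), alt = character(),
                              length = integer())
  class(v) <- c("variant_table", class(v))
  v
}

test_that("identical genomes give a single full-length anchor and no variants", {
  set.seed(31)
  s <- random_seq(10000)
  aln <- align_pair(s, s)
  expect_equal(nrow(aln$anchors), 1L)
  expect_equal(aln$anchors$rend, 10000L)
  expect_identical(aln$ref_aln, aln$qry_aln)
  expect_equal(nrow(call_variants(aln)), 0L)
})

test_that("planted edit scripts are reconstructed exactly", {
  set.seed(32)
  r <- random_seq(10000)
  q <- r
  # three SNPs, guaranteed alt != ref, away from each other
  snp_pos <- c(1500L, 4800L, 8200L)
  for (p in snp_pos) {
    cur <- substr(q, p, p)
    substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  }
  # one 20 bp deletion
  del_at <- 6000L
  q <- paste0(substr(q, 1, del_at - 1L), substr(q, del_at + 20L, nchar(q)))
  v <- call_variants(align_pair(r, q))
  expect_equal(sum(v$kind == "SNP"), 3L)
  expect_setequal(v$pos[v$kind == "SNP"], snp_pos)
  del <- v[v$kind == "deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$length, 20L)
  # left-normalised position is the leftmost equivalent placement
  dn <- del$pos
  expect_true(dn <= del_at)
  expect_identical(apply_variants(r, v), q)
})

test_that("indels left-normalise into homopolymer context", {
  v <- call_variants(align_pair("CCAAAG", "CCAAAAG"))
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "insertion")
  expect_equal(v$pos, 3L)   # leftmost A of the run
  expect_equal(v$alt, "A")
  expect_identical(apply_variants("CCAAAG", v), "CCAAAAG")

  v2 <- call_variants(align_pair("CCAAAAG", "CCAAAG"))
  expect_equal(v2$kind, "deletion")
  expect_equal(v2$pos, 3L)
  expect_equal(v2$ref, "A")
})

test_that("all twelve ordered base pairs split 4 transitions / 8 transversions", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- substitution_class(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls == "transversion"), 8L)
  expect_equal(substitution_class("A", "G"), "transition")
  expect_equal(substitution_class("C", "T"), "transition")
  expect_equal(substitution_class("A", "C"), "transversion")
})

test_that("coding effects are strand-aware and jointly translated", {
  # plus-strand CDS: GCT -> GCC at the third position is synonymous (Ala)
  lsc <- paste0(strrep("C", 30), "ATG", "GCT", "AAA", "TAA", strrep("G", 28))
  toy <- toy_plastome(lsc, random_seq(300), random_seq(150))
  ft <- feature_table("g1", "CDS", "+", 31L, 42L)
  v <- empty_ish <- data.table::data.table(
    kind = "SNP", pos = 36L, ref = "T", alt = "C", length = 1L)
  class(v) <- c("variant_table", class(v))
  cv <- classify_variants(v, toy$structure, ft, toy$genome)
  expect_equal(cv$effect, "synonymous")
  expect_equal(cv$class, "transition")
  expect_true(cv$coding)

  # nonsynonymous first-position change AAA (Lys) -> GAA (Glu)
  v2 <- data.table::data.table(kind = "SNP", pos = 37L, ref = "A",
                               alt = "G", length = 1L)
  class(v2) <- c("variant_table", class(v2))
  expect_equal(classify_variants(v2, toy$structure, ft, toy$genome)$effect,
               "nonsynonymous")

  # intergenic SNP -> noncoding
  v3 <- data.table::data.table(kind = "SNP", pos = 5L, ref = "C",
                               alt = "T", length = 1L)
  class(v3) <- c("variant_table", class(v3))
  c3 <- classify_variants(v3, toy$structure, ft, toy$genome)
  expect_equal(c3$effect, "noncoding")
  expect_equal(c3$region, "LSC")

  # minus-strand CDS: genome holds revcomp(ATG GCT AAA TAA)
  orf <- "ATGGCTAAATAA"
  lsc2 <- paste0(strrep("C", 30), revcomp(orf), strrep("G", 28))
  toy2 <- toy_plastome(lsc2, random_seq(300), random_seq(150))
  ft2 <- feature_table("g2", "CDS", "-", 31L, 42L)
  # genome position of the GCT third base (codon 2, position 3):
  # transcript index 6 -> genome position end - 6 + 1 = 42 - 5 = 37
  cur <- substr(genome_seq(toy2$genome), 37L, 37L)  # complement of T = A
  v4 <- data.table::data.table(kind = "SNP", pos = 37L, ref = cur,
                               alt = "G", length = 1L)  # C->G on transcript? no:
  class(v4) <- c("variant_table", class(v4))
  c4 <- classify_variants(v4, toy2$structure, ft2, toy2$genome)
  # genome A->G at that site is transcript T->C: GCT->GCC, synonymous
  expect_equal(c4$effect, "synonymous")

  # two SNPs in one codon are translated jointly
  v5 <- data.table::data.table(kind = c("SNP", "SNP"), pos = c(34L, 36L),
                               ref = c("G", "T"), alt = c("A", "A"),
                               length = 1L)
  class(v5) <- c("variant_table", class(v5))
  c5 <- classify_variants(v5, toy$structure, ft, toy$genome)
  # GCT -> ACA jointly: Ala -> Thr, both rows nonsynonymous
  expect_equal(c5$effect, c("nonsynonymous", "nonsynonymous"))
})

test_that("homopolymer association follows the run definition", {
  ref <- paste0("CCGT", strrep("A", 9), "GTCCGT")
  v <- data.table::data.table(kind = "insertion", pos = 5L, ref = "",
                              alt = "A", length = 1L)
  class(v) <- c("variant_table", class(v))
  hp <- homopolymer_association(v, ref, min_run = 5L)
  expect_true(hp$associated)
  expect_equal(hp$run_length, 9L)

  v2 <- data.table::data.table(kind = "insertion", pos = 5L, ref = "",
                               alt = "ACGTGCATGCAGTCATGCAT", length = 20L)
  class(v2) <- c("variant_table", class(v2))
  hp2 <- homopolymer_association(v2, "CCGTACGTGCAGTCAGGTCA", min_run = 5L)
  expect_false(hp2$associated)

  v3 <- data.table::data.table(kind = "SNP", pos = 5L, ref = "A",
                               alt = "G", length = 1L)
  class(v3) <- c("variant_table", class(v3))
  expect_error(homopolymer_association(v3, ref), "indel")
})

test_that("generator slippage truth agrees with the association caller", {
  sims <- small_sim(seed = 55L, mut_seed = 99L)
  cmp <- compare_plastomes(sims$sim$genome, sims$mut$genome,
                           sims$sim$features, min_ir_length = 500L)
  tr <- sims$mut$truth[sims$mut$truth$kind != "SNP", ]
  vv <- cmp$variants[cmp$variants$kind != "SNP", ]
  m <- merge(data.frame(pos = tr$pos, truth_hp = tr$hp_assoc),
             data.frame(pos = vv$pos, called_hp = vv$hp_assoc), by = "pos")
  expect_gte(nrow(m), 1L)
  expect_gte(mean(m$truth_hp == m$called_hp), 0.95)
})

test_that("variant round-trip and swap symmetry hold on simulated pairs", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(600:2000, 1L)
    r <- random_seq(n)
    q <- r
    # plastome-like divergence
    nsnp <- rbinom(1L, n, 0.002)
    for (p in sample.int(n - 10L, nsnp)) {
      cur <- substr(q, p, p)
      substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    if (runif(1) < 0.5) {
      p <- sample.int(n - 80L, 1L) + 30L
      L <- sample.int(10L, 1L)
      q <- paste0(substr(q, 1L, p - 1L), substr(q, p + L, nchar(q)))
    }
    v <- call_variants(align_pair(r, q))
    expect_identical(apply_variants(r, v), q)
    w <- call_variants(align_pair(q, r))
    expect_identical(apply_variants(q, w), r)
    expect_equal(sum(v$kind == "SNP"), sum(w$kind == "SNP"))
    expect_equal(sum(v$kind == "deletion"), sum(w$kind == "insertion"))
    expect_equal(sum(v$kind == "insertion"), sum(w$kind == "deletion"))
  }
})

test_that("summaries conserve counts and compute rates with one IR copy", {
  sims <- small_sim()
  cmp <- compare_plastomes(sims$sim$genome, sims$mut$genome,
                           sims$sim$features, min_ir_length = 500L)
  sm <- cmp$summary
  v <- cmp$variants
  expect_equal(sm$tn + sm$tv, sm$n_snp)
  expect_equal(sm$n_snp + sm$n_indel, nrow(v))
  expect_equal(sum(sm$per_gene$total), nrow(v))
  st <- cmp$structure_ref
  sc_len <- diff(st$lsc) + 1L + diff(st$ssc) + 1L
  expect_equal(sm$rates[["single_copy"]],
               sum(v$kind == "SNP" & v$region != "IR") / sc_len)
  expect_equal(sm$rates[["ir"]],
               sum(v$kind == "SNP" & v$region == "IR") / (diff(st$irb) + 1L))
  expect_true(all(v$in_both_ir_copies == (v$region == "IR")))
  # coding SNPs partition into synonymous + nonsynonymous + n/a
  cs <- v[v$kind == "SNP" & v$coding, ]
  expect_true(all(cs$effect %in% c("synonymous", "nonsynonymous", "n/a")))
  # empty summary
  sm0 <- summarize_variants(classify_variants(empty_variant_list(),
                                              sims$sim$structure,
                                              sims$sim$features,
                                              sims$sim$genome),
                            sims$sim$structure)
  expect_true(is.na(sm0$R))
  expect_equal(sm0$n_snp, 0L)
})

test_that("estimated Tn/Tv ratio recovers the generator kappa", {
  # kappa = 2 -> expected transition fraction 2/(2+2) = 1/2, R = 1
  spec <- plastome_spec(lsc_len = 40000L, irb_len = 3000L, ssc_len = 6000L,
                        n_cds_lsc = 10L, n_cds_ssc = 2L, n_cds_ir = 1L,
                        cds_len_range = c(300L, 600L), seed = 77L)
  sim <- generate_plastome(spec)
  mut <- mutate_genome(sim, mutation_spec(sub_rate = 0.011, kappa = 2,
                                          indel_rate = 0, seed = 3L))
  tr <- mut$truth[mut$truth$kind == "SNP", ]
  expect_gte(nrow(tr), 400L)
  cmp <- compare_plastomes(sim$genome, mut$genome, sim$features,
                           min_ir_length = 500L)
  sm <- cmp$summary
  n <- sm$tn + sm$tv
  phat <- sm$tn / n
  # binomial CI around p = 0.5
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})
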