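# Codon fixtures use fourfold-degenerate third positions (e.g. GCx = Ala,
# GGx = Gly, CTx = Leu) so synonymous changes can be planted exactly.

test_that("identical sequences give zero distances", {
  set.seed(41)
  cods <- sample(setdiff(names(Biostrings::getGeneticCode("11")),
                         c("TAA", "TAG", "TGA")), 200, replace = TRUE)
  caln <- make_codon_alignment(cods, cods)
  for (m in c("NG86", "YN00")) {
    ds <- estimate_ds_dn(caln, m)
    expect_equal(ds$Sd, 0)
    expect_equal(ds$Nd, 0)
    expect_equal(ds$dS, 0)
    expect_equal(ds$dN, 0)
  }
})

test_that("NG86 equals the enumeration oracle on planted synonymous transitions", {
  set.seed(42)
  ref <- sample(c("GCT", "GGA", "CTC", "ACG", "TCA", "GTT"), 300,
                replace = TRUE)
  qry <- ref
  # two synonymous third-position transitions at fourfold codons
  h1 <- which(ref == "GCT")[1]
  h2 <- which(ref == "GGA")[1]
  qry[h1] <- "GCC"       # GCT -> GCC (ts)
  qry[h2] <- "GGG"       # GGA -> GGG (ts)
  caln <- make_codon_alignment(ref, qry)
  ng <- estimate_ds_dn(caln, "NG86")
  expect_equal(ng$Sd, 2)
  expect_equal(ng$Nd, 0)
  # site count from the independent per-codon enumeration oracle
  S_oracle <- (enumerate_syn_sites(ref) + enumerate_syn_sites(qry)) / 2
  expect_equal(ng$S, S_oracle, tolerance = 1e-10)
  expect_equal(ng$dS, -0.75 * log(1 - 4 * (2 / S_oracle) / 3),
               tolerance = 1e-10)
  expect_equal(ng$dN, 0)
  yn <- estimate_ds_dn(caln, "YN00")
  expect_lt(abs(yn$dS - ng$dS) / ng$dS, 0.25)
})

test_that("NG86 and YN00 coincide when kappa = 1 and transitions are a third of differences", {
  # three synonymous changes at fourfold sites: 1 transition + 2
  # transversions makes the estimated kappa exactly 1 and the K80
  # correction collapse onto Jukes-Cantor.
  ref <- rep(c("GCT", "GGA", "CTC", "GTG"), each = 75)
  qry <- ref
  qry[1] <- "GCC"    # T->C transition
  qry[80] <- "GGT"   # A->T transversion
  qry[160] <- "CTA"  # C->A transversion
  caln <- make_codon_alignment(ref, qry)
  ng <- estimate_ds_dn(caln, "NG86")
  yn <- estimate_ds_dn(caln, "YN00")
  expect_equal(yn$kappa, 1, tolerance = 1e-10)
  expect_equal(yn$S, ng$S, tolerance = 1e-10)
  expect_equal(yn$N, ng$N, tolerance = 1e-10)
  expect_equal(yn$dS, ng$dS, tolerance = 1e-10)
})

test_that("distances are permutation invariant and monotone in differences", {
  set.seed(43)
  ref <- sample(c("GCT", "GGA", "CTC", "ACG", "AAA", "GAT"), 400,
                replace = TRUE)
  qry <- ref
  four <- which(ref %in% c("GCT", "GGA", "CTC"))
  qry[four[1:4]] <- sub(".$", "C", ref[four[1:4]])
  qry[four[1:4]] <- ifelse(qry[four[1:4]] == ref[four[1:4]],
                           sub(".$", "G", ref[four[1:4]]), qry[four[1:4]])
  caln <- make_codon_alignment(ref, qry)
  perm <- sample(length(ref))
  caln_p <- make_codon_alignment(ref[perm], qry[perm])
  for (m in c("NG86", "YN00")) {
    a <- estimate_ds_dn(caln, m)
    b <- estimate_ds_dn(caln_p, m)
    expect_equal(a$dS, b$dS)
    expect_equal(a$dN, b$dN)
    expect_equal(a$S, b$S)
  }
  # one more synonymous difference never decreases dS
  qry2 <- qry
  extra <- four[6]
  qry2[extra] <- sub(".$", "A", ref[extra])
  if (qry2[extra] == ref[extra]) qry2[extra] <- sub(".$", "G", ref[extra])
  d1 <- estimate_ds_dn(caln, "NG86")$dS
  d2 <- estimate_ds_dn(make_codon_alignment(ref, qry2), "NG86")$dS
  expect_gte(d2, d1)
})

test_that("codon alignment extraction pairs the right codons across indels", {
  sims <- small_sim(seed = 61L, mut_seed = 5L)
  cmp <- compare_plastomes(sims$sim$genome, sims$mut$genome,
                           sims$sim$features, min_ir_length = 500L)
  caln <- extract_codon_alignment(cmp$alignment, sims$sim$features,
                                  cmp$structure_ref)
  # differing codons correspond exactly to truth coding SNPs (the
  # generator plants no indels in CDS)
  tr <- sims$mut$truth
  coding_snps <- tr[tr$kind == "SNP" & tr$coding & tr$region != "IR", ]
  ndiff <- sum(caln$ref_codons != caln$qry_codons)
  # several SNPs can share a codon, so differing codons <= coding SNPs
  expect_lte(ndiff, nrow(coding_snps))
  expect_gte(ndiff, ceiling(nrow(coding_snps) / 3))
  # and the IR gene is excluded by default
  ir_genes <- unique(sims$sim$features$name[
    sims$sim$features$start > sims$sim$structure$irb[1] &
    sims$sim$features$end <= sims$sim$structure$irb[2]])
  expect_false(any(ir_genes %in% caln$gene))
})

test_that("five planted third-position changes give five differing codons", {
  lsc_orf <- paste0("ATG", strrep("GCT", 50), "TAA")   # 52 codons
  lsc <- paste0(random_seq(200), lsc_orf, random_seq(200))
  toy <- toy_plastome(lsc, random_seq(400), random_seq(200))
  ft <- feature_table("g1", "CDS", "+", 201L, 200L + nchar(lsc_orf))
  q <- genome_seq(toy$genome)
  at <- 200L + 3L + (c(2, 9, 17, 25, 40) - 1L) * 3L + 3L  # codon third bases
  for (p in at) substr(q, p, p) <- "C"                    # GCT -> GCC
  aln <- align_pair(genome_seq(toy$genome), q)
  caln <- extract_codon_alignment(aln, ft, toy$structure)
  expect_equal(sum(caln$ref_codons != caln$qry_codons), 5L)
  ds <- estimate_ds_dn(caln, "NG86")
  expect_equal(ds$Sd, 5)
  expect_equal(ds$Nd, 0)
})

test_that("internal stop codons are reported with gene and codon index", {
  lsc_orf <- paste0("ATG", "GCT", "TAA", "GCT", "TAA")   # stop at codon 3
  lsc <- paste0(random_seq(100), lsc_orf, random_seq(100))
  toy <- toy_plastome(lsc, random_seq(300), random_seq(150))
  ft <- feature_table("gX", "CDS", "+", 101L, 100L + nchar(lsc_orf))
  aln <- align_pair(genome_seq(toy$genome), genome_seq(toy$genome))
  expect_error(extract_codon_alignment(aln, ft, toy$structure),
               "internal stop codon.*gX")
})

test_that("saturated alignments raise a saturation signal", {
  ref <- rep("GCT", 100)
  qry <- rep("GCA", 100)   # every codon synonymous-different
  caln <- make_codon_alignment(ref, qry)
  expect_error(estimate_ds_dn(caln, "NG86"), "saturation")
})

test_that("clock ages scale correctly with rate and dS", {
  c1 <- clock_age(0.0029, rate_low = 2.9e-9, rate_high = 2.9e-9,
                  formula = "dS/r")
  expect_equal(c1$t_low, 1e6)
  expect_equal(c1$t_high, 1e6)
  # halving the rate doubles the age
  c2 <- clock_age(0.0029, rate_low = 2.9e-9 / 2, rate_high = 2.9e-9 / 2)
  expect_equal(c2$t_low, 2e6)
  # per-lineage formula halves the age
  c3 <- clock_age(0.0029, 2.9e-9, 2.9e-9, formula = "dS/(2r)")
  expect_equal(c3$t_low, 5e5)
  # the calibration interval for dS = 0.0017 under t = dS/r
  c4 <- clock_age(0.0017, 2.1e-9, 2.9e-9)
  expect_equal(c4$t_low, 0.0017 / 2.9e-9, tolerance = 1e-12)
  expect_equal(c4$t_high, 0.0017 / 2.1e-9, tolerance = 1e-12)
  expect_equal(round(c4$t_low / 1e3), 586)
  expect_equal(round(c4$t_high / 1e3), 810)
  expect_true(c4$t_low <= c4$t_high)
  expect_error(clock_age(0.001, 0, 2e-9), "rates")
})
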