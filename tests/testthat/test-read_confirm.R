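make_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs))) {
  data.table::data.table(id = ids, seq = seqs,
                         qual = strrep("I", nchar(seqs)))
}

test_that("exact, one-mismatch and two-mismatch reads behave at the threshold", {
  set.seed(51)
  g <- circular_genome("ref", random_seq(5000))
  s <- genome_seq(g)
  exact <- substr(s, 1001, 1036)
  one <- exact; substr(one, 10, 10) <- setdiff(c("A","C","G","T"),
                                               substr(one, 10, 10))[1]
  two <- one; substr(two, 25, 25) <- setdiff(c("A","C","G","T"),
                                             substr(two, 25, 25))[1]
  ra <- align_reads(make_reads(c(exact, one, two)), g)
  pl <- ra$placements
  expect_equal(nrow(pl), 2L)
  expect_equal(pl$pos[pl$read_id == "r001"], 1001L)
  expect_equal(pl$mismatches[pl$read_id == "r001"], 0L)
  expect_equal(pl$mismatches[pl$read_id == "r002"], 1L)
  expect_false("r003" %in% pl$read_id)
  expect_equal(ra$aligned_fraction, 2 / 3)
  # reverse-complement placement, and wrap across the origin
  rc <- revcomp(substr(s, 2001, 2036))
  wrap <- paste0(substr(s, 4990, 5000), substr(s, 1, 25))
  ra2 <- align_reads(make_reads(c(rc, wrap)), g)
  expect_equal(ra2$placements$pos, c(2001L, 4990L))
  expect_equal(ra2$placements$strand, c("-", "+"))
})

test_that("error-free simulated reads all align at their true positions", {
  sim <- small_sim(seed = 52L)$sim
  rs <- simulate_reads(sim$genome, 4000L, 36L, error_rate = 0, seed = 9L)
  ra <- align_reads(rs$reads, sim$genome)
  expect_equal(ra$aligned_fraction, 1.0)
  pl <- merge(ra$placements, rs$truth, by.x = "read_id", by.y = "id")
  uni <- pl[pl$multi == FALSE, ]
  expect_true(all(uni$pos.x == uni$pos.y & uni$strand.x == uni$strand.y))
  # multi-mapped reads sit in the IR; the primary placement is either the
  # true position or its mirror image in the other repeat copy
  mul <- pl[pl$multi == TRUE, ]
  if (nrow(mul) > 0L) {
    st <- sim$structure
    L <- 36L
    mirror_start <- function(p) {
      ira_end_of_read <- st$ira[2] - (p - st$irb[1])
      ira_end_of_read - L + 1L
    }
    ok <- mul$pos.x == mul$pos.y |
      mul$pos.x == vapply(mul$pos.y, mirror_start, numeric(1)) |
      mul$pos.y == vapply(mul$pos.x, mirror_start, numeric(1))
    expect_true(all(ok))
  }
})

test_that("pileup depth identity holds and empty alignments give zero depth", {
  sim <- small_sim(seed = 53L)$sim
  rs <- simulate_reads(sim$genome, 2000L, 36L, error_rate = 0.01, seed = 2L)
  ra <- align_reads(rs$reads, sim$genome)
  pu <- build_pileup(ra, sim$genome)
  expect_equal(sum(pu$depth), sum(ra$placements$len))
  expect_equal(pu$n, genome_length(sim$genome))

  # reads that align nowhere produce an all-zero pileup
  noisy <- make_reads(c(strrep("ACGT", 9), strrep("TGCA", 9)))
  g2 <- circular_genome("g2", random_seq(3000, gc = 0.5))
  ra0 <- align_reads(noisy, g2)
  if (nrow(ra0$placements) == 0L) {
    pu0 <- build_pileup(ra0, g2)
    expect_true(all(pu0$depth == 0L))
    expect_equal(pu0$breadth1, 0)
  }
})

test_that("uniform coverage reaches expected depth and breadth is monotone", {
  set.seed(54)
  g <- circular_genome("u", random_seq(20000))
  n_reads <- round(10 * 20000 / 36)   # 10x
  rs <- simulate_reads(g, n_reads, 36L, error_rate = 0, seed = 4L)
  ra <- align_reads(rs$reads, g)
  pu <- build_pileup(ra, g)
  expect_lt(abs(mean(pu$depth) - 10) / 10, 0.1)
  expect_gt(pu$breadth4, 0.97)
  # breadth at depth >= 4 is monotone non-decreasing in read count
  half <- simulate_reads(g, n_reads %/% 4L, 36L, error_rate = 0, seed = 4L)
  pu_half <- build_pileup(align_reads(half$reads, g), g)
  expect_lte(pu_half$breadth4, pu$breadth4)
})

test_that("pool variant calls are specific on reference reads and recover planted sites", {
  set.seed(55)
  g <- circular_genome("p", random_seq(12000))
  rs <- simulate_reads(g, 4000L, 36L, error_rate = 0, seed = 8L)
  pu <- build_pileup(align_reads(rs$reads, g), g)
  expect_equal(nrow(call_pool_variants(pu)), 0L)

  # a pool fixed for one SNP relative to the reference
  s2 <- genome_seq(g)
  substr(s2, 6000, 6000) <- setdiff(c("A","C","G","T"),
                                    substr(s2, 6000, 6000))[1]
  pool <- circular_genome("pool", s2)
  rs2 <- simulate_reads(pool, 4000L, 36L, error_rate = 0, seed = 8L)
  pu2 <- build_pileup(align_reads(rs2$reads, g), g)
  calls <- call_pool_variants(pu2, min_depth = 5L)
  expect_equal(calls$pos, 6000L)
  expect_true(calls$invariant)
  expect_equal(calls$alt, substr(s2, 6000, 6000))
})

test_that("overlap summaries count shared and private variation", {
  ref_v <- data.table::data.table(kind = c("SNP", "SNP", "SNP", "deletion"),
                                  pos = c(100L, 200L, 300L, 400L),
                                  ref = c("A", "C", "G", "AA"),
                                  alt = c("G", "T", "A", ""),
                                  length = c(1L, 1L, 1L, 2L))
  pool_a <- data.table::data.table(pos = c(100L, 200L, 999L))
  pool_b <- data.table::data.table(pos = c(100L, 555L))
  ov <- overlap_summary(list(up = pool_a, low = pool_b), ref_v, 10000L)
  expect_equal(ov$overlap["reference_pair", "up"], 2L)
  expect_equal(ov$overlap["reference_pair", "low"], 1L)
  expect_equal(ov$overlap["up", "low"], 1L)
  expect_equal(ov$n_shared, 1L)          # pos 100 in both pools + reference
  expect_equal(ov$snp_rate_percent, 100 * 2 / 10000)    # 3 SNPs - 1 shared
  expect_equal(ov$indel_rate_percent, 100 * 1 / 10000)
  # disjoint sets
  ov0 <- overlap_summary(list(a = data.table::data.table(pos = 1L)),
                         ref_v[0L], 1000L)
  expect_equal(ov0$overlap["reference_pair", "a"], 0L)
})

test_that("editing verification is strand-aware and calibrated", {
  set.seed(56)
  g <- circular_genome("e", random_seq(8000))
  s <- genome_seq(g)
  # pick a C on the forward strand and a G (edited gene on minus strand)
  cpos <- as.integer(gregexpr("C", substr(s, 3000, 4000))[[1]][1]) + 2999L
  gpos <- as.integer(gregexpr("G", substr(s, 5000, 6000))[[1]][1]) + 4999L
  sites <- data.frame(gene = c("gplus", "gminus"), pos = c(cpos, gpos),
                      change = c("S10L", "P50L"), strand = c("+", "-"))
  rs <- simulate_reads(g, 12000L, 36L, error_rate = 0,
                       editing = list(sites = sites, fraction = 0.4),
                       seed = 11L)
  pu <- build_pileup(align_reads(rs$reads, g), g)
  ver <- verify_editing(sites, pu)
  expect_true(all(ver$supported))
  for (i in 1:2) {
    p <- ver$support_fraction[i]
    n <- ver$depth[i]
    expect_lt(abs(p - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  }
  # unedited site: 0 editing reads out of full depth
  plain <- data.frame(gene = "x", pos = cpos + 50L, change = "syn",
                      strand = "+")
  # ensure the site is not a T already supported by mismatch tolerance
  ver0 <- verify_editing(plain, pu)
  if (pu$ref_base[cpos + 50L] != "T")
    expect_false(ver0$supported)
  expect_error(verify_editing(data.frame(gene = "y", pos = 99999L,
                                         change = "z", strand = "+"), pu),
               "outside")
})
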