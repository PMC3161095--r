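test_that("generation is bit-reproducible for a fixed seed", {
  spec <- plastome_spec(lsc_len = 5000L, irb_len = 800L, ssc_len = 1200L,
                        n_cds_lsc = 3L, n_cds_ssc = 1L, n_cds_ir = 1L,
                        cds_len_range = c(300L, 450L), seed = 42L)
  a <- generate_plastome(spec)
  b <- generate_plastome(spec)
  expect_identical(genome_seq(a$genome), genome_seq(b$genome))
  expect_identical(as.data.frame(a$features), as.data.frame(b$features))
  expect_identical(a$truth$ssrs, b$truth$ssrs)
  m1 <- mutate_genome(a, mutation_spec(seed = 3L))
  m2 <- mutate_genome(b, mutation_spec(seed = 3L))
  expect_identical(genome_seq(m1$genome), genome_seq(m2$genome))
  expect_identical(as.data.frame(m1$truth), as.data.frame(m2$truth))
})

test_that("detection recovers the generating geometry exactly", {
  spec <- plastome_spec(lsc_len = 5000L, irb_len = 800L, ssc_len = 1200L,
                        n_cds_lsc = 3L, n_cds_ssc = 1L, n_cds_ir = 1L,
                        cds_len_range = c(300L, 450L), seed = 7L)
  sim <- generate_plastome(spec)
  st <- detect_quadripartite(sim$genome, min_ir_length = 300L)
  expect_equal(st$lsc, c(1L, 5000L))
  expect_equal(st$irb, c(5001L, 5800L))
  expect_equal(st$ssc, c(5801L, 7000L))
  expect_equal(st$ira, c(7001L, 7800L))
  # IRb is the exact reverse complement of IRa by construction
  s <- genome_seq(sim$genome)
  expect_identical(revcomp(substr(s, 5001, 5800)), substr(s, 7001, 7800))
})

test_that("regional GC tracks the specification", {
  spec <- plastome_spec(lsc_len = 30000L, irb_len = 12000L,
                        ssc_len = 10000L, n_cds_lsc = 4L, n_cds_ssc = 1L,
                        n_cds_ir = 1L, cds_len_range = c(300L, 600L),
                        seed = 13L)
  sim <- generate_plastome(spec)
  st <- sim$structure
  g <- sim$genome
  # planted ORFs perturb composition slightly; 2 percentage points of
  # slack covers both sampling error and the coding fraction
  expect_lt(abs(gc_fraction(g, st$lsc[1], st$lsc[2]) - 33.10), 2)
  expect_lt(abs(gc_fraction(g, st$ssc[1], st$ssc[2]) - 36.43), 2)
  expect_lt(abs(gc_fraction(g, st$irb[1], st$irb[2]) - 44.01), 2)
})

test_that("zero mutation rates return an identical genome", {
  sim <- generate_plastome(plastome_spec(lsc_len = 5000L, irb_len = 800L,
                                         ssc_len = 1200L, n_cds_lsc = 3L,
                                         n_cds_ssc = 1L, n_cds_ir = 0L,
                                         cds_len_range = c(300L, 450L),
                                         seed = 21L))
  mut <- mutate_genome(sim, mutation_spec(sub_rate = 0, indel_rate = 0,
                                          seed = 1L))
  expect_identical(genome_seq(mut$genome), genome_seq(sim$genome))
  expect_equal(nrow(mut$truth), 0L)
})

test_that("planted substitution counts follow the binomial expectation", {
  spec <- plastome_spec(lsc_len = 80000L, irb_len = 12000L,
                        ssc_len = 12000L, n_cds_lsc = 6L, n_cds_ssc = 1L,
                        n_cds_ir = 1L, cds_len_range = c(300L, 600L),
                        seed = 31L)
  sim <- generate_plastome(spec)
  st <- sim$structure
  sc_len <- diff(st$lsc) + 1L + diff(st$ssc) + 1L
  ir_len <- diff(st$irb) + 1L
  mut <- mutate_genome(sim, mutation_spec(sub_rate = 0.001,
                                          ir_rate_factor = 0.072,
                                          indel_rate = 0, seed = 5L))
  n_snp <- sum(mut$truth$kind == "SNP")
  expected <- sc_len * 0.001 + ir_len * 0.001 * 0.072
  expect_lt(abs(n_snp - expected), 3 * sqrt(expected))
  # the IR carries far fewer substitutions than single-copy sequence
  n_ir <- sum(mut$truth$kind == "SNP" & mut$truth$region == "IR")
  expect_lt(n_ir / ir_len, 0.0005)
})

test_that("planted transition fraction follows kappa", {
  spec <- plastome_spec(lsc_len = 60000L, irb_len = 8000L, ssc_len = 8000L,
                        n_cds_lsc = 5L, n_cds_ssc = 1L, n_cds_ir = 1L,
                        cds_len_range = c(300L, 600L), seed = 33L)
  sim <- generate_plastome(spec)
  mut <- mutate_genome(sim, mutation_spec(sub_rate = 0.009, kappa = 2,
                                          indel_rate = 0, seed = 6L))
  tr <- mut$truth[mut$truth$kind == "SNP", ]
  expect_gte(nrow(tr), 500L)
  phat <- mean(tr$class == "transition")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})

test_that("the truth record reconstructs the derived genome exactly", {
  sims <- small_sim(seed = 71L, mut_seed = 8L)
  st <- sims$sim$structure
  red_ref <- substr(genome_seq(sims$sim$genome), 1, st$ira[1] - 1L)
  red_drv <- apply_variants(red_ref, sims$mut$truth)
  # the derived genome is the edited reduced genome plus the mirrored IRa
  full <- genome_seq(sims$mut$genome)
  expect_identical(substr(full, 1, nchar(red_drv)), red_drv)
  expect_equal(nchar(full) - nchar(red_drv),
               nchar(full) - (st$ira[1] - 1L) -
                 sum(ifelse(sims$mut$truth$kind == "insertion", 1L, -1L) *
                       sims$mut$truth$length *
                       (sims$mut$truth$kind != "SNP")))
})

test_that("simulated reads are exact substrings when error-free", {
  sim <- generate_plastome(plastome_spec(lsc_len = 4000L, irb_len = 600L,
                                         ssc_len = 1000L, n_cds_lsc = 2L,
                                         n_cds_ssc = 1L, n_cds_ir = 0L,
                                         cds_len_range = c(300L, 450L),
                                         seed = 81L))
  rs <- simulate_reads(sim$genome, 300L, 36L, error_rate = 0, seed = 2L)
  s2 <- paste0(genome_seq(sim$genome), genome_seq(sim$genome))
  for (i in seq_len(50L)) {
    r <- rs$reads$seq[i]
    hit <- grepl(r, s2, fixed = TRUE) || grepl(revcomp(r), s2, fixed = TRUE)
    expect_true(hit)
  }
  # truth matches the sampled substring
  tr <- rs$truth
  facing <- substring(s2, tr$pos, tr$pos + 35L)
  minus <- tr$strand == "-"
  want <- ifelse(minus, revcomp(facing), facing)
  expect_identical(rs$reads$seq, want)
})

test_that("read error rates match the requested rate", {
  sim <- generate_plastome(plastome_spec(lsc_len = 20000L, irb_len = 2000L,
                                         ssc_len = 4000L, n_cds_lsc = 3L,
                                         n_cds_ssc = 1L, n_cds_ir = 0L,
                                         cds_len_range = c(300L, 450L),
                                         seed = 91L))
  n_reads <- 30000L %/% 36L + 1L   # ~1e6 / 36 scaled down: 30 kb of bases
  rs <- simulate_reads(sim$genome, n_reads, 36L, error_rate = 0.01,
                       seed = 3L)
  s2 <- paste0(genome_seq(sim$genome), genome_seq(sim$genome))
  facing <- substring(s2, rs$truth$pos, rs$truth$pos + 35L)
  obs <- ifelse(rs$truth$strand == "-", revcomp(rs$reads$seq), rs$reads$seq)
  mm <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)), obs, facing)
  total <- n_reads * 36L
  rate <- sum(mm) / total
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / total))
})
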