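#' Specification for a synthetic plastome
#'
#' Defaults reproduce the geometry and composition of a switchgrass-like
#' plastome: LSC 81,729 bp / IR 22,704 bp / SSC 12,540 bp (139,677 bp in
#' all), region GC of 33.1% (LSC), 36.4% (SSC) and 44.0% (IR), planted
#' protein-coding genes on both strands, and mononucleotide
#' homopolymers enriched in single-copy noncoding sequence.
#'
#' @param lsc_len,irb_len,ssc_len Segment lengths in bp.
#' @param gc_lsc,gc_ssc,gc_ir GC fractions per region.
#' @param n_cds_lsc,n_cds_ssc,n_cds_ir Number of CDS planted per region
#'   (IR genes are automatically duplicated into IRa by construction).
#' @param cds_len_range CDS length bounds in bp (rounded to codons).
#' @param hp_rate_sc,hp_rate_ir Planted homopolymers per kb of
#'   single-copy / IR noncoding sequence.
#' @param hp_len_min,hp_len_mean,hp_len_max Planted run length
#'   distribution (shifted geometric, truncated).
#' @param seed Integer seed; generation is reproducible bit-for-bit.
#' @return A list of class `plastome_spec`.
#' @export
plastome_spec <- function(lsc_len = 81729L, irb_len = 22704L,
                          ssc_len = 12540L,
                          gc_lsc = 0.3310, gc_ssc = 0.3643, gc_ir = 0.4401,
                          n_cds_lsc = 40L, n_cds_ssc = 6L, n_cds_ir = 8L,
                          cds_len_range = c(300L, 1500L),
                          hp_rate_sc = 1.0, hp_rate_ir = 0.2,
                          hp_len_min = 5L, hp_len_mean = 7, hp_len_max = 15L,
                          seed = 1L) {
  spec <- list(lsc_len = as.integer(lsc_len), irb_len = as.integer(irb_len),
               ssc_len = as.integer(ssc_len),
               gc_lsc = gc_lsc, gc_ssc = gc_ssc, gc_ir = gc_ir,
               n_cds_lsc = n_cds_lsc, n_cds_ssc = n_cds_ssc,
               n_cds_ir = n_cds_ir, cds_len_range = cds_len_range,
               hp_rate_sc = hp_rate_sc, hp_rate_ir = hp_rate_ir,
               hp_len_min = as.integer(hp_len_min),
               hp_len_mean = hp_len_mean,
               hp_len_max = as.integer(hp_len_max),
               seed = as.integer(seed))
  stopifnot(spec$lsc_len > 0L, spec$irb_len > 0L, spec$ssc_len > 0L,
            gc_lsc > 0 && gc_lsc < 1, gc_ssc > 0 && gc_ssc < 1,
            gc_ir > 0 && gc_ir < 1)
  structure(spec, class = "plastome_spec")
}

#' Specification for the mutation process between two plastomes
#'
#' Defaults emulate the divergence observed between two conspecific
#' plastome ecotypes: substitution rate ~1.2e-3 per bp in the reduced
#' genome, a transition/transversion rate ratio kappa of 1.1 (an
#' observed Tn/Tv count ratio near 0.55), an indel rate ~4e-4 per bp
#' with ~74% of indels forced into homopolymer (slippage) contexts, and
#' geometric indel lengths truncated at 50 bp.
#'
#' @param sub_rate Substitutions per bp in single-copy sequence.
#' @param ir_rate_factor Multiplier on `sub_rate` inside the inverted
#'   repeat. Plastome IRs evolve much more slowly than single-copy
#'   sequence (copy-correction); the default 0.072 reproduces an IR
#'   rate near 9e-5 when the single-copy rate is 1.23e-3.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param indel_rate Indels per bp.
#' @param slippage_bias Fraction of indels planted at homopolymer runs.
#' @param indel_len_p Geometric parameter for random indel lengths
#'   (length = 1 + rgeom(p); truncated at `indel_len_max`).
#' @param indel_len_max Maximum indel length (default 50).
#' @param seed Integer seed.
#' @return A list of class `mutation_spec`.
#' @export
mutation_spec <- function(sub_rate = 0.00123, ir_rate_factor = 0.072,
                          kappa = 1.1,
                          indel_rate = 4e-4, slippage_bias = 0.74,
                          indel_len_p = 0.35, indel_len_max = 50L,
                          seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.05, indel_rate >= 0,
            indel_rate <= 0.05, kappa > 0,
            slippage_bias >= 0, slippage_bias <= 1,
            ir_rate_factor >= 0, ir_rate_factor <= 1)
  structure(list(sub_rate = sub_rate, ir_rate_factor = ir_rate_factor,
                 kappa = kappa,
                 indel_rate = indel_rate, slippage_bias = slippage_bias,
                 indel_len_p = indel_len_p,
                 indel_len_max = as.integer(indel_len_max),
                 seed = as.integer(seed)),
            class = "mutation_spec")
}

sense_codons <- function() {
  code <- genetic_code_11()
  names(code)[code != "*"]
}

# Random ORF whose codon composition follows the region's GC (stop
# codons resampled), so planted genes do not distort regional GC.
random_orf <- function(len_bp, gc = 0.4) {
  ncod <- max(3L, len_bp %/% 3L)
  n_body <- ncod - 2L
  body <- character(0L)
  while (length(body) < n_body) {
    cand <- apply(matrix(random_bases(3L * (n_body - length(body) + 8L), gc),
                         nrow = 3L), 2L, paste, collapse = "")
    cand <- cand[!cand %in% c("TAA", "TAG", "TGA")]
    body <- c(body, cand)
  }
  paste(c("ATG", body[seq_len(n_body)],
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

# Allocate n non-overlapping intervals of the given lengths inside
# [1, region_len], with a margin between them; simple rejection sampler.
allocate_slots <- function(region_len, lens, margin = 40L) {
  taken <- IRanges::IRanges()
  out <- integer(length(lens))
  for (i in seq_along(lens)) {
    if (region_len - lens[i] - margin <= 1L)
      stop("features requested exceed region capacity")
    for (try in 1:200) {
      st <- sample.int(region_len - lens[i] - margin, 1L) + margin %/% 2L
      iv <- IRanges::IRanges(st - margin, st + lens[i] - 1L + margin)
      if (length(IRanges::findOverlaps(iv, taken)) == 0L) {
        taken <- c(taken, iv)
        out[i] <- st
        break
      }
      if (try == 200L) stop("features requested exceed region capacity")
    }
  }
  out
}

#' Generate a synthetic plastome with annotations and ground truth
#'
#' Builds the quadripartite genome LSC + IRb + SSC + revcomp(IRb),
#' plants intact open reading frames (ATG start, no internal stop,
#' terminal stop; both strands) and mononucleotide homopolymer runs in
#' noncoding sequence at region-specific rates, and records everything
#' planted. Generation is deterministic given `spec$seed`.
#'
#' @param spec A `plastome_spec`.
#' @return A list: `genome` (`circular_genome`), `features`
#'   (`feature_table`, IR genes present as both copies), `structure`
#'   (`quadripartite`), `truth` (planted CDS and homopolymers plus the
#'   spec).
#' @export
generate_plastome <- function(spec) {
  stopifnot(inherits(spec, "plastome_spec"))
  set.seed(spec$seed)
  regions <- list(
    lsc = list(len = spec$lsc_len, gc = spec$gc_lsc, n_cds = spec$n_cds_lsc),
    irb = list(len = spec$irb_len, gc = spec$gc_ir, n_cds = spec$n_cds_ir),
    ssc = list(len = spec$ssc_len, gc = spec$gc_ssc, n_cds = spec$n_cds_ssc))
  offsets <- c(lsc = 0L, irb = spec$lsc_len,
               ssc = spec$lsc_len + spec$irb_len)
  vecs <- list()
  feat <- list()
  ssr_truth <- list()
  cds_truth <- list()
  gi <- 0L
  for (rn in names(regions)) {
    rg <- regions[[rn]]
    v <- random_bases(rg$len, rg$gc)
    cds_iv <- IRanges::IRanges()
    if (rg$n_cds > 0L) {
      lens <- (sample(seq(spec$cds_len_range[1L], spec$cds_len_range[2L]),
                      rg$n_cds, replace = TRUE) %/% 3L) * 3L
      starts <- allocate_slots(rg$len, lens)
      for (i in seq_len(rg$n_cds)) {
        gi <- gi + 1L
        orf <- random_orf(lens[i], gc = rg$gc)
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "-") revcomp(orf) else orf
        v[starts[i]:(starts[i] + lens[i] - 1L)] <-
          strsplit(ins, "", fixed = TRUE)[[1L]]
        gs <- offsets[[rn]] + starts[i]
        ge <- gs + lens[i] - 1L
        nm <- sprintf("gene%03d", gi)
        feat[[length(feat) + 1L]] <- data.table::data.table(
          name = nm, kind = "CDS", strand = strand,
          start = gs, end = ge, part = 1L, copy = 1L, start_codon = "none")
        cds_truth[[length(cds_truth) + 1L]] <- data.table::data.table(
          name = nm, region = toupper(rn), strand = strand,
          start = gs, end = ge)
        cds_iv <- c(cds_iv, IRanges::IRanges(starts[i], starts[i] + lens[i] - 1L))
      }
    }
    # homopolymers in noncoding sequence
    rate <- if (rn == "irb") spec$hp_rate_ir else spec$hp_rate_sc
    n_hp <- stats::rpois(1L, rate * rg$len / 1000)
    placed <- IRanges::IRanges()
    guard <- c(cds_iv, placed)
    h <- 0L; tries <- 0L
    while (h < n_hp && tries < 50L * n_hp + 50L) {
      tries <- tries + 1L
      L <- min(spec$hp_len_min +
                 stats::rgeom(1L, 1 / (spec$hp_len_mean - spec$hp_len_min + 1)),
               spec$hp_len_max)
      st <- sample.int(rg$len - L - 4L, 1L) + 2L
      iv <- IRanges::IRanges(st - 2L, st + L + 1L)
      if (length(IRanges::findOverlaps(iv, guard)) > 0L) next
      base <- sample(c("A", "T", "G", "C"), 1L,
                     prob = c(0.45, 0.45, 0.05, 0.05))
      v[st:(st + L - 1L)] <- base
      # enforce maximality: flanks must differ from the run base
      alt <- setdiff(c("A", "C", "G", "T"), base)
      if (v[st - 1L] == base) v[st - 1L] <- sample(alt, 1L)
      if (v[st + L] == base) v[st + L] <- sample(alt, 1L)
      guard <- c(guard, iv)
      h <- h + 1L
      ssr_truth[[length(ssr_truth) + 1L]] <- data.table::data.table(
        base = base, length = L, start = offsets[[rn]] + st,
        end = offsets[[rn]] + st + L - 1L, region = toupper(rn))
    }
    vecs[[rn]] <- v
  }
  # make the planted inverted repeat maximal: the bases flanking the two
  # IR copies must not be complementary, or detection would rightly
  # extend the repeat beyond the planted boundaries
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pick_not <- function(avoid) sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
  nl <- length(vecs$lsc); ns <- length(vecs$ssc)
  if (vecs$lsc[nl] == comp[[vecs$lsc[1L]]])
    vecs$lsc[nl] <- pick_not(c(comp[[vecs$lsc[1L]]], vecs$lsc[nl - 1L]))
  if (vecs$ssc[1L] == comp[[vecs$ssc[ns]]])
    vecs$ssc[1L] <- pick_not(c(comp[[vecs$ssc[ns]]], vecs$ssc[2L]))
  irb_seq <- paste(vecs$irb, collapse = "")
  seq <- paste0(paste(vecs$lsc, collapse = ""), irb_seq,
                paste(vecs$ssc, collapse = ""), revcomp(irb_seq))
  genome <- circular_genome(sprintf("synthetic-%d", spec$seed), seq)
  st <- quadripartite(spec$lsc_len, spec$irb_len, spec$ssc_len,
                      genome_id = genome$id)

  features <- data.table::rbindlist(feat)
  # IRa copies of IR-resident genes (the assembly duplicates them)
  irb_feats <- features[features$start > st$irb[1L] - 1L &
                        features$end <= st$irb[2L], ]
  if (nrow(irb_feats) > 0L) {
    o1 <- irb_feats$start - st$irb[1L]
    o2 <- irb_feats$end - st$irb[1L]
    L <- spec$irb_len
    ira_feats <- data.table::copy(irb_feats)
    ira_feats[, `:=`(start = st$ira[1L] + L - 1L - o2,
                     end = st$ira[1L] + L - 1L - o1,
                     strand = ifelse(irb_feats$strand == "+", "-", "+"),
                     copy = 2L)]
    features <- data.table::rbindlist(list(features, ira_feats))
  }
  features <- validate_feature_table(features, n = st$n)

  list(genome = genome, features = features, structure = st,
       truth = list(cds = data.table::rbindlist(cds_truth),
                    ssrs = if (length(ssr_truth) > 0L)
                             data.table::rbindlist(ssr_truth)
                           else data.table::data.table(),
                    spec = spec))
}

#' Mutate a plastome into a derived genome with recorded truth
#'
#' Plants substitutions (transition probability `kappa/(kappa+2)`) and
#' indels (slippage-biased into homopolymer runs) on the IR-reduced
#' genome, then rebuilds the derived genome as LSC' + IRb' + SSC' +
#' revcomp(IRb') so that IR mutations appear in both copies (mirroring
#' the homogenisation of real plastome inverted repeats). Substitutions
#' that would introduce a stop codon into a planted CDS are resampled;
#' indels are restricted to noncoding positions away from region
#' boundaries. Every event is recorded with its intended
#' classification.
#'
#' @param sim Output of [generate_plastome()] (genome, features,
#'   structure).
#' @param mspec A `mutation_spec`.
#' @return A list: `genome` (derived `circular_genome`), `truth` (one
#'   row per planted event: kind, pos, ref, alt, length, class, region,
#'   coding, hp_assoc, run_length).
#' @export
mutate_genome <- function(sim, mspec) {
  stopifnot(inherits(mspec, "mutation_spec"))
  set.seed(mspec$seed + 1L)
  genome <- sim$genome; st <- sim$structure; features <- sim$features
  s <- genome_seq(genome)
  m <- st$ira[1L] - 1L                  # reduced genome length
  red <- substr(s, 1L, m)
  sv <- strsplit(red, "", fixed = TRUE)[[1L]]

  cds <- cds_rows(features)
  cds <- cds[cds$end <= m, ]
  in_cds <- logical(m)
  for (i in seq_len(nrow(cds))) in_cds[cds$start[i]:cds$end[i]] <- TRUE
  boundary_guard <- unique(c(1:60, (st$lsc[2L] - 60L):(st$lsc[2L] + 60L),
                             (st$irb[2L] - 60L):(st$irb[2L] + 60L),
                             (m - 60L):m))

  trans_of <- c(A = "G", G = "A", C = "T", T = "C")
  tv_of <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))

  # --- substitutions -------------------------------------------------------
  # boundary zones are kept mutation-free so the derived genome's IR
  # stays maximal at exactly the planted junctions; the IR mutates at a
  # reduced rate (copy-corrected, like real plastome repeats)
  in_ir <- seq_len(m) >= st$irb[1L] & seq_len(m) <= st$irb[2L]
  eligible <- setdiff(seq_len(m), boundary_guard)
  elig_sc <- eligible[!in_ir[eligible]]
  elig_ir <- eligible[in_ir[eligible]]
  n_sc <- stats::rbinom(1L, length(elig_sc), mspec$sub_rate)
  n_ir <- stats::rbinom(1L, length(elig_ir),
                        mspec$sub_rate * mspec$ir_rate_factor)
  snp_pos <- sort(c(sample(elig_sc, n_sc), sample(elig_ir, n_ir)))
  n_snp <- length(snp_pos)
  p_ts <- mspec$kappa / (mspec$kappa + 2)
  truth_snp <- vector("list", n_snp)
  sv_new <- sv
  for (i in seq_along(snp_pos)) {
    p <- snp_pos[i]
    refb <- sv[p]
    if (refb == "N") next
    ok <- FALSE
    for (try in 1:8) {
      if (stats::runif(1L) < p_ts) {
        alt <- trans_of[[refb]]; cls <- "transition"
      } else {
        alt <- sample(tv_of[[refb]], 1L); cls <- "transversion"
      }
      if (!in_cds[p] || !creates_stop(sv_new, p, alt, cds)) { ok <- TRUE; break }
    }
    if (!ok) next
    sv_new[p] <- alt
    truth_snp[[i]] <- data.table::data.table(
      kind = "SNP", pos = p, ref = refb, alt = alt, length = 1L,
      class = cls, region = region_of(p, st), coding = in_cds[p],
      hp_assoc = FALSE, run_length = NA_integer_)
  }
  truth <- data.table::rbindlist(truth_snp)

  # --- indels (planted on the unmutated reference coordinates) -------------
  n_ind <- stats::rbinom(1L, m, mspec$indel_rate)
  runs <- seq_runs(red)
  runs <- runs[runs$length >= 5L & runs$base != "N" &
               !in_cds[runs$start] & !(runs$start %in% boundary_guard), ]
  events <- list()
  occupied <- snp_pos
  tries <- 0L
  while (length(events) < n_ind && tries < 60L * n_ind + 60L) {
    tries <- tries + 1L
    slip <- stats::runif(1L) < mspec$slippage_bias && nrow(runs) > 0L
    if (slip) {
      # slippage rates rise steeply with run length, so long runs are
      # preferentially hit
      r <- runs[sample.int(nrow(runs), 1L, prob = runs$length^2)]
      p <- r$start
      L <- 1L
      ins <- stats::runif(1L) < 0.5
      allele <- r$base
      hp <- TRUE; rl <- r$length
    } else {
      p <- sample.int(m - 60L, 1L) + 30L
      if (in_cds[p]) next
      L <- min(1L + stats::rgeom(1L, mspec$indel_len_p), mspec$indel_len_max)
      ins <- stats::runif(1L) < 0.5
      allele <- if (ins) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                               collapse = "")
                else substr(red, p, p + L - 1L)
      hp <- FALSE; rl <- NA_integer_
    }
    if (p %in% boundary_guard) next
    span <- (p - 55L):(p + L + 55L)
    if (any(span %in% occupied)) next
    if (!ins && any(in_cds[p:(p + L - 1L)])) next
    occupied <- c(occupied, span)
    norm <- leftalign_indel(red, p, allele)
    events[[length(events) + 1L]] <- data.table::data.table(
      kind = if (ins) "insertion" else "deletion",
      pos = norm$pos,
      ref = if (ins) "" else norm$allele,
      alt = if (ins) norm$allele else "",
      length = L, class = "n/a", region = region_of(p, st),
      coding = FALSE, hp_assoc = hp, run_length = rl)
  }
  if (length(events) > 0L)
    truth <- data.table::rbindlist(list(truth,
                                        data.table::rbindlist(events)))
  if (nrow(truth) == 0L)
    truth <- data.table::data.table(
      kind = character(), pos = integer(), ref = character(),
      alt = character(), length = integer(), class = character(),
      region = character(), coding = logical(), hp_assoc = logical(),
      run_length = integer())
  data.table::setorder(truth, pos)

  # --- build the derived genome -------------------------------------------
  derived_red <- apply_variants(paste(sv_new, collapse = ""),
                                truth[truth$kind != "SNP", ])
  # region boundary shifts from indels
  delta <- function(iv) {
    ind <- truth[truth$kind != "SNP" & truth$pos >= iv[1L] &
                 truth$pos <= iv[2L], ]
    sum(ifelse(ind$kind == "insertion", ind$length, -ind$length))
  }
  lsc_len2 <- diff(st$lsc) + 1L + delta(st$lsc)
  irb_len2 <- diff(st$irb) + 1L + delta(st$irb)
  ssc_len2 <- (m - st$ssc[1L] + 1L) + delta(c(st$ssc[1L], m))
  irb2 <- substr(derived_red, lsc_len2 + 1L, lsc_len2 + irb_len2)
  derived <- paste0(derived_red, revcomp(irb2))
  stopifnot(nchar(derived) == lsc_len2 + 2L * irb_len2 + ssc_len2)

  data.table::setattr(truth, "class",
                      c("variant_table", class(truth)))
  list(genome = circular_genome(paste0(genome$id, "-derived"), derived),
       truth = truth[])
}

# Would substituting position p with `alt` put a stop codon inside a CDS?
creates_stop <- function(sv, p, alt, cds) {
  hit <- cds[cds$start <= p & cds$end >= p, ]
  if (nrow(hit) == 0L) return(FALSE)
  row <- hit[1L, ]
  old <- sv[p]
  sv[p] <- alt
  if (row$strand == "+") {
    idx <- p - row$start + 1L
    ci <- (idx - 1L) %/% 3L
    cpos <- row$start + ci * 3L + 0:2
    codon <- paste(sv[cpos], collapse = "")
  } else {
    idx <- row$end - p + 1L
    ci <- (idx - 1L) %/% 3L
    cpos <- row$end - ci * 3L - (0:2)
    codon <- paste(sv[cpos], collapse = "")
    codon <- chartr("ACGT", "TGCA", codon)
  }
  sv[p] <- old
  is_stop <- codon %in% c("TAA", "TAG", "TGA")
  # the terminal stop codon is allowed to stay a stop
  last_codon <- ci == (row$end - row$start + 1L) %/% 3L - 1L
  is_stop && !last_codon
}

#' Simulate error-bearing short reads from a circular genome
#'
#' Uniform start positions on the circle, both strands. Per-base
#' substitution errors at `error_rate`. Optionally applies C-to-U
#' editing: a stated fraction of the reads overlapping each editing
#' site carries the edited base (T on the gene strand).
#'
#' @param genome A `circular_genome`.
#' @param n_reads Number of reads (> 0).
#' @param read_len Read length (default 36).
#' @param error_rate Per-base substitution error probability.
#' @param editing Optional list(`sites` = data.frame(pos, strand),
#'   `fraction` = editing fraction).
#' @param seed Integer seed.
#' @return A list: `reads` (`data.table` id/seq/qual), `truth`
#'   (placements: id, pos, strand).
#' @export
simulate_reads <- function(genome, n_reads, read_len = 36L,
                           error_rate = 0, editing = NULL, seed = 1L) {
  if (n_reads <= 0L) stop("n_reads must be > 0")
  s <- genome_seq(genome)
  n <- nchar(s)
  if (read_len > n) stop("read length exceeds genome length")
  set.seed(seed)
  s2 <- paste0(s, s)
  pos <- sample.int(n, n_reads, replace = TRUE)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  facing <- substring(s2, pos, pos + read_len - 1L)

  if (!is.null(editing)) {
    sites <- editing$sites
    frac <- editing$fraction
    for (j in seq_len(nrow(sites))) {
      off <- ((sites$pos[j] - pos) %% n) + 1L
      cover <- which(off >= 1L & off <= read_len)
      edit <- cover[stats::runif(length(cover)) < frac]
      eb <- if (sites$strand[j] == "+") "T" else "A"
      for (i in edit) substr(facing[i], off[i], off[i]) <- eb
    }
  }
  if (error_rate > 0) {
    total <- n_reads * read_len
    n_err <- stats::rbinom(1L, total, error_rate)
    if (n_err > 0L) {
      at <- sample.int(total, n_err)
      ri <- ((at - 1L) %/% read_len) + 1L
      ci <- ((at - 1L) %% read_len) + 1L
      for (e in seq_len(n_err)) {
        cur <- substr(facing[ri[e]], ci[e], ci[e])
        substr(facing[ri[e]], ci[e], ci[e]) <-
          sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
  }
  out_seq <- facing
  minus <- strand == "-"
  if (any(minus)) out_seq[minus] <- revcomp(out_seq[minus])
  ids <- sprintf("read%06d", seq_len(n_reads))
  list(reads = data.table::data.table(id = ids, seq = out_seq,
                                      qual = strrep("I", read_len)),
       truth = data.table::data.table(id = ids, pos = pos, strand = strand))
}
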