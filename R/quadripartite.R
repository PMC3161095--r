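#' Detect the quadripartite plastome structure
#'
#' Finds the maximal pair of disjoint, exactly reverse-complementary
#' repeats of length at least `min_ir_length` (the inverted repeats IRb
#' and IRa) and derives the canonical LSC / IRb / SSC / IRa layout. The
#' longer single-copy segment is labelled LSC and the canonical rotation
#' places its first base at position 1. Detection works on the doubled
#' sequence so repeats spanning the arbitrary linearisation point are
#' found.
#'
#' @param genome A `circular_genome`.
#' @param min_ir_length Minimum acceptable repeat length (default 1000
#'   to avoid spurious short palindromes; must be >= 100).
#' @param k Seed k-mer size used by the matcher (internal; capped at
#'   `min_ir_length`).
#' @return An object of class `quadripartite` with 1-based inclusive
#'   intervals `lsc`, `irb`, `ssc`, `ira` on the canonical rotation,
#'   the `offset` (original coordinate of canonical position 1) and the
#'   genome length `n`.
#' @export
detect_quadripartite <- function(genome, min_ir_length = 1000L, k = 31L) {
  stopifnot(inherits(genome, "circular_genome"))
  if (!genome$circular) stop("genome must be circular")
  if (min_ir_length < 100L) stop("min_ir_length must be >= 100")
  s <- genome_seq(genome)
  n <- nchar(s)
  k <- as.integer(min(k, min_ir_length, n %/% 3L))
  if (k < 8L) stop("genome too short for inverted-repeat detection")

  s2 <- paste0(s, s)
  rc <- revcomp(s)

  a_pos <- seq_len(2L * n - k + 1L)
  c_pos <- seq_len(n - k + 1L)
  dt_a <- data.table::data.table(kmer = substring(s2, a_pos, a_pos + k - 1L),
                                 a = a_pos)
  dt_c <- data.table::data.table(kmer = substring(rc, c_pos, c_pos + k - 1L),
                                 cc = c_pos)
  m <- merge(dt_a, dt_c, by = "kmer", allow.cartesian = TRUE)
  if (nrow(m) == 0L) stop("no quadripartite structure: no inverted repeat >= ",
                          min_ir_length, " bp")
  m[, d := a - cc]
  data.table::setorder(m, d, a)
  m[, run := cumsum(c(1L, diff(a) != 1L)), by = d]
  runs <- m[, .(a0 = min(a), c0 = min(cc), L = max(a) - min(a) + k),
            by = .(d, run)]
  runs <- runs[L >= min_ir_length & a0 <= n]
  # b-interval: original location of the segment whose reverse complement
  # was matched in rc.
  runs[, `:=`(b_start = n - c0 - L + 2L, b_end = n - c0 + 1L)]
  runs[, `:=`(a_start = a0, a_end = a0 + L - 1L)]

  # keep disjoint (on the circle) non-self pairs
  circ_overlap <- function(s1, e1, s2, e2) {
    # intervals on doubled coordinates; reduce to circle membership test
    p1 <- ((s1:e1 - 1L) %% n) + 1L
    p2 <- ((s2:e2 - 1L) %% n) + 1L
    any(p2 %in% p1)
  }
  if (nrow(runs) == 0L)
    stop("no quadripartite structure: no inverted repeat >= ",
         min_ir_length, " bp")
  ok <- vapply(seq_len(nrow(runs)), function(i) {
    with(runs[i], !circ_overlap(a_start, a_end, b_start, b_end) &&
                  2L * L <= n)
  }, logical(1L))
  runs <- runs[ok]
  if (nrow(runs) == 0L)
    stop("no quadripartite structure: no disjoint inverted repeat >= ",
         min_ir_length, " bp")

  # canonical key so that the (IRb,IRa) and (IRa,IRb) discoveries collapse
  runs[, key := paste(pmin((a_start - 1L) %% n + 1L, b_start),
                      pmax((a_start - 1L) %% n + 1L, b_start), L, sep = ":")]
  runs <- unique(runs, by = "key")
  best <- runs[L == max(L)]
  if (nrow(best) > 1L) {
    stop("ambiguous quadripartite structure: co-maximal repeat pairs at ",
         paste(best$key, collapse = "; "))
  }
  L <- best$L
  i1s <- ((best$a_start - 1L) %% n) + 1L
  i2s <- best$b_start
  # order the two copies by circle start
  starts <- sort(c(i1s, i2s))
  r1 <- c(starts[1L], ((starts[1L] + L - 2L) %% n) + 1L)
  r2 <- c(starts[2L], ((starts[2L] + L - 2L) %% n) + 1L)

  # single-copy arcs between the repeats (forward direction)
  arc_len <- function(from, to) ((to - from) %% n)  # bases strictly between
  end1 <- ((starts[1L] + L - 1L) %% n)  # 0-based position after copy 1
  end2 <- ((starts[2L] + L - 1L) %% n)
  gap12 <- (starts[2L] - 1L - end1) %% n   # arc between copy1 end and copy2 start
  gap21 <- (starts[1L] - 1L - end2) %% n
  if (gap12 + gap21 + 2L * L != n)
    stop("internal error: quadripartite cover mismatch")

  if (gap21 >= gap12) {
    lsc_len <- gap21; ssc_len <- gap12
    lsc_start0 <- (end2 %% n) + 1L      # first base after copy 2
    irb_start <- starts[1L]
  } else {
    lsc_len <- gap12; ssc_len <- gap21
    lsc_start0 <- (end1 %% n) + 1L
    irb_start <- starts[2L]
  }
  if (lsc_len == 0L) stop("no quadripartite structure: repeats are adjacent")

  st <- quadripartite(lsc_len, L, ssc_len, n = n, offset = lsc_start0,
                      genome_id = genome$id)
  validate_quadripartite(st, genome)
  st
}

#' Build a quadripartite structure object from segment lengths
#'
#' @param lsc_len,ir_len,ssc_len Segment lengths in bp.
#' @param n Genome length (defaults to the sum with two IR copies).
#' @param offset Original 1-based coordinate of canonical position 1.
#' @param genome_id Optional label.
#' @return A `quadripartite` object with canonical intervals.
#' @export
quadripartite <- function(lsc_len, ir_len, ssc_len,
                          n = lsc_len + 2L * ir_len + ssc_len,
                          offset = 1L, genome_id = NA_character_) {
  stopifnot(lsc_len > 0L, ir_len > 0L, ssc_len >= 0L,
            n == lsc_len + 2L * ir_len + ssc_len)
  lsc <- c(1L, lsc_len)
  irb <- c(lsc_len + 1L, lsc_len + ir_len)
  ssc <- c(irb[2L] + 1L, irb[2L] + ssc_len)
  ira <- c(ssc[2L] + 1L, n)
  structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 n = as.integer(n), offset = as.integer(offset),
                 genome_id = genome_id),
            class = "quadripartite")
}

validate_quadripartite <- function(st, genome) {
  g <- canonicalize_rotation(genome, st)
  s <- genome_seq(g)
  irb <- substr(s, st$irb[1L], st$irb[2L])
  ira <- substr(s, st$ira[1L], st$ira[2L])
  if (!identical(revcomp(irb), ira))
    stop("invalid structure: IRb is not the exact reverse complement of IRa")
  invisible(st)
}

#' @export
print.quadripartite <- function(x, ...) {
  seg <- structure_table(x)
  cat(sprintf("<quadripartite> genome %s (%s bp, canonical offset %d)\n",
              x$genome_id, format(x$n, big.mark = ","), x$offset))
  print(as.data.frame(seg))
  invisible(x)
}

#' Segment table for a quadripartite structure
#'
#' @param structure A `quadripartite` object.
#' @param genome Optional `circular_genome` (canonical rotation is applied
#'   internally); when given, per-segment GC percentages are included.
#' @return A `data.table` with one row per segment (1-based inclusive
#'   coordinates on the canonical rotation).
#' @export
structure_table <- function(structure, genome = NULL) {
  segs <- c("LSC", "IRb", "SSC", "IRa")
  iv <- list(structure$lsc, structure$irb, structure$ssc, structure$ira)
  out <- data.table::data.table(
    segment = segs,
    start = vapply(iv, `[`, integer(1L), 1L),
    end = vapply(iv, `[`, integer(1L), 2L))
  out[, length := end - start + 1L]
  if (!is.null(genome)) {
    g <- canonicalize_rotation(genome, structure)
    out[, gc_percent := vapply(seq_len(.N), function(i)
      round(gc_fraction(g, start[i], end[i]), 2L), numeric(1L))]
  }
  out[]
}

#' Rotate a genome to its canonical quadripartite origin
#'
#' The canonical rotation places the first LSC base at position 1, with
#' segments in the order LSC, IRb, SSC, IRa. Idempotent.
#'
#' @param genome A `circular_genome`.
#' @param structure The matching `quadripartite` structure.
#' @return The rotated `circular_genome`.
#' @export
canonicalize_rotation <- function(genome, structure) {
  if (genome_length(genome) != structure$n)
    stop("structure/genome length mismatch")
  rotate_genome(genome, structure$offset)
}

#' Region label for canonical positions
#'
#' @param pos Integer vector of 1-based canonical positions.
#' @param structure A `quadripartite` object.
#' @return Character vector over `LSC`, `SSC`, `IR` (both IR copies map
#'   to `IR`).
#' @export
region_of <- function(pos, structure) {
  if (any(pos < 1L | pos > structure$n)) stop("position outside genome")
  out <- character(length(pos))
  out[pos <= structure$lsc[2L]] <- "LSC"
  out[pos >= structure$irb[1L] & pos <= structure$irb[2L]] <- "IR"
  out[pos >= structure$ssc[1L] & pos <= structure$ssc[2L]] <- "SSC"
  out[pos >= structure$ira[1L]] <- "IR"
  out
}

#' Mirror an IRa position onto its IRb copy
#'
#' Positions inside IRa are reflected onto the corresponding base of IRb
#' (the two copies are exact reverse complements); all other positions
#' are returned unchanged. Used to count the inverted repeat once.
#'
#' @param pos Integer vector of canonical positions.
#' @param structure A `quadripartite` object.
#' @return Integer vector of positions with IRa collapsed onto IRb.
#' @export
mirror_ir_position <- function(pos, structure) {
  in_ira <- pos >= structure$ira[1L] & pos <= structure$ira[2L]
  pos[in_ira] <- structure$irb[1L] + (structure$ira[2L] - pos[in_ira])
  pos
}
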