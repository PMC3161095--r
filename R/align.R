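#' Align two near-identical genomes by unique-anchor chaining
#'
#' MUM-style whole-genome alignment: maximal exact matches that are
#' unique in both sequences (seeded with unique `min_anchor`-mers) are
#' chained to the highest-coverage co-linear chain (longest increasing
#' subsequence on query positions), and the inter-anchor gaps are closed
#' with affine-gap global alignment. Intended for genome pairs with
#' identity well above 95%, such as two plastomes of one species.
#'
#' For circular genomes both inputs must already be on the same rotation
#' convention (see [canonicalize_rotation()]). When comparing full
#' plastomes use [compare_plastomes()], which aligns the IR-reduced
#' form (LSC + IRb + SSC) so the inverted repeat is counted once.
#'
#' @param ref,query `circular_genome` objects or nucleotide strings.
#' @param min_anchor Anchor seed length (default 20 bp).
#' @param match,mismatch,gap_open,gap_extend Affine scoring used for the
#'   gap closure (defaults 1, -2, -4, -1; near-identical genomes are
#'   insensitive to these).
#' @param max_gap Largest inter-anchor gap the closer will attempt
#'   (guard against runaway alignments of diverged input).
#' @return An object of class `anchor_alignment`: gapped strings
#'   `ref_aln` and `qry_aln`, the `anchors` table, and input ids.
#' @export
align_pair <- function(ref, query, min_anchor = 20L,
                       match = 1, mismatch = -2, gap_open = 4,
                       gap_extend = 1, max_gap = 20000L) {
  r <- genome_seq(ref); q <- genome_seq(query)
  nr <- nchar(r); nq <- nchar(q)
  rid <- if (inherits(ref, "circular_genome")) ref$id else "ref"
  qid <- if (inherits(query, "circular_genome")) query$id else "query"

  if (identical(r, q)) {
    return(new_alignment(r, q, data.table::data.table(
      rstart = 1L, rend = nr, qstart = 1L, qend = nq), rid, qid))
  }

  k <- as.integer(min_anchor)
  anchors <- NULL
  if (nr > k && nq > k) {
    anchors <- find_anchors(r, q, k)
  }
  if (is.null(anchors) || nrow(anchors) == 0L) {
    if (max(nr, nq) > max_gap)
      stop("genomes too divergent: no unique anchors found")
    aln <- gap_align(r, q, match, mismatch, gap_open, gap_extend)
    return(new_alignment(aln[1L], aln[2L], data.table::data.table(
      rstart = integer(), rend = integer(),
      qstart = integer(), qend = integer()), rid, qid))
  }
  cov <- sum(anchors$rend - anchors$rstart + 1L)
  if (cov < 0.5 * nr || cov < 0.5 * nq)
    stop("genomes too divergent: anchor chain covers < 50% of a genome")

  # close gaps between consecutive anchors (and the two ends)
  ra <- character(0L); qa <- character(0L)
  prev_r <- 0L; prev_q <- 0L
  for (i in seq_len(nrow(anchors) + 1L)) {
    if (i <= nrow(anchors)) {
      rs <- anchors$rstart[i]; re <- anchors$rend[i]
      qs <- anchors$qstart[i]; qe <- anchors$qend[i]
    } else {
      rs <- nr + 1L; qs <- nq + 1L; re <- qe <- NA_integer_
    }
    gr <- if (rs > prev_r + 1L) substr(r, prev_r + 1L, rs - 1L) else ""
    gq <- if (qs > prev_q + 1L) substr(q, prev_q + 1L, qs - 1L) else ""
    if (nchar(gr) > max_gap || nchar(gq) > max_gap)
      stop("genomes too divergent: inter-anchor gap exceeds ", max_gap, " bp")
    if (nchar(gr) > 0L || nchar(gq) > 0L) {
      g <- gap_align(gr, gq, match, mismatch, gap_open, gap_extend)
      ra <- c(ra, g[1L]); qa <- c(qa, g[2L])
    }
    if (i <= nrow(anchors)) {
      anc <- substr(r, rs, re)
      ra <- c(ra, anc); qa <- c(qa, anc)
      prev_r <- re; prev_q <- qe
    }
  }
  new_alignment(paste(ra, collapse = ""), paste(qa, collapse = ""),
                anchors, rid, qid)
}

new_alignment <- function(ref_aln, qry_aln, anchors, ref_id, query_id) {
  stopifnot(nchar(ref_aln) == nchar(qry_aln))
  structure(list(ref_aln = ref_aln, qry_aln = qry_aln, anchors = anchors,
                 ref_id = ref_id, query_id = query_id),
            class = "anchor_alignment")
}

#' @export
print.anchor_alignment <- function(x, ...) {
  cat(sprintf("<anchor_alignment> %s vs %s: %d columns, %d anchors\n",
              x$ref_id, x$query_id, nchar(x$ref_aln), nrow(x$anchors)))
  invisible(x)
}

# Unique-k-mer seeds -> LIS chain -> merged, trimmed anchor intervals.
find_anchors <- function(r, q, k) {
  rpos <- seq_len(nchar(r) - k + 1L)
  qpos <- seq_len(nchar(q) - k + 1L)
  dr <- data.table::data.table(kmer = substring(r, rpos, rpos + k - 1L),
                               rpos = rpos)
  dq <- data.table::data.table(kmer = substring(q, qpos, qpos + k - 1L),
                               qpos = qpos)
  dr <- dr[, if (.N == 1L) .SD, by = kmer]
  dq <- dq[, if (.N == 1L) .SD, by = kmer]
  mm <- merge(dr, dq, by = "kmer")
  if (nrow(mm) == 0L) return(mm[, .(rstart = rpos, rend = rpos,
                                    qstart = qpos, qend = qpos)][0L])
  data.table::setorder(mm, rpos)
  keep <- lis_indices(mm$qpos)
  mm <- mm[keep]
  # merge consecutive same-diagonal seeds into maximal anchors
  mm[, d := rpos - qpos]
  mm[, grp := cumsum(c(1L, diff(rpos) != 1L | diff(d) != 0L))]
  anc <- mm[, .(rstart = min(rpos), rend = max(rpos) + k - 1L,
                qstart = min(qpos), qend = max(qpos) + k - 1L), by = grp]
  anc[, grp := NULL]
  # trim overlaps between consecutive anchors (exact matches, so trimming
  # the front of the later anchor preserves correctness)
  res <- vector("list", nrow(anc))
  prev_r <- 0L; prev_q <- 0L; j <- 0L
  for (i in seq_len(nrow(anc))) {
    a <- anc[i]
    t <- max(prev_r - a$rstart + 1L, prev_q - a$qstart + 1L, 0L)
    if (a$rend - a$rstart + 1L - t <= 0L) next
    a$rstart <- a$rstart + t; a$qstart <- a$qstart + t
    j <- j + 1L
    res[[j]] <- a
    prev_r <- a$rend; prev_q <- a$qend
  }
  data.table::rbindlist(res[seq_len(j)])
}

# Longest strictly increasing subsequence; returns indices.
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0L))
  tails <- integer(n)      # value of smallest tail of LIS of each length
  tails_idx <- integer(n)  # index of that tail in x
  prev <- integer(n)       # backpointers
  len <- 0L
  for (i in seq_len(n)) {
    lo <- findInterval(x[i] - 1L, tails[seq_len(len)]) + 1L
    tails[lo] <- x[i]
    tails_idx[lo] <- i
    prev[i] <- if (lo > 1L) tails_idx[lo - 1L] else 0L
    if (lo > len) len <- lo
  }
  out <- integer(len)
  cur <- tails_idx[len]
  for (j in rev(seq_len(len))) {
    out[j] <- cur
    cur <- prev[cur]
  }
  out
}

# Affine global alignment of two (possibly empty) strings, via
# Biostrings; returns c(gapped_a, gapped_b).
.sm_cache <- new.env(parent = emptyenv())

gap_align <- function(a, b, match = 1, mismatch = -2, gap_open = 4,
                      gap_extend = 1) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L && nb == 0L) return(c("", ""))
  if (na == 0L) return(c(strrep("-", nb), b))
  if (nb == 0L) return(c(a, strrep("-", na)))
  # equal-length micro-gaps between exact anchors are substitution runs:
  # with affine penalties a gap pair always scores below the mismatches
  if (na == nb && na <= 8L) return(c(a, b))
  key <- paste(match, mismatch)
  sm <- .sm_cache[[key]]
  if (is.null(sm)) {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                   mismatch = mismatch)
    .sm_cache[[key]] <- sm
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(b), subject = Biostrings::DNAString(a),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  c(as.character(Biostrings::alignedSubject(pa)),
    as.character(Biostrings::alignedPattern(pa)))
}
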