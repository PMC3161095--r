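#' Align short reads to a reference with at most one mismatch
#'
#' Ungapped, k-mer-seeded alignment: each read (and its reverse
#' complement) is seeded by its two halves against the doubled circular
#' reference, so a placement with at most `max_mismatch` substitutions
#' is always found if one exists (pigeonhole on read halves, for
#' `max_mismatch <= 1`). Reads with several equally good placements
#' (e.g. the two IR copies) are reported once at the first placement in
#' coordinate order and flagged as multi-mapping.
#'
#' @param reads A `data.table`/data.frame with columns `id` and `seq`
#'   (see [read_fastq()]), or a FASTQ path.
#' @param ref A `circular_genome`.
#' @param max_mismatch Maximum substitutions per retained placement
#'   (default 1, matching the confirmation protocol).
#' @return A list of class `read_alignment_set`: `placements`
#'   (`read_id`, `pos` 1-based on the reference, `strand`,
#'   `mismatches`, `multi`, `len`, `rseq` = the read oriented to the
#'   reference strand), `n_reads`, `aligned_fraction`.
#' @export
align_reads <- function(reads, ref, max_mismatch = 1L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  reads <- data.table::as.data.table(reads)
  stopifnot(all(c("id", "seq") %in% names(reads)))
  if (nrow(reads) == 0L) stop("no reads")
  lens <- nchar(reads$seq)
  if (any(lens < 20L)) stop("reads shorter than 20 bp are not supported")
  s <- genome_seq(ref)
  n <- nchar(s)
  s2 <- paste0(s, s)

  place_all <- list()
  for (L in sort(unique(lens))) {
    sub <- reads[lens == L]
    k <- L %/% 2L
    gpos <- seq_len(n)
    gidx <- data.table::data.table(kmer = substring(s2, gpos, gpos + k - 1L),
                                   gpos = gpos)
    data.table::setkey(gidx, kmer)
    cand <- list()
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") sub$seq else revcomp(sub$seq)
      q1 <- data.table::data.table(kmer = substr(rs, 1L, k),
                                   i = seq_len(nrow(sub)))
      q2 <- data.table::data.table(kmer = substr(rs, k + 1L, 2L * k),
                                   i = seq_len(nrow(sub)))
      c1 <- gidx[q1, on = "kmer", nomatch = NULL][, .(i, pos = gpos)]
      c2 <- gidx[q2, on = "kmer", nomatch = NULL][, .(i, pos = gpos - k)]
      cc <- data.table::rbindlist(list(c1, c2))
      if (nrow(cc) == 0L) next
      cc[, pos := ((pos - 1L) %% n) + 1L]
      cc <- unique(cc)
      cc[, strand := strand]
      cc[, rseq := rs[i]]
      cand[[length(cand) + 1L]] <- cc
    }
    if (length(cand) == 0L) next
    cc <- data.table::rbindlist(cand)
    tgt <- substring(s2, cc$pos, cc$pos + L - 1L)
    cc[, mm := mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                      rseq, tgt, USE.NAMES = FALSE)]
    cc <- cc[mm <= max_mismatch]
    if (nrow(cc) == 0L) next
    data.table::setorder(cc, i, mm, pos, strand)
    cc <- cc[, .SD[mm == mm[1L]], by = i]
    prim <- cc[, .(pos = pos[1L], strand = strand[1L],
                   mismatches = mm[1L], multi = .N > 1L,
                   rseq = rseq[1L]), by = i]
    prim[, `:=`(read_id = sub$id[i], len = L)]
    place_all[[length(place_all) + 1L]] <-
      prim[, .(read_id, pos, strand, mismatches, multi, len, rseq)]
  }
  placements <- if (length(place_all) > 0L) data.table::rbindlist(place_all)
                else data.table::data.table(read_id = character(),
                                            pos = integer(),
                                            strand = character(),
                                            mismatches = integer(),
                                            multi = logical(),
                                            len = integer(),
                                            rseq = character())
  structure(list(placements = placements, n_reads = nrow(reads),
                 aligned_fraction = nrow(placements) / nrow(reads),
                 genome_length = n, ref_id = ref$id),
            class = "read_alignment_set")
}

#' @export
print.read_alignment_set <- function(x, ...) {
  cat(sprintf("<read_alignment_set> %d/%d reads aligned (%.1f%%) to %s\n",
              nrow(x$placements), x$n_reads, 100 * x$aligned_fraction,
              x$ref_id))
  invisible(x)
}

#' Build a per-position pileup from read placements
#'
#' Tallies reference-strand base counts per position (ungapped
#' placements, circular wrap-around honoured) with a separate
#' forward-strand tally for strand-aware downstream checks.
#'
#' @param alignments A `read_alignment_set`.
#' @param ref The same reference `circular_genome`.
#' @return A list of class `pileup`: `counts` (4 x n matrix, rows
#'   A/C/G/T on the reference strand), `fwd` (forward-strand reads
#'   only), `depth` (per-position), `ref_base`, `breadth1`, `breadth4`
#'   (fractions of the genome at depth >= 1 and >= 4).
#' @export
build_pileup <- function(alignments, ref) {
  s <- genome_seq(ref)
  n <- nchar(s)
  if (alignments$genome_length != n)
    stop("alignments were made against a different reference length")
  pl <- alignments$placements
  tally <- function(rows) {
    if (length(rows) == 0L)
      return(matrix(0L, 4L, n, dimnames = list(c("A", "C", "G", "T"), NULL)))
    Ls <- pl$len[rows]
    pos0 <- rep(pl$pos[rows] - 1L, Ls) +
      unlist(lapply(Ls, seq_len)) - 1L
    posn <- (pos0 %% n) + 1L
    bases <- unlist(strsplit(pl$rseq[rows], "", fixed = TRUE), use.names = FALSE)
    bcode <- match(bases, c("A", "C", "G", "T"))
    keep <- !is.na(bcode)
    code <- (posn[keep] - 1L) * 4L + bcode[keep]
    cnt <- tabulate(code, nbins = 4L * n)
    matrix(cnt, nrow = 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
  }
  counts <- tally(seq_len(nrow(pl)))
  fwd <- tally(which(pl$strand == "+"))
  depth <- colSums(counts)
  structure(list(counts = counts, fwd = fwd, depth = depth,
                 ref_base = strsplit(s, "", fixed = TRUE)[[1L]],
                 breadth1 = mean(depth >= 1L),
                 breadth4 = mean(depth >= 4L), n = n),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf(
    "<pileup> %d positions; mean depth %.2f; breadth %.1f%% (>=1), %.1f%% (>=4)\n",
    x$n, mean(x$depth), 100 * x$breadth1, 100 * x$breadth4))
  invisible(x)
}

#' Call variable positions from a read-pool pileup
#'
#' Reports positions with depth at least `min_depth` where a
#' non-reference base reaches the `min_alt_frac` frequency. Positions
#' where every covering read differs from the reference are flagged
#' `invariant` (fixed differences between the pool and the reference).
#' The one-mismatch aligner is ungapped, so pool calls are substitution
#' sites; indel detection from reads is not attempted.
#'
#' @param pileup A `pileup`.
#' @param min_depth Minimum depth (default 5, i.e. depth > 4).
#' @param min_alt_frac Minimum non-reference allele frequency
#'   (default 0.8).
#' @param pool Label recorded on every call.
#' @return A `data.table`: `pos`, `ref`, `alt`, `depth`, `alt_count`,
#'   `alt_frac`, `invariant`, `pool`.
#' @export
call_pool_variants <- function(pileup, min_depth = 5L, min_alt_frac = 0.8,
                               pool = "pool") {
  if (min_depth < 1L) stop("min_depth must be >= 1")
  ok <- which(pileup$depth >= min_depth)
  if (length(ok) == 0L)
    return(data.table::data.table(pos = integer(), ref = character(),
                                  alt = character(), depth = integer(),
                                  alt_count = integer(), alt_frac = numeric(),
                                  invariant = logical(), pool = character()))
  bases <- c("A", "C", "G", "T")
  refb <- pileup$ref_base[ok]
  cnt <- pileup$counts[, ok, drop = FALSE]
  ridx <- match(refb, bases)
  cnt_alt <- cnt
  cnt_alt[cbind(ridx, seq_along(ok))] <- -1L
  alt_i <- max.col(t(cnt_alt), ties.method = "first")
  alt_count <- cnt[cbind(alt_i, seq_along(ok))]
  depth <- pileup$depth[ok]
  frac <- alt_count / depth
  sel <- alt_count > 0L & frac >= min_alt_frac
  data.table::data.table(
    pos = ok[sel], ref = refb[sel], alt = bases[alt_i[sel]],
    depth = as.integer(depth[sel]), alt_count = as.integer(alt_count[sel]),
    alt_frac = frac[sel],
    invariant = alt_count[sel] == depth[sel], pool = pool)
}

#' Overlap of pool calls with reference-pair variants
#'
#' Builds the membership table of variable positions over the
#' reference-pair variant set and any number of labelled pool call
#' sets, and derives inter-ecotype polymorphism rates: reference-pair
#' differences minus the portion shared by every pool (variation
#' segregating within both pools is not ecotype-diagnostic), per genome
#' length, in percent.
#'
#' @param call_sets Named list of pool call tables
#'   (from [call_pool_variants()]).
#' @param reference_variants A `variant_table` of the genome-pair
#'   comparison.
#' @param genome_length Reference length used for the rate denominators.
#' @return A list: `membership` (position x set logical table),
#'   `overlap` (pairwise overlap counts), `snp_rate_percent`,
#'   `indel_rate_percent`, `n_shared`.
#' @export
overlap_summary <- function(call_sets, reference_variants, genome_length) {
  stopifnot(length(call_sets) >= 1L, !is.null(names(call_sets)))
  ref_snp <- reference_variants$pos[reference_variants$kind == "SNP"]
  ref_indel <- reference_variants$pos[reference_variants$kind != "SNP"]
  sets <- c(list(reference_pair = c(ref_snp, ref_indel)),
            lapply(call_sets, function(x) x$pos))
  all_pos <- sort(unique(unlist(sets)))
  membership <- data.table::data.table(pos = all_pos)
  for (nm in names(sets)) membership[, (nm) := pos %in% sets[[nm]]]
  sn <- names(sets)
  overlap <- outer(sn, sn, Vectorize(function(a, b)
    length(intersect(sets[[a]], sets[[b]]))))
  dimnames(overlap) <- list(sn, sn)
  # variation found in EVERY pool segregates within both ecotype groups
  # and is therefore not diagnostic of the reference pair; it is
  # subtracted before the rates. With a single pool nothing can be shown
  # to be shared across pools, so nothing is subtracted.
  shared <- if (length(call_sets) >= 2L)
    Reduce(intersect, lapply(call_sets, function(x) x$pos))
  else integer(0L)
  snp_rate <- 100 * length(setdiff(ref_snp, shared)) / genome_length
  indel_rate <- 100 * length(setdiff(ref_indel, shared)) / genome_length
  list(membership = membership, overlap = overlap,
       snp_rate_percent = snp_rate, indel_rate_percent = indel_rate,
       n_shared = length(shared))
}

#' Verify predicted C-to-U RNA-editing sites against a pileup
#'
#' For each predicted site the strand-aware edited base is counted
#' (gene on `+`: reference `C`, edited reads show `T`; gene on `-`:
#' reference `G` on the forward strand, edited reads show `A`). A site
#' is flagged supported when at least one editing read is seen at depth
#' of 4 or more.
#'
#' @param sites A data.frame with columns `gene`, `pos` (forward-strand
#'   coordinate), `change` (predicted amino-acid change text) and
#'   `strand` (gene strand).
#' @param pileup A `pileup` covering the coordinates.
#' @param min_depth Depth required to assess a site (default 4).
#' @return The sites table with `depth`, `editing_reads`,
#'   `support_fraction` and `supported` columns added.
#' @export
verify_editing <- function(sites, pileup, min_depth = 4L) {
  sites <- data.table::as.data.table(sites)
  stopifnot(all(c("gene", "pos", "strand") %in% names(sites)))
  if (any(sites$pos < 1L | sites$pos > pileup$n))
    stop("editing site coordinate outside genome")
  edited_base <- ifelse(sites$strand == "+", "T", "A")
  bases <- c("A", "C", "G", "T")
  idx <- cbind(match(edited_base, bases), sites$pos)
  sites[, depth := pileup$depth[pos]]
  sites[, editing_reads := pileup$counts[idx]]
  sites[, support_fraction := ifelse(depth > 0L, editing_reads / depth, NA_real_)]
  sites[, supported := editing_reads >= 1L & depth >= min_depth]
  sites[]
}
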