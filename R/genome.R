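#' Construct a circular genome object
#'
#' A lightweight container for a (usually circular) plastome sequence.
#' The sequence is stored as a single upper-case character string over
#' the alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @param id Character label for the genome (e.g. an accession).
#' @param sequence Nucleotide string. Lower case is accepted and folded
#'   to upper case.
#' @param circular Logical; plastomes are circular molecules, so `TRUE`
#'   by default.
#' @return An object of class `circular_genome` with elements `id`,
#'   `sequence` and `circular`.
#' @export
circular_genome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", sequence)) {
    bad <- gregexpr("[^ACGTN]", sequence)[[1]]
    stop("non-IUPAC residues at positions: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  structure(list(id = as.character(id), sequence = sequence,
                 circular = isTRUE(circular)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp (%s)\n", x$id,
              format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Genome length in base pairs
#' @param genome A `circular_genome` or a plain nucleotide string.
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome_seq(genome))

# Accept either a circular_genome or a bare string in low-level code.
genome_seq <- function(genome) {
  if (inherits(genome, "circular_genome")) genome$sequence else genome
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of nucleotide strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Rotate a circular genome
#'
#' Returns the genome re-linearised so that original position
#' `offset` becomes position 1. `offset = 1` is the identity.
#'
#' @param genome A `circular_genome`.
#' @param offset 1-based position that becomes the new origin.
#' @return A rotated `circular_genome`.
#' @export
rotate_genome <- function(genome, offset) {
  s <- genome_seq(genome)
  n <- nchar(s)
  offset <- ((as.integer(offset) - 1L) %% n) + 1L
  if (offset == 1L) return(genome)
  if (!genome$circular) stop("cannot rotate a linear genome")
  rot <- paste0(substr(s, offset, n), substr(s, 1L, offset - 1L))
  circular_genome(genome$id, rot, circular = TRUE)
}

#' GC content of a genome or interval, in percent
#'
#' Computes `100 * (G + C) / (A + C + G + T)` over the selected span;
#' `N` bases are excluded from the denominator.
#'
#' @param genome A `circular_genome` or nucleotide string.
#' @param start,end Optional 1-based inclusive interval bounds; the whole
#'   sequence when omitted.
#' @return GC percentage (numeric scalar).
#' @export
gc_fraction <- function(genome, start = NULL, end = NULL) {
  s <- genome_seq(genome)
  n <- nchar(s)
  if (!is.null(start) || !is.null(end)) {
    if (is.null(start)) start <- 1L
    if (is.null(end)) end <- n
    if (start < 1L || end > n || start > end) stop("interval out of bounds")
    s <- substr(s, start, end)
  }
  d <- Biostrings::DNAString(s)
  cnt <- Biostrings::letterFrequency(d, c("A", "C", "G", "T"))
  denom <- sum(cnt)
  if (denom == 0L) stop("undefined GC: no A/C/G/T bases in interval")
  unname(100 * (cnt[["C"]] + cnt[["G"]]) / denom)
}

# Fast maximal-run decomposition of a sequence, used by the SSR scanner
# and the mutation simulator.
seq_runs <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  ends <- cumsum(r$lengths)
  data.table::data.table(base = r$values, length = r$lengths,
                         start = ends - r$lengths + 1L, end = ends)
}

# Random nucleotide vector at a given GC fraction.
random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}
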