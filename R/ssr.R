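#' Scan a genome for mononucleotide microsatellites
#'
#' Reports every maximal single-base run of length `min_length` or more,
#' in coordinate order. On circular genomes a run spanning the
#' linearisation origin is merged into a single record whose `start`
#' lies near the end of the sequence and whose `end` wraps past it
#' (`end = start + length - 1`, possibly greater than the genome
#' length). `N` runs are never reported.
#'
#' @param genome A `circular_genome` or nucleotide string.
#' @param min_length Minimum run length (>= 2; the census default is 5,
#'   the marker-table convention is 10).
#' @return A `data.table` with columns `base`, `base_class`
#'   (`A/T` or `G/C`), `length`, `start`, `end` (1-based inclusive).
#' @export
scan_homopolymers <- function(genome, min_length = 5L) {
  if (min_length < 2L) stop("min_length must be >= 2")
  s <- genome_seq(genome)
  n <- nchar(s)
  runs <- seq_runs(s)
  circular <- inherits(genome, "circular_genome") && genome$circular
  if (circular && nrow(runs) > 1L &&
      runs$base[1L] == runs$base[nrow(runs)]) {
    # merge the origin-spanning run: it starts in the tail and wraps
    last <- nrow(runs)
    runs$length[last] <- runs$length[last] + runs$length[1L]
    runs$end[last] <- runs$start[last] + runs$length[last] - 1L
    runs <- runs[-1L]
  }
  out <- runs[runs$length >= min_length & runs$base != "N", ]
  out[, base_class := ifelse(base %in% c("A", "T"), "A/T", "G/C")]
  data.table::setcolorder(out, c("base", "base_class", "length",
                                 "start", "end"))
  data.table::setorder(out, start)
  out[]
}

#' Stratify microsatellite records by size class, region and coding capacity
#'
#' Counts runs per (size class x stratum) where the strata are
#' single-copy coding, single-copy noncoding, IR coding and IR
#' noncoding. Runs resident in IRa are collapsed onto their IRb mirror
#' so each IR run is counted once; stratum lengths likewise count the
#' inverted repeat once.
#'
#' @param records Output of [scan_homopolymers()] on the canonical
#'   rotation.
#' @param structure A `quadripartite` object.
#' @param features A `feature_table`.
#' @param size_classes Integer breakpoints; the final class is open
#'   (default `c(5,6,7,8,9,10)` giving classes 5,6,7,8,9,10+).
#' @return A list of class `ssr_stratification`: `counts` (size class x
#'   stratum matrix), `lengths` (bp per stratum, IR once) and
#'   `size_classes`.
#' @export
stratify_ssrs <- function(records, structure, features,
                          size_classes = c(5L, 6L, 7L, 8L, 9L, 10L)) {
  strata <- c("SC coding", "SC noncoding", "IR coding", "IR noncoding")
  classes <- c(utils::head(size_classes, -1L),
               paste0(size_classes[length(size_classes)], "+"))
  counts <- matrix(0L, nrow = length(classes), ncol = length(strata),
                   dimnames = list(classes, strata))
  if (nrow(records) > 0L) {
    if (any(records$start < 1L | records$start > structure$n))
      stop("record coordinates outside genome")
    keep <- !(records$start >= structure$ira[1L] &
              records$start <= structure$ira[2L])
    rec <- records[keep & records$length >= size_classes[1L], ]
    if (nrow(rec) > 0L) {
      ctx <- classify_position(rec$start, structure, features)
      region2 <- ifelse(ctx$region == "IR", "IR", "SC")
      stratum <- paste(region2, ifelse(ctx$coding, "coding", "noncoding"))
      cls <- classes[pmin(findInterval(rec$length, size_classes),
                          length(classes))]
      tab <- table(factor(cls, levels = classes),
                   factor(stratum, levels = strata))
      counts <- counts + unclass(tab)
    }
  }
  lengths <- stratum_lengths(structure, features)
  structure(list(counts = counts, lengths = lengths,
                 size_classes = size_classes),
            class = "ssr_stratification")
}

# bp per stratum with the IR counted once (IRb only).
stratum_lengths <- function(structure, features) {
  cds <- features[features$kind == "CDS", ]
  cov <- if (nrow(cds) > 0L) {
    IRanges::reduce(IRanges::IRanges(cds$start, pmin(cds$end, structure$n)))
  } else IRanges::IRanges()
  seg_cov <- function(iv) {
    seg <- IRanges::IRanges(iv[1L], iv[2L])
    sum(IRanges::width(IRanges::intersect(cov, seg)))
  }
  sc_len <- diff(structure$lsc) + 1L + diff(structure$ssc) + 1L
  ir_len <- diff(structure$irb) + 1L
  sc_cod <- seg_cov(structure$lsc) + seg_cov(structure$ssc)
  ir_cod <- seg_cov(structure$irb)
  c("SC coding" = sc_cod, "SC noncoding" = sc_len - sc_cod,
    "IR coding" = ir_cod, "IR noncoding" = ir_len - ir_cod)
}

#' Homopolymer incidence rates per kb
#'
#' @param strat An `ssr_stratification`.
#' @return Matrix of counts per kb of stratum length; cells with a
#'   zero-length stratum are `NA` (with a warning).
#' @export
ssr_rate_per_kb <- function(strat) {
  len_kb <- strat$lengths / 1000
  if (any(len_kb == 0)) warning("zero-length stratum: rates undefined")
  rates <- sweep(strat$counts, 2L, len_kb, "/")
  rates[, len_kb == 0] <- NA_real_
  rates
}

#' Goodness-of-fit test against a length-proportional null
#'
#' Pearson chi-square test of observed run counts per stratum against
#' expected counts proportional to stratum lengths (the inverted repeat
#' counted once upstream).
#'
#' @param observed Integer vector of observed counts (>= 2 strata,
#'   total > 0).
#' @param stratum_lengths Stratum lengths in bp (all > 0).
#' @return A list of class `ssr_gof`: `chi_square`, `df`, `p_value`,
#'   `expected`, and `low_expected` (`TRUE` when any expected count is
#'   below 5, in which case the chi-square approximation is doubtful).
#' @export
goodness_of_fit <- function(observed, stratum_lengths) {
  if (length(observed) < 2L) stop("need at least 2 strata")
  if (length(observed) != length(stratum_lengths))
    stop("observed and stratum_lengths differ in length")
  if (sum(observed) <= 0L) stop("observed total must be > 0")
  if (any(stratum_lengths <= 0)) stop("zero-length stratum: expected count 0")
  p <- stratum_lengths / sum(stratum_lengths)
  low <- FALSE
  ht <- withCallingHandlers(
    stats::chisq.test(observed, p = p),
    warning = function(w) {
      low <<- TRUE
      invokeRestart("muffleWarning")
    })
  structure(list(chi_square = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), expected = unname(ht$expected),
                 low_expected = low),
            class = "ssr_gof")
}

#' @export
print.ssr_gof <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g%s\n",
              x$chi_square, x$df, x$p_value,
              if (x$low_expected) " (expected count < 5 in some cell)" else ""))
  invisible(x)
}

#' Per-size-class goodness-of-fit tests
#'
#' Collapses the stratification onto one margin (single-copy vs IR, or
#' coding vs noncoding) and tests each size class against the
#' length-proportional null. No multiple-testing correction is applied
#' across size classes; interpret the per-class p-values accordingly.
#'
#' @param strat An `ssr_stratification`.
#' @param margin `"region"` or `"coding"`.
#' @return A `data.table` with one row per size class: observed counts,
#'   `chi_square`, `p_value`, `low_expected`.
#' @export
gof_by_size_class <- function(strat, margin = c("region", "coding")) {
  margin <- match.arg(margin)
  grp <- if (margin == "region") c("SC", "SC", "IR", "IR")
         else c("coding", "noncoding", "coding", "noncoding")
  counts <- t(rowsum(t(strat$counts), grp))
  lens <- as.vector(rowsum(strat$lengths, grp))
  names(lens) <- rownames(rowsum(strat$lengths, grp))
  lens <- lens[colnames(counts)]
  out <- lapply(rownames(counts), function(cl) {
    obs <- counts[cl, ]
    if (sum(obs) == 0L)
      return(data.table::data.table(size_class = cl,
                                    t(obs), chi_square = NA_real_,
                                    p_value = NA_real_, low_expected = NA))
    g <- goodness_of_fit(obs, lens)
    data.table::data.table(size_class = cl, t(obs),
                           chi_square = g$chi_square, p_value = g$p_value,
                           low_expected = g$low_expected)
  })
  data.table::rbindlist(out)
}

#' Marker-style microsatellite report
#'
#' The marker-table convention: runs of 10 bp or more with their
#' location context, complement-merged sequence class and 1-based
#' coordinates.
#'
#' @param genome Canonical-rotation `circular_genome`.
#' @param structure A `quadripartite` object.
#' @param features A `feature_table`.
#' @param min_length Minimum reported run length (default 10).
#' @return A `data.table` with `location`, `sequence_class`, `length`,
#'   `start`, `end`.
#' @export
ssr_marker_table <- function(genome, structure, features, min_length = 10L) {
  rec <- scan_homopolymers(genome, min_length = min_length)
  if (nrow(rec) == 0L)
    return(data.table::data.table(location = character(),
                                  sequence_class = character(),
                                  length = integer(), start = integer(),
                                  end = integer()))
  ctx <- classify_position(pmin(rec$start, structure$n), structure, features)
  loc <- ifelse(is.na(ctx$feature), "intergenic", ctx$feature)
  data.table::data.table(
    location = loc,
    sequence_class = sprintf("(%s)%d", rec$base_class, rec$length),
    length = rec$length, start = rec$start, end = rec$end)
}
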