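#' Extract a gap-free codon alignment for single-copy CDS
#'
#' Splices every qualifying CDS out of a pairwise genome alignment,
#' strand-normalises it, and pairs reference and query codons. Codons
#' overlapping alignment gaps (indels) are excluded and counted. By
#' default only single-copy CDS are used (genes inside the inverted
#' repeat are excluded), matching the usual restriction of synonymous-
#' rate estimates to single-copy coding sequence.
#'
#' @param aln An `anchor_alignment` of the reference against the query
#'   (IR-reduced genomes from [compare_plastomes()] are the expected
#'   input).
#' @param features Reference `feature_table`.
#' @param structure Reference `quadripartite` object.
#' @param include_ir Include CDS resident in the inverted repeat
#'   (default `FALSE`).
#' @return A list of class `codon_alignment`: `ref_codons`,
#'   `qry_codons` (character vectors of codons), `gene` (per-codon gene
#'   label), `n_excluded` (codons dropped at indels).
#' @export
extract_codon_alignment <- function(aln, features, structure,
                                    include_ir = FALSE) {
  rv <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1L]]
  qv <- strsplit(aln$qry_aln, "", fixed = TRUE)[[1L]]
  col_of <- which(rv != "-")            # alignment column of each ref pos

  cds <- cds_rows(features)
  if (nrow(cds) == 0L) stop("no CDS features")
  keys <- unique(cds[, c("name", "copy")])
  ref_codons <- character(0L); qry_codons <- character(0L)
  gene <- character(0L); n_excl <- 0L
  for (g in seq_len(nrow(keys))) {
    rows <- cds_rows(features, name = keys$name[g], copy = keys$copy[g])
    span <- c(min(rows$start), max(rows$end))
    in_ir <- region_of(pmin(span, structure$n), structure)
    if (!include_ir && any(in_ir == "IR")) next
    gpos <- unlist(lapply(seq_len(nrow(rows)), function(j)
      rows$start[j]:rows$end[j]))
    if (max(gpos) > length(col_of)) next      # outside the aligned span
    minus <- rows$strand[1L] == "-"
    if (minus) gpos <- rev(gpos)
    if (length(gpos) %% 3L != 0L) {
      warning("CDS length of ", keys$name[g],
              " not a multiple of 3; gene skipped")
      next
    }
    cols <- col_of[gpos]
    rb <- rv[cols]; qb <- qv[cols]
    if (minus) {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
      rb <- unname(comp[rb]); qb <- unname(comp[qb])
    }
    # query side must also be gap-free at these columns and the columns
    # contiguous in the query (no insertion splitting a codon is allowed
    # to contaminate the codon pairing; insertions between codons are
    # harmless because we read columns, not query coordinates)
    nc <- length(rb) %/% 3L
    rc <- apply(matrix(rb, nrow = 3L), 2L, paste, collapse = "")
    qc <- apply(matrix(qb, nrow = 3L), 2L, paste, collapse = "")
    bad <- grepl("[-N]", rc) | grepl("[-N]", qc)
    n_excl <- n_excl + sum(bad)
    rc <- rc[!bad]; qc <- qc[!bad]
    keep_i <- which(!bad)
    # internal stops are a contract violation (mis-annotated frame)
    chk <- function(cod, label) {
      aa <- translate_codons(cod)
      internal <- which(aa == "*" & keep_i < nc)
      if (length(internal) > 0L)
        stop("internal stop codon in ", label, " of ", keys$name[g],
             " at codon ", keep_i[internal[1L]])
    }
    chk(rc, "reference"); chk(qc, "query")
    # drop the terminal stop codon from the estimate
    fin <- keep_i == nc
    rc <- rc[!fin]; qc <- qc[!fin]
    ref_codons <- c(ref_codons, rc)
    qry_codons <- c(qry_codons, qc)
    gene <- c(gene, rep(keys$name[g], length(rc)))
  }
  structure(list(ref_codons = ref_codons, qry_codons = qry_codons,
                 gene = gene, n_excluded = n_excl),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d codons over %d genes (%d excluded at indels)\n",
              length(x$ref_codons), length(unique(x$gene)), x$n_excluded))
  invisible(x)
}

# --- site and difference counting ------------------------------------------

# Weighted synonymous site fraction per position for one codon.
# Changes producing stop codons are excluded from the weights.
codon_site_weights <- function(codon, kappa, code) {
  bases <- c("A", "C", "G", "T")
  aa0 <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    b0 <- substr(codon, p, p)
    syn_w <- 0; tot_w <- 0
    for (b in setdiff(bases, b0)) {
      mut <- codon
      substr(mut, p, p) <- b
      aa1 <- code[[mut]]
      if (aa1 == "*") next
      w <- if (is_transition(b0, b)) kappa else 1
      tot_w <- tot_w + w
      if (aa1 == aa0) syn_w <- syn_w + w
    }
    if (tot_w > 0) s <- s + syn_w / tot_w
  }
  s  # synonymous sites for this codon (out of 3)
}

is_transition <- function(a, b) {
  (a %in% c("A", "G")) == (b %in% c("A", "G"))
}

# Pathway-averaged difference counts between two codons. Returns
# synonymous/nonsynonymous counts split by transition/transversion.
# Orderings passing through a stop codon are excluded (all orderings
# are used if every one hits a stop).
codon_diff_counts <- function(c1, c2, code) {
  res <- c(syn_ts = 0, syn_tv = 0, non_ts = 0, non_tv = 0)
  if (c1 == c2) return(res)
  dpos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  paths <- perms(dpos)
  acc <- NULL
  for (drop_stop in c(TRUE, FALSE)) {
    tallies <- list()
    for (ord in paths) {
      cur <- c1
      tally <- c(syn_ts = 0, syn_tv = 0, non_ts = 0, non_tv = 0)
      ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (drop_stop && code[[nxt]] == "*") { ok <- FALSE; break }
        ts <- is_transition(substr(cur, p, p), substr(c2, p, p))
        syn <- code[[nxt]] == code[[cur]] && code[[nxt]] != "*" &&
               code[[cur]] != "*"
        key <- paste0(if (syn) "syn" else "non", "_", if (ts) "ts" else "tv")
        tally[key] <- tally[key] + 1
        cur <- nxt
      }
      if (ok) tallies[[length(tallies) + 1L]] <- tally
    }
    if (length(tallies) > 0L) { acc <- tallies; break }
  }
  Reduce(`+`, acc) / length(acc)
}

perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# K80 distance from transition proportion P and transversion proportion Q.
k80_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturation: K80 correction undefined")
  -0.5 * log(w1) - 0.25 * log(w2)
}

jc_distance <- function(p) {
  arg <- 1 - 4 * p / 3
  if (arg <= 0) stop("saturation: Jukes-Cantor correction undefined")
  -0.75 * log(arg)
}

# kappa from fourfold-degenerate plus nondegenerate codon positions via
# K80 (transition/transversion rate ratio). Falls back to 1 when the
# pooled sites carry no differences.
estimate_kappa <- function(ref_codons, qry_codons, code) {
  deg <- position_degeneracy(code)
  ts <- 0L; tv <- 0L; tot <- 0L
  for (i in seq_along(ref_codons)) {
    c1 <- ref_codons[i]; c2 <- qry_codons[i]
    d1 <- deg[[c1]]; d2 <- deg[[c2]]
    for (p in 1:3) {
      cls1 <- d1[p]; cls2 <- d2[p]
      if (!(cls1 == cls2 && cls1 %in% c(0L, 4L))) next
      tot <- tot + 1L
      b1 <- substr(c1, p, p); b2 <- substr(c2, p, p)
      if (b1 == b2) next
      if (is_transition(b1, b2)) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  if (tot == 0L || (ts + tv) == 0L) return(1)
  P <- ts / tot; Q <- tv / tot
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturation: kappa estimate undefined")
  a <- -0.5 * log(w1) + 0.25 * log(w2)
  b <- -0.5 * log(w2)
  if (b <= 0) return(1)
  max(2 * a / b, 1e-6)
}

# Degeneracy class (0, 2 or 4) of each codon position: 4 when every
# change is synonymous, 0 when none is, 2 otherwise.
position_degeneracy <- function(code) {
  bases <- c("A", "C", "G", "T")
  codons <- names(code)[code != "*"]
  out <- vector("list", length(codons))
  names(out) <- codons
  for (cod in codons) {
    cls <- integer(3L)
    for (p in 1:3) {
      b0 <- substr(cod, p, p)
      syn <- 0L; tot <- 0L
      for (b in setdiff(bases, b0)) {
        mut <- cod
        substr(mut, p, p) <- b
        if (code[[mut]] == "*") next
        tot <- tot + 1L
        if (code[[mut]] == code[[cod]]) syn <- syn + 1L
      }
      cls[p] <- if (tot > 0L && syn == tot) 4L else if (syn == 0L) 0L else 2L
    }
    out[[cod]] <- cls
  }
  out
}

#' Estimate synonymous and nonsynonymous divergence
#'
#' Counts synonymous and nonsynonymous sites and differences over a
#' codon alignment and corrects them to per-site distances.
#'
#' `NG86` uses equal mutation weights and a Jukes-Cantor correction.
#' `YN00` (the default) estimates the transition/transversion rate
#' ratio kappa from fourfold-degenerate plus nondegenerate positions,
#' weights site counts by kappa and the observed codon usage, and
#' corrects the synonymous and nonsynonymous classes with a K80
#' distance. Pathways between codons differing at more than one
#' position are averaged over stop-free orderings in both methods.
#'
#' @param caln A `codon_alignment`.
#' @param method `"YN00"` or `"NG86"`.
#' @return A list of class `ds_estimate`: `S`, `N` (site counts), `Sd`,
#'   `Nd` (difference counts), `kappa`, `dS`, `dN`, `method`.
#' @export
estimate_ds_dn <- function(caln, method = c("YN00", "NG86")) {
  method <- match.arg(method)
  rc <- caln$ref_codons; qc <- caln$qry_codons
  if (length(rc) == 0L) stop("empty codon alignment")
  ok <- !grepl("[^ACGT]", rc) & !grepl("[^ACGT]", qc)
  rc <- rc[ok]; qc <- qc[ok]
  code <- genetic_code_11()

  kappa <- if (method == "YN00") estimate_kappa(rc, qc, code) else 1

  # site counts weighted by codon usage (each codon occurrence in both
  # sequences contributes); memoised per distinct codon
  uc <- unique(c(rc, qc))
  sw <- vapply(uc, codon_site_weights, numeric(1L), kappa = kappa,
               code = code)
  S <- (sum(sw[rc]) + sum(sw[qc])) / 2
  N <- 3 * length(rc) - S

  diffs <- which(rc != qc)
  tot <- c(syn_ts = 0, syn_tv = 0, non_ts = 0, non_tv = 0)
  if (length(diffs) > 0L) {
    pair_key <- paste(rc[diffs], qc[diffs])
    for (pk in unique(pair_key)) {
      i <- which(pair_key == pk)[1L]
      cnt <- codon_diff_counts(rc[diffs[i]], qc[diffs[i]], code)
      tot <- tot + cnt * sum(pair_key == pk)
    }
  }
  Sd <- tot[["syn_ts"]] + tot[["syn_tv"]]
  Nd <- tot[["non_ts"]] + tot[["non_tv"]]

  if (method == "NG86") {
    dS <- if (S > 0) jc_distance(Sd / S) else 0
    dN <- if (N > 0) jc_distance(Nd / N) else 0
  } else {
    dS <- if (S > 0) k80_distance(tot[["syn_ts"]] / S, tot[["syn_tv"]] / S)
          else 0
    dN <- if (N > 0) k80_distance(tot[["non_ts"]] / N, tot[["non_tv"]] / N)
          else 0
  }
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, kappa = kappa,
                 dS = dS, dN = dN, method = method,
                 n_codons = length(rc)),
            class = "ds_estimate")
}

#' @export
print.ds_estimate <- function(x, ...) {
  cat(sprintf(
    "%s over %d codons: S = %.1f, N = %.1f, Sd = %.2f, Nd = %.2f\n",
    x$method, x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("kappa = %.3f, dS = %.5f, dN = %.5f\n", x$kappa, x$dS, x$dN))
  invisible(x)
}

#' Molecular-clock age from synonymous divergence
#'
#' Converts a synonymous distance into a divergence-time interval for a
#' pair of calibration rates (synonymous substitutions per site per
#' year). The default formula `t = dS/r` attributes the full pairwise
#' distance to the time axis of the calibration; `t = dS/(2r)` treats
#' the rate as per-lineage.
#'
#' @param ds A `ds_estimate` (or a bare dS value).
#' @param rate_low,rate_high Calibration rate bounds (default the grass
#'   chloroplast single-copy range 2.1e-9 to 2.9e-9).
#' @param formula `"dS/r"` (default) or `"dS/(2r)"`.
#' @return A list of class `clock_estimate`: `t_low`, `t_high` (years),
#'   the rates and the `formula_id`.
#' @export
clock_age <- function(ds, rate_low = 2.1e-9, rate_high = 2.9e-9,
                      formula = c("dS/r", "dS/(2r)")) {
  formula <- match.arg(formula)
  dS <- if (inherits(ds, "ds_estimate")) ds$dS else as.numeric(ds)
  if (!is.finite(dS) || dS < 0) stop("dS undefined")
  if (rate_low <= 0 || rate_high <= 0) stop("rates must be > 0")
  div <- if (formula == "dS/r") 1 else 2
  t_low <- dS / (div * max(rate_low, rate_high))
  t_high <- dS / (div * min(rate_low, rate_high))
  structure(list(t_low = t_low, t_high = t_high,
                 rate_low = min(rate_low, rate_high),
                 rate_high = max(rate_low, rate_high),
                 formula_id = formula, dS = dS),
            class = "clock_estimate")
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat(sprintf("divergence %.0f-%.0f kyr (dS = %.5f, rates %.2g-%.2g, t = %s)\n",
              x$t_low / 1e3, x$t_high / 1e3, x$dS, x$rate_low, x$rate_high,
              x$formula_id))
  invisible(x)
}
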