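#' Call SNPs and indels from a pairwise alignment
#'
#' Emits one variant per mismatch column (SNP) and one per maximal gap
#' run (insertion/deletion). Indels are left-normalised: shifted to the
#' leftmost equivalent placement within their homopolymer / repeat
#' context, VCF-style but with the anchor base excluded, so allele
#' strings contain only the inserted or deleted bases. Applying the
#' variant list to the reference with [apply_variants()] reproduces the
#' query exactly.
#'
#' @param aln An `anchor_alignment` from [align_pair()].
#' @return A `data.table` of class `variant_table` with columns `kind`
#'   (`SNP`/`insertion`/`deletion`), `pos` (1-based on the reference:
#'   for SNPs the substituted base; for deletions the first deleted
#'   base; for insertions the reference position at which the inserted
#'   bases would sit), `ref`, `alt`, `length`.
#' @export
call_variants <- function(aln) {
  rv <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1L]]
  qv <- strsplit(aln$qry_aln, "", fixed = TRUE)[[1L]]
  rpos <- cumsum(rv != "-")
  refseq <- paste(rv[rv != "-"], collapse = "")

  out <- list()
  snp_cols <- which(rv != "-" & qv != "-" & rv != qv)
  if (length(snp_cols) > 0L) {
    out[[1L]] <- data.table::data.table(
      kind = "SNP", pos = rpos[snp_cols], ref = rv[snp_cols],
      alt = qv[snp_cols], length = 1L)
  }
  gap_runs <- function(isgap) {
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    data.table::data.table(start = ends - r$lengths + 1L, end = ends,
                           gap = r$values)[gap == TRUE]
  }
  del <- gap_runs(qv == "-")
  if (nrow(del) > 0L) {
    out[[length(out) + 1L]] <- del[, {
      allele <- vapply(seq_len(.N), function(i)
        paste(rv[start[i]:end[i]], collapse = ""), character(1L))
      norm <- leftalign_indel(refseq, rpos[start], allele)
      data.table::data.table(kind = "deletion", pos = norm$pos,
                             ref = norm$allele, alt = "",
                             length = nchar(norm$allele))
    }]
  }
  ins <- gap_runs(rv == "-")
  if (nrow(ins) > 0L) {
    out[[length(out) + 1L]] <- ins[, {
      allele <- vapply(seq_len(.N), function(i)
        paste(qv[start[i]:end[i]], collapse = ""), character(1L))
      # insertion sits before the next reference base
      ipos <- rpos[start] + 1L
      norm <- leftalign_indel(refseq, ipos, allele)
      data.table::data.table(kind = "insertion", pos = norm$pos,
                             ref = "", alt = norm$allele,
                             length = nchar(norm$allele))
    }]
  }
  if (length(out) == 0L) return(empty_variant_table())
  v <- data.table::rbindlist(out, fill = TRUE)
  data.table::setorder(v, pos, kind)
  data.table::setattr(v, "class", c("variant_table", class(v)))
  v[]
}

empty_variant_table <- function() {
  v <- data.table::data.table(kind = character(), pos = integer(),
                              ref = character(), alt = character(),
                              length = integer())
  data.table::setattr(v, "class", c("variant_table", class(v)))
  v
}

# Shift indels to their leftmost equivalent placement. `pos` is the
# reference coordinate of the first affected base (for insertions, the
# coordinate the inserted bases would occupy). Vectorised over events.
leftalign_indel <- function(refseq, pos, allele) {
  n <- length(pos)
  for (i in seq_len(n)) {
    p <- pos[i]; a <- allele[i]; L <- nchar(a)
    if (L == 0L) next
    while (p > 1L) {
      prev <- substr(refseq, p - 1L, p - 1L)
      last <- substr(a, L, L)
      if (prev != last) break
      a <- paste0(prev, substr(a, 1L, L - 1L))
      p <- p - 1L
    }
    pos[i] <- p; allele[i] <- a
  }
  list(pos = pos, allele = allele)
}

#' Apply a variant list to a reference sequence
#'
#' Reconstructs the query from the reference plus its called variants.
#' Events are applied right-to-left so coordinates never shift.
#'
#' @param ref A `circular_genome` or nucleotide string.
#' @param variants A `variant_table`.
#' @return The edited nucleotide string.
#' @export
apply_variants <- function(ref, variants) {
  s <- genome_seq(ref)
  if (nrow(variants) == 0L) return(s)
  v <- variants[order(-pos)]
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    if (v$kind[i] == "SNP") {
      substr(s, p, p) <- v$alt[i]
    } else if (v$kind[i] == "deletion") {
      s <- paste0(substr(s, 1L, p - 1L),
                  substr(s, p + v$length[i], nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, p - 1L), v$alt[i],
                  substr(s, p, nchar(s)))
    }
  }
  s
}

#' Transition / transversion classification of base pairs
#'
#' @param ref,alt Character vectors of single bases.
#' @return `"transition"` when both bases are purines or both
#'   pyrimidines, otherwise `"transversion"`.
#' @export
substitution_class <- function(ref, alt) {
  pur <- c("A", "G")
  ifelse((ref %in% pur) == (alt %in% pur), "transition", "transversion")
}

#' Classify called variants by region, coding context and effect
#'
#' Adds region/coding context from [classify_position()], the
#' transition/transversion class for SNPs, the coding effect
#' (synonymous / nonsynonymous, translation table 11, strand-aware,
#' start-codon overrides honoured; codons hit by two SNPs are translated
#' jointly), and homopolymer association for indels.
#'
#' @param variants A `variant_table` from [call_variants()].
#' @param structure A `quadripartite` object (IR-reduced structures from
#'   [compare_plastomes()] also accepted).
#' @param features A `feature_table`.
#' @param ref The reference `circular_genome` (canonical rotation).
#' @param min_run Minimum run length for homopolymer association
#'   (default 5).
#' @return The variant table with columns `region`, `coding`, `feature`,
#'   `subcontext`, `class`, `effect`, `hp_assoc`, `hp_run_length` added.
#' @export
classify_variants <- function(variants, structure, features, ref,
                              min_run = 5L) {
  v <- data.table::copy(variants)
  if (nrow(v) == 0L) {
    v[, `:=`(region = character(), coding = logical(),
             feature = character(), subcontext = character(),
             class = character(), effect = character(),
             hp_assoc = logical(), hp_run_length = integer())]
    return(v)
  }
  nmax <- structure$n
  ctx <- classify_position(pmin(v$pos, nmax), structure, features)
  v[, `:=`(region = ctx$region, coding = ctx$coding,
           feature = ctx$feature, subcontext = ctx$subcontext)]
  v[, class := ifelse(kind == "SNP", substitution_class(ref, alt), "n/a")]
  v[, effect := "n/a"]
  v[kind != "SNP", effect := "n/a"]
  v[kind == "SNP" & !coding, effect := "noncoding"]

  csnp <- which(v$kind == "SNP" & v$coding)
  if (length(csnp) > 0L) {
    v$effect[csnp] <- coding_effect(v[csnp], features, ref)
  }
  v[, hp_assoc := FALSE]
  v[, hp_run_length := NA_integer_]
  ind <- which(v$kind != "SNP")
  for (i in ind) {
    hp <- homopolymer_association(v[i], ref, min_run = min_run)
    v$hp_assoc[i] <- hp$associated
    v$hp_run_length[i] <- hp$run_length
  }
  v[]
}

# Synonymous/nonsynonymous calls for coding SNPs, joint translation for
# codons carrying more than one SNP.
coding_effect <- function(snps, features, ref) {
  s <- genome_seq(ref)
  eff <- rep("n/a", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    gene <- snps$feature[i]
    rows <- cds_rows(features, name = gene)
    rows <- rows[rows$copy == rows$copy[1L], ]
    if (nrow(rows) == 0L) next
    # transcript-order exon positions
    gpos <- unlist(lapply(seq_len(nrow(rows)), function(j)
      rows$start[j]:rows$end[j]))
    minus <- rows$strand[1L] == "-"
    if (minus) gpos <- rev(gpos)
    cds_len <- length(gpos)
    if (cds_len %% 3L != 0L) {
      warning("CDS length of ", gene, " not a multiple of 3; effect n/a")
      next
    }
    idx <- match(snps$pos[i], gpos)
    if (is.na(idx)) next
    codon_i <- (idx - 1L) %/% 3L + 1L
    cpos <- gpos[((codon_i - 1L) * 3L + 1L):(codon_i * 3L)]
    ref_codon <- codon_from_positions(s, cpos, minus)
    # apply every SNP of this gene that falls in the same codon
    sib <- which(snps$feature == gene & snps$pos %in% cpos)
    alt_s <- s
    for (j in sib) {
      p <- snps$pos[j]
      substr(alt_s, p, p) <- snps$alt[j]
    }
    alt_codon <- codon_from_positions(alt_s, cpos, minus)
    ref_aa <- translate_codons(ref_codon)
    alt_aa <- translate_codons(alt_codon)
    if (codon_i == 1L && rows$start_codon[1L] != "none") {
      # non-ATG start translated as Met when flagged as the start
      if (ref_codon == rows$start_codon[1L]) ref_aa <- "M"
      if (alt_codon == rows$start_codon[1L]) alt_aa <- "M"
    }
    eff[i] <- if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
  }
  eff
}

# `cpos` is already in transcript order (descending genome coordinates
# for minus-strand genes), so only complementation is needed.
codon_from_positions <- function(s, cpos, minus) {
  b <- substring(s, cpos, cpos)
  codon <- paste(b, collapse = "")
  if (minus) codon <- chartr("ACGTN", "TGCAN", codon)
  codon
}

#' Homopolymer association of an indel
#'
#' An indel is homopolymer-associated when the indel allele together
#' with its flanks contains a single-base run of at least `min_run`
#' bases after applying the indel in either direction. The reported run
#' length is the length of that run in the reference.
#'
#' @param v A single-row `variant_table` (an indel).
#' @param ref Reference `circular_genome` or string.
#' @param min_run Minimum qualifying run length (default 5).
#' @return A list: `associated` (logical) and `run_length` (reference
#'   run length in bp, `NA` when not associated).
#' @export
homopolymer_association <- function(v, ref, min_run = 5L) {
  if (nrow(v) != 1L || v$kind == "SNP")
    stop("homopolymer_association expects a single indel")
  s <- genome_seq(ref)
  n <- nchar(s)
  L <- v$length
  w0 <- max(1L, v$pos - min_run - L - 2L)
  w1 <- min(n, v$pos + L + min_run + 2L)
  win <- substr(s, w0, w1)
  ipos <- v$pos - w0 + 1L  # indel position within window
  if (v$kind == "deletion") {
    applied <- paste0(substr(win, 1L, ipos - 1L),
                      substr(win, ipos + L, nchar(win)))
    span <- c(ipos - 1L, ipos)        # bases flanking the deleted run
  } else {
    applied <- paste0(substr(win, 1L, ipos - 1L), v$alt,
                      substr(win, ipos, nchar(win)))
    span <- c(ipos, ipos + L - 1L)    # the inserted bases
  }
  hit_base <- NA_character_
  for (seqv in list(applied, win)) {
    runs <- seq_runs(seqv)
    touch <- runs[runs$length >= min_run &
                  runs$end >= span[1L] - 1L & runs$start <= span[2L] + 1L, ]
    if (nrow(touch) > 0L) {
      hit_base <- touch$base[which.max(touch$length)]
      break
    }
  }
  if (is.na(hit_base)) return(list(associated = FALSE,
                                   run_length = NA_integer_))
  # reference run length of that base at the locus
  rruns <- seq_runs(win)
  near <- rruns[rruns$base == hit_base &
                rruns$end >= ipos - 1L & rruns$start <= ipos + L + 1L, ]
  rl <- if (nrow(near) > 0L) max(near$length) else 0L
  list(associated = TRUE, run_length = as.integer(rl))
}

#' Summarise classified variants, Tn/Tv ratio and regional rates
#'
#' Builds the per-gene polymorphism matrix (indels, transitions,
#' transversions, nonsynonymous, total), coding/noncoding subtotals, the
#' transition:transversion ratio `R = Tn/Tv`, and per-region
#' substitution rates per nucleotide with single-IR-copy denominators.
#'
#' @param variants A classified `variant_table`.
#' @param structure A `quadripartite` object.
#' @return A list of class `variant_summary`: `per_gene` table,
#'   `subtotals`, `R`, `rates` (per-nucleotide SNP rates for single-copy
#'   and IR), and the counts used.
#' @export
summarize_variants <- function(variants, structure) {
  v <- data.table::as.data.table(variants)
  n_snp <- sum(v$kind == "SNP")
  tn <- sum(v$kind == "SNP" & v$class == "transition")
  tv <- sum(v$kind == "SNP" & v$class == "transversion")
  stopifnot(tn + tv == n_snp)
  n_indel <- sum(v$kind != "SNP")
  R <- if (tv > 0L) round(tn / tv, 2L) else NA_real_

  v[, gene_lab := ifelse(coding, feature, "noncoding")]
  per_gene <- v[, .(
    indel = sum(kind != "SNP"),
    tn = sum(kind == "SNP" & class == "transition"),
    tv = sum(kind == "SNP" & class == "transversion"),
    nonsyn = sum(effect == "nonsynonymous"),
    total = .N), by = gene_lab][order(gene_lab != "noncoding", gene_lab)]
  subtotals <- v[, .(
    indel = sum(kind != "SNP"),
    tn = sum(kind == "SNP" & class == "transition"),
    tv = sum(kind == "SNP" & class == "transversion"),
    nonsyn = sum(effect == "nonsynonymous"),
    total = .N), by = .(stratum = ifelse(coding, "coding", "noncoding"))]

  sc_len <- diff(structure$lsc) + 1L + diff(structure$ssc) + 1L
  ir_len <- diff(structure$irb) + 1L
  sc_snps <- sum(v$kind == "SNP" & v$region %in% c("LSC", "SSC"))
  ir_snps <- sum(v$kind == "SNP" & v$region == "IR")
  rates <- c(single_copy = sc_snps / sc_len, ir = ir_snps / ir_len)

  structure(list(per_gene = per_gene, subtotals = subtotals,
                 n_snp = n_snp, n_indel = n_indel, tn = tn, tv = tv,
                 R = R, rates = rates,
                 indel_bp = sum(v$length[v$kind != "SNP"])),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("%d SNPs (%d Tn, %d Tv, R = %s), %d indels (%d bp)\n",
              x$n_snp, x$tn, x$tv,
              ifelse(is.na(x$R), "n/a", format(x$R, nsmall = 2L)),
              x$n_indel, x$indel_bp))
  cat(sprintf("SNP rate per nucleotide: single-copy %.5g, IR %.5g\n",
              x$rates[["single_copy"]], x$rates[["ir"]]))
  invisible(x)
}

#' Compare two plastomes end to end
#'
#' Detects the quadripartite structure of both genomes, canonicalises
#' their rotations, drops the IRa copy (so the inverted repeat is
#' represented once), aligns the reduced genomes, and calls and
#' classifies variants. IR variants are flagged as present in both
#' copies.
#'
#' @param ref,query `circular_genome` objects.
#' @param features Reference `feature_table` on the canonical rotation.
#' @param min_ir_length Passed to [detect_quadripartite()].
#' @param min_anchor,min_run Passed to [align_pair()] /
#'   [classify_variants()].
#' @return A list of class `plastome_comparison`: structures, the
#'   reduced alignment, the classified `variants` (with `in_both_ir_copies`),
#'   and the `summary`.
#' @export
compare_plastomes <- function(ref, query, features,
                              min_ir_length = 1000L, min_anchor = 20L,
                              min_run = 5L) {
  st_r <- detect_quadripartite(ref, min_ir_length)
  st_q <- detect_quadripartite(query, min_ir_length)
  gr <- canonicalize_rotation(ref, st_r)
  gq <- canonicalize_rotation(query, st_q)
  red_r <- circular_genome(gr$id, substr(genome_seq(gr), 1L, st_r$ira[1L] - 1L),
                           circular = FALSE)
  red_q <- circular_genome(gq$id, substr(genome_seq(gq), 1L, st_q$ira[1L] - 1L),
                           circular = FALSE)
  ft_red <- features[features$end < st_r$ira[1L], ]
  aln <- align_pair(red_r, red_q, min_anchor = min_anchor)
  v <- call_variants(aln)
  v <- classify_variants(v, st_r, ft_red, red_r, min_run = min_run)
  v[, in_both_ir_copies := region == "IR"]
  structure(list(structure_ref = st_r, structure_query = st_q,
                 alignment = aln, variants = v,
                 summary = summarize_variants(v, st_r)),
            class = "plastome_comparison")
}
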