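#' Construct a feature table
#'
#' A flat annotation table: one row per interval (exon part) of a
#' feature. Multi-exon features share a `name` and are ordered by
#' `part`. Coordinates are 1-based inclusive on the canonical rotation.
#'
#' @param name Character vector of feature (gene) names.
#' @param kind Feature kind: `CDS`, `tRNA`, `rRNA`, `intron` or `exon`.
#' @param strand `+` or `-`.
#' @param start,end Integer interval bounds.
#' @param part Exon index within the feature (default 1).
#' @param copy Copy index for IR-duplicated genes (default 1).
#' @param start_codon Start-codon override: `none`, `GCG` or `GTG`
#'   (plastid genes such as rpl2 and rps19 use non-ATG starts).
#' @return A `feature_table` (a `data.table`).
#' @export
feature_table <- function(name, kind, strand, start, end,
                          part = 1L, copy = 1L, start_codon = "none") {
  ft <- data.table::data.table(
    name = as.character(name), kind = as.character(kind),
    strand = as.character(strand),
    start = as.integer(start), end = as.integer(end),
    part = as.integer(part), copy = as.integer(copy),
    start_codon = as.character(start_codon))
  validate_feature_table(ft)
}

validate_feature_table <- function(ft, n = NULL) {
  stopifnot(all(ft$kind %in% c("CDS", "tRNA", "rRNA", "intron", "exon", "gene")),
            all(ft$strand %in% c("+", "-")),
            all(ft$start <= ft$end), all(ft$start >= 1L))
  if (!is.null(n) && any(ft$end > n)) stop("feature interval outside genome")
  data.table::setattr(ft, "class", c("feature_table", class(ft)))
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d intervals, %d features\n",
              nrow(x), length(unique(paste(x$name, x$copy)))))
  NextMethod()
}

# CDS exon rows, ordered along the transcript. Row selection is done on
# precomputed indices so argument names cannot collide with data.table
# column scoping.
cds_rows <- function(features, name = NULL, copy = NULL) {
  keep <- features$kind == "CDS"
  if (!is.null(name)) keep <- keep & features$name == name
  if (!is.null(copy)) keep <- keep & features$copy == copy
  ft <- features[which(keep), ]
  ft[base::order(ft$name, ft$copy, ft$part), ]
}

#' Classify genomic positions by region and coding context
#'
#' @param pos Integer vector of canonical 1-based positions.
#' @param structure A `quadripartite` object.
#' @param features A `feature_table`.
#' @return A `data.table` with columns `pos`, `region` (`LSC`/`SSC`/`IR`),
#'   `coding` (inside a CDS exon), `feature` (name or `NA`) and
#'   `subcontext` (`exon`, `intron` or `intergenic`). Structural RNA
#'   genes count as `exon` subcontext but not as `coding`.
#' @export
classify_position <- function(pos, structure, features) {
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > structure$n)) stop("position outside genome")
  out <- data.table::data.table(pos = pos,
                                region = region_of(pos, structure),
                                coding = FALSE,
                                feature = NA_character_,
                                subcontext = "intergenic")
  if (nrow(features) > 0L) {
    exonic <- features[features$kind %in% c("CDS", "tRNA", "rRNA", "exon"), ]
    q <- IRanges::IRanges(start = pos, width = 1L)
    if (nrow(exonic) > 0L) {
      subj <- IRanges::IRanges(exonic$start, exonic$end)
      hit <- IRanges::findOverlaps(q, subj, select = "first")
      has <- !is.na(hit)
      out$feature[has] <- exonic$name[hit[has]]
      out$subcontext[has] <- "exon"
      out$coding[has] <- exonic$kind[hit[has]] == "CDS"
    }
    # gene spans (per name/copy) to distinguish intron from intergenic
    spans <- data.table::as.data.table(features)[
      , .(start = min(start), end = max(end), name = name[1L]),
      by = .(name, copy)]
    sp <- IRanges::IRanges(spans$start, spans$end)
    hit2 <- IRanges::findOverlaps(q, sp, select = "first")
    inside <- !is.na(hit2) & out$subcontext == "intergenic"
    out$subcontext[inside] <- "intron"
    out$feature[inside] <- spans$name[hit2[inside]]
  }
  out[]
}

#' Gene-content summary
#'
#' Counts distinct gene names, names duplicated with one copy in each
#' inverted repeat, and the conventional plastome gene count
#' (unique + duplicated).
#'
#' @param features A `feature_table`.
#' @param structure A `quadripartite` object.
#' @return A list with `unique_genes`, `ir_duplicated`, `total` and the
#'   vector of duplicated names.
#' @export
summarize_gene_content <- function(features, structure) {
  if (nrow(features) == 0L) stop("empty feature table")
  ft <- data.table::as.data.table(features)[kind %in% c("CDS", "tRNA", "rRNA")]
  spans <- ft[, .(start = min(start), end = max(end)), by = .(name, copy)]
  inside <- function(s, e, iv) s >= iv[1L] & e <= iv[2L]
  spans[, in_irb := inside(start, end, structure$irb)]
  spans[, in_ira := inside(start, end, structure$ira)]
  per_gene <- spans[, .(copies = .N, irb = any(in_irb), ira = any(in_ira)),
                    by = name]
  if (any(per_gene$copies > 2L))
    warning("gene(s) with more than two copies counted by distinct name: ",
            paste(per_gene$name[per_gene$copies > 2L], collapse = ", "))
  dup <- per_gene$name[per_gene$irb & per_gene$ira]
  list(unique_genes = nrow(per_gene),
       ir_duplicated = length(dup),
       total = nrow(per_gene) + length(dup),
       duplicated_names = dup)
}

#' Features spanning the IR junctions
#'
#' Reports, for each of the four region junctions, any feature whose span
#' crosses the junction and the number of its bases lying inside the
#' inverted repeat (the IR-duplicated portion of the gene).
#'
#' @param structure A `quadripartite` object.
#' @param features A `feature_table`.
#' @return A `data.table` with columns `junction`, `gene`,
#'   `duplicated_length`; zero rows when no feature spans a junction.
#' @export
ir_boundary_duplication <- function(structure, features) {
  spans <- data.table::as.data.table(features)[
    , .(start = min(start), end = max(end)), by = .(name, copy)]
  n <- structure$n
  junctions <- list(
    list(id = "LSC/IRb", after = structure$lsc[2L], ir = structure$irb),
    list(id = "IRb/SSC", after = structure$irb[2L], ir = structure$irb),
    list(id = "SSC/IRa", after = structure$ssc[2L], ir = structure$ira),
    list(id = "IRa/LSC", after = structure$ira[2L], ir = structure$ira))
  res <- list()
  for (j in junctions) {
    # Features spanning the circular origin (the IRa/LSC junction) are
    # represented with end > n ("unwrapped" coordinates), so the uniform
    # rule start <= junction < end covers all four junctions.
    hit <- spans[start <= j$after & end >= j$after + 1L]
    if (nrow(hit) > 0L) {
      ov <- pmin(hit$end, j$ir[2L]) - pmax(hit$start, j$ir[1L]) + 1L
      res[[length(res) + 1L]] <- data.table::data.table(
        junction = j$id, gene = hit$name, duplicated_length = pmax(ov, 0L))
    }
  }
  if (length(res) == 0L)
    return(data.table::data.table(junction = character(),
                                  gene = character(),
                                  duplicated_length = integer()))
  data.table::rbindlist(res)
}

# Plastid (bacterial) genetic code, translation table 11.
genetic_code_11 <- function() Biostrings::getGeneticCode("11")

# Translate a vector of codons; start-codon overrides handled by callers.
translate_codons <- function(codons) {
  gc <- genetic_code_11()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Extract the coding sequence of a feature copy
#'
#' Concatenates the exon intervals in transcript order and reverse
#' complements for minus-strand genes.
#'
#' @param genome A `circular_genome` (canonical rotation).
#' @param features A `feature_table`.
#' @param name Gene name.
#' @param copy Copy index (default 1).
#' @return Nucleotide string of the spliced CDS.
#' @export
cds_sequence <- function(genome, features, name, copy = 1L) {
  rows <- cds_rows(features, name = name, copy = copy)
  if (nrow(rows) == 0L) stop("no CDS rows for ", name)
  s <- genome_seq(genome)
  parts <- substring(s, rows$start, rows$end)
  cds <- paste(parts, collapse = "")
  if (rows$strand[1L] == "-") cds <- revcomp(cds)
  cds
}
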