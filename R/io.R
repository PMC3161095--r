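#' Read a genome (FASTA or GenBank), optionally with annotations
#'
#' FASTA input returns the (first) record as a `circular_genome`;
#' annotations can be supplied separately as GFF3. GenBank flat files
#' provide both sequence and features: `join()`/`complement()`
#' multi-interval locations are supported and CDS with non-ATG starts
#' (GCG/GTG) are flagged with a start-codon override.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"genbank"`.
#' @param gff3 Optional GFF3 annotation path (FASTA input).
#' @param circular Mark the genome circular (default TRUE).
#' @return A list: `genome` (`circular_genome`), `features`
#'   (`feature_table` or `NULL`).
#' @export
read_genome <- function(path, format = c("auto", "fasta", "genbank"),
                        gff3 = NULL, circular = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank|gbff)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L) stop("no FASTA records in ", path)
    genome <- circular_genome(sub("\\s.*", "", names(ss)[1L]),
                              as.character(ss[[1L]]), circular = circular)
    features <- if (!is.null(gff3)) read_gff3(gff3) else NULL
    return(list(genome = genome, features = features))
  }
  read_genbank(path, circular = circular)
}

# Minimal GenBank flat-file parser: LOCUS/ORIGIN sequence plus
# CDS/tRNA/rRNA features with join()/complement() locations and /gene
# qualifiers. Enough for plastome records; not a general parser.
read_genbank <- function(path, circular = TRUE) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus) > 0L) strsplit(trimws(locus[1L]), "\\s+")[[1L]][2L]
        else basename(path)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("truncated GenBank record: no ORIGIN")
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  genome <- circular_genome(id, seq, circular = circular)

  fstart <- grep("^FEATURES", lines)
  features <- NULL
  if (length(fstart) > 0L) {
    body <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    is_key <- grepl("^ {5}\\S", body)
    idx <- cumsum(is_key)
    rows <- list()
    for (fi in unique(idx[idx > 0L])) {
      chunk <- body[idx == fi]
      key <- strsplit(trimws(chunk[1L]), "\\s+")[[1L]]
      kind <- key[1L]
      if (!kind %in% c("CDS", "tRNA", "rRNA")) next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^\\s+/", chunk)
      loc_end <- if (length(qual_at) > 0L) qual_at[1L] - 1L else length(chunk)
      loc <- paste0(key[2L],
                    paste(trimws(chunk[seq_len(loc_end)[-1L]]), collapse = ""))
      gene <- sub('.*/gene="([^"]+)".*', "\\1",
                  paste(chunk, collapse = " "))
      if (identical(gene, paste(chunk, collapse = " ")))
        gene <- sub('.*/locus_tag="([^"]+)".*', "\\1",
                    paste(chunk, collapse = " "))
      if (identical(gene, paste(chunk, collapse = " ")))
        gene <- sprintf("%s_%d", kind, fi)
      iv <- parse_gb_location(loc)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        name = gene, kind = kind, strand = iv$strand,
        start = iv$start, end = iv$end, part = seq_along(iv$start),
        copy = 1L, start_codon = "none")
    }
    if (length(rows) > 0L) {
      features <- data.table::rbindlist(rows)
      # number duplicate copies (IR genes appear twice)
      features[, copy := seq_len(.N), by = .(name, kind, part)]
      features <- validate_feature_table(features)
      features <- flag_alt_starts(features, genome)
    }
  }
  list(genome = genome, features = features)
}

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  loc <- sub("^order\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  bounds <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
  })
  start <- vapply(bounds, function(b) b[1L], integer(1L))
  end <- vapply(bounds, function(b) b[length(b)], integer(1L))
  list(start = start, end = end, strand = strand)
}

# Record GCG/GTG start-codon overrides by inspecting the first codon.
flag_alt_starts <- function(features, genome) {
  keys <- unique(features[features$kind == "CDS", c("name", "copy")])
  for (i in seq_len(nrow(keys))) {
    cds <- try(cds_sequence(genome, features, keys$name[i], keys$copy[i]),
               silent = TRUE)
    if (inherits(cds, "try-error")) next
    first <- substr(cds, 1L, 3L)
    if (first %in% c("GCG", "GTG")) {
      sel <- features$name == keys$name[i] & features$copy == keys$copy[i] &
        features$kind == "CDS"
      features$start_codon[sel] <- first
    }
  }
  features
}

#' Read features from a GFF3 file
#'
#' Keeps CDS, tRNA, rRNA and exon records; the gene name is taken from
#' the `gene=`, `Name=` or `ID=` attribute (first available).
#'
#' @param path GFF3 file.
#' @return A `feature_table`.
#' @export
read_gff3 <- function(path) {
  g <- data.table::fread(path, sep = "\t", header = FALSE, skip = "##",
                         col.names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"),
                         colClasses = list(character = c(1, 2, 3, 6, 7, 8, 9)))
  g <- g[g$type %in% c("CDS", "tRNA", "rRNA", "exon"), ]
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]+"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "=[^;]+"), a))) > 0L,
           sub(paste0(".*", key, "="), "", m), NA_character_)
  }
  nm <- rep(NA_character_, nrow(g))
  for (key in c("gene", "Name", "ID", "Parent")) {
    take <- is.na(nm)
    if (!any(take)) break
    val <- vapply(g$attributes[take], function(a) {
      m <- regmatches(a, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), a,
                                 perl = TRUE))
      if (length(m) == 0L) NA_character_ else sub(paste0(".*", key, "="), "", m)
    }, character(1L), USE.NAMES = FALSE)
    nm[take] <- val
  }
  nm[is.na(nm)] <- sprintf("feature_%d", which(is.na(nm)))
  one_attr <- function(key) {
    vapply(g$attributes, function(a) {
      m <- regmatches(a, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), a,
                                 perl = TRUE))
      if (length(m) == 0L) NA_character_ else sub(paste0(".*", key, "="), "", m)
    }, character(1L), USE.NAMES = FALSE)
  }
  copy <- suppressWarnings(as.integer(one_attr("copy")))
  part <- suppressWarnings(as.integer(one_attr("part")))
  ft <- data.table::data.table(name = nm, kind = g$type, strand = g$strand,
                               start = as.integer(g$start),
                               end = as.integer(g$end),
                               part = ifelse(is.na(part), 1L, part),
                               copy = ifelse(is.na(copy), 1L, copy),
                               start_codon = "none")
  data.table::setorder(ft, name, copy, start)
  if (all(is.na(part)))
    ft[, part := seq_len(.N), by = .(name, kind, copy)]
  validate_feature_table(ft)
}

#' Write a feature table as GFF3
#' @param features A `feature_table`.
#' @param path Output file.
#' @param seqid Sequence name for column 1.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(features, path, seqid = "genome") {
  lines <- c("##gff-version 3",
             sprintf("%s\tplastcmp\t%s\t%d\t%d\t.\t%s\t.\tID=%s.%d;gene=%s;copy=%d;part=%d",
                     seqid, features$kind, features$start, features$end,
                     features$strand, features$name, features$copy,
                     features$name, features$copy, features$part))
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs Named character vector (or `circular_genome`).
#' @param path Output file.
#' @param width Line width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "circular_genome"))
    seqs <- stats::setNames(seqs$sequence, seqs$id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (plain text or gzip).
#' @return A `data.table` with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: ", length(lines),
         " lines (truncated record near record ", length(lines) %/% 4L + 1L, ")")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
               nchar(seqs) != nchar(quals))
  if (length(bad) > 0L)
    stop("malformed FASTQ record at index ", bad[1L])
  data.table::data.table(id = sub("^@", "", sub("\\s.*", "", ids)),
                         seq = seqs, qual = quals)
}

#' Write reads as FASTQ
#' @param reads A `data.table` with `id`, `seq`, `qual`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Write classified variants as VCF 4.2
#'
#' Indels are emitted VCF-style with the anchor base included in the
#' alleles (the in-memory representation excludes it); INFO carries the
#' classification (REGION, CODING, CLASS, EFFECT, HP_ASSOC, HP_LEN).
#'
#' @param variants A classified `variant_table`.
#' @param ref Reference `circular_genome`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, ref, path) {
  s <- genome_seq(ref)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", ref$id, nchar(s)),
           "##INFO=<ID=REGION,Number=1,Type=String,Description=\"LSC/SSC/IR\">",
           "##INFO=<ID=CODING,Number=0,Type=Flag,Description=\"Inside a CDS exon\">",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"transition/transversion\">",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"synonymous/nonsynonymous/noncoding\">",
           "##INFO=<ID=HP_ASSOC,Number=0,Type=Flag,Description=\"Homopolymer-associated indel\">",
           "##INFO=<ID=HP_LEN,Number=1,Type=Integer,Description=\"Reference homopolymer run length\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind == "SNP") {
      pos <- v$pos; refa <- v$ref; alta <- v$alt
    } else {
      pos <- max(v$pos - 1L, 1L)
      anchor <- substr(s, pos, pos)
      if (v$kind == "deletion") {
        refa <- paste0(anchor, v$ref); alta <- anchor
      } else {
        refa <- anchor; alta <- paste0(anchor, v$alt)
      }
    }
    info <- c(sprintf("REGION=%s", v$region),
              if (isTRUE(v$coding)) "CODING",
              if (v$class != "n/a") sprintf("CLASS=%s", v$class),
              if (!is.null(v$effect) && v$effect != "n/a")
                sprintf("EFFECT=%s", v$effect),
              if (isTRUE(v$hp_assoc)) "HP_ASSOC",
              if (!is.na(v$hp_run_length))
                sprintf("HP_LEN=%d", v$hp_run_length))
    rows[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       ref$id, pos, refa, alta, paste(info, collapse = ";"))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Run the full comparison pipeline and write a report bundle
#'
#' Structure detection, microsatellite census, variant calling and
#' classification, synonymous divergence and clock dating, and (when
#' reads are given) read confirmation — with all tables written under
#' `outdir` plus a JSON summary and a machine-readable run manifest
#' recording every threshold used.
#'
#' @param ref,query `circular_genome` objects (or FASTA paths).
#' @param features Reference `feature_table` (or GFF3 path).
#' @param outdir Output directory (created).
#' @param reads Optional reads table / FASTQ path for the confirmation
#'   stage.
#' @param min_ir_length,ssr_min_len,min_anchor,min_run,min_depth,
#'   min_alt_frac Stage thresholds.
#' @param rate_low,rate_high,clock_formula Clock calibration.
#' @param seed Seed recorded in the manifest.
#' @return A list of class `pipeline_result` with every stage's objects;
#'   files are written as a side effect.
#' @export
run_pipeline <- function(ref, query, features, outdir,
                         reads = NULL,
                         min_ir_length = 1000L, ssr_min_len = 10L,
                         min_anchor = 20L, min_run = 5L,
                         min_depth = 5L, min_alt_frac = 0.8,
                         rate_low = 2.1e-9, rate_high = 2.9e-9,
                         clock_formula = "dS/r", seed = 1L) {
  if (is.character(ref)) ref <- read_genome(ref)$genome
  if (is.character(query)) query <- read_genome(query)$genome
  if (is.character(features)) features <- read_gff3(features)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) data.table::fwrite(x, file.path(outdir, f),
                                           sep = "\t")

  cmp <- compare_plastomes(ref, query, features,
                           min_ir_length = min_ir_length,
                           min_anchor = min_anchor, min_run = min_run)
  st <- cmp$structure_ref
  gr <- canonicalize_rotation(ref, st)
  tsv(structure_table(st, ref), "structure.tsv")

  ssr10 <- ssr_marker_table(gr, st, features, min_length = ssr_min_len)
  tsv(ssr10, "ssr_markers.tsv")
  rec5 <- scan_homopolymers(gr, min_length = 5L)
  strat <- stratify_ssrs(rec5, st, features)
  tsv(data.table::as.data.table(strat$counts, keep.rownames = "size_class"),
      "ssr_stratification.tsv")
  gof <- gof_by_size_class(strat, margin = "region")
  tsv(gof, "ssr_gof_region.tsv")
  gof_cod <- gof_by_size_class(strat, margin = "coding")
  tsv(gof_cod, "ssr_gof_coding.tsv")

  red_ref <- circular_genome(gr$id, substr(genome_seq(gr), 1L,
                                           st$ira[1L] - 1L), circular = FALSE)
  tsv(cmp$variants, "variants.tsv")
  write_vcf(cmp$variants, red_ref, file.path(outdir, "variants.vcf"))
  large_indels <- cmp$variants[cmp$variants$kind != "SNP" &
                               cmp$variants$length >= 17L, ]
  tsv(large_indels, "large_indels.tsv")
  tsv(cmp$summary$per_gene, "variant_summary.tsv")

  caln <- extract_codon_alignment(cmp$alignment, features, st)
  ds <- estimate_ds_dn(caln, method = "YN00")
  clock <- clock_age(ds, rate_low, rate_high, formula = clock_formula)
  tsv(data.table::data.table(S = ds$S, N = ds$N, Sd = ds$Sd, Nd = ds$Nd,
                             kappa = ds$kappa, dS = ds$dS, dN = ds$dN,
                             t_low_yr = clock$t_low,
                             t_high_yr = clock$t_high),
      "divergence.tsv")

  reads_out <- NULL
  if (!is.null(reads)) {
    aln_r <- align_reads(reads, gr)
    pu <- build_pileup(aln_r, gr)
    calls <- call_pool_variants(pu, min_depth = min_depth,
                                min_alt_frac = min_alt_frac)
    tsv(calls, "pool_calls.tsv")
    reads_out <- list(alignments = aln_r, pileup = pu, calls = calls)
  }

  summary <- list(
    genome_length_ref = genome_length(ref),
    genome_length_query = genome_length(query),
    ir_length = diff(st$irb) + 1L, lsc_length = diff(st$lsc) + 1L,
    ssc_length = diff(st$ssc) + 1L,
    gc_percent = round(gc_fraction(ref), 2L),
    n_snps = cmp$summary$n_snp, n_indels = cmp$summary$n_indel,
    indel_bp = cmp$summary$indel_bp,
    R = cmp$summary$R, rates = as.list(cmp$summary$rates),
    dS = ds$dS, dN = ds$dN,
    t_low_yr = clock$t_low, t_high_yr = clock$t_high,
    n_ssr_markers = nrow(ssr10))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(ref = ref$id, query = query$id, seed = seed,
                   thresholds = list(min_ir_length = min_ir_length,
                                     ssr_min_len = ssr_min_len,
                                     min_anchor = min_anchor,
                                     min_run = min_run,
                                     min_depth = min_depth,
                                     min_alt_frac = min_alt_frac,
                                     rate_low = rate_low,
                                     rate_high = rate_high,
                                     clock_formula = clock_formula),
                   package_version = as.character(utils::packageVersion("plastcmp")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(comparison = cmp, structure = st, ssr = strat,
                 ssr_markers = ssr10, gof_region = gof,
                 gof_coding = gof_cod, ds = ds, clock = clock,
                 reads = reads_out, summary = summary),
            class = "pipeline_result")
}

#' Pipeline configuration object
#'
#' Bundles every threshold and calibration the pipeline uses, with the
#' package defaults. Configurations serialize to a plain-text
#' `key = value` file and round-trip exactly.
#'
#' @param ... Named overrides of the defaults (see [run_pipeline()] for
#'   the meaning of each threshold).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_ir_length = 1000L, ssr_min_len = 10L, min_anchor = 20L,
              min_run = 5L, min_depth = 5L, min_alt_frac = 0.8,
              rate_low = 2.1e-9, rate_high = 2.9e-9,
              clock_formula = "dS/r", seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown configuration keys: ",
                             paste(bad, collapse = ", "))
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.integer(cfg[[nm]])) as.integer(over[[nm]])
                 else if (is.numeric(cfg[[nm]])) as.numeric(over[[nm]])
                 else as.character(over[[nm]])
  }
  stopifnot(cfg$min_ir_length >= 100L, cfg$min_anchor >= 8L,
            cfg$min_depth >= 1L, cfg$min_alt_frac > 0, cfg$min_alt_frac <= 1,
            cfg$rate_low > 0, cfg$rate_high > 0,
            cfg$clock_formula %in% c("dS/r", "dS/(2r)"))
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as plain text
#' @param config A `pipeline_config`.
#' @param path Output file (`key = value` lines).
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    sprintf("%s = %s", nm,
            if (is.character(v)) v else format(v, digits = 17))
  }, character(1L))
  writeLines(fmt, path)
  invisible(path)
}

#' Read a pipeline configuration from plain text
#' @param path A file written by [write_config()] (unknown keys error).
#' @return A `pipeline_config`; `read_config(write_config(x)) == x`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  do.call(pipeline_config, stats::setNames(as.list(vals), keys))
}
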