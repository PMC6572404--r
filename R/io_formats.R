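#' Read a genome (or amplicon/clone collection) from FASTA
#'
#' Sequences are uppercased; IUPAC ambiguity codes are preserved.  Input
#' order of records is kept.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_config("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop_config("FASTA format error at line 1: empty file (%s)", path)
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">"))
    stop_config("FASTA format error at line %d: expected '>' header", first)
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_genome(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

cx_columns <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                "context", "trinucleotide")

#' Validate and normalise a per-cytosine count table
#'
#' @param dt A data.frame with the seven cytosine-report columns
#'   (`chrom`, `pos`, `strand`, `count_meth`, `count_unmeth`, `context`,
#'   `trinucleotide`).
#' @return A `data.table` sorted by (chrom, pos), with a derived
#'   `coverage` column; zero-coverage rows are retained (`coverage == 0`).
#' @export
cx_table <- function(dt) {
  dt <- data.table::as.data.table(dt)
  missing <- setdiff(cx_columns, names(dt))
  if (length(missing))
    stop_config("cytosine table lacks column(s): %s",
                paste(missing, collapse = ", "))
  dt <- dt[, cx_columns, with = FALSE]
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop_config("row %d: invalid strand '%s'", bad[1L], dt$strand[bad[1L]])
  for (cc in c("pos", "count_meth", "count_unmeth")) {
    v <- dt[[cc]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop_config("row %d: column '%s' must be a non-negative integer",
                  bad[1L], cc)
    data.table::set(dt, j = cc, value = as.integer(v))
  }
  bad <- which(dt$pos < 1L)
  if (length(bad)) stop_config("row %d: pos must be >= 1", bad[1L])
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH", "Unknown"))
  if (length(bad))
    stop_config("row %d: invalid context '%s'", bad[1L], dt$context[bad[1L]])
  dt[, coverage := count_meth + count_unmeth]
  data.table::setorder(dt, chrom, pos)
  dt[]
}

#' Read a 7-column per-cytosine (CX) report
#'
#' Tab-separated, headerless: chrom, 1-based position, strand, methylated
#' count, unmethylated count, context (CG/CHG/CHH/Unknown), trinucleotide.
#' Zero-coverage rows are retained and identifiable via `coverage == 0`.
#'
#' @param path Path to the report.
#' @return `data.table` of cytosine records, sorted by (chrom, pos).
#' @export
read_cx_report <- function(path) {
  if (!file.exists(path)) stop_config("CX report not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) != 7L)
    stop_config("CX report must have 7 tab-separated columns, found %d",
                ncol(dt))
  data.table::setnames(dt, cx_columns)
  for (cc in c("pos", "count_meth", "count_unmeth")) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad))
      stop_config("line %d: column '%s' is not an integer ('%s')",
                  bad[1L], cc, dt[[cc]][bad[1L]])
    data.table::set(dt, j = cc, value = v)
  }
  cx_table(dt)
}

#' Write a per-cytosine table as a 7-column CX report
#'
#' @param cx Cytosine table (see [cx_table()]).
#' @param path Output path.
#' @export
write_cx_report <- function(cx, path) {
  cx <- cx_table(cx)
  data.table::fwrite(cx[, cx_columns, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Construct an annotation set
#'
#' All coordinates are 0-based half-open; conversion from 1-based closed
#' formats (GFF3) happens at the format boundary only.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @param exons data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @param repeats data.frame with `chrom`, `start`, `end` (may be empty).
#' @param promoter_span Promoter length in bp upstream of the TSS
#'   (default 2000).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes, exons, repeats = NULL,
                           promoter_span = 2000L) {
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  repeats <- data.table::as.data.table(
    repeats %||% data.table::data.table(chrom = character(),
                                        start = integer(), end = integer()))
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (any(genes$end <= genes$start))
    stop_config("gene with end <= start: %s",
                genes$gene_id[which(genes$end <= genes$start)[1L]])
  m <- merge(exons, genes[, .(gene_id, gstart = start, gend = end)],
             by = "gene_id")
  bad <- m[start < gstart | end > gend]
  if (nrow(bad))
    stop_config("exon outside gene span for gene '%s'", bad$gene_id[1L])
  data.table::setorder(genes, chrom, start)
  data.table::setorder(exons, chrom, start)
  structure(list(genes = genes, exons = exons, repeats = repeats,
                 promoter_span = as.integer(promoter_span)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "annotation_set: %d genes, %d exons, %d repeats (promoter span %d bp)\n",
    nrow(x$genes), nrow(x$exons), nrow(x$repeats), x$promoter_span))
  invisible(x)
}

# promoter / downstream / intron intervals, strand-aware, 0-based half-open.
# promoters are clipped at coordinate 0.
ann_promoters <- function(ann) {
  g <- ann$genes
  sp <- ann$promoter_span
  data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    start = ifelse(g$strand == "+", pmax(0L, g$start - sp), g$end),
    end = ifelse(g$strand == "+", g$start, g$end + sp))
}

ann_downstream <- function(ann) {
  g <- ann$genes
  sp <- ann$promoter_span
  data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    start = ifelse(g$strand == "+", g$end, pmax(0L, g$start - sp)),
    end = ifelse(g$strand == "+", g$end + sp, g$start))
}

ann_introns <- function(ann) {
  ex <- ann$exons
  g <- ann$genes
  out <- lapply(split(ex, by = "gene_id"), function(e) {
    data.table::setorder(e, start)
    if (nrow(e) < 2L) return(NULL)
    data.table::data.table(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
                           strand = e$strand[1L],
                           start = e$end[-nrow(e)], end = e$start[-1L])
  })
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L)
    out <- data.table::data.table(gene_id = character(), chrom = character(),
                                  strand = character(), start = integer(),
                                  end = integer())
  out[end > start]
}

#' Read gene/repeat annotation from GFF3 or BED
#'
#' GFF3 `gene` and `exon` features are used (exon `Parent` may point at the
#' gene or at an mRNA whose `Parent` is the gene); feature types containing
#' "repeat" become repeat intervals.  BED6 records become single-exon genes;
#' BED12 blocks become exons.  1-based closed GFF coordinates are converted
#' to the internal 0-based half-open convention.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param promoter_span Promoter span in bp (default 2000).
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path, promoter_span = 2000L) {
  if (!file.exists(path)) stop_config("annotation file not found: %s", path)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  is_gff <- "type" %in% names(df)
  if (is_gff) {
    typ <- tolower(as.character(df$type))
    idcol <- if ("ID" %in% names(df)) "ID" else "Name"
    gid <- as.character(df[[idcol]])
    parent <- if ("Parent" %in% names(df))
      vapply(df$Parent, function(p) if (length(p)) as.character(p[1L])
             else NA_character_, character(1))
    else rep(NA_character_, nrow(df))
    gsel <- typ == "gene"
    genes <- data.table::data.table(
      gene_id = gid[gsel], chrom = as.character(df$seqnames[gsel]),
      strand = as.character(df$strand[gsel]),
      start = df$start[gsel] - 1L, end = df$end[gsel])
    # map mRNA id -> gene id so exon Parents resolve either way
    msel <- typ %in% c("mrna", "transcript")
    tx2gene <- if (any(msel)) stats::setNames(parent[msel], gid[msel])
    else character()
    esel <- typ == "exon"
    epar <- parent[esel]
    egene <- ifelse(epar %in% genes$gene_id, epar,
                    unname(tx2gene[epar]))
    if (any(is.na(egene) & any(esel)) && any(esel) && anyNA(egene))
      stop_config("exon with unresolvable Parent: '%s'",
                  epar[which(is.na(egene))[1L]])
    exons <- data.table::data.table(
      gene_id = egene, chrom = as.character(df$seqnames[esel]),
      strand = as.character(df$strand[esel]),
      start = df$start[esel] - 1L, end = df$end[esel])
    exons <- unique(exons)
    rsel <- grepl("repeat", typ)
    repeats <- data.table::data.table(
      chrom = as.character(df$seqnames[rsel]),
      start = df$start[rsel] - 1L, end = df$end[rsel])
  } else {
    # BED via rtracklayer: already converted to 1-based closed GRanges
    genes <- data.table::data.table(
      gene_id = as.character(df$name %||% paste0("gene", seq_len(nrow(df)))),
      chrom = as.character(df$seqnames),
      strand = as.character(df$strand),
      start = df$start - 1L, end = df$end)
    genes[strand == "*", strand := "+"]
    if ("blocks" %in% names(df)) {
      bl <- gr$blocks
      exons <- data.table::rbindlist(lapply(seq_along(bl), function(i) {
        b <- bl[[i]]
        data.table::data.table(
          gene_id = genes$gene_id[i], chrom = genes$chrom[i],
          strand = genes$strand[i],
          start = genes$start[i] + BiocGenerics::start(b) - 1L,
          end = genes$start[i] + BiocGenerics::end(b))
      }))
    } else {
      exons <- genes[, .(gene_id, chrom, strand, start, end)]
    }
    repeats <- NULL
  }
  annotation_set(genes, exons, repeats, promoter_span)
}

#' Write an annotation set as GFF3
#'
#' Inverse of [read_annotation()] for the gene/exon/repeat subset: internal
#' 0-based half-open coordinates are emitted as 1-based closed GFF3.
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- ann$genes
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tmethscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       g$gene_id[i]), con)
    e <- ann$exons[gene_id == g$gene_id[i]]
    if (nrow(e))
      writeLines(sprintf(
        "%s\tmethscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        e$chrom, e$start + 1L, e$end, e$strand, e$gene_id,
        seq_len(nrow(e)), e$gene_id), con)
  }
  r <- ann$repeats
  if (nrow(r))
    writeLines(sprintf(
      "%s\tmethscan\trepeat_region\t%d\t%d\t.\t+\t.\tID=repeat%d",
      r$chrom, r$start + 1L, r$end, seq_len(nrow(r))), con)
  invisible(path)
}

#' Write DMRs as BED6+
#'
#' 0-based half-open BED; `name` is `context:direction`, `score` is
#' `min(1000, round(-10 log10 p))`, extra columns carry per-sample weighted
#' methylation levels and the p-value.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (is.null(dmrs) || nrow(dmrs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  p <- pmax(dmrs$p_value, 1e-300)
  bed <- data.table::data.table(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = paste0(dmrs$context, ":", dmrs$direction),
    score = pmin(1000, round(-10 * log10(p))),
    strand = ".",
    ml_a = sprintf("%.6g", dmrs$ml_a), ml_b = sprintf("%.6g", dmrs$ml_b),
    p_value = sprintf("%.6g", dmrs$p_value))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write per-window weighted methylation levels as bedGraph
#'
#' Windows with no covered site are skipped (bedGraph has no NA).
#'
#' @param windows Window table from [windowed_ml()].
#' @param path Output path.
#' @param track_name Optional track line name.
#' @export
write_bedgraph <- function(windows, path, track_name = NULL) {
  con <- file(path, "w")
  if (!is.null(track_name))
    writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  close(con)
  w <- windows[!is.na(weighted_ml),
               .(chrom, start, end, v = sprintf("%.6g", weighted_ml))]
  data.table::fwrite(w, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
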