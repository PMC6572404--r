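#' Extract the 9-mer around a cytosine (4 bases each side)
#'
#' Read 5'->3' on the site's strand ('-' strand sites are
#' reverse-complemented), so the cytosine sits at position 5 of 9.
#' Sites whose window crosses a contig end or contains a non-ACGT base
#' return `NA`.
#'
#' @param genome Named character vector of uppercase sequences.
#' @param chrom,pos,strand Site coordinates (1-based forward `pos`).
#' @return Character vector of 9-mers (or `NA`).
#' @export
extract_ninemer <- function(genome, chrom, pos, strand) {
  check_genome(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  out <- rep(NA_character_, n)
  for (cn in unique(chrom)) {
    seqc <- genome[[cn]]
    comp <- comp_base(seqc)
    len <- nchar(seqc)
    i <- which(chrom == cn)
    p <- pos[i]
    ok <- p - 4L >= 1L & p + 4L <= len
    plus <- strand[i] == "+"
    v <- rep(NA_character_, length(i))
    if (any(ok & plus))
      v[ok & plus] <- substring(seqc, p[ok & plus] - 4L, p[ok & plus] + 4L)
    if (any(ok & !plus)) {
      pm <- p[ok & !plus]
      # complement read right-to-left = reverse complement of fwd window
      parts <- lapply(4L:-4L, function(o) substring(comp, pm + o, pm + o))
      v[ok & !plus] <- do.call(paste0, parts)
    }
    v[!grepl("^[ACGT]{9}$", v)] <- NA_character_
    out[i] <- v
  }
  out
}

#' Build a 9-mer sequence-preference table around methylated cytosines
#'
#' Two views of sequence preference: (a) a position frequency matrix over
#' the 9-mers of *methylated* sites (ready for logo rendering; the centre
#' column is all-C by construction); (b) per-9-mer percent methylation over
#' all *tested* sites carrying that 9-mer, `100 * methylated / tested`.
#' Motifs observed at fewer than `low_conf_min` tested sites are flagged
#' low-confidence.
#'
#' @param genome Named character vector of sequences.
#' @param cx Cytosine table with `status` from [call_methylated_sites()].
#' @param context Optional context restriction.
#' @param low_conf_min Minimum tested sites for a confident motif
#'   percentage (default 10).
#' @return Object of class `motif_table`: list with `position_freqs`
#'   (4 x 9 matrix), `motifs` (data.table), `k = 9`, `center = 5`.
#' @export
build_motif_table <- function(genome, cx, context = NULL,
                              low_conf_min = 10L) {
  if (!"status" %in% names(cx))
    stop_config("run call_methylated_sites() first")
  t <- data.table::as.data.table(cx)[status != "untested"]
  if (!is.null(context)) {
    sel_ctx <- t$context == context
    t <- t[sel_ctx]
  }
  t[, motif := extract_ninemer(genome, chrom, pos, strand)]
  t <- t[!is.na(motif)]
  meth <- t[status == "methylated"]
  bases <- c("A", "C", "G", "T")
  pf <- matrix(0, nrow = 4L, ncol = 9L,
               dimnames = list(bases, paste0("p", 1:9)))
  if (nrow(meth)) {
    for (j in 1:9) {
      tab <- table(factor(substring(meth$motif, j, j), levels = bases))
      pf[, j] <- as.numeric(tab) / nrow(meth)
    }
  }
  motifs <- t[, .(n_methylated = sum(status == "methylated"),
                  n_tested = .N), by = motif]
  motifs[, `:=`(percent = 100 * n_methylated / n_tested,
                low_confidence = n_tested < low_conf_min)]
  data.table::setorder(motifs, -n_tested)
  structure(list(position_freqs = pf, motifs = motifs[], k = 9L,
                 center = 5L),
            class = "motif_table")
}

#' @export
print.motif_table <- function(x, ...) {
  cat(sprintf("motif_table: %d distinct 9-mers (%d low-confidence)\n",
              nrow(x$motifs), sum(x$motifs$low_confidence)))
  invisible(x)
}

#' Write the position frequency matrix of a motif table as TSV
#'
#' One row per position, one column per base: directly consumable by logo
#' renderers.
#'
#' @param mt A `motif_table`.
#' @param path Output path.
#' @export
write_motif_pfm <- function(mt, path) {
  m <- t(mt$position_freqs)
  dt <- data.table::data.table(position = seq_len(nrow(m)))
  for (b in colnames(m)) dt[[b]] <- m[, b]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
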