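#' Classify cytosine context (CG / CHG / CHH) from genome sequence
#'
#' The context is read from the two bases 3' of the cytosine on its own
#' strand (H = A, C or T).  For '-' strand sites the forward sequence holds
#' a G at `pos` and the context bases are the complements of the two
#' preceding forward bases.  Sites within 2 bp of a contig end, or whose
#' context bases are not A/C/G/T, are `Unknown`.
#'
#' @param genome Named character vector of uppercase sequences.
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 1-based forward-coordinate position(s) of the cytosine.
#' @param strand "+" or "-" per site.
#' @param trinucleotide If `TRUE` return a data.table with both the context
#'   and the trinucleotide (5'->3' on the site's strand, N-padded at ends).
#' @return Character vector of contexts, or a data.table when
#'   `trinucleotide = TRUE`.
#' @export
classify_context <- function(genome, chrom, pos, strand,
                             trinucleotide = FALSE) {
  check_genome(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-")))
    stop_config("strand must be '+' or '-'")
  if (!all(chrom %in% names(genome)))
    stop_config("unknown chromosome: %s",
                setdiff(chrom, names(genome))[1L])
  b1 <- b2 <- b3 <- character(n)
  for (cn in unique(chrom)) {
    seqc <- genome[[cn]]
    len <- nchar(seqc)
    i <- which(chrom == cn)
    p <- pos[i]
    if (any(p < 1L | p > len))
      stop_config("position out of range on %s", cn)
    plus <- strand[i] == "+"
    base0 <- substring(seqc, p, p)
    if (any(plus & base0 != "C"))
      stop_config("site is not a cytosine on '+' strand (%s:%d)",
                  cn, p[which(plus & base0 != "C")[1L]])
    if (any(!plus & base0 != "G"))
      stop_config("site is not a cytosine on '-' strand (%s:%d)",
                  cn, p[which(!plus & base0 != "G")[1L]])
    # next two bases 5'->3' on the site's strand
    b1[i] <- "C"
    b2[i] <- ifelse(plus,
                    ifelse(p + 1L <= len, substring(seqc, p + 1L, p + 1L), ""),
                    ifelse(p - 1L >= 1L,
                           comp_base(substring(seqc, p - 1L, p - 1L)), ""))
    b3[i] <- ifelse(plus,
                    ifelse(p + 2L <= len, substring(seqc, p + 2L, p + 2L), ""),
                    ifelse(p - 2L >= 1L,
                           comp_base(substring(seqc, p - 2L, p - 2L)), ""))
  }
  ok2 <- b2 %in% c("A", "C", "G", "T")
  ok3 <- b3 %in% c("A", "C", "G", "T")
  ctx <- rep("Unknown", n)
  ctx[ok2 & b2 == "G"] <- "CG"
  ctx[ok2 & ok3 & b2 != "G" & b3 == "G"] <- "CHG"
  ctx[ok2 & ok3 & b2 != "G" & b3 != "G"] <- "CHH"
  if (!trinucleotide) return(ctx)
  tri <- paste0(b1, ifelse(nzchar(b2), b2, "N"), ifelse(nzchar(b3), b3, "N"))
  data.table::data.table(context = ctx, trinucleotide = tri)
}

#' Per-site methylation level
#'
#' ML = count_meth / (count_meth + count_unmeth); `NA` (undefined, never 0)
#' for zero-coverage sites.
#'
#' @param cx Cytosine table.
#' @return Numeric vector aligned with the rows of `cx`.
#' @export
site_ml <- function(cx) {
  cov <- cx$count_meth + cx$count_unmeth
  ifelse(cov > 0, cx$count_meth / cov, NA_real_)
}

#' Call methylated sites with a one-sided exact binomial test
#'
#' Each covered site's methylated count is modelled as
#' Binomial(coverage, r); the null r equals the bisulfite conversion-failure
#' rate, the alternative r exceeds it.  P-values are corrected across tested
#' sites (Benjamini-Hochberg by default) and a site is called methylated
#' when its corrected p-value is at most `alpha`.  Zero-coverage sites stay
#' `untested`.
#'
#' @param cx Cytosine table.
#' @param conversion_error Null methylation rate (conversion-failure
#'   probability), default 0.005.
#' @param alpha Significance level, default 0.05.
#' @param correction Multiple-testing method for [stats::p.adjust()]
#'   (default "BH"; use "none" to test at raw alpha).
#' @return `cx` with added columns `p_value`, `q_value` and
#'   `status` in {methylated, unmethylated, untested}.
#' @export
call_methylated_sites <- function(cx, conversion_error = 0.005,
                                  alpha = 0.05, correction = "BH") {
  if (conversion_error < 0 || conversion_error >= 1)
    stop_config("conversion_error must be in [0, 1)")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  cx <- cx_table(cx)
  covered <- cx$coverage > 0L
  p <- rep(NA_real_, nrow(cx))
  # one-sided upper tail: P(X >= k) under Bin(n, conversion_error)
  p[covered] <- stats::pbinom(cx$count_meth[covered] - 1L,
                              cx$coverage[covered],
                              conversion_error, lower.tail = FALSE)
  q <- rep(NA_real_, nrow(cx))
  q[covered] <- stats::p.adjust(p[covered], method = correction)
  status <- rep("untested", nrow(cx))
  status[covered] <- ifelse(q[covered] <= alpha, "methylated", "unmethylated")
  cx[, `:=`(p_value = p, q_value = q, status = status)]
  cx[]
}

#' Weighted methylation level in fixed-width genomic windows
#'
#' Chromosomes are tiled from coordinate 0 in `bin_size` bins (the terminal
#' window may be shorter).  Counts are pooled before dividing, giving the
#' weighted ML; windows with zero pooled reads have `weighted_ml = NA`.
#'
#' @param cx Cytosine table.
#' @param bin_size Window width in bp, default 10000 (10 kb).
#' @param context Optional context restriction ("CG", "CHG" or "CHH");
#'   `NULL` pools all contexts.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, windows with no cytosine are emitted too (with `n_sites = 0`)
#'   and terminal windows are clipped to the chromosome end.
#' @return data.table with `chrom`, `start`, `end` (0-based half-open),
#'   `context`, `n_sites`, `pooled_meth`, `pooled_unmeth`, `weighted_ml`.
#' @export
windowed_ml <- function(cx, bin_size = 10000L, context = NULL,
                        chrom_lengths = NULL) {
  if (bin_size < 1L) stop_config("bin_size must be >= 1")
  cx <- cx_table(cx)
  ctx_label <- context %||% "all"
  if (!is.null(context)) {
    sel_ctx <- cx$context == context
    cx <- cx[sel_ctx]
  }
  cx[, bin := (pos - 1L) %/% as.integer(bin_size)]
  agg <- cx[, .(n_sites = .N, pooled_meth = sum(count_meth),
                pooled_unmeth = sum(count_unmeth)), by = .(chrom, bin)]
  if (!is.null(chrom_lengths)) {
    full <- data.table::rbindlist(lapply(names(chrom_lengths), function(cn) {
      nb <- max(1L, ceiling(chrom_lengths[[cn]] / bin_size))
      data.table::data.table(chrom = cn, bin = seq_len(nb) - 1L)
    }))
    agg <- merge(full, agg, by = c("chrom", "bin"), all.x = TRUE)
    for (cc in c("n_sites", "pooled_meth", "pooled_unmeth"))
      data.table::set(agg, which(is.na(agg[[cc]])), cc, 0L)
  }
  agg[, `:=`(start = bin * as.integer(bin_size),
             end = (bin + 1L) * as.integer(bin_size))]
  if (!is.null(chrom_lengths))
    agg[, end := pmin(end, chrom_lengths[chrom])]
  agg[, `:=`(context = ctx_label,
             weighted_ml = ifelse(pooled_meth + pooled_unmeth > 0,
                                  pooled_meth / (pooled_meth + pooled_unmeth),
                                  NA_real_))]
  data.table::setorder(agg, chrom, start)
  agg[, .(chrom, start, end, context, n_sites, pooled_meth, pooled_unmeth,
          weighted_ml)]
}

#' Genome-wide per-context methylation summary
#'
#' For sites that passed [call_methylated_sites()]: (a) the share each
#' context contributes to all methylated sites (sums to 100); (b) within
#' each context, the fraction of tested sites called methylated; (c) the
#' weighted methylation level (pooled counts), which estimates the
#' underlying per-context methylation rate.
#'
#' @param cx Cytosine table with `status` set.
#' @return data.table with one row per context (CG, CHG, CHH).
#' @export
genome_context_fractions <- function(cx) {
  if (!"status" %in% names(cx))
    stop_config("run call_methylated_sites() first")
  t <- cx[status != "untested" & context %in% c("CG", "CHG", "CHH")]
  out <- t[, .(n_tested = .N,
               n_methylated = sum(status == "methylated"),
               pooled_meth = sum(count_meth),
               pooled_unmeth = sum(count_unmeth)),
           by = context]
  out <- out[match(c("CG", "CHG", "CHH"), context, nomatch = 0L)]
  tot_meth <- sum(out$n_methylated)
  out[, `:=`(
    pct_of_methylated = if (tot_meth > 0) 100 * n_methylated / tot_meth
    else NA_real_,
    frac_sites_methylated = n_methylated / n_tested,
    weighted_ml = pooled_meth / (pooled_meth + pooled_unmeth))]
  out[]
}

#' Histogram of per-site methylation levels
#'
#' Site MLs are binned over \[0, 1\] in `n_bins` equal bins (default 4,
#' i.e. quartile bands); the first bin is closed on the left, subsequent
#' bins are left-open.  Zero-coverage sites are excluded.
#'
#' @param cx Cytosine table.
#' @param context Optional context restriction.
#' @param n_bins Number of bins (>= 1).
#' @return data.table with `bin_low`, `bin_high`, `count`, `proportion`.
#' @export
ml_level_histogram <- function(cx, context = NULL, n_bins = 4L) {
  if (n_bins < 1L) stop_config("n_bins must be >= 1")
  cx <- cx_table(cx)
  if (!is.null(context)) {
    sel_ctx <- cx$context == context
    cx <- cx[sel_ctx]
  }
  ml <- site_ml(cx)
  ml <- ml[!is.na(ml)]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- if (length(ml))
    as.vector(table(cut(ml, breaks, include.lowest = TRUE)))
  else rep(0L, n_bins)
  data.table::data.table(
    bin_low = breaks[-length(breaks)], bin_high = breaks[-1L],
    count = counts,
    proportion = if (sum(counts) > 0) counts / sum(counts) else
      rep(0, n_bins))
}
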