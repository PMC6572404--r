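# match cytosines to 0-based half-open intervals; returns the join with one
# row per (site, interval) pair.  `iv` needs chrom/start/end (+ id columns).
sites_in_intervals <- function(cx, iv) {
  if (nrow(iv) == 0L || nrow(cx) == 0L)
    return(cbind(cx[0L], iv[0L, setdiff(names(iv), c("chrom")), with = FALSE]))
  s <- data.table::copy(cx)
  s[, `:=`(istart = pos - 1L, iend = pos - 1L)]
  v <- data.table::copy(iv)
  v[, iend := end - 1L]            # half-open -> closed for foverlaps
  data.table::setnames(v, "start", "istart")
  data.table::setkey(v, chrom, istart, iend)
  hit <- data.table::foverlaps(s, v, type = "within", nomatch = NULL)
  hit
}

#' Weighted methylation level per genomic feature class
#'
#' Pooled-count weighted ML for promoters (2 kb upstream of the TSS,
#' strand-aware), exons, introns and repeats.  A site overlapping several
#' features of one class counts once for that class; a site in two classes
#' contributes to both.
#'
#' @param cx Cytosine table.
#' @param ann An [annotation_set()].
#' @param context Optional context restriction.
#' @return data.table with `feature`, `n_sites`, `pooled_meth`,
#'   `pooled_unmeth`, `weighted_ml` (NA where no covered site).
#' @export
feature_ml <- function(cx, ann, context = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  cx <- cx_table(cx)
  if (!is.null(context)) {
    sel_ctx <- cx$context == context
    cx <- cx[sel_ctx]
  }
  cx[, xid := .I]
  classes <- list(
    promoter = ann_promoters(ann)[, .(chrom, start, end)],
    exon = ann$exons[, .(chrom, start, end)],
    intron = ann_introns(ann)[, .(chrom, start, end)],
    repeat_ = ann$repeats[, .(chrom, start, end)])
  out <- data.table::rbindlist(lapply(names(classes), function(cl) {
    hit <- sites_in_intervals(cx, classes[[cl]])
    u <- unique(hit, by = "xid")
    data.table::data.table(
      feature = sub("_$", "", cl), n_sites = nrow(u),
      pooled_meth = sum(u$count_meth), pooled_unmeth = sum(u$count_unmeth))
  }))
  out[, weighted_ml := ifelse(pooled_meth + pooled_unmeth > 0,
                              pooled_meth / (pooled_meth + pooled_unmeth),
                              NA_real_)]
  out[]
}

#' Classify genes by expression level
#'
#' A gene is `none` when FPKM < 1 (not expressed).  Quartiles are computed
#' over expressed genes only (FPKM >= 1): `low` up to the lower quartile,
#' `medium` up to the upper quartile, `high` above it.  Boundary values go
#' to the lower class; FPKM exactly 1 is `low`.
#'
#' @param fpkm_table data.frame with `gene_id` and an FPKM column.
#' @param sample Name of the FPKM column (default "fpkm").
#' @return data.table with `gene_id`, `fpkm`, `class` (factor
#'   none/low/medium/high).
#' @export
classify_expression <- function(fpkm_table, sample = "fpkm") {
  dt <- data.table::as.data.table(fpkm_table)
  if (nrow(dt) == 0L) stop_config("empty FPKM table")
  if (!all(c("gene_id", sample) %in% names(dt)))
    stop_config("FPKM table needs columns 'gene_id' and '%s'", sample)
  f <- dt[[sample]]
  if (any(is.na(f) | f < 0)) stop_config("FPKM must be >= 0")
  cls <- rep("none", nrow(dt))
  expressed <- f >= 1
  if (any(expressed)) {
    q <- stats::quantile(f[expressed], c(0.25, 0.75), names = FALSE)
    cls[expressed & f <= q[1L]] <- "low"
    cls[expressed & f > q[1L] & f <= q[2L]] <- "medium"
    cls[expressed & f > q[2L]] <- "high"
  }
  data.table::data.table(
    gene_id = dt$gene_id, fpkm = f,
    class = factor(cls, levels = c("none", "low", "medium", "high")))
}

# signed gene-relative coordinate of sites for one strand convention:
# s < 0 upstream, [0, L) body, >= L downstream (L = gene length)
gene_relative_pos <- function(pos0, gstart, gend, gstrand) {
  ifelse(gstrand == "+", pos0 - gstart, (gend - 1L) - pos0)
}

#' Metagene methylation profile (upstream flank / gene body / downstream)
#'
#' Counts are pooled per bin across genes: flank bins are fixed width
#' (`flank / n_bins_flank` bp, by absolute distance from the TSS/TES), body
#' bins are proportional to gene length.  '-' strand genes are flipped so
#' bin 1 is always the far upstream end.  Genes shorter than `n_bins_body`
#' bp are excluded.  With a `classing` (see [classify_expression()]) one
#' profile per expression class is returned, else a single "all" profile.
#'
#' @param cx Cytosine table.
#' @param ann An [annotation_set()].
#' @param context Optional context restriction.
#' @param n_bins_flank,n_bins_body Bin counts (defaults 20 and 20).
#' @param classing Optional data.table `gene_id`/`class`; must cover every
#'   gene of the annotation.
#' @param flank Flank span in bp (default 2000).
#' @return data.table with `class`, `region` (upstream/body/downstream),
#'   `bin` (1 .. 2*n_bins_flank + n_bins_body), pooled counts and
#'   `weighted_ml`.
#' @export
metagene_profile <- function(cx, ann, context = NULL, n_bins_flank = 20L,
                             n_bins_body = 20L, classing = NULL,
                             flank = 2000L) {
  stopifnot(inherits(ann, "annotation_set"))
  cx <- cx_table(cx)
  if (!is.null(context)) {
    sel_ctx <- cx$context == context
    cx <- cx[sel_ctx]
  }
  genes <- ann$genes[end - start >= n_bins_body]
  if (!is.null(classing)) {
    classing <- data.table::as.data.table(classing)
    missing <- setdiff(genes$gene_id, classing$gene_id)
    if (length(missing))
      stop_config("classing lacks gene(s): %s", missing[1L])
    genes <- merge(genes, classing[, .(gene_id, class)], by = "gene_id")
  } else genes[, class := "all"]
  win <- genes[, .(gene_id, chrom, strand, gstart = start, gend = end,
                   class, start = pmax(0L, start - as.integer(flank)),
                   end = end + as.integer(flank))]
  hit <- sites_in_intervals(cx, win)
  wf <- flank / n_bins_flank
  hit[, pos0 := pos - 1L]
  hit[, `:=`(s = gene_relative_pos(pos0, gstart, gend, strand),
             L = gend - gstart)]
  # sites in the clipped upstream flank of '+' genes near coord 0 keep
  # their true signed offset; drop anything beyond the flank span
  hit <- hit[s >= -flank & s < L + flank]
  hit[, bin := ifelse(
    s < 0, floor((s + flank) / wf) + 1L,
    ifelse(s < L,
           n_bins_flank + 1L + pmin(floor(s / L * n_bins_body),
                                    n_bins_body - 1L),
           n_bins_flank + n_bins_body + 1L + pmin(floor((s - L) / wf),
                                                  n_bins_flank - 1L)))]
  total_bins <- 2L * n_bins_flank + n_bins_body
  grid <- data.table::CJ(class = unique(genes$class),
                         bin = seq_len(total_bins))
  agg <- hit[, .(pooled_meth = sum(count_meth),
                 pooled_unmeth = sum(count_unmeth),
                 n_sites = .N), by = .(class, bin)]
  agg <- merge(grid, agg, by = c("class", "bin"), all.x = TRUE)
  for (cc in c("pooled_meth", "pooled_unmeth", "n_sites"))
    data.table::set(agg, which(is.na(agg[[cc]])), cc, 0L)
  agg[, `:=`(
    region = ifelse(bin <= n_bins_flank, "upstream",
                    ifelse(bin <= n_bins_flank + n_bins_body, "body",
                           "downstream")),
    weighted_ml = ifelse(pooled_meth + pooled_unmeth > 0,
                         pooled_meth / (pooled_meth + pooled_unmeth),
                         NA_real_))]
  data.table::setorder(agg, class, bin)
  agg[, .(class, region, bin, n_sites, pooled_meth, pooled_unmeth,
          weighted_ml)]
}

# per-gene weighted ML in upstream / body / downstream regions
per_gene_region_ml <- function(cx, ann, context = NULL, flank = 2000L) {
  cx <- cx_table(cx)
  if (!is.null(context)) {
    sel_ctx <- cx$context == context
    cx <- cx[sel_ctx]
  }
  genes <- ann$genes
  win <- genes[, .(gene_id, chrom, strand, gstart = start, gend = end,
                   start = pmax(0L, start - as.integer(flank)),
                   end = end + as.integer(flank))]
  hit <- sites_in_intervals(cx, win)
  hit[, pos0 := pos - 1L]
  hit[, s := gene_relative_pos(pos0, gstart, gend, strand)]
  hit <- hit[s >= -flank & s < (gend - gstart) + flank]
  hit[, region := ifelse(s < 0, "upstream",
                         ifelse(s < gend - gstart, "body", "downstream"))]
  agg <- hit[, .(pooled_meth = sum(count_meth),
                 pooled_unmeth = sum(count_unmeth)),
             by = .(gene_id, region)]
  agg[, ml := ifelse(pooled_meth + pooled_unmeth > 0,
                     pooled_meth / (pooled_meth + pooled_unmeth), NA_real_)]
  agg[]
}

#' Methylation by expression group with rank tests
#'
#' Genes are grouped Low = {none, low} and High = {medium, high} by
#' expression class; per gene and region (upstream 2 kb, body, downstream
#' 2 kb) the weighted ML is computed, and the two groups are compared per
#' region with a two-sided Mann-Whitney U test on per-gene MLs.
#'
#' @param cx Cytosine table.
#' @param ann An [annotation_set()].
#' @param classing Output of [classify_expression()] covering the genes.
#' @param context Optional context restriction.
#' @param flank Flank span in bp (default 2000).
#' @return data.table with `region`, group sizes, group median MLs and
#'   `p_value` (NA when a group has < 2 genes with defined ML).
#' @export
ml_by_expression <- function(cx, ann, classing, context = NULL,
                             flank = 2000L) {
  stopifnot(inherits(ann, "annotation_set"))
  classing <- data.table::as.data.table(classing)
  missing <- setdiff(ann$genes$gene_id, classing$gene_id)
  if (length(missing))
    stop_config("classing lacks gene(s): %s", missing[1L])
  pg <- per_gene_region_ml(cx, ann, context, flank)
  pg <- merge(pg, classing[, .(gene_id, class)], by = "gene_id")
  pg[, grp := ifelse(class %in% c("none", "low"), "L", "H")]
  out <- pg[!is.na(ml),
            {
              l <- ml[grp == "L"]; h <- ml[grp == "H"]
              p <- if (length(l) >= 2L && length(h) >= 2L)
                stats::wilcox.test(l, h, exact = FALSE)$p.value
              else NA_real_
              .(n_low = length(l), n_high = length(h),
                median_ml_low = if (length(l)) stats::median(l) else NA_real_,
                median_ml_high = if (length(h)) stats::median(h) else
                  NA_real_,
                p_value = p)
            },
            by = region]
  data.table::setorder(out, region)
  out[]
}
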