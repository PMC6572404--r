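#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric convention: conditioning on the margins, the
#' p-value sums the probabilities of all tables whose probability does not
#' exceed the observed table's (with the standard relative tolerance of
#' 1e-7 for floating-point ties).  Vectorised over tables.
#'
#' @param a,b,c,d Cell counts: rows are samples, columns are
#'   methylated/unmethylated (or any 2x2 layout; the test is
#'   label-symmetric).
#' @return Numeric vector of p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) stop_config("counts must be non-negative")
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]                 # row-1 total
    nn <- c[i] + d[i]                # row-2 total
    k <- a[i] + c[i]                 # column-1 total
    if (m + nn == 0L) return(1)
    support <- max(0L, k - nn):min(k, m)
    dens <- stats::dhyper(support, m, nn, k)
    dobs <- stats::dhyper(a[i], m, nn, k)
    min(1, sum(dens[dens <= dobs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Sliding windows along a chromosome
#'
#' Windows `[k*step, k*step + window)` for k = 0, 1, ...; the final window
#' is clipped at the chromosome end and every base below `chrom_len` is
#' covered by at least one window.
#'
#' @param chrom_len Chromosome length (bp).
#' @param window Window width (default 1000).
#' @param step Step length (default 100); must satisfy
#'   `window >= step >= 1`.
#' @return data.table with `start`, `end` (0-based half-open).
#' @export
sliding_windows <- function(chrom_len, window = 1000L, step = 100L) {
  window <- as.integer(window); step <- as.integer(step)
  chrom_len <- as.integer(chrom_len)
  if (step < 1L || window < step)
    stop_config("need window >= step >= 1")
  if (chrom_len < 1L) stop_config("chrom_len must be >= 1")
  kmax <- if (chrom_len <= window) 0L
  else as.integer(ceiling((chrom_len - window) / step))
  starts <- (0:kmax) * step
  data.table::data.table(start = starts,
                         end = pmin(starts + window, chrom_len))
}

# join two cytosine tables on (chrom, pos, strand) and keep sites covered
# at >= min_cov in BOTH samples (and in the requested context)
matched_sites <- function(cx_a, cx_b, context = NULL, min_cov = 4L) {
  a <- cx_table(cx_a)[, .(chrom, pos, strand, context,
                          cm_a = count_meth, cu_a = count_unmeth)]
  b <- cx_table(cx_b)[, .(chrom, pos, strand,
                          cm_b = count_meth, cu_b = count_unmeth)]
  m <- merge(a, b, by = c("chrom", "pos", "strand"))
  if (!is.null(context)) {
    sel_ctx <- m$context == context
    m <- m[sel_ctx]
  }
  m <- m[cm_a + cu_a >= min_cov & cm_b + cu_b >= min_cov]
  data.table::setorder(m, chrom, pos)
  m
}

#' Fisher test of one genomic window between two samples
#'
#' Pools methylated/unmethylated counts over context sites inside
#' `[start, end)` that are covered at `min_cov` or more in both samples,
#' then applies the two-sided Fisher exact test to the 2x2 sample-by-state
#' table.  Undefined (`p = NA`) when fewer than `min_sites` sites qualify.
#'
#' @param cx_a,cx_b Cytosine tables for the two samples.
#' @param chrom,start,end Window (0-based half-open).
#' @param context Optional context restriction.
#' @param min_sites Minimum qualifying sites (default 5).
#' @param min_cov Minimum per-sample coverage per site (default 4).
#' @return List with `p_value`, `ml_a`, `ml_b`, `n_sites`.
#' @export
window_test <- function(cx_a, cx_b, chrom, start, end, context = NULL,
                        min_sites = 5L, min_cov = 4L) {
  if (min_sites < 1L) stop_config("min_sites must be >= 1")
  m <- matched_sites(cx_a, cx_b, context, min_cov)
  m <- m[m$chrom == chrom & pos - 1L >= start & pos - 1L < end]
  if (nrow(m) < min_sites)
    return(list(p_value = NA_real_, ml_a = NA_real_, ml_b = NA_real_,
                n_sites = nrow(m)))
  sm_a <- sum(m$cm_a); su_a <- sum(m$cu_a)
  sm_b <- sum(m$cm_b); su_b <- sum(m$cu_b)
  list(p_value = fisher_exact_p(sm_a, su_a, sm_b, su_b),
       ml_a = sm_a / (sm_a + su_a), ml_b = sm_b / (sm_b + su_b),
       n_sites = nrow(m))
}

# merge same-direction windows that overlap or lie within merge_gap;
# input must have chrom/start/end/direction (+ p_value); returns groups
merge_window_runs <- function(w, merge_gap) {
  data.table::setorder(w, chrom, direction, start)
  w[, grp := {
    new_run <- c(TRUE, start[-1L] > cummax(head(end, -1L)) + merge_gap)
    cumsum(new_run)
  }, by = .(chrom, direction)]
  w
}

#' Call differentially methylated regions by sliding-window Fisher testing
#'
#' Every window (default 1000 bp, step 100 bp) is tested with
#' [window_test()]; windows with `p < alpha` and an absolute weighted-ML
#' difference of at least `min_ml_diff` are kept, and overlapping or
#' near-adjacent (within `merge_gap`) same-direction windows are merged.
#' Each merged region is re-scored from its pooled counts (overlapping
#' windows share reads, so combining window p-values would be invalid).
#' Direction is that of sample B relative to sample A: `hypo` when
#' `ml_b < ml_a`.
#'
#' @param cx_a,cx_b Cytosine tables for samples A and B.
#' @param context Context to test (default "CG"); `NULL` pools contexts.
#' @param window,step Sliding-window geometry (defaults 1000 / 100 bp).
#' @param alpha Window significance threshold (default 0.01).
#' @param min_sites,min_cov Site filters as in [window_test()].
#' @param min_ml_diff Minimum |ml_a - ml_b| per window (default 0.1).
#' @param merge_gap Maximum gap between merged windows (default = `step`).
#' @param chrom_lengths Optional named vector; defaults to the maximum
#'   observed cytosine position per chromosome.
#' @return data.table of DMRs: `chrom`, `start`, `end`, `context`,
#'   `direction`, `ml_a`, `ml_b`, `p_value` (pooled re-score), `p_min`
#'   (smallest constituent-window p), `n_windows`, `n_sites`.
#' @export
call_dmrs <- function(cx_a, cx_b, context = "CG", window = 1000L,
                      step = 100L, alpha = 0.01, min_sites = 5L,
                      min_cov = 4L, min_ml_diff = 0.1, merge_gap = step,
                      chrom_lengths = NULL) {
  if (identical(cx_a, cx_b))
    stop_config("the same cytosine collection was passed as both samples")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  m <- matched_sites(cx_a, cx_b, context, min_cov)
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    context = character(), direction = character(), ml_a = numeric(),
    ml_b = numeric(), p_value = numeric(), p_min = numeric(),
    n_windows = integer(), n_sites = integer())
  if (nrow(m) == 0L) return(empty)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(split(m$pos, m$chrom), max, numeric(1))
  ctx_label <- context %||% "all"
  kept <- list()
  for (cn in unique(m$chrom)) {
    mc <- m[chrom == cn]
    p0 <- mc$pos - 1L
    cs_ma <- cumsum(mc$cm_a); cs_ua <- cumsum(mc$cu_a)
    cs_mb <- cumsum(mc$cm_b); cs_ub <- cumsum(mc$cu_b)
    wdt <- sliding_windows(chrom_lengths[[cn]], window, step)
    # index range of sites with start <= p0 < end
    i1 <- findInterval(wdt$start - 0.5, p0) + 1L
    i2 <- findInterval(wdt$end - 0.5, p0)
    ns <- i2 - i1 + 1L
    ok <- ns >= min_sites
    if (!any(ok)) next
    at <- function(cs, i) ifelse(i >= 1L, cs[pmax(i, 1L)], 0)
    sm_a <- at(cs_ma, i2[ok]) - at(cs_ma, i1[ok] - 1L)
    su_a <- at(cs_ua, i2[ok]) - at(cs_ua, i1[ok] - 1L)
    sm_b <- at(cs_mb, i2[ok]) - at(cs_mb, i1[ok] - 1L)
    su_b <- at(cs_ub, i2[ok]) - at(cs_ub, i1[ok] - 1L)
    ml_a <- sm_a / (sm_a + su_a)
    ml_b <- sm_b / (sm_b + su_b)
    # ML-difference filter first: the exact test is the expensive part
    cand <- !is.na(ml_a) & !is.na(ml_b) & abs(ml_a - ml_b) >= min_ml_diff
    if (!any(cand)) next
    p <- rep(NA_real_, sum(ok))
    p[cand] <- fisher_exact_p(sm_a[cand], su_a[cand], sm_b[cand],
                              su_b[cand])
    sig <- which(cand & p < alpha)
    if (!length(sig)) next
    kept[[cn]] <- data.table::data.table(
      chrom = cn, start = wdt$start[ok][sig], end = wdt$end[ok][sig],
      p_value = p[sig], ml_a = ml_a[sig], ml_b = ml_b[sig],
      direction = ifelse(ml_b[sig] < ml_a[sig], "hypo", "hyper"))
  }
  if (!length(kept)) return(empty)
  w <- merge_window_runs(data.table::rbindlist(kept), merge_gap)
  dmrs <- w[, .(start = min(start), end = max(end),
                p_min = min(p_value), n_windows = .N),
            by = .(chrom, direction, grp)]
  # re-score each merged region from pooled counts over its union span
  res <- lapply(seq_len(nrow(dmrs)), function(i) {
    mc <- m[chrom == dmrs$chrom[i] & pos - 1L >= dmrs$start[i] &
              pos - 1L < dmrs$end[i]]
    sm_a <- sum(mc$cm_a); su_a <- sum(mc$cu_a)
    sm_b <- sum(mc$cm_b); su_b <- sum(mc$cu_b)
    list(p_value = fisher_exact_p(sm_a, su_a, sm_b, su_b),
         ml_a = sm_a / (sm_a + su_a), ml_b = sm_b / (sm_b + su_b),
         n_sites = nrow(mc))
  })
  dmrs[, `:=`(p_value = vapply(res, `[[`, numeric(1), "p_value"),
              ml_a = vapply(res, `[[`, numeric(1), "ml_a"),
              ml_b = vapply(res, `[[`, numeric(1), "ml_b"),
              n_sites = vapply(res, `[[`, integer(1), "n_sites"),
              context = ctx_label)]
  dmrs[, grp := NULL]
  data.table::setorder(dmrs, chrom, start)
  dmrs[, .(chrom, start, end, context, direction, ml_a, ml_b, p_value,
           p_min, n_windows, n_sites)]
}

# interval intersection length between one interval and a set
overlap_bp <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

#' Associate DMRs with genes
#'
#' A gene is DMR-associated when a DMR intersects its gene body or its
#' 2 kb flanks.  The compartment of each (DMR, gene) link follows the
#' precedence promoter > exon > intron > downstream; overlap with repeats
#' is reported independently per DMR.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param ann An [annotation_set()].
#' @return List with `links` (dmr_id, gene_id, direction, compartment,
#'   repeat_overlap) and `genes` (per-gene DMR summary).
#' @export
associate_genes <- function(dmrs, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  dmrs <- data.table::as.data.table(dmrs)
  empty <- list(
    links = data.table::data.table(dmr_id = integer(),
                                   gene_id = character(),
                                   direction = character(),
                                   compartment = character(),
                                   repeat_overlap = logical()),
    genes = data.table::data.table(gene_id = character(),
                                   n_dmrs = integer(),
                                   directions = character()))
  if (nrow(dmrs) == 0L) return(empty)
  dmrs[, dmr_id := .I]
  comps <- list(promoter = ann_promoters(ann),
                exon = ann$exons,
                intron = ann_introns(ann),
                downstream = ann_downstream(ann))
  rp <- ann$repeats
  sp <- ann$promoter_span
  g <- ann$genes
  links <- list()
  for (i in seq_len(nrow(dmrs))) {
    d <- dmrs[i]
    cand <- g[chrom == d$chrom & start - sp < d$end & end + sp > d$start]
    if (nrow(cand) == 0L) next
    for (j in seq_len(nrow(cand))) {
      gid <- cand$gene_id[j]
      comp <- NA_character_
      for (cl in names(comps)) {
        iv <- comps[[cl]][gene_id == gid]
        if (nrow(iv) &&
            any(overlap_bp(d$start, d$end, iv$start, iv$end) > 0L)) {
          comp <- cl
          break
        }
      }
      if (is.na(comp)) next
      links[[length(links) + 1L]] <- data.table::data.table(
        dmr_id = d$dmr_id, gene_id = gid, direction = d$direction,
        compartment = comp)
    }
  }
  if (!length(links)) return(empty)
  links <- data.table::rbindlist(links)
  rep_ov <- if (nrow(rp)) vapply(seq_len(nrow(dmrs)), function(i) {
    any(rp$chrom == dmrs$chrom[i] &
          overlap_bp(dmrs$start[i], dmrs$end[i], rp$start, rp$end) > 0L)
  }, logical(1)) else rep(FALSE, nrow(dmrs))
  links[, repeat_overlap := rep_ov[dmr_id]]
  genes <- links[, .(n_dmrs = data.table::uniqueN(dmr_id),
                     directions = paste(sort(unique(direction)),
                                        collapse = ",")),
                 by = gene_id]
  list(links = links[], genes = genes[])
}

#' Distribution of DMRs over genomic compartments
#'
#' Each DMR is assigned one primary compartment (promoter, exon, intron,
#' downstream, repeat, other) by maximal base-pair overlap; ties follow the
#' precedence promoter > exon > intron > downstream > repeat.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param ann An [annotation_set()].
#' @return data.table with `compartment`, `n`, `share_pct` (sums to 100).
#' @export
dmr_compartment_distribution <- function(dmrs, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  dmrs <- data.table::as.data.table(dmrs)
  if (nrow(dmrs) == 0L)
    return(data.table::data.table(compartment = character(), n = integer(),
                                  share_pct = numeric()))
  comps <- list(promoter = ann_promoters(ann),
                exon = ann$exons,
                intron = ann_introns(ann),
                downstream = ann_downstream(ann),
                repeat_ = ann$repeats)
  assign_one <- function(i) {
    ov <- vapply(comps, function(iv) {
      if (nrow(iv) == 0L) return(0L)
      iv <- iv[iv$chrom == dmrs$chrom[i]]
      if (nrow(iv) == 0L) return(0L)
      max(overlap_bp(dmrs$start[i], dmrs$end[i], iv$start, iv$end))
    }, integer(1))
    if (all(ov == 0L)) return("other")
    sub("_$", "", names(comps)[which.max(ov)])  # which.max: first = precedence
  }
  comp <- vapply(seq_len(nrow(dmrs)), assign_one, character(1))
  out <- data.table::as.data.table(table(compartment = comp))
  data.table::setnames(out, "N", "n")
  out[, share_pct := 100 * n / sum(n)]
  out[]
}
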