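#' Assign differential-expression status from fold change and FDR
#'
#' `up` when the (linear) fold change is at least `fc_threshold` and FDR is
#' at most `fdr_threshold`; `down` symmetrically when the fold change is at
#' most `1 / fc_threshold`; otherwise `ns`.  Thresholds are inclusive.
#'
#' @param deg_table data.frame with `gene_id`, a fold-change column
#'   (`fold_change`, linear B/A, or `log2_fold_change`) and `fdr`.
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return data.table with added `status` column (up/down/ns).
#' @export
filter_degs <- function(deg_table, fc_threshold = 2, fdr_threshold = 0.05) {
  dt <- data.table::as.data.table(deg_table)
  if (!"gene_id" %in% names(dt))
    stop_config("DEG table needs a 'gene_id' column")
  if (!"fold_change" %in% names(dt)) {
    if (!"log2_fold_change" %in% names(dt))
      stop_config("DEG table needs 'fold_change' or 'log2_fold_change'")
    dt[, fold_change := 2^log2_fold_change]
  }
  if (!"fdr" %in% names(dt)) stop_config("DEG table needs an 'fdr' column")
  dt[, status := "ns"]
  dt[fold_change >= fc_threshold & fdr <= fdr_threshold, status := "up"]
  dt[fold_change <= 1 / fc_threshold & fdr <= fdr_threshold,
     status := "down"]
  dt[]
}

#' DMR-gene by DEG enrichment (Fisher exact)
#'
#' For each DMR direction (hypo/hyper) and DEG status (up/down) the genes
#' are cross-tabulated against the universe and tested with a two-sided
#' Fisher exact test.  The odds ratio is the sample cross-product; when any
#' cell is zero a 0.5 continuity correction is applied to the odds ratio
#' (never to the p-value) and flagged.
#'
#' @param dmr_genes Named list of gene-id vectors by direction, e.g.
#'   `list(hypo = ..., hyper = ...)`.
#' @param deg_genes Named list of gene-id vectors by status, e.g.
#'   `list(up = ..., down = ...)`.
#' @param universe Character vector of all genes eligible for both
#'   analyses; every set must be contained in it.
#' @return data.table with one row per direction-status pair: 2x2 counts,
#'   `odds_ratio`, `continuity`, `p_value`.
#' @export
dmr_deg_enrichment <- function(dmr_genes, deg_genes, universe) {
  universe <- unique(universe)
  for (nm in names(dmr_genes))
    if (length(setdiff(dmr_genes[[nm]], universe)))
      stop_config("DMR gene set '%s' is not contained in the universe", nm)
  for (nm in names(deg_genes))
    if (length(setdiff(deg_genes[[nm]], universe)))
      stop_config("DEG set '%s' is not contained in the universe", nm)
  out <- list()
  for (dir in names(dmr_genes)) for (st in names(deg_genes)) {
    D <- unique(dmr_genes[[dir]]); E <- unique(deg_genes[[st]])
    n11 <- length(intersect(D, E))
    n12 <- length(D) - n11
    n21 <- length(E) - n11
    n22 <- length(universe) - n11 - n12 - n21
    p <- stats::fisher.test(matrix(c(n11, n12, n21, n22), 2L,
                                   byrow = TRUE))$p.value
    continuity <- any(c(n11, n12, n21, n22) == 0L)
    orr <- if (length(D) == 0L || length(E) == 0L) NA_real_
    else if (continuity)
      ((n11 + 0.5) * (n22 + 0.5)) / ((n12 + 0.5) * (n21 + 0.5))
    else (n11 * n22) / (n12 * n21)
    out[[length(out) + 1L]] <- data.table::data.table(
      direction = dir, status = st, n_overlap = n11, n_dmr_only = n12,
      n_deg_only = n21, n_neither = n22, odds_ratio = orr,
      continuity = continuity, p_value = p)
  }
  data.table::rbindlist(out)
}

#' Counts of every intersection region of named sets
#'
#' @param set_map Named list of vectors (duplicates within a set are
#'   dropped).
#' @return data.table with a logical membership column per set, the
#'   `region` label (e.g. "A&B") and `count`; only non-empty membership
#'   patterns over the union are enumerated, empty regions report 0.
#' @export
venn_counts <- function(set_map) {
  stopifnot(length(set_map) >= 1L, !is.null(names(set_map)))
  sets <- lapply(set_map, unique)
  nms <- names(sets)
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(patterns) <- nms
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe), ncol = k,
                   dimnames = list(NULL, nms))
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == as.logical(p))))
  })
  out <- data.table::as.data.table(patterns)
  out[, region := apply(patterns, 1L, function(p)
    paste(nms[as.logical(p)], collapse = "&"))]
  out[, count := as.integer(counts)]
  out[]
}

#' Relative quantification by the 2^-ddCt method
#'
#' `2 ^ -((target_ct - reference_ct) -
#' (calibrator_target_ct - calibrator_reference_ct))`: the target gene's Ct
#' is normalised to a reference gene, then to a calibrator sample.
#'
#' @param target_ct,reference_ct Ct values in the sample of interest.
#' @param calibrator_target_ct,calibrator_reference_ct Ct values in the
#'   calibrator sample.
#' @return Relative quantity (1 when nothing differs).
#' @export
ddct <- function(target_ct, reference_ct, calibrator_target_ct,
                 calibrator_reference_ct) {
  stopifnot(all(is.finite(c(target_ct, reference_ct, calibrator_target_ct,
                            calibrator_reference_ct))))
  2^-((target_ct - reference_ct) -
        (calibrator_target_ct - calibrator_reference_ct))
}
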