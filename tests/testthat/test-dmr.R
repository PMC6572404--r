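test_that("sliding windows enumerate, clip, and cover every base", {
  w <- sliding_windows(1200, 1000, 100)
  expect_equal(w$start, c(0L, 100L, 200L))
  expect_equal(w$end, c(1000L, 1100L, 1200L))
  # window == step tiles without overlap
  w2 <- sliding_windows(950, 200, 200)
  expect_equal(w2$start, seq(0L, 800L, by = 200L))
  expect_equal(w2$end[nrow(w2)], 950L)
  # chromosome shorter than the window: single clipped window
  w3 <- sliding_windows(300, 1000, 100)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$end, 300L)
  # coverage property on irregular sizes
  for (len in c(1L, 999L, 1000L, 1001L, 1234L)) {
    ww <- sliding_windows(len, 1000, 100)
    covered <- rep(FALSE, len)
    for (i in seq_len(nrow(ww)))
      covered[(ww$start[i] + 1L):ww$end[i]] <- TRUE
    expect_true(all(covered), info = len)
  }
  expect_error(sliding_windows(100, 10, 20), "window >= step")
})

test_that("the exact 2x2 p-value matches fisher.test across random tables", {
  set.seed(51)
  tab <- matrix(sample(0:40, 400, replace = TRUE), ncol = 4)
  ours <- fisher_exact_p(tab[, 1], tab[, 2], tab[, 3], tab[, 4])
  ref <- apply(tab, 1, function(r)
    fisher.test(matrix(r, 2, byrow = TRUE))$p.value)
  expect_equal(ours, ref, tolerance = 1e-12)
  # closed-form extreme: [[30,0],[0,30]]
  expect_equal(fisher_exact_p(30, 0, 0, 30), 2 / choose(60, 30),
               tolerance = 1e-12)
})

test_that("window test pools qualifying sites and applies the filters", {
  a <- make_cx("chr1", c(101L, 201L, 301L, 401L, 501L), "+",
               c(10L, 10L, 10L, 10L, 10L), c(2L, 2L, 2L, 2L, 2L))
  b <- make_cx("chr1", c(101L, 201L, 301L, 401L, 501L), "+",
               c(10L, 10L, 10L, 10L, 10L), c(2L, 2L, 2L, 2L, 2L))
  out <- window_test(a, b, "chr1", 0L, 1000L)
  expect_equal(out$p_value, 1)
  expect_equal(out$n_sites, 5L)
  # too few qualifying sites -> undefined
  out2 <- window_test(a, b, "chr1", 0L, 1000L, min_sites = 6L)
  expect_true(is.na(out2$p_value))
  # min_cov excludes sites below coverage in either sample
  b2 <- data.table::copy(b)
  b2[1, c("count_meth", "count_unmeth") := list(1L, 1L)]
  out3 <- window_test(a, cx_table(b2), "chr1", 0L, 1000L, min_cov = 4L)
  expect_equal(out3$n_sites, 4L)
})

test_that("a planted DMR is recovered with correct direction and extent", {
  regions <- data.frame(chrom = "chr1", start = 8000L, end = 10000L)
  pd <- planted_dmr_frame(regions, "CG", "petal", "stamen", 0.8, 0.2)
  cfg <- sim_config(seed = 1, n_chroms = 1, chrom_len = 30000,
                    n_genes = 8, n_repeats = 5, planted_dmrs = pd)
  sim <- simulate_genome(cfg)
  a <- simulate_methylome(sim$genome, cfg, "petal")$cx
  b <- simulate_methylome(sim$genome, cfg, "stamen")$cx
  d <- call_dmrs(a, b, context = "CG")
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "hypo")
  ov <- min(d$end, 10000L) - max(d$start, 8000L)
  expect_gte(ov / 2000, 0.8)
  # swapping samples flips direction, keeps coordinates and p-values
  d2 <- call_dmrs(b, a, context = "CG")
  expect_equal(d2$direction, "hyper")
  expect_equal(d2[, .(chrom, start, end, p_value)],
               d[, .(chrom, start, end, p_value)])
  expect_equal(d2$ml_a, d$ml_b)
  # an impossible ML difference empties the result
  expect_equal(nrow(call_dmrs(a, b, context = "CG", min_ml_diff = 1.0)),
               0L)
  expect_error(call_dmrs(a, a), "same cytosine collection")
})

test_that("merged DMRs are idempotent under re-merging", {
  regions <- data.frame(chrom = "chr1",
                        start = c(5000L, 15000L), end = c(7000L, 17000L))
  pd <- planted_dmr_frame(regions, "CG", "petal", "stamen", 0.9, 0.1)
  cfg <- sim_config(seed = 2, n_chroms = 1, chrom_len = 25000,
                    n_genes = 5, n_repeats = 0, planted_dmrs = pd)
  sim <- simulate_genome(cfg)
  a <- simulate_methylome(sim$genome, cfg, "petal")$cx
  b <- simulate_methylome(sim$genome, cfg, "stamen")$cx
  d <- call_dmrs(a, b, context = "CG", merge_gap = 100L)
  # same-direction DMRs are separated by more than the merge gap
  data.table::setorder(d, chrom, start)
  if (nrow(d) > 1L)
    expect_true(all(d$start[-1L] > d$end[-nrow(d)] + 100L))
  remerged <- methscan:::merge_window_runs(data.table::copy(d), 100L)
  # nothing merges further: one run per DMR
  expect_equal(data.table::uniqueN(remerged,
                                   by = c("chrom", "direction", "grp")),
               nrow(d))
})

test_that("null data yields about the nominal window false-positive rate", {
  cfg <- sim_config(seed = 7, n_chroms = 1, chrom_len = 60000,
                    n_genes = 10, n_repeats = 0)
  sim <- simulate_genome(cfg)
  a <- simulate_methylome(sim$genome, cfg, "petal")$cx
  b <- simulate_methylome(sim$genome, cfg, "stamen")$cx
  m <- methscan:::matched_sites(a, b, "CG", 4L)
  wdt <- sliding_windows(60000, 1000, 100)
  p0 <- m$pos - 1L
  ps <- vapply(seq_len(nrow(wdt)), function(i) {
    sel <- p0 >= wdt$start[i] & p0 < wdt$end[i]
    if (sum(sel) < 5L) return(NA_real_)
    fisher_exact_p(sum(m$cm_a[sel]), sum(m$cu_a[sel]),
                   sum(m$cm_b[sel]), sum(m$cu_b[sel]))
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  fp <- mean(ps < 0.01)
  se <- sqrt(0.01 * 0.99 / length(ps))
  # exact test is conservative; windows overlap so use a generous band
  expect_lte(fp, 0.01 + 3 * se + 0.01)
})

test_that("DMR-gene association respects compartment precedence", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 10000L, end = 16000L)
  exons <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = c(10000L, 14000L), end = c(12000L, 16000L))
  reps <- data.frame(chrom = "chr1", start = 30000L, end = 31000L)
  ann <- annotation_set(genes, exons, reps)
  dmr <- function(s, e) data.table::data.table(
    chrom = "chr1", start = s, end = e, context = "CG",
    direction = "hypo", ml_a = 0.8, ml_b = 0.2, p_value = 1e-6)
  # fully inside the intron
  out <- associate_genes(dmr(12500L, 13000L), ann)
  expect_equal(out$links$compartment, "intron")
  # spanning promoter and first exon: promoter wins
  out2 <- associate_genes(dmr(9500L, 10500L), ann)
  expect_equal(out2$links$compartment, "promoter")
  # gene desert far from any gene: no links
  out3 <- associate_genes(dmr(40000L, 41000L), ann)
  expect_equal(nrow(out3$links), 0L)
  # repeat overlap is reported independently
  out4 <- associate_genes(dmr(15500L, 30500L), ann)
  expect_true(all(out4$links$repeat_overlap))
})

test_that("compartment distribution assigns by maximal overlap", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 10000L, end = 16000L)
  exons <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 10000L, end = 16000L)
  ann <- annotation_set(genes, exons)
  dmrs <- data.table::data.table(
    chrom = "chr1", start = c(9400L, 40000L), end = c(10400L, 41000L),
    context = "CG", direction = "hypo", ml_a = 0.8, ml_b = 0.2,
    p_value = 1e-6)
  out <- dmr_compartment_distribution(dmrs, ann)
  # 600 bp promoter vs 400 bp exon -> promoter; the second DMR is "other"
  expect_equal(out[compartment == "promoter"]$n, 1L)
  expect_equal(out[compartment == "other"]$n, 1L)
  expect_equal(sum(out$share_pct), 100)
  # intergenic-only input
  out2 <- dmr_compartment_distribution(dmrs[2L], ann)
  expect_equal(out2$compartment, "other")
  expect_equal(out2$share_pct, 100)
  expect_equal(nrow(dmr_compartment_distribution(dmrs[0L], ann)), 0L)
})
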