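test_that("feature ML pools counts per class", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 5000L, end = 6000L)
  ann <- make_ann(genes)
  # sites only inside the exon (= whole single-exon gene body)
  cx <- make_cx("chr1", c(5101L, 5201L), "+", c(5L, 5L), c(5L, 5L))
  out <- feature_ml(cx, ann)
  expect_equal(out[feature == "exon"]$weighted_ml, 0.5)
  expect_true(is.na(out[feature == "promoter"]$weighted_ml))
  expect_true(is.na(out[feature == "intron"]$weighted_ml))
  expect_true(is.na(out[feature == "repeat"]$weighted_ml))
  # empty annotation: everything undefined
  empty <- annotation_set(
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer()),
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer()))
  out0 <- feature_ml(cx, empty)
  expect_true(all(is.na(out0$weighted_ml)))
})

test_that("planted intron-high / exon-low rates are recovered in order", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 1000L, end = 4000L)
  exons <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = c(1000L, 3000L), end = c(2000L, 4000L))
  ann <- annotation_set(genes, exons)
  set.seed(31)
  pos <- seq(1001L, 4000L, by = 7L)
  in_intron <- pos - 1L >= 2000L & pos - 1L < 3000L
  cov <- rpois(length(pos), 30)
  meth <- rbinom(length(pos), cov, ifelse(in_intron, 0.5, 0.2))
  cx <- make_cx("chr1", pos, "+", meth, cov - meth)
  out <- feature_ml(cx, ann)
  expect_gt(out[feature == "intron"]$weighted_ml,
            out[feature == "exon"]$weighted_ml)
})

test_that("expression classes follow the FPKM threshold and quartiles", {
  tab <- data.frame(gene_id = paste0("g", 1:100), fpkm = as.numeric(1:100))
  cls <- classify_expression(tab)
  q <- quantile(as.numeric(1:100), c(0.25, 0.75), names = FALSE)
  expect_equal(as.character(cls$class[cls$fpkm <= q[1]]),
               rep("low", sum(tab$fpkm <= q[1])))
  expect_equal(as.character(cls$class[cls$fpkm > q[2]]),
               rep("high", sum(tab$fpkm > q[2])))
  expect_equal(as.character(cls$class[cls$fpkm == 50]), "medium")
  # threshold: below 1 is none, exactly 1 is expressed (low)
  cls2 <- classify_expression(data.frame(gene_id = c("a", "b", "c"),
                                         fpkm = c(0.5, 1, 300)))
  expect_equal(as.character(cls2$class), c("none", "low", "high"))
  # all unexpressed: no crash, all none
  cls3 <- classify_expression(data.frame(gene_id = "a", fpkm = 0.2))
  expect_equal(as.character(cls3$class), "none")
  expect_error(classify_expression(data.frame(gene_id = character(),
                                              fpkm = numeric())), "empty")
  # gene order invariance
  shuffled <- tab[sample(nrow(tab)), ]
  cls4 <- classify_expression(shuffled)
  m <- merge(cls, cls4, by = "gene_id")
  expect_true(all(m$class.x == m$class.y))
})

test_that("metagene profile is flat for a uniform-rate genome", {
  cfg <- sim_config(seed = 17, n_chroms = 1, chrom_len = 80000,
                    n_genes = 25, n_repeats = 0,
                    base_rates = c(CG = 0.3, CHG = 0.3, CHH = 0.3),
                    mean_coverage = 30)
  sim <- simulate_genome(cfg)
  cx <- simulate_methylome(sim$genome, cfg, "petal")$cx
  prof <- metagene_profile(cx, sim$annotation)
  expect_equal(nrow(prof), 60L)
  expect_lt(max(prof$weighted_ml) - min(prof$weighted_ml), 0.05)
  expect_lt(abs(mean(prof$weighted_ml) - 0.3), 0.02)
})

test_that("a '-' strand gene profiles identically to its '+' mirror", {
  L <- 10000L
  gp <- data.frame(gene_id = "gp", chrom = "cp", strand = "+",
                   start = 4000L, end = 6000L)
  gm <- data.frame(gene_id = "gm", chrom = "cm", strand = "-",
                   start = L - 6000L, end = L - 4000L)
  set.seed(41)
  pos_p <- sort(sample(2000:8000, 400))
  cov <- rpois(400, 20)
  meth <- rbinom(400, cov, plogis((pos_p - 5000) / 800))
  cx_p <- make_cx("cp", pos_p, "+", meth, cov - meth)
  # mirror: position p on '+' maps to L - p + 1 viewed from the '-' gene
  cx_m <- make_cx("cm", L - pos_p + 1L, "-", meth, cov - meth)
  ann_p <- make_ann(gp); ann_m <- make_ann(gm)
  prof_p <- metagene_profile(cx_p, ann_p)
  prof_m <- metagene_profile(cx_m, ann_m)
  expect_equal(prof_p$weighted_ml, prof_m$weighted_ml)
  expect_equal(prof_p$pooled_meth, prof_m$pooled_meth)
})

test_that("metagene bins conserve the counts inside gene +/- flank spans", {
  cfg <- sim_config(seed = 19, n_chroms = 1, chrom_len = 30000,
                    n_genes = 6, n_repeats = 0)
  sim <- simulate_genome(cfg)
  cx <- simulate_methylome(sim$genome, cfg, "petal")$cx
  prof <- metagene_profile(cx, sim$annotation)
  g <- sim$annotation$genes
  expected <- sum(vapply(seq_len(nrow(g)), function(i) {
    sel <- cx$chrom == g$chrom[i] & cx$pos - 1L >= g$start[i] - 2000L &
      cx$pos - 1L < g$end[i] + 2000L
    sum(cx$count_meth[sel] + cx$count_unmeth[sel])
  }, numeric(1)))
  expect_equal(sum(prof$pooled_meth + prof$pooled_unmeth), expected)
})

test_that("short genes are excluded and missing classing genes error", {
  genes <- data.frame(gene_id = c("tiny", "ok"), chrom = "chr1",
                      strand = "+", start = c(100L, 1000L),
                      end = c(110L, 2000L))
  ann <- make_ann(genes)
  cx <- make_cx("chr1", 1500L, "+", 3L, 1L)
  prof <- metagene_profile(cx, ann, n_bins_body = 20L)
  expect_equal(sum(prof$pooled_meth), 3L)   # only the long gene
  expect_error(metagene_profile(cx, ann,
                                classing = data.frame(gene_id = "tiny",
                                                      class = "none")),
               "classing")
})

test_that("expression-group rank tests behave at the extremes", {
  # 40 genes side by side; low-expression genes highly methylated
  n <- 40L
  starts <- (seq_len(n) - 1L) * 1000L + 100L
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                      chrom = "chr1", strand = "+", start = starts,
                      end = starts + 800L)
  ann <- make_ann(genes, promoter_span = 50L)
  pos <- unlist(lapply(starts, function(s) s + c(100L, 400L, 700L)))
  hi <- rep(c(TRUE, FALSE), each = n / 2L)[rep(seq_len(n), each = 3L)]
  cx <- make_cx("chr1", pos + 1L, "+",
                ifelse(hi, 9L, 1L), ifelse(hi, 1L, 9L))
  classing <- data.frame(
    gene_id = genes$gene_id,
    class = rep(c("none", "high"), each = n / 2L))
  out <- ml_by_expression(cx, ann, classing)
  body <- out[region == "body"]
  expect_lt(body$p_value, 1e-6)
  expect_gt(body$median_ml_low, body$median_ml_high)
  # identical groups: p close to 1
  classing2 <- data.frame(gene_id = genes$gene_id,
                          class = rep(c("none", "high"), times = n / 2L))
  out2 <- ml_by_expression(cx, ann, classing2)
  expect_gt(out2[region == "body"]$p_value, 0.5)
  # one group absent: p undefined
  classing3 <- data.frame(gene_id = genes$gene_id, class = "none")
  out3 <- ml_by_expression(cx, ann, classing3)
  expect_true(all(is.na(out3$p_value)))
})
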