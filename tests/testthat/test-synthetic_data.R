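test_that("genome simulation is deterministic and respects GC content", {
  cfg <- sim_config(seed = 3, n_chroms = 2, chrom_len = 10000, n_genes = 6,
                    n_repeats = 4)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotation$genes, s2$annotation$genes)

  cfg_gc <- sim_config(seed = 3, n_chroms = 1, chrom_len = 2000,
                       n_genes = 1, n_repeats = 0, gc_content = 1)
  g <- simulate_genome(cfg_gc)$genome
  expect_true(grepl("^[GC]+$", g[["chr1"]]))

  # genes cannot fit
  cfg_big <- sim_config(seed = 1, n_chroms = 1, chrom_len = 5000,
                        n_genes = 10, n_repeats = 0,
                        gene_len_range = c(800L, 900L))
  expect_error(simulate_genome(cfg_big), "cannot place")
})

test_that("genes do not overlap and exons stay within genes", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_len = 50000,
                    n_genes = 30, n_repeats = 20)
  ann <- simulate_genome(cfg)$annotation
  g <- data.table::copy(ann$genes)
  data.table::setorder(g, chrom, start)
  by_chrom <- split(g, g$chrom)
  for (gc in by_chrom)
    if (nrow(gc) > 1)
      expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  # repeats avoid genes
  r <- ann$repeats
  for (i in seq_len(nrow(r))) {
    gg <- g[g$chrom == r$chrom[i]]
    expect_true(all(pmin(r$end[i], gg$end) - pmax(r$start[i], gg$start)
                    <= 0))
  }
})

test_that("methylome generator hits the degenerate corners", {
  cfg0 <- sim_config(seed = 2, n_chroms = 1, chrom_len = 3000, n_genes = 1,
                     n_repeats = 0, conversion_error = 0,
                     base_rates = c(CG = 0, CHG = 0, CHH = 0))
  sim <- simulate_genome(cfg0)
  mm <- simulate_methylome(sim$genome, cfg0, "petal")
  expect_true(all(mm$cx$count_meth == 0L))

  cfg1 <- sim_config(seed = 2, n_chroms = 1, chrom_len = 3000, n_genes = 1,
                     n_repeats = 0, conversion_error = 0,
                     base_rates = c(CG = 1, CHG = 1, CHH = 1))
  mm1 <- simulate_methylome(sim$genome, cfg1, "petal")
  cx1 <- mm1$cx[context != "Unknown"]
  expect_true(all(cx1$count_meth == cx1$coverage))
})

test_that("generator context labels equal classifier labels at every site", {
  cfg <- sim_config(seed = 4, n_chroms = 2, chrom_len = 4000, n_genes = 2,
                    n_repeats = 2)
  sim <- simulate_genome(cfg)
  cx <- simulate_methylome(sim$genome, cfg, "stamen")$cx
  got <- classify_context(sim$genome, cx$chrom, cx$pos, cx$strand,
                          trinucleotide = TRUE)
  expect_identical(cx$context, got$context)
  expect_identical(cx$trinucleotide, got$trinucleotide)
})

test_that("planted DMR shifts pooled ML by close to the planted difference", {
  regions <- data.frame(chrom = "chr1", start = 1000L, end = 3000L)
  pd <- planted_dmr_frame(regions, "CG", "petal", "stamen", 0.8, 0.2)
  cfg <- sim_config(seed = 1, n_chroms = 1, chrom_len = 5000, n_genes = 1,
                    n_repeats = 0, planted_dmrs = pd, mean_coverage = 30)
  sim <- simulate_genome(cfg)
  a <- simulate_methylome(sim$genome, cfg, "petal")$cx
  b <- simulate_methylome(sim$genome, cfg, "stamen")$cx
  in_reg <- function(cx) {
    r <- cx[context == "CG" & pos - 1L >= 1000L & pos - 1L < 3000L]
    sum(r$count_meth) / sum(r$coverage)
  }
  expect_gte(nrow(a[context == "CG" & pos - 1L >= 1000L &
                      pos - 1L < 3000L]), 10)
  expect_lt(abs((in_reg(a) - in_reg(b)) - 0.6), 0.1)
})

test_that("the per-site truth table matches configured rates", {
  regions <- data.frame(chrom = "chr1", start = 500L, end = 1500L)
  pd <- planted_dmr_frame(regions, "CHG", "petal", "stamen", 0.9, 0.1)
  cfg <- sim_config(seed = 6, n_chroms = 1, chrom_len = 3000, n_genes = 1,
                    n_repeats = 0, planted_dmrs = pd)
  sim <- simulate_genome(cfg)
  tr <- simulate_methylome(sim$genome, cfg, "stamen")$truth
  inside <- tr$context == "CHG" & tr$pos - 1L >= 500L & tr$pos - 1L < 1500L
  expect_true(all(tr$rate[inside] == 0.1))
  expect_true(all(tr$rate[tr$context == "CHG" & !inside] == 0.4))
  expect_true(all(tr$rate[tr$context == "CG"] == 0.6))
})

test_that("expression simulation plants hypo-DMR/up-DEG coupling", {
  cfg0 <- sim_config(seed = 8, n_chroms = 1, chrom_len = 60000,
                     n_genes = 20, n_repeats = 0)
  sim <- simulate_genome(cfg0)
  g <- sim$annotation$genes
  # plant hypo-DMRs squarely inside the promoters of the first 5 genes
  pr <- methscan:::ann_promoters(sim$annotation)[gene_id %in%
                                                   g$gene_id[1:5]]
  regions <- data.frame(chrom = pr$chrom,
                        start = pmax(pr$start, pr$end - 500L),
                        end = pr$end)
  pd <- planted_dmr_frame(regions, "CG", "petal", "stamen_petaloid",
                          0.8, 0.2)
  cfg <- sim_config(seed = 8, n_chroms = 1, chrom_len = 60000,
                    n_genes = 20, n_repeats = 0, planted_dmrs = pd,
                    planted_assoc = 1)
  deg <- simulate_expression(sim$annotation, cfg,
                             comparison = c("petal", "stamen_petaloid"))
  st <- filter_degs(deg)
  expect_true(all(st[gene_id %in% pr$gene_id]$status == "up"))
  # every gene whose promoter overlaps a planted region is forced up
  # (neighbouring genes' promoters may also overlap the planted spans)
  all_pr <- methscan:::ann_promoters(sim$annotation)
  expected <- unique(unlist(lapply(seq_len(nrow(regions)), function(i)
    all_pr$gene_id[all_pr$chrom == regions$chrom[i] &
                     pmin(all_pr$end, regions$end[i]) -
                     pmax(all_pr$start, regions$start[i]) > 0])))
  expect_identical(sort(st[planted_up == TRUE]$gene_id), sort(expected))
  # with planted_assoc = 0 nothing is forced
  cfg0p <- sim_config(seed = 8, n_chroms = 1, chrom_len = 60000,
                      n_genes = 20, n_repeats = 0, planted_dmrs = pd,
                      planted_assoc = 0)
  deg0 <- simulate_expression(sim$annotation, cfg0p,
                              comparison = c("petal", "stamen_petaloid"))
  expect_true(all(!deg0$planted_up))
})

test_that("clone simulation respects rates and conversion error", {
  amp <- "ACGTACGTCCGGATCGATTACG"
  all1 <- simulate_clones(amp, 1, n_clones = 5, conversion_error = 0,
                          seed = 1)
  expect_true(all(all1$clones$clones == amp))
  all0 <- simulate_clones(amp, 0, n_clones = 5, conversion_error = 0,
                          seed = 1)
  expect_true(all(all0$clones$clones == gsub("C", "T", amp)))
  expect_error(simulate_clones("AGGT", 0.5), "no cytosine")

  # binomial spread at rate 0.5: mean methylated clones per site over seeds
  counts <- vapply(1:20, function(sd) {
    sc <- simulate_clones("AAAACAAAA", 0.5, n_clones = 10,
                          conversion_error = 0, seed = sd)
    sum(substring(sc$clones$clones, 5, 5) == "C")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 5), 1)   # 3 SE of Bin(10, .5)/sqrt(20)
})

test_that("YAML configs map onto sim_config faithfully", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 9", "n_chroms: 1", "chrom_len: 5000", "n_genes: 2",
    "n_repeats: 1", "gene_len_range: [500, 800]",
    "base_rates: {CG: 0.7, CHG: 0.3, CHH: 0.05}",
    "planted_dmrs:",
    "  - {chrom: chr1, start: 1000, end: 2000, context: CG, sample: petal, rate: 0.9}",
    "  - {chrom: chr1, start: 1000, end: 2000, context: CG, sample: stamen, rate: 0.1}"),
    f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$base_rates$petal[["CG"]], 0.7)
  expect_equal(nrow(cfg$planted_dmrs), 2L)
  # identical to the directly-constructed config
  cfg2 <- sim_config(seed = 9, n_chroms = 1, chrom_len = 5000,
                     n_genes = 2, n_repeats = 1,
                     gene_len_range = c(500L, 800L),
                     base_rates = c(CG = 0.7, CHG = 0.3, CHH = 0.05),
                     planted_dmrs = cfg$planted_dmrs)
  expect_identical(simulate_genome(cfg)$genome, simulate_genome(cfg2)$genome)
  writeLines("bogus_key: 1", f)
  expect_error(read_sim_config(f), "unknown config key")
})

test_that("simulation outputs are byte-identical across runs", {
  cfg <- sim_config(seed = 12, n_chroms = 1, chrom_len = 4000, n_genes = 2,
                    n_repeats = 2, gene_len_range = c(500L, 800L))
  sim <- simulate_genome(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cx_report(simulate_methylome(sim$genome, cfg, "petal")$cx, f1)
  write_cx_report(simulate_methylome(sim$genome, cfg, "petal")$cx, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
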