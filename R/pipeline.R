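#' Run the full simulate-and-analyse pipeline
#'
#' One-command end-to-end demonstration on generated data: simulates a
#' genome, three organ methylomes and an expression table under `config`,
#' then runs every analysis stage in dependency order (site calling ->
#' context summaries / motifs / profiles -> DMR calling -> DMR-gene ->
#' DMR-by-DEG enrichment -> clone validation) and writes all tables,
#' tracks and a JSON run manifest with per-file checksums.  Reruns with an
#' identical config are byte-identical.
#'
#' @param config A [sim_config()]; its `planted_dmrs` default to three CG
#'   DMRs between the first two samples when none are configured, so the
#'   demo exercises the differential stages.
#' @param out_dir Output directory (created; must not exist or be empty).
#' @param comparison Two sample names for the differential stages
#'   (default the first two).
#' @param dmr_args Optional list of overrides for [call_dmrs()] arguments.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         comparison = config$samples[1:2],
                         dmr_args = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)))
    stop_config("output directory exists and is not empty: %s", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf("[methscan] %s", sprintf(...)))
  if (is.null(config$planted_dmrs)) {
    # default demo truth: three CG DMRs, hypo in the second sample
    third <- config$chrom_len %/% 4L
    regions <- data.table::data.table(
      chrom = "chr1", start = third * (1:3), end = third * (1:3) + 2000L)
    config$planted_dmrs <- planted_dmr_frame(
      regions, "CG", comparison[1L], comparison[2L], 0.8, 0.2)
  }

  log_stage("simulate: genome (%d x %d bp, seed %d)", config$n_chroms,
            config$chrom_len, config$seed)
  sim <- simulate_genome(config)
  genome <- sim$genome
  ann <- sim$annotation
  chrom_lengths <- vapply(genome, nchar, integer(1))
  write_fasta(genome, file.path(out_dir, "genome.fa"))
  write_annotation_gff3(ann, file.path(out_dir, "annotation.gff3"))
  data.table::fwrite(config$planted_dmrs,
                     file.path(out_dir, "truth_planted_dmrs.tsv"),
                     sep = "\t")

  cx <- list()
  for (s in config$samples) {
    log_stage("simulate: methylome %s", s)
    mm <- simulate_methylome(genome, config, s)
    cx[[s]] <- call_methylated_sites(mm$cx, config$conversion_error)
    write_cx_report(mm$cx, file.path(out_dir, sprintf("cx_%s.tsv", s)))
    data.table::fwrite(mm$truth,
                       file.path(out_dir, sprintf("truth_rates_%s.tsv", s)),
                       sep = "\t")
  }

  log_stage("methylome: context summaries and windowed ML")
  fractions <- data.table::rbindlist(lapply(config$samples, function(s)
    cbind(sample_id = s, genome_context_fractions(cx[[s]]))))
  data.table::fwrite(fractions,
                     file.path(out_dir, "context_fractions.tsv"),
                     sep = "\t")
  for (s in config$samples) for (ctx in c("CG", "CHG", "CHH")) {
    w <- windowed_ml(cx[[s]], bin_size = 10000L, context = ctx,
                     chrom_lengths = chrom_lengths)
    write_bedgraph(w, file.path(out_dir,
                                sprintf("ml_%s_%s.bedgraph", s, ctx)))
  }
  hists <- data.table::rbindlist(lapply(config$samples, function(s)
    data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx)
      cbind(sample_id = s, context = ctx,
            ml_level_histogram(cx[[s]], ctx))))))
  data.table::fwrite(hists, file.path(out_dir, "ml_histograms.tsv"),
                     sep = "\t")

  log_stage("motifs: 9-mer preference (%s)", comparison[1L])
  mt <- build_motif_table(genome, cx[[comparison[1L]]], context = "CG")
  write_motif_pfm(mt, file.path(out_dir, "motif_pfm_CG.tsv"))
  data.table::fwrite(mt$motifs, file.path(out_dir, "motif_ml_CG.tsv"),
                     sep = "\t")

  log_stage("expression: simulate and classify")
  deg <- simulate_expression(ann, config, comparison)
  data.table::fwrite(deg, file.path(out_dir, "expression.tsv"), sep = "\t")
  classing <- classify_expression(deg,
                                  paste0("fpkm_", comparison[1L]))
  data.table::fwrite(classing, file.path(out_dir, "expression_classes.tsv"),
                     sep = "\t")

  log_stage("profiles: features and metagenes (%s)", comparison[1L])
  fml <- data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx)
    cbind(context = ctx, feature_ml(cx[[comparison[1L]]], ann, ctx))))
  data.table::fwrite(fml, file.path(out_dir, "feature_ml.tsv"), sep = "\t")
  prof <- data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx)
    cbind(context = ctx,
          metagene_profile(cx[[comparison[1L]]], ann, ctx,
                           classing = classing))))
  data.table::fwrite(prof, file.path(out_dir, "metagene_profiles.tsv"),
                     sep = "\t")
  mbe <- data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx)
    cbind(context = ctx,
          ml_by_expression(cx[[comparison[1L]]], ann, classing, ctx))))
  data.table::fwrite(mbe, file.path(out_dir, "ml_by_expression.tsv"),
                     sep = "\t")

  log_stage("dmr: %s vs %s", comparison[1L], comparison[2L])
  dmrs <- data.table::rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx)
    do.call(call_dmrs, c(list(cx[[comparison[1L]]], cx[[comparison[2L]]],
                              context = ctx,
                              chrom_lengths = chrom_lengths), dmr_args))))
  data.table::setorder(dmrs, chrom, start)
  write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
  data.table::fwrite(dmrs, file.path(out_dir, "dmrs.tsv"), sep = "\t")
  assoc <- associate_genes(dmrs, ann)
  data.table::fwrite(assoc$links, file.path(out_dir, "dmr_gene_links.tsv"),
                     sep = "\t")
  comp_dist <- dmr_compartment_distribution(dmrs, ann)
  data.table::fwrite(comp_dist,
                     file.path(out_dir, "dmr_compartments.tsv"), sep = "\t")

  log_stage("integration: DEG filter and enrichment")
  deg_status <- filter_degs(deg)
  dmr_genes <- list(
    hypo = unique(assoc$links[direction == "hypo"]$gene_id),
    hyper = unique(assoc$links[direction == "hyper"]$gene_id))
  deg_sets <- list(up = deg_status[status == "up"]$gene_id,
                   down = deg_status[status == "down"]$gene_id)
  enrich <- dmr_deg_enrichment(dmr_genes, deg_sets, ann$genes$gene_id)
  data.table::fwrite(enrich, file.path(out_dir, "dmr_deg_enrichment.tsv"),
                     sep = "\t")
  venn <- venn_counts(list(dmr = unique(assoc$links$gene_id),
                           deg = deg_status[status != "ns"]$gene_id))
  data.table::fwrite(venn, file.path(out_dir, "venn_counts.tsv"),
                     sep = "\t")

  log_stage("clones: validation amplicon")
  # amplicon from the first gene's promoter region
  g1 <- ann$genes[1L]
  pr <- ann_promoters(ann)[gene_id == g1$gene_id]
  ast <- max(pr$start, pr$end - 400L)
  amp <- substr(genome[[g1$chrom]], ast + 1L, pr$end)
  sc <- simulate_clones(amp, 0.6, n_clones = 10L,
                        conversion_error = config$conversion_error,
                        seed = sub_seed(config$seed, 30L),
                        offset = -(pr$end - ast))
  calls <- call_sites(sc$clones)
  write_lollipop_tsv(calls, file.path(out_dir, "clone_sites.tsv"))
  regsum <- region_summary(calls, min(calls$sites$rel_pos),
                           max(calls$sites$rel_pos))
  data.table::fwrite(regsum, file.path(out_dir, "clone_region_summary.tsv"),
                     sep = "\t")

  log_stage("manifest")
  files <- sort(setdiff(dir(out_dir), "manifest.json"))
  manifest <- list(
    package = "methscan",
    version = as.character(utils::packageVersion("methscan")),
    seed = config$seed,
    samples = config$samples,
    comparison = comparison,
    parameters = list(
      n_chroms = config$n_chroms, chrom_len = config$chrom_len,
      gc_content = config$gc_content, n_genes = config$n_genes,
      n_repeats = config$n_repeats, mean_coverage = config$mean_coverage,
      conversion_error = config$conversion_error,
      promoter_span = config$promoter_span,
      dmr = c(list(window = 1000, step = 100, alpha = 0.01, min_sites = 5,
                   min_cov = 4, min_ml_diff = 0.1), dmr_args)),
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = file_md5(file.path(out_dir, f)),
           bytes = file.info(file.path(out_dir, f))$size)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genome = genome, annotation = ann, cx = cx, dmrs = dmrs,
                 assoc = assoc, enrichment = enrich, deg = deg_status,
                 manifest = manifest, out_dir = out_dir))
}
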