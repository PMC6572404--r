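#' Simulation configuration
#'
#' Defines the conditions of a synthetic WGBS study: a small
#' multi-chromosome genome with genes and repeats, three "organ" samples
#' with context-dependent methylation (high CG, intermediate CHG, low CHH),
#' Poisson read coverage, bisulfite conversion error, optionally planted
#' DMRs and a planted hypo-DMR/up-regulation coupling.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_chroms,chrom_len Genome shape (default 2 x 100 kb).
#' @param gc_content GC fraction (default 0.4, a typical plant genome).
#' @param n_genes,n_repeats Total feature counts (defaults 60 / 40).
#' @param gene_len_range,repeat_len_range Feature length ranges in bp.
#' @param promoter_span Promoter length (default 2000).
#' @param samples Sample names (default the three floral organs).
#' @param base_rates Named per-context methylation rates, either one vector
#'   shared by all samples (default CG 0.6, CHG 0.4, CHH 0.08) or a list
#'   keyed by sample.
#' @param mean_coverage Poisson mean read depth (default 30).
#' @param conversion_error Probability an unmethylated C reads as C
#'   (default 0.005).
#' @param planted_dmrs Optional data.frame of per-sample rate overrides
#'   with columns `chrom`, `start`, `end` (0-based half-open), `context`,
#'   `sample`, `rate`; see [planted_dmr_frame()].
#' @param planted_assoc Probability that a gene whose promoter overlaps a
#'   planted hypo-DMR is forced up-regulated (default 0.8).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_len = 100000L,
                       gc_content = 0.4, n_genes = 60L, n_repeats = 40L,
                       gene_len_range = c(800L, 3000L),
                       repeat_len_range = c(200L, 1000L),
                       promoter_span = 2000L,
                       samples = c("petal", "stamen_petaloid", "stamen"),
                       base_rates = c(CG = 0.6, CHG = 0.4, CHH = 0.08),
                       mean_coverage = 30, conversion_error = 0.005,
                       planted_dmrs = NULL, planted_assoc = 0.8) {
  if (!is_count(seed)) stop_config("seed must be a non-negative integer")
  if (gc_content < 0 || gc_content > 1)
    stop_config("gc_content must be in [0, 1]")
  if (conversion_error < 0 || conversion_error >= 1)
    stop_config("conversion_error must be in [0, 1)")
  if (planted_assoc < 0 || planted_assoc > 1)
    stop_config("planted_assoc must be in [0, 1]")
  rates <- if (is.list(base_rates)) base_rates else
    stats::setNames(rep(list(base_rates), length(samples)), samples)
  for (r in rates) {
    if (!all(c("CG", "CHG", "CHH") %in% names(r)))
      stop_config("base_rates needs CG, CHG and CHH entries")
    if (any(r < 0 | r > 1)) stop_config("base_rates must be in [0, 1]")
  }
  if (!is.null(planted_dmrs)) {
    planted_dmrs <- data.table::as.data.table(planted_dmrs)
    need <- c("chrom", "start", "end", "context", "sample", "rate")
    if (!all(need %in% names(planted_dmrs)))
      stop_config("planted_dmrs needs columns: %s",
                  paste(need, collapse = ", "))
    if (any(planted_dmrs$rate < 0 | planted_dmrs$rate > 1))
      stop_config("planted rates must be in [0, 1]")
    if (!all(planted_dmrs$sample %in% samples))
      stop_config("planted_dmrs names unknown sample")
    key <- planted_dmrs[, .(n_samples = data.table::uniqueN(sample),
                            n_rates = data.table::uniqueN(rate)),
                        by = .(chrom, start, end, context)]
    if (any(key$n_samples >= 2L & key$n_rates < 2L))
      stop_config("planted DMRs must differ in rate between samples")
  }
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_len = as.integer(chrom_len),
                 gc_content = gc_content, n_genes = as.integer(n_genes),
                 n_repeats = as.integer(n_repeats),
                 gene_len_range = as.integer(gene_len_range),
                 repeat_len_range = as.integer(repeat_len_range),
                 promoter_span = as.integer(promoter_span),
                 samples = samples, base_rates = rates,
                 mean_coverage = mean_coverage,
                 conversion_error = conversion_error,
                 planted_dmrs = planted_dmrs,
                 planted_assoc = planted_assoc),
            class = "sim_config")
}

#' Build a planted-DMR rate-override table for two samples
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param context Context of the planted difference (default "CG").
#' @param sample_a,sample_b The two samples.
#' @param rate_a,rate_b Their methylation rates inside the regions.
#' @return data.table usable as `planted_dmrs` in [sim_config()].
#' @export
planted_dmr_frame <- function(regions, context = "CG", sample_a, sample_b,
                              rate_a, rate_b) {
  regions <- data.table::as.data.table(regions)
  data.table::rbindlist(list(
    regions[, .(chrom, start, end, context = context, sample = sample_a,
                rate = rate_a)],
    regions[, .(chrom, start, end, context = context, sample = sample_b,
                rate = rate_b)]))
}

#' Read a simulation configuration from a YAML file
#'
#' Flat keys mirror the arguments of [sim_config()]; `planted_dmrs` may be
#' given as a list of records with the usual columns.
#'
#' @param path Path to a YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$base_rates)) y$base_rates <- unlist(y$base_rates)
  if (!is.null(y$planted_dmrs))
    y$planted_dmrs <- data.table::rbindlist(y$planted_dmrs)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop_config("unknown config key: %s", unknown[1L])
  do.call(sim_config, y)
}

# derive an integer sub-seed; stays within 32-bit range
sub_seed <- function(seed, k) as.integer((seed + k * 1000003) %% 2147483629)

#' Simulate a genome with gene/repeat annotation
#'
#' Random sequence at the configured GC content; genes are placed without
#' overlap (1-5 exons each, alternating with introns of at least 50 bp);
#' repeats fall in intergenic space and may overlap one another.
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector) and `annotation`
#'   (an [annotation_set()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  genome <- vapply(chrom_names, function(cn) {
    paste(sample(names(probs), config$chrom_len, replace = TRUE,
                 prob = probs), collapse = "")
  }, character(1))
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1L)))
  genes <- list(); exons <- list()
  for (ci in seq_along(chrom_names)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    lens <- sample(config$gene_len_range[1L]:config$gene_len_range[2L], k,
                   replace = TRUE)
    if (sum(lens) > 0.7 * config$chrom_len)
      stop_config("cannot place %d genes of total length %d on a %d bp chromosome",
                  k, sum(lens), config$chrom_len)
    free <- config$chrom_len - sum(lens)
    cuts <- sort(runif(k, 0, free))
    gaps <- floor(diff(c(0, cuts)))
    starts <- cumsum(gaps) + cumsum(c(0L, head(lens, -1L)))
    gid <- sprintf("gene_%s_%02d", chrom_names[ci], seq_len(k))
    strand <- sample(c("+", "-"), k, replace = TRUE)
    genes[[ci]] <- data.table::data.table(
      gene_id = gid, chrom = chrom_names[ci], strand = strand,
      start = as.integer(starts), end = as.integer(starts + lens))
    exons[[ci]] <- data.table::rbindlist(lapply(seq_len(k), function(j) {
      L <- lens[j]
      n_ex <- sample(1:5, 1L)
      n_ex <- min(n_ex, (L %/% 50L + 1L) %/% 2L)
      n_ex <- max(n_ex, 1L)
      nseg <- 2L * n_ex - 1L
      if (nseg == 1L) {
        seg <- L
      } else {
        u <- runif(nseg)
        seg <- floor(u / sum(u) * (L - 50L * nseg)) + 50L
        seg[nseg] <- L - sum(seg[-nseg])
      }
      bnd <- cumsum(c(0L, seg))
      ei <- seq(1L, nseg, by = 2L)    # odd segments are exons
      data.table::data.table(
        gene_id = gid[j], chrom = chrom_names[ci], strand = strand[j],
        start = as.integer(starts[j] + bnd[ei]),
        end = as.integer(starts[j] + bnd[ei + 1L]))
    }))
  }
  genes <- data.table::rbindlist(genes)
  exons <- data.table::rbindlist(exons)
  # repeats: rejection-sampled into intergenic space
  repeats <- list()
  tries <- 0L
  while (length(repeats) < config$n_repeats && tries < 50L * config$n_repeats) {
    tries <- tries + 1L
    cn <- sample(chrom_names, 1L)
    len <- sample(config$repeat_len_range[1L]:config$repeat_len_range[2L],
                  1L)
    if (config$chrom_len <= len) next
    st <- sample.int(config$chrom_len - len, 1L) - 1L
    g <- genes[chrom == cn]
    if (nrow(g) && any(overlap_bp(st, st + len, g$start, g$end) > 0L)) next
    repeats[[length(repeats) + 1L]] <- data.table::data.table(
      chrom = cn, start = st, end = st + len)
  }
  repeats <- if (length(repeats)) data.table::rbindlist(repeats) else NULL
  list(genome = genome,
       annotation = annotation_set(genes, exons, repeats,
                                   config$promoter_span))
}

# enumerate all cytosines of a genome on both strands with context and
# trinucleotide, using a character-array scan (deliberately a different
# mechanism from classify_context so the two can cross-check each other)
scan_cytosines <- function(genome) {
  out <- lapply(names(genome), function(cn) {
    ch <- strsplit(genome[[cn]], "", fixed = TRUE)[[1]]
    n <- length(ch)
    ctx_of <- function(b1, b2) {
      ok1 <- !is.na(b1) & b1 %in% c("A", "C", "G", "T")
      ok2 <- !is.na(b2) & b2 %in% c("A", "C", "G", "T")
      ifelse(ok1 & b1 == "G", "CG",
             ifelse(ok1 & ok2 & b2 == "G", "CHG",
                    ifelse(ok1 & ok2, "CHH", "Unknown")))
    }
    pad <- function(b) ifelse(is.na(b) | !b %in% c("A", "C", "G", "T"),
                              "N", b)
    pp <- which(ch == "C")
    p1 <- ifelse(pp + 1L <= n, ch[pmin(pp + 1L, n)], NA)
    p2 <- ifelse(pp + 2L <= n, ch[pmin(pp + 2L, n)], NA)
    mp <- which(ch == "G")
    m1 <- comp_base(ifelse(mp - 1L >= 1L, ch[pmax(mp - 1L, 1L)], NA))
    m2 <- comp_base(ifelse(mp - 2L >= 1L, ch[pmax(mp - 2L, 1L)], NA))
    data.table::data.table(
      chrom = cn,
      pos = c(pp, mp),
      strand = rep(c("+", "-"), c(length(pp), length(mp))),
      context = c(ctx_of(p1, p2), ctx_of(m1, m2)),
      trinucleotide = c(paste0("C", pad(p1), pad(p2)),
                        paste0("C", pad(m1), pad(m2))))
  })
  dt <- data.table::rbindlist(out)
  data.table::setorder(dt, chrom, pos, strand)
  dt
}

#' Simulate one sample's per-cytosine methylation counts
#'
#' Every cytosine on both strands gets a true methylation rate (the
#' sample's base rate for its context, overridden inside planted DMR
#' regions), Poisson coverage, and a binomial methylated count at the
#' conversion-error-adjusted rate \eqn{r + (1 - r) e} where \eqn{e} is the
#' conversion error.
#'
#' @param genome Named character vector from [simulate_genome()].
#' @param config A [sim_config()].
#' @param sample_id One of `config$samples`.
#' @return List with `cx` (cytosine table) and `truth` (per-site true
#'   rate table).
#' @export
simulate_methylome <- function(genome, config, sample_id) {
  stopifnot(inherits(config, "sim_config"))
  k <- match(sample_id, config$samples)
  if (is.na(k)) stop_config("unknown sample '%s'", sample_id)
  set.seed(sub_seed(config$seed, 10L + k))
  sites <- scan_cytosines(genome)
  rates <- config$base_rates[[sample_id]]
  r <- rep(0, nrow(sites))
  for (ctx in c("CG", "CHG", "CHH"))
    r[sites$context == ctx] <- rates[[ctx]]
  pd <- config$planted_dmrs
  if (!is.null(pd)) {
    pd <- pd[sample == sample_id]
    for (i in seq_len(nrow(pd))) {
      sel <- sites$chrom == pd$chrom[i] & sites$pos - 1L >= pd$start[i] &
        sites$pos - 1L < pd$end[i] & sites$context == pd$context[i]
      r[sel] <- pd$rate[i]
    }
  }
  cov <- stats::rpois(nrow(sites), config$mean_coverage)
  p_eff <- r + (1 - r) * config$conversion_error
  meth <- stats::rbinom(nrow(sites), cov, p_eff)
  cx <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    count_meth = meth, count_unmeth = cov - meth,
    context = sites$context, trinucleotide = sites$trinucleotide)
  truth <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    context = sites$context, rate = r)
  list(cx = cx_table(cx), truth = truth)
}

#' Simulate a differential-expression table with planted associations
#'
#' Genes whose promoter overlaps a planted hypo-DMR (rate lower in
#' `comparison[2]` than in `comparison[1]`) are up-regulated (fold change
#' in \[2, 8\], FDR < 0.05) with probability `planted_assoc`; all other
#' genes draw null fold changes and uniform FDRs.
#'
#' @param ann An [annotation_set()].
#' @param config A [sim_config()] (supplies `planted_dmrs`,
#'   `planted_assoc`, seed and sample names).
#' @param comparison Character vector of two sample names (A, B); fold
#'   change is B over A.  Defaults to the first two configured samples.
#' @return data.table with `gene_id`, per-sample `fpkm_*` columns,
#'   `fold_change`, `fdr` and the truth column `planted_up`.
#' @export
simulate_expression <- function(ann, config,
                                comparison = config$samples[1:2]) {
  stopifnot(inherits(ann, "annotation_set"),
            inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 20L))
  g <- ann$genes
  hypo_genes <- character()
  pd <- config$planted_dmrs
  if (!is.null(pd) && nrow(pd)) {
    wide <- data.table::dcast(pd, chrom + start + end + context ~ sample,
                              value.var = "rate")
    a <- comparison[1L]; b <- comparison[2L]
    if (all(c(a, b) %in% names(wide))) {
      hypo_reg <- wide[wide[[b]] < wide[[a]]]
      if (nrow(hypo_reg)) {
        pr <- ann_promoters(ann)
        hit <- unlist(lapply(seq_len(nrow(hypo_reg)), function(i) {
          sel <- pr$chrom == hypo_reg$chrom[i] &
            overlap_bp(hypo_reg$start[i], hypo_reg$end[i],
                       pr$start, pr$end) > 0L
          pr$gene_id[sel]
        }))
        hypo_genes <- unique(hit)
      }
    }
  }
  n <- nrow(g)
  base <- stats::rlnorm(n, meanlog = 1, sdlog = 1.2)
  fpkm <- lapply(config$samples, function(s)
    base * 2^stats::rnorm(n, 0, 0.25))
  names(fpkm) <- paste0("fpkm_", config$samples)
  planted <- g$gene_id %in% hypo_genes &
    stats::runif(n) < config$planted_assoc
  fold_change <- 2^stats::rnorm(n, 0, 0.3)
  fdr <- stats::runif(n)
  fold_change[planted] <- 2^stats::runif(sum(planted), 1, 3)
  fdr[planted] <- stats::runif(sum(planted), 0, 0.049)
  out <- data.table::as.data.table(c(list(gene_id = g$gene_id), fpkm))
  bcol <- paste0("fpkm_", comparison[2L])
  acol <- paste0("fpkm_", comparison[1L])
  data.table::set(out, j = bcol, value = out[[acol]] * fold_change)
  data.table::set(out, j = "fold_change", value = fold_change)
  data.table::set(out, j = "fdr", value = fdr)
  data.table::set(out, j = "planted_up", value = planted)
  out[]
}

#' Simulate clone (Sanger) bisulfite sequences from an amplicon
#'
#' Each clone copies the amplicon; every cytosine is methylated with its
#' per-site rate (then reads C) or unmethylated (then reads T, except that
#' conversion fails with probability `conversion_error` and leaves a C).
#'
#' @param amplicon Reference sequence (must contain a cytosine).
#' @param rates Per-site methylation rate: a single value for all
#'   cytosines, or a vector with one entry per cytosine in amplicon order.
#' @param n_clones Number of clones (default 10).
#' @param conversion_error Conversion-failure probability (default 0.005).
#' @param seed RNG seed.
#' @param offset Promoter-relative offset of the amplicon (see
#'   [clone_set()]).
#' @return List with `clones` (a [clone_set()]) and `truth` (data.table
#'   `pos`, `rate`).
#' @export
simulate_clones <- function(amplicon, rates, n_clones = 10L,
                            conversion_error = 0.005, seed = 1L,
                            offset = NULL) {
  amplicon <- toupper(amplicon)
  cpos <- which(strsplit(amplicon, "", fixed = TRUE)[[1]] == "C")
  if (length(cpos) == 0L) stop_config("amplicon contains no cytosine")
  if (length(rates) == 1L) rates <- rep(rates, length(cpos))
  if (length(rates) != length(cpos))
    stop_config("need one rate per cytosine (%d), got %d", length(cpos),
                length(rates))
  if (any(rates < 0 | rates > 1)) stop_config("rates must be in [0, 1]")
  set.seed(as.integer(seed %% 2147483629))
  clones <- vapply(seq_len(n_clones), function(i) {
    ch <- strsplit(amplicon, "", fixed = TRUE)[[1]]
    meth <- stats::runif(length(cpos)) < rates
    fail <- stats::runif(length(cpos)) < conversion_error
    ch[cpos] <- ifelse(meth | fail, "C", "T")
    paste(ch, collapse = "")
  }, character(1))
  names(clones) <- sprintf("clone_%02d", seq_len(n_clones))
  list(clones = clone_set(amplicon, clones, offset),
       truth = data.table::data.table(pos = cpos, rate = rates))
}
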