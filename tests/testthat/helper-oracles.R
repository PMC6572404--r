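# Independent oracles used to cross-check the implementation.
# These deliberately use different mechanisms (regex scans, direct
# combinatorial sums, naive DP) than the package code.

# random genome fixture
random_genome <- function(n_chroms = 1L, len = 1000L, seed = 1L,
                          gc = 0.4) {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(seq_len(n_chroms), function(i)
    paste(sample(names(probs), len, TRUE, probs), collapse = ""),
    character(1))
  names(out) <- paste0("chr", seq_len(n_chroms))
  out
}

rc_oracle <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# brute-force double-strand regex scan of cytosine contexts.
# '+' strand: lookahead regex on the forward sequence; '-' strand: the same
# regexes on the reverse complement, with positions mapped back.
oracle_context_scan <- function(genome) {
  pats <- c(CG = "(?=CG)", CHG = "(?=C[ACT]G)", CHH = "(?=C[ACT][ACT])")
  one_strand <- function(s) {
    hits <- lapply(pats, function(p) {
      m <- gregexpr(p, s, perl = TRUE)[[1]]
      if (m[1] == -1) integer() else as.integer(m)
    })
    data.table::rbindlist(lapply(names(hits), function(ctx)
      data.table::data.table(pos = hits[[ctx]], context = ctx)))
  }
  out <- lapply(names(genome), function(cn) {
    s <- genome[[cn]]
    len <- nchar(s)
    plus <- one_strand(s)
    plus[, `:=`(chrom = cn, strand = "+")]
    rcs <- rc_oracle(s)
    minus <- one_strand(rcs)
    minus[, `:=`(pos = len - pos + 1L, chrom = cn, strand = "-")]
    # any cytosine not matched by the three regexes is Unknown (contig
    # edge); enumerate all Cs per strand to add them
    allc_p <- as.integer(gregexpr("C", s, fixed = TRUE)[[1]])
    if (length(allc_p) && allc_p[1] == -1L) allc_p <- integer()
    allc_m <- as.integer(gregexpr("C", rcs, fixed = TRUE)[[1]])
    if (length(allc_m) && allc_m[1] == -1L) allc_m <- integer()
    allc_m <- len - allc_m + 1L
    unk_p <- setdiff(allc_p, plus$pos)
    unk_m <- setdiff(allc_m, minus$pos)
    data.table::rbindlist(list(
      plus, minus,
      data.table::data.table(pos = unk_p, context = "Unknown",
                             chrom = cn, strand = "+"),
      data.table::data.table(pos = unk_m, context = "Unknown",
                             chrom = cn, strand = "-")))
  })
  out <- data.table::rbindlist(out)
  data.table::setorder(out, chrom, pos, strand)
  out[, .(chrom, pos, strand, context)]
}

# direct combinatorial two-sided Fisher p for one 2x2 table, via choose()
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  pobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(prob[prob <= pobs * (1 + 1e-7)]))
}

# minimal affine-gap global aligner (Gotoh) in plain R, bisulfite-aware,
# same tie-break order as the package aligner; for short oracle cases only
oracle_align <- function(ref, query, match = 2, mismatch = -2,
                         gap_open = -5, gap_extend = -1) {
  r <- strsplit(ref, "")[[1]]; q <- strsplit(query, "")[[1]]
  n <- length(r); m <- length(q)
  NEG <- -Inf
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(NA_integer_, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) { X[i, 1] <- gap_open + (i - 2) * gap_extend
    tX[i, 1] <- if (i == 2) 0L else 1L }
  for (j in 2:(m + 1)) { Y[1, j] <- gap_open + (j - 2) * gap_extend
    tY[1, j] <- if (j == 2) 0L else 2L }
  sc <- function(a, b) if (a == b || (a == "C" && b == "T")) match else
    mismatch
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    w <- which.max(cand)
    M[i, j] <- cand[w] + sc(r[i - 1], q[j - 1]); tM[i, j] <- w - 1L
    cand <- c(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
              Y[i - 1, j] + gap_open)
    w <- which.max(cand)
    X[i, j] <- cand[w]; tX[i, j] <- w - 1L
    cand <- c(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
              Y[i, j - 1] + gap_extend)
    w <- which.max(cand)
    Y[i, j] <- cand[w]; tY[i, j] <- w - 1L
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(fin) - 1L
  score <- fin[state + 1L]
  map <- integer(n)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == 0L) {
      map[i] <- j
      state <- tM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (state == 1L) {
      state <- tX[i + 1, j + 1]; i <- i - 1
    } else {
      state <- tY[i + 1, j + 1]; j <- j - 1
    }
  }
  list(ref_to_query = map, score = score)
}

# a tiny deterministic cytosine table builder
make_cx <- function(chrom, pos, strand, meth, unmeth,
                    context = "CG", tri = "CGA") {
  cx_table(data.frame(chrom = chrom, pos = pos, strand = strand,
                      count_meth = meth, count_unmeth = unmeth,
                      context = context, trinucleotide = tri))
}

# small annotation fixture: one chromosome, configurable genes
make_ann <- function(genes, exons = NULL, repeats = NULL,
                     promoter_span = 2000L) {
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        strand = genes$strand, start = genes$start,
                        end = genes$end)
  annotation_set(genes, exons, repeats, promoter_span)
}
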