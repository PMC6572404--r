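#' Bundle an amplicon reference with clone sequences
#'
#' @param amplicon Reference (pre-bisulfite) amplicon sequence.
#' @param clones Character vector of clone sequences (named or not).
#' @param offset Promoter-relative coordinate of the first amplicon base
#'   (e.g. -1648).  Convention: -1 is the base immediately upstream of the
#'   TSS and there is no position 0.  `NULL` keeps 1-based amplicon
#'   coordinates.
#' @return Object of class `clone_set`.
#' @export
clone_set <- function(amplicon, clones, offset = NULL) {
  amplicon <- toupper(amplicon)
  if (!grepl("C", amplicon, fixed = TRUE))
    stop_config("amplicon contains no cytosine")
  clones <- toupper(clones)
  if (length(clones) == 0L) stop_config("no clone sequences given")
  if (is.null(names(clones)))
    names(clones) <- paste0("clone_", seq_along(clones))
  structure(list(amplicon = amplicon, clones = clones,
                 offset = if (is.null(offset)) NULL else as.integer(offset)),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("clone_set: %d bp amplicon, %d clones%s\n",
              nchar(x$amplicon), length(x$clones),
              if (is.null(x$offset)) "" else
                sprintf(", offset %d", x$offset)))
  invisible(x)
}

# promoter-relative coordinate of 1-based amplicon positions
amplicon_rel_pos <- function(pos, offset) {
  if (is.null(offset)) return(pos)
  raw <- offset + pos - 1L
  ifelse(offset < 0L & raw >= 0L, raw + 1L, raw)
}

#' Align one clone to the amplicon (bisulfite-aware global alignment)
#'
#' Affine-gap global alignment where reference C matched to clone T counts
#' as a match (bisulfite conversion reads unmethylated C as T); other
#' substitutions score as mismatches.  Tie-breaking is deterministic
#' (diagonal, then up, then left).  Clones whose alignment identity falls
#' below `min_identity` are rejected.
#'
#' @param amplicon Reference sequence.
#' @param clone Clone sequence.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param min_identity Identity floor in \[0, 1\] (default 0.7).
#' @return List with `ref_to_clone` (1-based clone index per amplicon base,
#'   0 when deleted), `score`, `identity`, `accepted`.
#' @export
align_clone <- function(amplicon, clone, match = 2, mismatch = -2,
                        gap_open = -5, gap_extend = -1,
                        min_identity = 0.7) {
  if (!nzchar(amplicon) || !nzchar(clone))
    stop_config("sequences must be non-empty")
  al <- .align_bisulfite(toupper(amplicon), toupper(clone), match, mismatch,
                         gap_open, gap_extend)
  identity <- al$n_match / al$n_cols
  list(ref_to_clone = al$ref_to_query, score = al$score,
       identity = identity, accepted = identity >= min_identity)
}

#' Call per-site clone methylation over an amplicon
#'
#' Each clone is aligned to the amplicon; at every amplicon cytosine the
#' aligned clone bases are tallied: C = methylated, T = unmethylated
#' (converted), anything else (mutation, gap) is excluded from the
#' denominator.  Percent methylation is `100 * C / (C + T)`.  Context is
#' classified from the amplicon sequence.
#'
#' @param cs A [clone_set()].
#' @param min_identity Alignment identity floor; clones below it are
#'   reported in `rejected` and excluded.
#' @return List with `sites` (data.table: `pos`, `rel_pos`, `context`,
#'   `n_C`, `n_T`, `n_other`, `percent`, `uncalled`), `calls` (site x clone
#'   character matrix) and `rejected` (clone names).
#' @export
call_sites <- function(cs, min_identity = 0.7) {
  stopifnot(inherits(cs, "clone_set"))
  amp <- cs$amplicon
  cpos <- which(strsplit(amp, "", fixed = TRUE)[[1]] == "C")
  genome <- c(amplicon = amp)
  ctx <- classify_context(genome, "amplicon", cpos, "+")
  calls <- matrix(NA_character_, nrow = length(cpos),
                  ncol = length(cs$clones),
                  dimnames = list(NULL, names(cs$clones)))
  rejected <- character()
  for (cn in names(cs$clones)) {
    al <- align_clone(amp, cs$clones[[cn]], min_identity = min_identity)
    if (!al$accepted) {
      rejected <- c(rejected, cn)
      next
    }
    qi <- al$ref_to_clone[cpos]
    calls[, cn] <- ifelse(qi > 0L,
                          substring(cs$clones[[cn]], qi, qi), "-")
  }
  keep <- setdiff(colnames(calls), rejected)
  cm <- calls[, keep, drop = FALSE]
  n_C <- rowSums(cm == "C", na.rm = TRUE)
  n_T <- rowSums(cm == "T", na.rm = TRUE)
  n_other <- rowSums(!is.na(cm) & cm != "C" & cm != "T")
  sites <- data.table::data.table(
    pos = cpos,
    rel_pos = amplicon_rel_pos(cpos, cs$offset),
    context = ctx, n_C = as.integer(n_C), n_T = as.integer(n_T),
    n_other = as.integer(n_other),
    percent = ifelse(n_C + n_T > 0, 100 * n_C / (n_C + n_T), NA_real_),
    uncalled = n_C + n_T == 0L)
  list(sites = sites, calls = calls, rejected = rejected)
}

#' Per-context percent methylation over a promoter-relative region
#'
#' Pools clone calls over amplicon cytosines inside `[from, to]`
#' (promoter-relative when the clone set has an offset): percent is
#' `100 * sum(C) / sum(C + T)` per context.
#'
#' @param site_calls Output of [call_sites()].
#' @param from,to Region bounds (inclusive, same coordinate system as
#'   `rel_pos`).
#' @return data.table with `context`, `n_sites`, `n_C`, `n_T`, `percent`
#'   (NA for contexts without called sites in the region).
#' @export
region_summary <- function(site_calls, from, to) {
  s <- site_calls$sites
  if (from > to) stop_config("region: need from <= to")
  if (to < min(s$rel_pos) || from > max(s$rel_pos))
    stop_config("region [%s, %s] lies outside the amplicon", from, to)
  r <- s[rel_pos >= from & rel_pos <= to]
  out <- r[, .(n_sites = .N, n_C = sum(n_C), n_T = sum(n_T)),
           by = context]
  all_ctx <- data.table::data.table(context = c("CG", "CHG", "CHH"))
  out <- merge(all_ctx, out, by = "context", all.x = TRUE)
  for (cc in c("n_sites", "n_C", "n_T"))
    data.table::set(out, which(is.na(out[[cc]])), cc, 0L)
  out[, percent := ifelse(n_C + n_T > 0, 100 * n_C / (n_C + n_T),
                          NA_real_)]
  out[]
}

#' Bisulfite conversion efficiency from control sites
#'
#' `100 * sum(T) / sum(C + T)` over sites of the designated control
#' contexts (default non-CG), which are presumed unmethylated: residual C
#' reads there reflect conversion failure.
#'
#' @param site_calls Output of [call_sites()].
#' @param control_contexts Contexts treated as unmethylated controls
#'   (default CHG and CHH).
#' @return Percent efficiency, or `NA` when no control site has calls.
#' @export
conversion_efficiency <- function(site_calls,
                                  control_contexts = c("CHG", "CHH")) {
  s <- site_calls$sites[context %in% control_contexts]
  tot <- sum(s$n_C) + sum(s$n_T)
  if (tot == 0L) return(NA_real_)
  100 * sum(s$n_T) / tot
}

#' Write a per-site lollipop table for clone bisulfite results
#'
#' @param site_calls Output of [call_sites()].
#' @param path Output path.
#' @export
write_lollipop_tsv <- function(site_calls, path) {
  s <- data.table::copy(site_calls$sites)
  cm <- site_calls$calls
  s[, calls := apply(cm, 1L, function(r)
    paste(ifelse(is.na(r), ".", r), collapse = ""))]
  data.table::fwrite(s, path, sep = "\t")
  invisible(path)
}
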