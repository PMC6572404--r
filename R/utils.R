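# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# complement of a vector of single bases (IUPAC beyond ACGT -> N)
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# reverse-complement character sequences (vectorised, pure character)
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# check a genome object: named character vector of A/C/G/T/N... sequences
check_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)) ||
      anyDuplicated(names(genome)))
    stop_config("genome must be a named character vector with unique names")
  invisible(genome)
}

# md5 of a file, as character
file_md5 <- function(path) unname(tools::md5sum(path))
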