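# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a fixed, local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded simulation functions never leak global state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split equal-length sequences into a character matrix (reads x positions).
seq_to_matrix <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(character(0), nrow = 0, ncol = 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length", call. = FALSE)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

matrix_to_seq <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  apply(m, 1L, paste, collapse = "")
}

# Phred+33 string <-> integer quality conversions.
qual_to_int <- function(q) {
  lapply(q, function(s) if (nchar(s) == 0L) integer(0) else utf8ToInt(s) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(v) if (length(v) == 0L) "" else intToUtf8(v + 33L),
         character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
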