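# Independent brute-force oracles used to check implementation operations.
# These deliberately re-derive results by enumeration/naive algorithms and
# share no code with the package internals they verify.

# Brute-force 3'-quality trimming: evaluate the running-sum score of every
# possible removed suffix and pick the maximum (ties -> shortest removal).
oracle_trim_keep_length <- function(quals, threshold) {
  L <- length(quals)
  scores <- vapply(0:L, function(nrem) {
    if (nrem == 0L) 0 else sum(threshold - quals[(L - nrem + 1L):L])
  }, numeric(1))
  L - (which.max(scores) - 1L)  # which.max: first (shortest removal) at ties
}

# Exact coupon-collector full-coverage probability by inclusion-exclusion.
oracle_full_coverage_prob <- function(M, n) {
  j <- 0:M
  sum((-1)^j * choose(M, j) * ((M - j) / M)^n)
}

# Naive O(n^3) agglomerative clustering with complete linkage, returning the
# cophenetic distance matrix.
oracle_complete_linkage_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1L]) best <- c(h, i, j)
      }
    }
    i <- best[2L]; j <- best[3L]
    coph[clusters[[i]], clusters[[j]]] <- best[1L]
    coph[clusters[[j]], clusters[[i]]] <- best[1L]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny all-thymine reference with the start-codon anchor near the 3' end, so
# "U-75A"-style labels can be asserted directly.
make_poly_t_reference <- function() {
  s <- strrep("T", 158)
  substr(s, 130, 130) <- "A"   # A of the start codon at 0-based 129
  substr(s, 132, 132) <- "G"
  reference_amplicon(s, mutated_region = c(24, 133), aug_index = 129)
}

call_reads_nmut <- function(seqs, ref) {
  sortseqmap:::call_mutations_batch(seqs, ref)$n_mut
}

# Random valid reference of length L (seeded by the caller).
make_random_reference <- function(L, aug_index = NULL) {
  reference_amplicon(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = ""),
                     aug_index = aug_index)
}
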