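# Mutation calling and the single-mutation count matrix: reads that survived
# the exact-length filter are compared position by position against the
# reference (the amplicon design guarantees collinearity, so no alignment is
# needed), classified by mutation count, and reads carrying exactly one
# substitution populate the 3L x samples count matrix.

#' Call substitutions in a length-matched read
#'
#' @param seq A single read sequence of exactly the reference length.
#' @param ref A `reference_amplicon`.
#' @return Data frame of mismatching positions (`position`, `ref_base`,
#'   `alt_base`, and `label` when an anchor is set), ordered by position.
#' @export
call_mutations <- function(seq, ref) {
  stopifnot(inherits(ref, "reference_amplicon"))
  if (nchar(seq) != ref$length) {
    stop("read length (", nchar(seq), ") does not match the reference (",
         ref$length, "); the exact-length filter must run first",
         call. = FALSE)
  }
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  pos <- which(s != ref$chars) - 1L
  out <- data.frame(position = pos, ref_base = ref$chars[pos + 1L],
                    alt_base = s[pos + 1L], stringsAsFactors = FALSE)
  if (!is.null(ref$aug_index) && nrow(out) > 0L) {
    out$label <- format_label(ref, out$position, out$alt_base)
  }
  out
}

# Vectorized calling over many reads: returns a flat data frame
# (read_index, position, alt_base) plus per-read mutation counts.
call_mutations_batch <- function(seqs, ref) {
  n <- length(seqs)
  if (n == 0L) {
    return(list(calls = data.frame(read_index = integer(0),
                                   position = integer(0),
                                   alt_base = character(0)),
                n_mut = integer(0)))
  }
  if (any(nchar(seqs) != ref$length)) {
    stop("all reads must match the reference length", call. = FALSE)
  }
  m <- seq_to_matrix(seqs)
  refm <- matrix(ref$chars, nrow = n, ncol = ref$length, byrow = TRUE)
  mis <- m != refm
  n_mut <- as.integer(rowSums(mis))
  idx <- which(mis, arr.ind = TRUE)
  calls <- data.frame(read_index = idx[, 1L], position = idx[, 2L] - 1L,
                      alt_base = m[idx], stringsAsFactors = FALSE)
  calls <- calls[order(calls$read_index, calls$position), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, n_mut = n_mut)
}

#' Histogram of per-read mutation counts
#'
#' @param n_mut Integer vector of mutation counts per read (one entry per
#'   length-filtered read), or a `read_set` plus `ref`.
#' @param ref Required when `n_mut` is a `read_set`.
#' @return List with `counts` and `fractions` over the classes
#'   `0, 1, 2, 3, 4+`.
#' @export
mutation_count_histogram <- function(n_mut, ref = NULL) {
  if (inherits(n_mut, "read_set")) {
    stopifnot(!is.null(ref))
    n_mut <- call_mutations_batch(n_mut$seq, ref)$n_mut
  }
  cls <- cut(n_mut, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf),
             labels = c("0", "1", "2", "3", "4+"))
  counts <- table(cls)
  list(counts = as.integer(counts),
       fractions = if (length(n_mut) > 0L)
         as.numeric(counts) / length(n_mut) else rep(NA_real_, 5L),
       classes = c("0", "1", "2", "3", "4+"))
}

new_mutation_count_matrix <- function(counts, mutations, samples,
                                      aux_multi = NULL, histograms = NULL,
                                      mutated_region = NULL) {
  structure(list(counts = counts, mutations = mutations, samples = samples,
                 aux_multi = aux_multi, histograms = histograms,
                 mutated_region = mutated_region),
            class = "mutation_count_matrix")
}

#' @export
print.mutation_count_matrix <- function(x, ...) {
  cat("mutation_count_matrix:", nrow(x$counts), "mutations x",
      ncol(x$counts), "samples;", sum(x$counts),
      "single-mutation reads total\n")
  invisible(x)
}

#' Build the single-mutation count matrix
#'
#' Rows are the full enumeration of 3L single substitutions (see
#' [enumerate_mutations()]); a cell holds the number of reads in that sample
#' carrying exactly that mutation and no other. Reads with zero or multiple
#' mutations contribute nothing to the matrix; multi-mutation reads are
#' retained in an auxiliary per-sample table for later use.
#'
#' @param sample_reads Named list (by sample id) of `read_set`s of
#'   length-filtered reads, or of character vectors of sequences.
#' @param ref A `reference_amplicon`.
#' @param samples Optional sample-metadata data frame with a `sample_id`
#'   column matching `names(sample_reads)`.
#' @return A `mutation_count_matrix` with elements `counts` (integer matrix),
#'   `mutations`, `samples`, `aux_multi` (multi-mutation reads), and
#'   `histograms` (per-sample mutation-count histograms).
#' @export
build_count_matrix <- function(sample_reads, ref, samples = NULL) {
  stopifnot(is.list(sample_reads), length(sample_reads) > 0L,
            !is.null(names(sample_reads)))
  muts <- enumerate_mutations(ref)
  rn <- if ("label" %in% names(muts)) muts$label else
    paste0(muts$position, "/", muts$ref_base, ">", muts$alt_base)
  key <- paste(muts$position, muts$alt_base)
  counts <- matrix(0L, nrow = nrow(muts), ncol = length(sample_reads),
                   dimnames = list(rn, names(sample_reads)))
  aux_multi <- list()
  histograms <- list()
  for (sid in names(sample_reads)) {
    rs <- sample_reads[[sid]]
    seqs <- if (inherits(rs, "read_set")) rs$seq else as.character(rs)
    ids <- if (inherits(rs, "read_set")) rs$id else
      paste0(sid, "_", seq_along(seqs))
    cb <- call_mutations_batch(seqs, ref)
    histograms[[sid]] <- mutation_count_histogram(cb$n_mut)
    single <- which(cb$n_mut == 1L)
    sc <- cb$calls[cb$calls$read_index %in% single, , drop = FALSE]
    row_idx <- match(paste(sc$position, sc$alt_base), key)
    tab <- tabulate(row_idx, nbins = nrow(muts))
    counts[, sid] <- as.integer(tab)
    multi <- which(cb$n_mut >= 2L)
    if (length(multi) > 0L) {
      mc <- cb$calls[cb$calls$read_index %in% multi, , drop = FALSE]
      lab <- if ("label" %in% names(muts))
        muts$label[match(paste(mc$position, mc$alt_base), key)] else
          paste0(mc$position, ">", mc$alt_base)
      aux_multi[[sid]] <- data.frame(
        read_id = ids[multi],
        n_mut = cb$n_mut[multi],
        mutations = vapply(split(lab, mc$read_index), paste, character(1),
                           collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = names(sample_reads),
                          stringsAsFactors = FALSE)
  } else {
    stopifnot(all(names(sample_reads) %in% samples$sample_id))
    samples <- samples[match(names(sample_reads), samples$sample_id), ,
                       drop = FALSE]
    rownames(samples) <- NULL
  }
  new_mutation_count_matrix(counts, muts, samples, aux_multi = aux_multi,
                            histograms = histograms,
                            mutated_region = ref$mutated_region)
}

#' Per-sample single-mutation fractions
#'
#' Divides each sample's column by its total single-mutation read count, so
#' each retained column sums to 1. Samples with zero single-mutation reads
#' are excluded with a warning.
#'
#' @param mcm A `mutation_count_matrix`.
#' @return A numeric matrix of fractions (possibly fewer columns than the
#'   input).
#' @export
mutation_fractions <- function(mcm) {
  stopifnot(inherits(mcm, "mutation_count_matrix"))
  totals <- colSums(mcm$counts)
  if (any(totals == 0)) {
    warning("excluding sample(s) with zero single-mutation reads: ",
            paste(colnames(mcm$counts)[totals == 0], collapse = ", "),
            call. = FALSE)
  }
  keep <- totals > 0
  sweep(mcm$counts[, keep, drop = FALSE], 2L, totals[keep], "/")
}

#' Sensitivity and specificity for the mutagenized region
#'
#' For each sample: sensitivity is the fraction of the `3 * |region|` target
#' mutations observed at least once; specificity is the fraction of
#' single-mutation reads whose mutation lies inside the mutagenized region
#' (as opposed to the primer flanks). Also returns the per-mutation fractions
#' split into the two subgroups, from which cumulative distributions can be
#' drawn.
#'
#' @param mcm A `mutation_count_matrix`.
#' @param ref The `reference_amplicon`.
#' @return List with `stats` (data frame `sample_id`, `sensitivity`,
#'   `specificity`) and `fractions` (long data frame `sample_id`, `mutation`,
#'   `fraction`, `in_region`).
#' @export
region_detection_stats <- function(mcm, ref) {
  stopifnot(inherits(mcm, "mutation_count_matrix"))
  in_region <- mcm$mutations$position >= ref$mutated_region[1L] &
    mcm$mutations$position < ref$mutated_region[2L]
  totals <- colSums(mcm$counts)
  sens <- apply(mcm$counts[in_region, , drop = FALSE], 2L,
                function(col) mean(col >= 1L))
  spec <- colSums(mcm$counts[in_region, , drop = FALSE]) / totals
  fr <- mutation_fractions(mcm)
  long <- data.frame(
    sample_id = rep(colnames(fr), each = nrow(fr)),
    mutation = rep(rownames(fr), times = ncol(fr)),
    fraction = as.numeric(fr),
    in_region = rep(in_region, times = ncol(fr)),
    stringsAsFactors = FALSE)
  list(stats = data.frame(sample_id = colnames(mcm$counts),
                          sensitivity = unname(sens),
                          specificity = unname(spec),
                          stringsAsFactors = FALSE),
       fractions = long)
}
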