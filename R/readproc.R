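# Read-level stages: 3'-end quality trimming, paired-end merging by ungapped
# overlap scan, and the exact-length filter that removes indel-bearing or
# improperly merged reads.

#' Construct a set of sequencing reads
#'
#' A light container for FASTQ records: parallel vectors of identifiers,
#' sequences and Sanger phred+33 quality strings.
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of sequences (may contain N).
#' @param qual Character vector of phred+33 quality strings, same lengths as
#'   `seq`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 qual = as.character(qual)),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads\n")
  invisible(x)
}

subset_reads <- function(reads, idx) {
  read_set(reads$id[idx], reads$seq[idx], reads$qual[idx])
}

#' Trim low-quality 3' ends
#'
#' Running-sum rule: the removed suffix is the one maximizing
#' `sum(q_threshold - q_i)` over its bases, with ties broken towards the
#' shortest removal (the empty suffix, with sum 0, competes). This is the
#' standard 3'-end quality-trimming rule of common trimming tools. Reads may
#' be trimmed to length zero.
#'
#' @param reads A [read_set()].
#' @param q_threshold Phred threshold (default 30).
#' @return A trimmed `read_set`.
#' @export
#' @examples
#' r <- read_set("r1", "ACGTAA", intToUtf8(c(40, 40, 2, 40, 2, 2) + 33))
#' trim_quality(r, 30)$seq   # "AC"
trim_quality <- function(reads, q_threshold = 30) {
  stopifnot(inherits(reads, "read_set"), q_threshold >= 0)
  quals <- qual_to_int(reads$qual)
  keep_len <- vapply(quals, function(q) {
    L <- length(q)
    if (L == 0L) return(0L)
    cs <- cumsum(q_threshold - rev(q))  # cs[j]: score of removing last j bases
    m <- max(cs)
    if (m <= 0) return(L)               # empty removal (score 0) wins ties
    L - which.max(cs)                   # which.max: shortest removal at ties
  }, integer(1))
  read_set(reads$id,
           substr(reads$seq, 1L, keep_len),
           substr(reads$qual, 1L, keep_len))
}

# Overlap scan for one length-group of read pairs. r2 sequences must already
# be reverse-complemented (and their qualities reversed). Returns per-read
# best overlap and mismatch count. Bases are mapped to small integers so the
# inner comparisons run on numeric matrices.
scan_overlaps <- function(m1, m2, min_overlap) {
  n <- nrow(m1)
  code <- function(m, unknown) {
    # ambiguous bases never match anything (distinct codes per mate)
    matrix(match(m, c("A", "C", "G", "T"), nomatch = unknown), nrow = nrow(m))
  }
  m1 <- code(m1, 5L); m2 <- code(m2, 6L)
  L1 <- ncol(m1); L2 <- ncol(m2)
  max_ov <- min(L1, L2)
  best_ov <- rep(NA_integer_, n)
  best_mm <- rep(NA_integer_, n)
  if (max_ov < min_overlap) return(list(ov = best_ov, mm = best_mm))
  for (ov in seq.int(min_overlap, max_ov)) {
    a <- m1[, (L1 - ov + 1L):L1, drop = FALSE]
    b <- m2[, 1L:ov, drop = FALSE]
    mm <- as.integer(rowSums(a != b))
    if (ov == min_overlap) {
      best_ov[] <- ov
      best_mm <- mm
    } else {
      # better mismatch fraction, or equal fraction (tie -> longer overlap)
      upd <- mm * best_ov <= best_mm * ov
      best_ov[upd] <- ov
      best_mm[upd] <- mm[upd]
    }
  }
  list(ov = best_ov, mm = best_mm)
}

#' Merge read pairs by ungapped overlap
#'
#' For each pair, read 2 is reverse-complemented and every ungapped overlap
#' length `ov >= min_overlap` (up to the shorter read length) is scored by its
#' mismatch fraction; the overlap minimizing the fraction wins, with ties
#' broken towards the longer overlap. Pairs with no admissible overlap are
#' rejected with reason `"no_overlap"`; pairs whose best mismatch fraction
#' exceeds `max_mismatch_fraction` with reason `"too_many_mismatches"`. At
#' overlap mismatches the base with the higher quality is taken (tie: the
#' read-1 base) and the merged quality is the maximum of the two; outside the
#' overlap, source bases are copied.
#'
#' @param r1,r2 [read_set()]s of mates in matching order.
#' @param min_overlap Minimum admissible overlap (default 30).
#' @param max_mismatch_fraction Maximum mismatch fraction in the chosen
#'   overlap (default 0.02).
#' @return A list with `merged` (a `read_set` with attributes
#'   `overlap_length`) and `rejected` (data frame: `id`, `reason`).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 30L, max_mismatch_fraction = 0.02) {
  stopifnot(inherits(r1, "read_set"), inherits(r2, "read_set"),
            length(r1) == length(r2), min_overlap >= 1)
  n <- length(r1)
  if (n == 0L) {
    return(list(merged = read_set(character(0), character(0), character(0)),
                rejected = data.frame(id = character(0), reason = character(0),
                                      stringsAsFactors = FALSE)))
  }
  rc_seq <- revcomp(r2$seq)
  rc_qual <- vapply(r2$qual, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)

  best_ov <- rep(NA_integer_, n)
  best_mm <- rep(NA_integer_, n)
  key <- paste(nchar(r1$seq), nchar(rc_seq))
  for (grp in split(seq_len(n), key)) {
    L1 <- nchar(r1$seq[grp[1L]]); L2 <- nchar(rc_seq[grp[1L]])
    if (min(L1, L2) < min_overlap) next
    res <- scan_overlaps(seq_to_matrix(r1$seq[grp]),
                         seq_to_matrix(rc_seq[grp]), min_overlap)
    best_ov[grp] <- res$ov
    best_mm[grp] <- res$mm
  }

  reason <- rep(NA_character_, n)
  reason[is.na(best_ov)] <- "no_overlap"
  ok <- !is.na(best_ov)
  too_many <- ok & best_mm / best_ov > max_mismatch_fraction
  reason[too_many] <- "too_many_mismatches"
  keep <- ok & !too_many

  ids <- r1$id
  merged_seq <- character(n)
  merged_qual <- character(n)
  kidx <- which(keep)
  if (length(kidx) > 0L) {
    mkey <- paste(nchar(r1$seq[kidx]), nchar(rc_seq[kidx]), best_ov[kidx])
    for (grp in split(kidx, mkey)) {
      L1 <- nchar(r1$seq[grp[1L]]); L2 <- nchar(rc_seq[grp[1L]])
      ov <- best_ov[grp[1L]]
      M1 <- seq_to_matrix(r1$seq[grp]); M2 <- seq_to_matrix(rc_seq[grp])
      Q1 <- do.call(rbind, qual_to_int(r1$qual[grp]))
      Q2 <- do.call(rbind, qual_to_int(rc_qual[grp]))
      o1 <- (L1 - ov + 1L):L1; o2 <- 1L:ov
      take2 <- Q2[, o2, drop = FALSE] > Q1[, o1, drop = FALSE]  # tie -> read 1
      ov_base <- M1[, o1, drop = FALSE]
      ov_base[take2] <- M2[, o2, drop = FALSE][take2]
      ov_qual <- pmax(Q1[, o1, drop = FALSE], Q2[, o2, drop = FALSE])
      Sm <- cbind(M1[, seq_len(L1 - ov), drop = FALSE], ov_base,
                  M2[, seq.int(ov + 1L, length.out = L2 - ov), drop = FALSE])
      Qm <- cbind(Q1[, seq_len(L1 - ov), drop = FALSE], ov_qual,
                  Q2[, seq.int(ov + 1L, length.out = L2 - ov), drop = FALSE])
      merged_seq[grp] <- matrix_to_seq(Sm)
      merged_qual[grp] <- apply(Qm, 1L, function(v) intToUtf8(v + 33L))
    }
  }
  merged <- read_set(ids[keep], merged_seq[keep], merged_qual[keep])
  attr(merged, "overlap_length") <- best_ov[keep]
  list(merged = merged,
       rejected = data.frame(id = ids[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Exact-length filter
#'
#' Keeps only merged reads whose length equals the reference amplicon length.
#' Reads with insertions, deletions or improper merges necessarily have an
#' incorrect length and are removed here.
#'
#' @param merged A [read_set()] of merged reads.
#' @param expected_length The reference amplicon length.
#' @return A `read_set` containing only reads of the expected length.
#' @export
length_filter <- function(merged, expected_length) {
  keep <- nchar(merged$seq) == expected_length
  out <- subset_reads(merged, keep)
  ov <- attr(merged, "overlap_length")
  if (!is.null(ov)) attr(out, "overlap_length") <- ov[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Process one sample's FASTQ pair through the read-level stages
#'
#' Quality-trims both mates, merges pairs, applies the exact-length filter,
#' and drops reads containing N (which cannot be assigned to a substitution
#' class). Returns the retained reads plus a QC tally.
#'
#' @param fastq_1,fastq_2 Paths to the mate FASTQ files (gzip-transparent).
#' @param ref A `reference_amplicon`.
#' @param q_threshold Trimming phred threshold.
#' @param min_overlap,max_mismatch_fraction Merging parameters.
#' @return List with `reads` (kept `read_set`, all of reference length) and
#'   `qc` (list of stage tallies).
#' @export
process_sample <- function(fastq_1, fastq_2, ref, q_threshold = 30,
                           min_overlap = 30L, max_mismatch_fraction = 0.02) {
  r1 <- read_fastq(fastq_1)
  r2 <- read_fastq(fastq_2)
  if (length(r1) != length(r2)) {
    stop("mate FASTQ files have different read counts", call. = FALSE)
  }
  n_in <- length(r1)
  r1 <- trim_quality(r1, q_threshold)
  r2 <- trim_quality(r2, q_threshold)
  mg <- merge_pairs(r1, r2, min_overlap = min_overlap,
                    max_mismatch_fraction = max_mismatch_fraction)
  n_merged <- length(mg$merged)
  flt <- length_filter(mg$merged, ref$length)
  n_wrong_length <- attr(flt, "n_dropped")
  has_n <- grepl("N", flt$seq, fixed = TRUE)
  n_with_n <- sum(has_n)
  kept <- subset_reads(flt, !has_n)
  rej <- table(factor(mg$rejected$reason,
                      levels = c("no_overlap", "too_many_mismatches")))
  list(
    reads = kept,
    qc = list(input_pairs = n_in,
              merged = n_merged,
              rejected_no_overlap = unname(rej[["no_overlap"]]),
              rejected_too_many_mismatches =
                unname(rej[["too_many_mismatches"]]),
              wrong_length = n_wrong_length,
              containing_n = n_with_n,
              kept = length(kept))
  )
}
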