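# Core domain types: the reference amplicon, the single-substitution mutation
# space, and the RNA-alphabet labelling convention anchored at the start codon.

#' Construct a reference amplicon
#'
#' The reference amplicon is the fixed-length sequenced region of a sort-seq
#' experiment. It carries the mutagenized sub-interval (the error-prone-PCR
#' target, as opposed to the flanking primer-derived sequence) and the position
#' of the A of the start codon, which anchors the biological coordinate system
#' used in mutation labels.
#'
#' Internally all coordinates are 0-based with half-open intervals. Biological
#' labels use the start-codon convention: the A of AUG is +1, the base
#' immediately 5' of it is -1, and there is no position 0.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param name Identifier for the amplicon.
#' @param mutated_region Integer vector `c(start, end)`: 0-based half-open
#'   interval of the mutagenized core. Defaults to a centered window of
#'   `min(109, L)` nucleotides.
#' @param aug_index 0-based index of the A of the start codon, or `NULL` if no
#'   anchor is defined (labels then unavailable).
#' @return An object of class `reference_amplicon`.
#' @export
#' @examples
#' ref <- reference_amplicon("ACGTACGT", mutated_region = c(2, 6), aug_index = 4)
reference_amplicon <- function(sequence, name = "amplicon",
                               mutated_region = NULL, aug_index = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("reference sequence must be non-empty", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% DNA_BASES)) {
    stop("reference sequence must contain only A, C, G, T", call. = FALSE)
  }
  if (is.null(mutated_region)) {
    w <- min(109L, L)
    start <- (L - w) %/% 2L
    mutated_region <- c(start, start + w)
  }
  mutated_region <- as.integer(mutated_region)
  if (length(mutated_region) != 2L ||
      mutated_region[1L] < 0L ||
      mutated_region[1L] >= mutated_region[2L] ||
      mutated_region[2L] > L) {
    stop("mutated_region must satisfy 0 <= start < end <= length(sequence)",
         call. = FALSE)
  }
  if (!is.null(aug_index)) {
    aug_index <- as.integer(aug_index)
    if (aug_index < 0L || aug_index >= L) {
      stop("aug_index must lie inside the amplicon", call. = FALSE)
    }
  }
  structure(
    list(name = name, sequence = sequence, chars = chars, length = L,
         mutated_region = mutated_region, aug_index = aug_index),
    class = "reference_amplicon"
  )
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat("reference_amplicon '", x$name, "': ", x$length, " nt, mutagenized core [",
      x$mutated_region[1L], ", ", x$mutated_region[2L], ")",
      if (!is.null(x$aug_index)) paste0(", AUG A at index ", x$aug_index) else "",
      "\n", sep = "")
  invisible(x)
}

#' Read a reference amplicon from a single-record FASTA file
#'
#' @param fasta Path to a FASTA file containing exactly one record.
#' @inheritParams reference_amplicon
#' @return A `reference_amplicon`.
#' @export
read_reference <- function(fasta, mutated_region = NULL, aug_index = NULL) {
  dss <- Biostrings::readDNAStringSet(fasta)
  if (length(dss) != 1L) {
    stop("reference FASTA must contain exactly one record", call. = FALSE)
  }
  reference_amplicon(as.character(dss[[1L]]),
                     name = names(dss)[1L] %||% "amplicon",
                     mutated_region = mutated_region, aug_index = aug_index)
}

#' Enumerate the single-substitution mutation space
#'
#' Lists all 3L possible single-nucleotide substitutions of an L-nt amplicon,
#' ordered by position (ascending) and then by alternative base in fixed order
#' A < C < G < T, skipping the reference base. The ordering is the project-wide
#' row order of all count matrices.
#'
#' @param ref A `reference_amplicon`.
#' @return A data frame with columns `position` (0-based), `ref_base`,
#'   `alt_base` and, if the amplicon has a start-codon anchor, `label`.
#' @export
#' @examples
#' ref <- reference_amplicon("ACGT")
#' enumerate_mutations(ref)   # 12 rows
enumerate_mutations <- function(ref) {
  stopifnot(inherits(ref, "reference_amplicon"))
  L <- ref$length
  position <- rep(seq_len(L) - 1L, each = 3L)
  ref_base <- rep(ref$chars, each = 3L)
  alt_base <- unlist(lapply(ref$chars, function(b) setdiff(DNA_BASES, b)),
                     use.names = FALSE)
  out <- data.frame(position = position, ref_base = ref_base,
                    alt_base = alt_base, stringsAsFactors = FALSE)
  if (!is.null(ref$aug_index)) {
    out$label <- format_label(ref, out$position, out$alt_base)
  }
  out
}

# 0-based amplicon index -> signed start-codon-relative position (no zero).
aug_relative <- function(ref, position) {
  if (is.null(ref$aug_index)) {
    stop("amplicon has no start-codon anchor (aug_index is NULL)", call. = FALSE)
  }
  rel <- position - ref$aug_index
  ifelse(rel >= 0L, rel + 1L, rel)
}

aug_to_index <- function(ref, signed_pos) {
  if (any(signed_pos == 0L)) {
    stop("there is no position 0 in start-codon-relative coordinates",
         call. = FALSE)
  }
  rel <- ifelse(signed_pos > 0L, signed_pos - 1L, signed_pos)
  ref$aug_index + rel
}

#' Format and parse start-codon-relative mutation labels
#'
#' Labels are written in the RNA alphabet (T shown as U) as
#' `<ref><signed position><alt>`, e.g. `"U-75A"`: the reference base, the
#' position relative to the A of the start codon (+1 at the A, -1 immediately
#' 5' of it, no 0), and the alternative base.
#'
#' @param ref A `reference_amplicon` with `aug_index` set.
#' @param position 0-based amplicon index (vectorized).
#' @param alt_base Alternative base, DNA alphabet (vectorized).
#' @return `format_label` returns a character vector of labels; `parse_label`
#'   returns a data frame with columns `position`, `ref_base`, `alt_base`,
#'   `label`.
#' @export
format_label <- function(ref, position, alt_base) {
  stopifnot(inherits(ref, "reference_amplicon"))
  position <- as.integer(position)
  if (any(position < 0L | position >= ref$length)) {
    stop("position out of amplicon bounds", call. = FALSE)
  }
  ref_base <- ref$chars[position + 1L]
  if (any(alt_base == ref_base)) {
    stop("alt_base must differ from the reference base", call. = FALSE)
  }
  rel <- aug_relative(ref, position)
  paste0(chartr("T", "U", ref_base), rel, chartr("T", "U", alt_base))
}

#' @rdname format_label
#' @param label Character vector of labels such as `"U-75A"`.
#' @export
parse_label <- function(ref, label) {
  stopifnot(inherits(ref, "reference_amplicon"))
  m <- regmatches(label, regexec("^([ACGU])(-?[0-9]+)([ACGU])$", label))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed mutation label(s): ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  }
  ref_rna <- vapply(m, `[`, character(1), 2L)
  signed <- as.integer(vapply(m, `[`, character(1), 3L))
  alt_rna <- vapply(m, `[`, character(1), 4L)
  position <- aug_to_index(ref, signed)
  if (any(position < 0L | position >= ref$length)) {
    stop("label position outside the amplicon: ",
         paste(label[position < 0L | position >= ref$length], collapse = ", "),
         call. = FALSE)
  }
  ref_base <- chartr("U", "T", ref_rna)
  alt_base <- chartr("U", "T", alt_rna)
  mismatch <- ref_base != ref$chars[position + 1L]
  if (any(mismatch)) {
    stop("label reference base disagrees with the amplicon at 0-based ",
         "position(s) ", paste(position[mismatch], collapse = ", "),
         call. = FALSE)
  }
  if (any(alt_base == ref_base)) {
    stop("label alternative base equals the reference base", call. = FALSE)
  }
  data.frame(position = position, ref_base = ref_base, alt_base = alt_base,
             label = label, stringsAsFactors = FALSE)
}

#' Built-in synthetic reference amplicon
#'
#' A synthetic 158-nt amplicon emulating the layout of a bacterial 5'-UTR
#' reporter construct: a 109-nt mutagenized core flanked by primer-derived
#' sequence, a GGGG Shine-Dalgarno motif at start-codon-relative positions
#' -12..-9, and the AUG start codon near the 3' end (A at 0-based index 129).
#' The sequence is synthetic (fixed, generated once); it is not a natural
#' sequence.
#'
#' @return A `reference_amplicon` of length 158 with `mutated_region = c(24, 133)`
#'   and `aug_index = 129`.
#' @export
default_reference <- function() {
  seq158 <- paste0(
    "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACG",
    "CCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGGGGGTTCTAATAATGGACTTAGCAACA",
    "AGTCGCCTAGAAAG"
  )
  reference_amplicon(seq158, name = "synthetic_utr_amplicon",
                     mutated_region = c(24L, 133L), aug_index = 129L)
}
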