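# File-format plumbing: FASTQ/FASTA via Biostrings (gzip-transparent), sample
# sheets and count matrices as TSV, QC and manifests as JSON.

#' Read a FASTQ file into a read_set
#'
#' @param path FASTQ path (plain or gzipped).
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  read_set(ids, as.character(x),
           as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read_set as FASTQ
#'
#' @param reads A [read_set()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(
    dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

write_fasta <- function(ref, path) {
  dna <- Biostrings::DNAStringSet(ref$sequence)
  names(dna) <- ref$name
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' A sample sheet is a TSV with columns `sample_id`, `fastq_1`, `fastq_2`,
#' `plasmid` (`control`/`srna`), `gate` (`unsorted`/`all`/`high`/`low`) and
#' `replicate` (integer >= 1). The (plasmid, gate, replicate) triple must be
#' unique.
#'
#' @param path TSV path.
#' @param check_files If `TRUE`, error when a FASTQ path does not exist.
#' @return A validated data frame.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, check_files = check_files)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data frame.
#' @export
validate_sample_sheet <- function(sheet, check_files = FALSE) {
  required <- c("sample_id", "fastq_1", "fastq_2", "plasmid", "gate",
                "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id) > 0L) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (!all(sheet$plasmid %in% c("control", "srna"))) {
    stop("plasmid must be 'control' or 'srna'", call. = FALSE)
  }
  if (!all(sheet$gate %in% c("unsorted", "all", "high", "low"))) {
    stop("gate must be one of unsorted, all, high, low", call. = FALSE)
  }
  if (any(sheet$replicate < 1)) {
    stop("replicate must be >= 1", call. = FALSE)
  }
  if (anyDuplicated(sheet[c("plasmid", "gate", "replicate")]) > 0L) {
    stop("duplicate (plasmid, gate, replicate) in sample sheet",
         call. = FALSE)
  }
  if (check_files) {
    paths <- c(sheet$fastq_1, sheet$fastq_2)
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0L) {
      stop("missing FASTQ file(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  sheet
}

#' Write a mutation count matrix as TSV
#'
#' Rows are labeled with start-codon-relative mutation labels (or
#' `position/ref>alt` if no anchor is set); columns are sample ids.
#'
#' @param mcm A `mutation_count_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mcm, path) {
  df <- data.frame(mutation = rownames(mcm$counts), mcm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation count matrix written by [write_count_matrix()]
#'
#' @param path TSV path.
#' @param ref The `reference_amplicon` the matrix was built against.
#' @param samples Optional sample-metadata data frame (`sample_id`, `plasmid`,
#'   `gate`, `replicate`).
#' @return A `mutation_count_matrix`.
#' @export
read_count_matrix <- function(path, ref, samples = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df[[1L]]
  storage.mode(counts) <- "integer"
  muts <- enumerate_mutations(ref)
  expected <- if ("label" %in% names(muts)) muts$label else
    paste0(muts$position, "/", muts$ref_base, ">", muts$alt_base)
  if (!identical(rownames(counts), expected)) {
    stop("count matrix rows do not match the mutation enumeration of the ",
         "reference", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(counts),
                          stringsAsFactors = FALSE)
  }
  new_mutation_count_matrix(counts, muts, samples,
                            mutated_region = ref$mutated_region)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
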