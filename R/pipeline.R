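# Pipeline orchestration: config schema and validation, stage wiring
# (process -> count -> enrich -> cluster), and deterministic output manifests.

#' Default pipeline configuration
#'
#' @param reference_fasta Path to the single-record reference FASTA.
#' @param mutated_region 0-based half-open `c(start, end)` of the mutagenized
#'   core, or `NULL` for the centered default.
#' @param aug_index 0-based index of the A of the start codon, or `NULL`.
#' @param baseline,contrast Condition labels (`plasmid_gate`) for the
#'   enrichment contrast; there is no preferred default -- sorted pools can
#'   be compared against the all-sorted or the unsorted sample.
#' @param alpha Adjusted-p significance threshold.
#' @param q_threshold,min_overlap,max_mismatch_fraction Read-processing
#'   parameters.
#' @param distance,linkage Clustering parameters.
#' @param seed Integer seed recorded in the manifest.
#' @return A named list (the config schema).
#' @export
pipeline_config <- function(reference_fasta, mutated_region = NULL,
                            aug_index = NULL, baseline, contrast,
                            alpha = 0.05, q_threshold = 30,
                            min_overlap = 30L, max_mismatch_fraction = 0.02,
                            distance = "euclidean", linkage = "complete",
                            seed = 1L) {
  cfg <- list(
    reference = list(fasta = reference_fasta,
                     mutated_region = mutated_region,
                     aug_index = aug_index),
    trim = list(q_threshold = q_threshold),
    merge = list(min_overlap = min_overlap,
                 max_mismatch_fraction = max_mismatch_fraction),
    contrast = list(baseline = baseline, contrast = contrast),
    alpha = alpha,
    cluster = list(distance = distance, linkage = linkage),
    seed = seed)
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks the config (a nested list, e.g. parsed from YAML) against the
#' schema; violations are reported with their field paths. Missing input
#' files are reported before any work is done.
#'
#' @param cfg Config list.
#' @return The validated config, invisibly usable.
#' @export
validate_config <- function(cfg) {
  fail <- function(path, msg) {
    stop("config field '", path, "': ", msg, call. = FALSE)
  }
  need <- function(path, value, test, msg) {
    if (is.null(value) || !test(value)) fail(path, msg)
  }
  need("reference.fasta", cfg$reference$fasta,
       function(x) is.character(x) && length(x) == 1L, "must be a file path")
  if (!file.exists(cfg$reference$fasta)) {
    fail("reference.fasta", paste0("file not found: ", cfg$reference$fasta))
  }
  mr <- cfg$reference$mutated_region
  if (!is.null(mr)) {
    mr <- unlist(mr)
    if (length(mr) != 2L || !is.numeric(mr) || mr[1L] < 0 || mr[1L] >= mr[2L]) {
      fail("reference.mutated_region", "must be c(start, end), 0 <= start < end")
    }
  }
  need("trim.q_threshold", cfg$trim$q_threshold,
       function(x) is.numeric(x) && x >= 0, "must be a non-negative number")
  need("merge.min_overlap", cfg$merge$min_overlap,
       function(x) is.numeric(x) && x >= 1, "must be >= 1")
  need("merge.max_mismatch_fraction", cfg$merge$max_mismatch_fraction,
       function(x) is.numeric(x) && x >= 0 && x <= 1, "must be in [0, 1]")
  need("contrast.baseline", cfg$contrast$baseline,
       function(x) is.character(x) && length(x) == 1L,
       "must be a condition label such as 'srna_all'")
  need("contrast.contrast", cfg$contrast$contrast,
       function(x) is.character(x) && length(x) == 1L,
       "must be a condition label such as 'srna_high'")
  need("alpha", cfg$alpha,
       function(x) is.numeric(x) && x > 0 && x < 1, "must be in (0, 1)")
  need("cluster.distance", cfg$cluster$distance, is.character,
       "must be a distance name")
  need("cluster.linkage", cfg$cluster$linkage, is.character,
       "must be a linkage name")
  need("seed", cfg$seed, function(x) is.numeric(x) && length(x) == 1L,
       "must be a single integer")
  cfg
}

#' Read a YAML pipeline config
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Processes every sample of the sheet through trimming, merging and the
#' exact-length filter; builds the single-mutation count matrix; computes the
#' enrichment table for the configured contrast; clusters the samples; and
#' writes all artifacts plus a manifest to `outdir`. Rerunning with identical
#' inputs and seed produces byte-identical outputs.
#'
#' @param cfg Config list (see [pipeline_config()] / [read_config()]).
#' @param sample_sheet Path to the sample sheet TSV, or a data frame.
#' @param outdir Output directory.
#' @return Invisibly, a list with the in-memory results (`mcm`, `enrichment`,
#'   `hclust`, `qc`, `region_stats`, `concordance`) and output paths.
#' @export
run_pipeline <- function(cfg, sample_sheet, outdir) {
  cfg <- validate_config(cfg)
  sheet <- if (is.character(sample_sheet)) {
    read_sample_sheet(sample_sheet)
  } else {
    validate_sample_sheet(sample_sheet, check_files = TRUE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- read_reference(cfg$reference$fasta,
                        mutated_region =
                          if (!is.null(cfg$reference$mutated_region))
                            unlist(cfg$reference$mutated_region),
                        aug_index = cfg$reference$aug_index)

  # process: read-level stages per sample
  sample_reads <- list()
  qc <- list()
  for (i in seq_len(nrow(sheet))) {
    ps <- process_sample(sheet$fastq_1[i], sheet$fastq_2[i], ref,
                         q_threshold = cfg$trim$q_threshold,
                         min_overlap = cfg$merge$min_overlap,
                         max_mismatch_fraction =
                           cfg$merge$max_mismatch_fraction)
    sample_reads[[sheet$sample_id[i]]] <- ps$reads
    qc[[sheet$sample_id[i]]] <- ps$qc
  }

  # count
  mcm <- build_count_matrix(sample_reads, ref, samples = sheet)
  count_path <- file.path(outdir, "count_matrix.tsv")
  write_count_matrix(mcm, count_path)
  region <- region_detection_stats(mcm, ref)
  qc_path <- file.path(outdir, "qc.json")
  write_json_file(list(
    samples = qc,
    histograms = lapply(mcm$histograms, function(h)
      list(classes = h$classes, counts = h$counts, fractions = h$fractions)),
    region_stats = region$stats,
    expected_error_free_read_fraction =
      error_free_fraction(cfg$trim$q_threshold, ref$length)), qc_path)

  # enrich
  enr <- enrichment_table(mcm, baseline = cfg$contrast$baseline,
                          contrast = cfg$contrast$contrast,
                          alpha = cfg$alpha)
  enrich_path <- file.path(outdir, "enrichment.tsv")
  write.table(enr, enrich_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # cluster
  fr <- mutation_fractions(mcm)
  z <- pattern_matrix(fr)
  hc <- cluster_samples(z, distance = cfg$cluster$distance,
                        linkage = cfg$cluster$linkage)
  pattern_path <- file.path(outdir, "pattern_matrix.tsv")
  write.table(data.frame(mutation = rownames(z), z, check.names = FALSE),
              pattern_path, sep = "\t", quote = FALSE, row.names = FALSE)
  newick_path <- file.path(outdir, "samples.nwk")
  export_newick(hc, newick_path)
  order_path <- file.path(outdir, "sample_order.txt")
  writeLines(hc$labels[hc$order], order_path)
  concordance <- replicate_concordance(hc, sheet)

  # manifest (no timestamps: reruns must be byte-identical)
  outputs <- c(count_path, qc_path, enrich_path, pattern_path, newick_path,
               order_path)
  manifest <- list(
    tool = "sortseqmap",
    version = as.character(packageVersion("sortseqmap")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(outdir, "manifest.json")
  write_json_file(manifest, manifest_path)

  invisible(list(mcm = mcm, enrichment = enr, hclust = hc, qc = qc,
                 region_stats = region$stats, concordance = concordance,
                 ref = ref,
                 paths = list(count_matrix = count_path, qc = qc_path,
                              enrichment = enrich_path,
                              pattern_matrix = pattern_path,
                              newick = newick_path, manifest = manifest_path)))
}
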