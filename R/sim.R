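# Sort-seq simulator: mutant plasmid library -> per-cell fluorescence with and
# without the repressing sRNA -> FACS gating -> paired-end reads with
# base-call errors. Every downstream stage of the pipeline can be exercised on
# its output, with full ground truth.

#' Construct a fluorescence effect model
#'
#' Phenotypes are modeled on the log10 fluorescence scale. A cell's value is
#'
#' `basal + sum(expression_shift) - srna_repression * I(srna plasmid) *
#'  prod(1 - regulation_loss) + Normal(0, noise_sd)`
#'
#' where the sum and product run over the mutations carried by the clone. The
#' two effect axes represent the two ways a mutation can raise expression in
#' the presence of a repressing sRNA: a change of the translation rate itself
#' (`expression_shift`, applied always) and a loss of sRNA-mediated repression
#' (`regulation_loss`, the fraction of repression abolished, only visible with
#' the sRNA plasmid). Mutations absent from the table are silent.
#'
#' @param basal Basal log10 fluorescence of the wild-type construct without
#'   sRNA.
#' @param srna_repression Log10-fold repression applied when the cell carries
#'   the sRNA plasmid (1 = 10-fold).
#' @param effects Data frame with columns `label`, `expression_shift`,
#'   `regulation_loss` (the latter in \[0, 1\]).
#' @param noise_sd Standard deviation of log10 fluorescence noise (>= 0).
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(basal = 3, srna_repression = 1,
                         effects = data.frame(label = character(0),
                                              expression_shift = numeric(0),
                                              regulation_loss = numeric(0)),
                         noise_sd = 0.3) {
  stopifnot(is.data.frame(effects),
            all(c("label", "expression_shift", "regulation_loss") %in%
                  names(effects)))
  if (any(effects$regulation_loss < 0 | effects$regulation_loss > 1)) {
    stop("regulation_loss must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(basal = basal, srna_repression = srna_repression,
                 effects = effects, noise_sd = noise_sd),
            class = "effect_model")
}

#' Default effect model for the built-in synthetic amplicon
#'
#' Assigns, in start-codon-relative coordinates on [default_reference()]:
#' * full loss of sRNA regulation (`regulation_loss = 1`) for all 57
#'   substitutions at positions -79..-61, emulating an sRNA binding site;
#' * an expression increase (`expression_shift = +0.5`) for the 24
#'   substitutions at -24..-17, emulating destabilization of the stem-loop
#'   that sequesters the ribosome-binding site;
#' * an expression decrease (`expression_shift = -0.8`) for substitutions in
#'   the Shine-Dalgarno motif (-12..-9) and the start codon (+1..+3).
#'
#' All other mutations are phenotypically silent.
#'
#' @param ref A `reference_amplicon` (default [default_reference()]).
#' @return An `effect_model`.
#' @export
default_effect_model <- function(ref = default_reference()) {
  muts <- enumerate_mutations(ref)
  rel <- aug_relative(ref, muts$position)
  eff <- data.frame(label = character(0), expression_shift = numeric(0),
                    regulation_loss = numeric(0), stringsAsFactors = FALSE)
  add <- function(eff, labels, shift, loss) {
    rbind(eff, data.frame(label = labels, expression_shift = shift,
                          regulation_loss = loss, stringsAsFactors = FALSE))
  }
  eff <- add(eff, muts$label[rel >= -79 & rel <= -61], 0, 1)
  eff <- add(eff, muts$label[rel >= -24 & rel <= -17], 0.5, 0)
  eff <- add(eff, muts$label[(rel >= -12 & rel <= -9) | (rel >= 1 & rel <= 3)],
             -0.8, 0)
  effect_model(basal = 3, srna_repression = 1, effects = eff, noise_sd = 0.3)
}

#' Generate a mutant clone library
#'
#' Draws `n_clones` independent clones. Each clone's number of mutations is
#' drawn from `mutation_count_distribution` (a probability vector over 0-4
#' mutations; the last class is taken as exactly 4). Mutation positions are
#' drawn without replacement over the whole amplicon with per-region weights
#' splitting probability mass between the mutagenized core and the primer
#' flanks; the alternative base is uniform over the three non-reference bases.
#'
#' @param ref A `reference_amplicon`.
#' @param n_clones Number of clones.
#' @param mutation_count_distribution Numeric vector of length 5 (counts
#'   0,1,2,3,4) summing to 1.
#' @param region_weights Named numeric `c(core = , flanks = )`: total
#'   probability mass of a mutation falling in the mutagenized core vs the
#'   flanks. With the default `c(core = 0.9, flanks = 0.1)` roughly 90% of
#'   mutations land in the core, mirroring the specificity typical of
#'   amplicon-targeted error-prone PCR.
#' @param seed Integer seed.
#' @return A list of class `clone_library` with `clones` (data frame:
#'   `clone_id`, `n_mut`) and `mutations` (data frame: `clone_id`, `position`,
#'   `ref_base`, `alt_base`, `label`).
#' @export
generate_library <- function(ref, n_clones,
                             mutation_count_distribution =
                               c(`0` = 0.45, `1` = 0.35, `2` = 0.13,
                                 `3` = 0.04, `4` = 0.03),
                             region_weights = c(core = 0.9, flanks = 0.1),
                             seed) {
  stopifnot(inherits(ref, "reference_amplicon"), n_clones >= 1)
  p <- as.numeric(mutation_count_distribution)
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("mutation_count_distribution must be 5 probabilities summing to 1",
         call. = FALSE)
  }
  L <- ref$length
  core <- seq.int(ref$mutated_region[1L], ref$mutated_region[2L] - 1L)
  in_core <- seq_len(L) - 1L
  in_core <- in_core %in% core
  w <- numeric(L)
  n_flank <- sum(!in_core)
  w[in_core] <- region_weights[["core"]] / sum(in_core)
  if (n_flank > 0L) w[!in_core] <- region_weights[["flanks"]] / n_flank
  if (n_flank == 0L) w <- w / sum(w)

  with_local_seed(seed, {
    n_mut <- sample.int(5L, n_clones, replace = TRUE, prob = p) - 1L
    clone_ids <- seq_len(n_clones)
    mutated <- which(n_mut > 0L)
    pos_list <- lapply(mutated, function(i) {
      sample.int(L, n_mut[i], replace = FALSE, prob = w) - 1L
    })
    positions <- as.integer(unlist(pos_list, use.names = FALSE))
    clone_of <- as.integer(rep(mutated, n_mut[mutated]))
    ref_base <- as.character(ref$chars[positions + 1L])
    alt_idx <- sample.int(3L, length(positions), replace = TRUE)
    alt_base <- vapply(seq_along(positions), function(j) {
      setdiff(DNA_BASES, ref_base[j])[alt_idx[j]]
    }, character(1))
    if (length(alt_base) == 0L) alt_base <- character(0)
    mutations <- data.frame(
      clone_id = clone_of, position = positions, ref_base = ref_base,
      alt_base = alt_base, stringsAsFactors = FALSE)
    if (!is.null(ref$aug_index)) {
      mutations$label <- format_label(ref, mutations$position,
                                      mutations$alt_base)
    }
    mutations <- mutations[order(mutations$clone_id, mutations$position), ,
                           drop = FALSE]
    rownames(mutations) <- NULL
    structure(list(clones = data.frame(clone_id = clone_ids, n_mut = n_mut),
                   mutations = mutations, ref_name = ref$name),
              class = "clone_library")
  })
}

# Full mutant sequence of every clone (character vector indexed by clone_id).
clone_sequences <- function(library, ref) {
  seqs <- rep(ref$sequence, nrow(library$clones))
  m <- library$mutations
  for (j in seq_len(nrow(m))) {
    substr(seqs[m$clone_id[j]], m$position[j] + 1L, m$position[j] + 1L) <-
      m$alt_base[j]
  }
  seqs
}

#' Assign log10 fluorescence values to clones or cells
#'
#' Applies the [effect_model()] algebra to each genotype. With
#' `noise_sd = 0` in the model the value is deterministic.
#'
#' @param library A `clone_library`.
#' @param clone_id Integer vector of clone ids (one per cell); defaults to all
#'   clones once.
#' @param plasmid `"control"` or `"srna"`.
#' @param model An `effect_model`.
#' @param seed Integer seed (used for the Gaussian noise).
#' @return Numeric vector of log10 fluorescence values, one per element of
#'   `clone_id`.
#' @export
assign_fluorescence <- function(library, plasmid = c("control", "srna"),
                                model, clone_id = library$clones$clone_id,
                                seed = 1L) {
  plasmid <- match.arg(plasmid)
  stopifnot(inherits(model, "effect_model"))
  n_clones <- nrow(library$clones)
  shift <- numeric(n_clones)
  retained <- rep(1, n_clones)
  m <- library$mutations
  if (nrow(m) > 0L && nrow(model$effects) > 0L) {
    hit <- match(m$label, model$effects$label)
    known <- !is.na(hit)
    if (any(known)) {
      sh <- model$effects$expression_shift[hit[known]]
      rl <- model$effects$regulation_loss[hit[known]]
      cid <- m$clone_id[known]
      shift <- shift + as.numeric(
        tapply(sh, factor(cid, levels = seq_len(n_clones)), sum,
               default = 0))
      logret <- as.numeric(
        tapply(log1p(-pmin(rl, 1 - 1e-15)),
               factor(cid, levels = seq_len(n_clones)), sum, default = 0))
      retained <- exp(logret)
      retained[as.numeric(tapply(rl == 1,
                                 factor(cid, levels = seq_len(n_clones)),
                                 any, default = FALSE)) > 0] <- 0
    }
  }
  det <- model$basal + shift -
    model$srna_repression * (plasmid == "srna") * retained
  values <- det[clone_id]
  if (model$noise_sd > 0) {
    values <- with_local_seed(seed, values + rnorm(length(values), 0,
                                                   model$noise_sd))
  }
  values
}

#' FACS gates derived from the wild-type fluorescence distribution
#'
#' Gates are set against the wild-type construct in the same plasmid
#' background, mirroring how sorting gates are drawn on the unmutagenized
#' reporter strain: `high` captures the upper `p_tail` quantile of the
#' wild-type log10 fluorescence distribution, `low` the lower `p_tail`
#' quantile, and `all` spans the whole support. Quantiles are computed in
#' closed form from the Gaussian noise model.
#'
#' @param model An `effect_model`.
#' @param plasmid `"control"` or `"srna"`.
#' @param p_tail Tail probability of the wild type inside the high/low gate.
#' @return Named list of gates, each `c(lo, hi)` on log10 fluorescence
#'   (half-open `[lo, hi)`).
#' @export
make_gates <- function(model, plasmid = c("control", "srna"), p_tail = 0.05) {
  plasmid <- match.arg(plasmid)
  wt_mean <- model$basal - model$srna_repression * (plasmid == "srna")
  sdv <- max(model$noise_sd, 1e-12)
  list(
    high = c(qnorm(1 - p_tail, wt_mean, sdv), Inf),
    low = c(-Inf, qnorm(p_tail, wt_mean, sdv)),
    all = c(-Inf, Inf),
    unsorted = c(-Inf, Inf)
  )
}

#' Sort cells into fluorescence gates
#'
#' @param cells Data frame with at least a `fluorescence` column.
#' @param gates Named list of `c(lo, hi)` intervals (half-open).
#' @param target_cells_per_gate Subsample (without replacement) each gate pool
#'   to at most this many cells.
#' @param seed Integer seed (used only when subsampling).
#' @return Named list of data frames (subsets of `cells`).
#' @export
sort_cells <- function(cells, gates, target_cells_per_gate = Inf, seed = 1L) {
  stopifnot(is.data.frame(cells), "fluorescence" %in% names(cells))
  with_local_seed(seed, {
    lapply(gates, function(g) {
      pool <- cells[cells$fluorescence >= g[1L] & cells$fluorescence < g[2L], ,
                    drop = FALSE]
      if (nrow(pool) == 0L) {
        warning("empty gate pool", call. = FALSE)
      } else if (nrow(pool) > target_cells_per_gate) {
        pool <- pool[sample.int(nrow(pool), target_cells_per_gate), ,
                     drop = FALSE]
      }
      pool
    })
  })
}

# Apply i.i.d. substitution errors at per-cycle phred-derived rates to a
# character matrix of reads (rows = reads).
apply_substitution_errors <- function(mat, qual_by_cycle) {
  if (nrow(mat) == 0L) return(mat)
  p_err <- 10^(-qual_by_cycle / 10)
  err <- matrix(stats::runif(length(mat)) <
                  rep(p_err, each = nrow(mat)), nrow = nrow(mat))
  idx <- which(err)
  if (length(idx) > 0L) {
    orig <- mat[idx]
    pick <- sample.int(3L, length(idx), replace = TRUE)
    mat[idx] <- vapply(seq_along(idx), function(j) {
      setdiff(DNA_BASES, orig[j])[pick[j]]
    }, character(1))
  }
  mat
}

# Introduce a single 1-bp insertion or deletion at a random position of a
# template sequence. One event per read at most, so that every indel-bearing
# fragment has an incorrect length and is removable by the length filter.
apply_single_indel <- function(seqs) {
  vapply(seqs, function(s) {
    L <- nchar(s)
    if (stats::runif(1) < 0.5 && L > 1L) {       # deletion
      pos <- sample.int(L, 1L)
      paste0(substr(s, 1L, pos - 1L), substr(s, pos + 1L, L))
    } else {                                     # insertion
      pos <- sample.int(L + 1L, 1L) - 1L
      paste0(substr(s, 1L, pos), sample(DNA_BASES, 1L),
             substr(s, pos + 1L, L))
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end sequencing of a sorted cell pool
#'
#' Each read pair covers one template molecule drawn (with replacement) from
#' the pool: read 1 is the 5' prefix of the amplicon, read 2 the reverse
#' complement of the 3' suffix. Bases are flipped to a uniformly chosen other
#' base with probability `10^(-q/10)` taken from the per-cycle quality
#' profile; qualities are written as Sanger phred+33. A per-read probability
#' of a single 1-bp insertion/deletion event lets the simulator produce the
#' incorrect-length reads that the downstream length filter must remove.
#'
#' @param templates Character vector of template sequences (one per cell in
#'   the pool).
#' @param n_reads Number of read pairs to generate (templates sampled with
#'   replacement).
#' @param read_length Cycles per read; `2 * read_length` must exceed the
#'   amplicon length by at least `min_overlap_margin`.
#' @param quality_profile Integer phred score per cycle (recycled if scalar).
#' @param indel_read_prob Probability that a template molecule acquires one
#'   1-bp indel.
#' @param min_overlap_margin Required read-pair overlap (default 30).
#' @param id_prefix Prefix for read identifiers.
#' @param seed Integer seed.
#' @return List with `r1`, `r2` (each a [read_set()]) and `truth` (data frame:
#'   `read_id`, `template_index`, `has_indel`).
#' @export
sequence_pool <- function(templates, n_reads, read_length = 100L,
                          quality_profile = 30L, indel_read_prob = 0,
                          min_overlap_margin = 30L, id_prefix = "read",
                          seed = 1L) {
  stopifnot(length(templates) > 0L, n_reads >= 1)
  amp_len <- unique(nchar(templates))
  if (2L * read_length < max(amp_len) + min_overlap_margin) {
    stop("2*read_length must be at least the amplicon length plus ",
         min_overlap_margin, " for merging to be possible", call. = FALSE)
  }
  # Inf = error-free sequencing; written qualities are capped at phred 60
  qp <- rep_len(as.numeric(quality_profile), read_length)
  if (any(qp < 0)) stop("quality_profile must be non-negative", call. = FALSE)
  wq <- as.integer(round(pmin(qp, 60)))
  with_local_seed(seed, {
    tmpl_idx <- sample.int(length(templates), n_reads, replace = TRUE)
    seqs <- templates[tmpl_idx]
    has_indel <- stats::runif(n_reads) < indel_read_prob
    if (any(has_indel)) seqs[has_indel] <- apply_single_indel(seqs[has_indel])
    lens <- nchar(seqs)
    r1 <- substr(seqs, 1L, read_length)
    r2 <- revcomp(substring(seqs, lens - read_length + 1L, lens))
    # group by template length for matrix-vectorized error injection
    out1 <- character(n_reads); out2 <- character(n_reads)
    for (grp in split(seq_len(n_reads), nchar(r1))) {
      m <- apply_substitution_errors(seq_to_matrix(r1[grp]),
                                     qp[seq_len(nchar(r1[grp[1L]]))])
      out1[grp] <- matrix_to_seq(m)
    }
    for (grp in split(seq_len(n_reads), nchar(r2))) {
      m <- apply_substitution_errors(seq_to_matrix(r2[grp]),
                                     qp[seq_len(nchar(r2[grp[1L]]))])
      out2[grp] <- matrix_to_seq(m)
    }
    ids <- sprintf("%s_%06d", id_prefix, seq_len(n_reads))
    qual_for_len <- function(lens) {
      uq <- vapply(sort(unique(lens)),
                   function(l) intToUtf8(wq[seq_len(l)] + 33L), character(1))
      names(uq) <- sort(unique(lens))
      unname(uq[as.character(lens)])
    }
    q1 <- qual_for_len(nchar(out1))
    q2 <- qual_for_len(nchar(out2))
    list(r1 = read_set(ids, out1, q1),
         r2 = read_set(ids, out2, q2),
         truth = data.frame(read_id = ids, template_index = tmpl_idx,
                            has_indel = has_indel, stringsAsFactors = FALSE))
  })
}

#' Default sample plan for a simulated experiment
#'
#' Four conditions in triplicate: the repressed library sorted for high
#' fluorescence and for all fluorescence levels (the primary contrast for
#' mapping loss-of-regulation mutations), plus the control-plasmid library
#' sorted high and low (which expose expression-changing mutations).
#'
#' @param replicates Number of biological replicates per condition.
#' @return Data frame with columns `plasmid`, `gate`, `replicate`.
#' @export
default_sample_plan <- function(replicates = 3L) {
  cond <- data.frame(
    plasmid = c("srna", "srna", "control", "control"),
    gate = c("high", "all", "high", "low"),
    stringsAsFactors = FALSE)
  plan <- cond[rep(seq_len(nrow(cond)), each = replicates), , drop = FALSE]
  plan$replicate <- rep(seq_len(replicates), times = nrow(cond))
  rownames(plan) <- NULL
  plan
}

#' Simulate a complete sort-seq experiment
#'
#' Generates one mutant library, grows an independent culture per (plasmid,
#' replicate), assigns per-cell fluorescence under the effect model, sorts
#' cells into the gates required by the sample plan, sequences each sorted
#' pool, and writes per-sample paired FASTQ files, a sample sheet, a clone
#' truth table and a per-read truth table. With a fixed seed all outputs are
#' deterministic.
#'
#' @param ref A `reference_amplicon`.
#' @param model An `effect_model`.
#' @param outdir Output directory (created if needed).
#' @param plan Sample plan data frame (`plasmid`, `gate`, `replicate`).
#' @param n_clones Clones in the mutant library.
#' @param n_cells Cells per culture.
#' @param n_reads Read pairs per sample.
#' @param read_length Read length in cycles.
#' @param quality_profile Phred score per cycle (scalar or vector).
#' @param indel_read_prob Per-read probability of a 1-bp indel.
#' @param p_tail Gate tail probability (see [make_gates()]).
#' @param target_cells_per_gate Cap on sorted pool size.
#' @param mutation_count_distribution,region_weights Passed to
#'   [generate_library()].
#' @param seed Integer seed governing all randomness.
#' @return Invisibly, a list with `sample_sheet` (data frame and path),
#'   `library`, `truth_reads` (per-sample read truth), and file paths.
#' @export
simulate_experiment <- function(ref = default_reference(),
                                model = default_effect_model(ref),
                                outdir,
                                plan = default_sample_plan(),
                                n_clones = 10000L,
                                n_cells = 50000L,
                                n_reads = 50000L,
                                read_length = 100L,
                                quality_profile = 30L,
                                indel_read_prob = 0.01,
                                p_tail = 0.05,
                                target_cells_per_gate = 1e6,
                                mutation_count_distribution =
                                  c(`0` = 0.45, `1` = 0.35, `2` = 0.13,
                                    `3` = 0.04, `4` = 0.03),
                                region_weights = c(core = 0.9, flanks = 0.1),
                                seed) {
  stopifnot(all(c("plasmid", "gate", "replicate") %in% names(plan)))
  if (anyDuplicated(plan[c("plasmid", "gate", "replicate")]) > 0L) {
    stop("duplicate (plasmid, gate, replicate) in the sample plan",
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  lib <- generate_library(ref, n_clones,
                          mutation_count_distribution =
                            mutation_count_distribution,
                          region_weights = region_weights, seed = seed)
  templates_by_clone <- clone_sequences(lib, ref)

  sheet <- plan
  sheet$sample_id <- sprintf("%s_%s_%d", plan$plasmid, plan$gate,
                             plan$replicate)
  sheet$fastq_1 <- file.path(outdir, paste0(sheet$sample_id, "_R1.fastq"))
  sheet$fastq_2 <- file.path(outdir, paste0(sheet$sample_id, "_R2.fastq"))

  truth_reads <- vector("list", nrow(sheet))
  cultures <- unique(plan[c("plasmid", "replicate")])
  sample_seed_base <- as.integer(seed) %% 1000000L
  for (ci in seq_len(nrow(cultures))) {
    plasmid <- cultures$plasmid[ci]
    repl <- cultures$replicate[ci]
    cseed <- sample_seed_base + 1000L * ci
    cells <- with_local_seed(cseed, data.frame(
      clone_id = sample.int(n_clones, n_cells, replace = TRUE)))
    cells$fluorescence <- assign_fluorescence(
      lib, plasmid = plasmid, model = model, clone_id = cells$clone_id,
      seed = cseed + 1L)
    gates <- make_gates(model, plasmid = plasmid, p_tail = p_tail)
    rows <- which(plan$plasmid == plasmid & plan$replicate == repl)
    pools <- sort_cells(cells, gates[unique(plan$gate[rows])],
                        target_cells_per_gate = target_cells_per_gate,
                        seed = cseed + 2L)
    for (ri in rows) {
      pool <- pools[[plan$gate[ri]]]
      if (nrow(pool) == 0L) {
        stop("gate '", plan$gate[ri], "' produced an empty pool", call. = FALSE)
      }
      sp <- sequence_pool(templates_by_clone[pool$clone_id],
                          n_reads = n_reads, read_length = read_length,
                          quality_profile = quality_profile,
                          indel_read_prob = indel_read_prob,
                          id_prefix = sheet$sample_id[ri],
                          seed = cseed + 10L + ri)
      write_fastq(sp$r1, sheet$fastq_1[ri])
      write_fastq(sp$r2, sheet$fastq_2[ri])
      tr <- sp$truth
      tr$sample_id <- sheet$sample_id[ri]
      tr$clone_id <- pool$clone_id[tr$template_index]
      tr$n_mut <- lib$clones$n_mut[tr$clone_id]
      truth_reads[[ri]] <- tr
    }
  }
  truth_reads <- do.call(rbind, truth_reads)

  sheet_path <- file.path(outdir, "sample_sheet.tsv")
  write.table(sheet[c("sample_id", "fastq_1", "fastq_2", "plasmid", "gate",
                      "replicate")],
              sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(lib$clones, file.path(outdir, "truth_clones.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(lib$mutations, file.path(outdir, "truth_clone_mutations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth_reads, file.path(outdir, "truth_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(ref, file.path(outdir, "reference.fasta"))

  invisible(list(sample_sheet = sheet, sample_sheet_path = sheet_path,
                 library = lib, truth_reads = truth_reads, outdir = outdir))
}
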