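test_that("library generation follows the mutation-count distribution", {
  ref <- default_reference()

  wt_only <- generate_library(ref, 200,
                              mutation_count_distribution = c(1, 0, 0, 0, 0),
                              seed = 1)
  expect_true(all(wt_only$clones$n_mut == 0))
  expect_equal(nrow(wt_only$mutations), 0L)

  lib <- generate_library(ref, 10000, seed = 2)
  frac1 <- mean(lib$clones$n_mut == 1)
  se <- sqrt(0.35 * 0.65 / 10000)
  expect_lt(abs(frac1 - 0.35), 3 * se)

  core_only <- generate_library(ref, 500,
                                region_weights = c(core = 1, flanks = 0),
                                seed = 3)
  expect_true(all(core_only$mutations$position >= ref$mutated_region[1] &
                    core_only$mutations$position < ref$mutated_region[2]))

  # genotypes are internally consistent
  expect_true(all(lib$mutations$ref_base !=
                    lib$mutations$alt_base))
  expect_true(all(lib$mutations$ref_base ==
                    ref$chars[lib$mutations$position + 1]))
  # same seed, same library
  lib2 <- generate_library(ref, 10000, seed = 2)
  expect_identical(lib, lib2)
})

test_that("fluorescence model algebra holds without noise", {
  ref <- default_reference()
  em <- enumerate_mutations(ref)
  bs_label <- em$label[1]
  model <- effect_model(
    basal = 3, srna_repression = 1,
    effects = data.frame(label = bs_label, expression_shift = 0,
                         regulation_loss = 1),
    noise_sd = 0)

  # library of one wild-type clone and one binding-site mutant
  lib <- list(clones = data.frame(clone_id = 1:2, n_mut = c(0L, 1L)),
              mutations = data.frame(
                clone_id = 2L, position = em$position[1],
                ref_base = em$ref_base[1], alt_base = em$alt_base[1],
                label = bs_label, stringsAsFactors = FALSE))
  class(lib) <- "clone_library"

  expect_equal(assign_fluorescence(lib, "control", model), c(3, 3))
  # wild type repressed by the sRNA; regulation-loss mutant fully escapes
  expect_equal(assign_fluorescence(lib, "srna", model), c(2, 3))
  # unknown mutations are silent
  model0 <- effect_model(basal = 3, srna_repression = 1, noise_sd = 0)
  expect_equal(assign_fluorescence(lib, "srna", model0), c(2, 2))
})

test_that("gating selects the right cells and subsamples pools", {
  cells <- data.frame(fluorescence = c(-2, -1, 0, 1, 2))
  gates <- list(all = c(-Inf, Inf), high = c(1, Inf), low = c(-Inf, -1))
  pools <- sort_cells(cells, gates, seed = 1)
  expect_equal(nrow(pools$all), 5)
  expect_equal(pools$high$fluorescence, c(1, 2))
  expect_equal(pools$low$fluorescence, -2)
  expect_length(intersect(rownames(pools$high), rownames(pools$low)), 0)

  sub <- sort_cells(cells, list(all = c(-Inf, Inf)),
                    target_cells_per_gate = 2, seed = 1)
  expect_equal(nrow(sub$all), 2)
  expect_warning(sort_cells(cells, list(empty = c(10, 20)), seed = 1),
                 "empty gate")

  # two-component mixture: high-gate occupancy matches the normal tail
  set.seed(21)
  n <- 20000
  comp <- rbinom(n, 1, 0.3)
  fl <- rnorm(n, mean = ifelse(comp == 1, 3, 2), sd = 0.3)
  cut <- 2.8
  pools <- sort_cells(data.frame(fluorescence = fl), list(high = c(cut, Inf)),
                      seed = 2)
  p_exp <- 0.3 * pnorm(cut, 3, 0.3, lower.tail = FALSE) +
    0.7 * pnorm(cut, 2, 0.3, lower.tail = FALSE)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(nrow(pools$high) / n - p_exp), 3 * se)
})

test_that("wild-type gates derived from the effect model are consistent", {
  model <- effect_model(basal = 3, srna_repression = 1, noise_sd = 0.3)
  g_ctrl <- make_gates(model, "control", p_tail = 0.05)
  g_srna <- make_gates(model, "srna", p_tail = 0.05)
  expect_equal(g_ctrl$high[1], qnorm(0.95, 3, 0.3))
  expect_equal(g_srna$high[1], qnorm(0.95, 2, 0.3))
  expect_true(g_ctrl$low[2] < g_ctrl$high[1])
  expect_equal(g_ctrl$all, c(-Inf, Inf))
})

test_that("sequencing geometry and error rates behave as configured", {
  ref <- default_reference()
  tmpl <- ref$sequence

  expect_error(sequence_pool(tmpl, 10, read_length = 90, seed = 1),
               "amplicon length")

  # read_length 100 on a 158-nt amplicon leaves a 42-base overlap
  sp <- sequence_pool(tmpl, 50, read_length = 100, quality_profile = Inf,
                      seed = 2)
  expect_equal(unique(nchar(sp$r1$seq)), 100L)
  expect_equal(sp$r1$seq[1], substr(tmpl, 1, 100))
  rc <- sortseqmap:::revcomp(sp$r2$seq[1])
  expect_equal(rc, substr(tmpl, 59, 158))

  # flat q30 profile: observed per-base mismatch rate ~0.001
  sp30 <- sequence_pool(tmpl, 400, read_length = 100, quality_profile = 30,
                        seed = 3)
  obs <- sum(sortseqmap:::seq_to_matrix(sp30$r1$seq) !=
               matrix(strsplit(substr(tmpl, 1, 100), "")[[1]],
                      nrow = 400, ncol = 100, byrow = TRUE))
  n_bases <- 400 * 100
  se <- sqrt(0.001 * 0.999 / n_bases)
  expect_lt(abs(obs / n_bases - 0.001), 3 * se)

  # qualities are phred+33 and reproducible byte-for-byte with the seed
  expect_true(all(utf8ToInt(sp30$r1$qual[1]) - 33 == 30))
  sp30b <- sequence_pool(tmpl, 400, read_length = 100, quality_profile = 30,
                         seed = 3)
  expect_identical(sp30, sp30b)
})

test_that("a simulated experiment writes a consistent, valid sample sheet", {
  ref <- default_reference()
  out <- file.path(tempfile(), "sim")
  sim <- simulate_experiment(ref, outdir = out,
                             plan = default_sample_plan(replicates = 2),
                             n_clones = 300, n_cells = 2000, n_reads = 400,
                             seed = 5)
  on.exit(unlink(dirname(out), recursive = TRUE))
  sheet <- read_sample_sheet(sim$sample_sheet_path)
  expect_equal(nrow(sheet), 8)
  expect_true(all(file.exists(sheet$fastq_1)))
  r1 <- read_fastq(sheet$fastq_1[1])
  expect_length(r1, 400)
  # truth table covers every read of every sample
  expect_equal(nrow(sim$truth_reads), 8 * 400)
  # duplicate condition rows are rejected
  bad_plan <- rbind(default_sample_plan(1), default_sample_plan(1))
  expect_error(simulate_experiment(ref, outdir = out, plan = bad_plan,
                                   n_clones = 10, n_cells = 10, n_reads = 10,
                                   seed = 1),
               "duplicate")
})
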