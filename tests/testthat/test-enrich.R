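test_that("median-of-ratios size factors recover depth ratios", {
  m <- matrix(c(5, 8, 12, 5, 8, 12), ncol = 2)
  expect_equal(size_factors(m), c(1, 1))
  m2 <- matrix(c(3, 7, 10, 6, 14, 20), ncol = 2)  # column 2 = 2 x column 1
  sf <- size_factors(m2)
  expect_equal(sf[2] / sf[1], 2)
  # single sample: factor 1
  expect_equal(size_factors(matrix(c(4, 9, 2), ncol = 1)), 1)
  # no all-positive row: warned fallback to column totals
  m3 <- matrix(c(0, 10, 5, 0), ncol = 2)
  expect_warning(sf3 <- size_factors(m3), "column-total")
  expect_equal(sf3[1] / sf3[2], 2)
})

test_that("dispersion estimation is conservative but recovers the truth", {
  cond <- rep(c("A", "B"), each = 3)
  # identical replicate counts: raw moment estimate is non-positive, clamped
  m <- matrix(rep(c(10, 20, 30, 40, 55, 70, 85, 100, 130, 160), 6), ncol = 6)
  d <- estimate_dispersions(m, cond, rep(1, 6))
  expect_true(all(attr(d, "raw") <= 0))
  expect_true(all(d >= 1e-8))

  # Poisson data: no overdispersion, final estimates near the floor
  set.seed(101)
  mu <- exp(rnorm(474, log(50), 0.8))
  mp <- sapply(c(0.8, 1, 1.25, 0.9, 1.1, 1), function(s) rpois(474, mu * s))
  dp <- estimate_dispersions(mp, cond, size_factors(mp))
  expect_lt(median(dp, na.rm = TRUE), 0.01)
  expect_gte(min(dp, na.rm = TRUE), 1e-8)

  # NB data with true dispersion 0.1 at high means: recovered within 2x
  mn <- sapply(rep(1, 6), function(s) rnbinom(300, mu = 500, size = 10))
  dn <- estimate_dispersions(mn, cond, rep(1, 6))
  expect_gt(median(dn, na.rm = TRUE), 0.05)
  expect_lt(median(dn, na.rm = TRUE), 0.2)

  # all-zero rows are excluded from testing
  mz <- rbind(matrix(5, 12, 6), 0)
  dz <- estimate_dispersions(mz, cond, rep(1, 6))
  expect_true(is.na(dz[13]))
  expect_error(estimate_dispersions(m, letters[1:6], rep(1, 6)),
               "replicates")
})

test_that("the conditioned NB exact test behaves like its definition", {
  # perfectly balanced counts under equal size factors: observed = mode
  expect_equal(nb_exact_test(c(10, 10, 10), c(10, 10, 10),
                             rep(1, 3), rep(1, 3), 0.1), 1)
  # symmetric in the two conditions
  p1 <- nb_exact_test(c(30, 25, 35), c(5, 8, 6), rep(1, 3), rep(1, 3), 0.05)
  p2 <- nb_exact_test(c(5, 8, 6), c(30, 25, 35), rep(1, 3), rep(1, 3), 0.05)
  expect_equal(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
  # no reads, no test
  expect_true(is.na(nb_exact_test(c(0, 0), c(0, 0), rep(1, 2), rep(1, 2),
                                  0.1)))
})

test_that("as dispersion vanishes the test reduces to the exact binomial", {
  # exhaustive over all splits of small totals, balanced and unbalanced
  # replicate structures (equal per-sample size factors)
  for (ks in c(1, 2, 3, 5, 9, 17, 33, 60)) {
    for (ka in 0:ks) {
      p_nb <- nb_exact_test(ka, ks - ka, 1, 1, alpha = 1e-12)
      p_bin <- binom.test(ka, ks, p = 0.5)$p.value
      expect_equal(p_nb, p_bin, tolerance = 1e-6)
    }
  }
  # unequal group sizes: conditional success probability sA/(sA+sB)
  for (ka in c(0, 7, 40, 120, 200)) {
    for (kb in c(0, 3, 61, 150)) {
      if (ka + kb == 0 || ka + kb > 200) next
      p_nb <- nb_exact_test(rep(ka / 2, 2), kb, c(1, 1), 1, alpha = 1e-12)
      p_bin <- binom.test(ka, ka + kb, p = 2 / 3)$p.value
      expect_equal(p_nb, p_bin, tolerance = 1e-6)
    }
  }
})

test_that("Benjamini-Hochberg adjustment is monotone and exceeds p", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.011)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("enrichment calls recover a strong spike and flip with the contrast", {
  set.seed(111)
  n <- 200
  mu <- rep(2000, n)
  cond <- rep(c("A", "B"), each = 3)
  cnt <- sapply(rep(1, 6), function(s) rnbinom(n, mu = mu, size = 1 / 0.05))
  cnt[7, 4:6] <- rnbinom(3, mu = 8 * 2000, size = 1 / 0.05)  # 8-fold spike
  rownames(cnt) <- paste0("m", seq_len(n))
  e <- enrichment_table(cnt, baseline = "A", contrast = "B",
                        condition_of = cond)
  expect_equal(e$call[7], "over")
  expect_lt(e$p_adjusted[7], 0.05)
  expect_gt(e$log2_ratio[7], 2)
  # invariants of the result table
  expect_true(all(e$p_adjusted >= e$p_value, na.rm = TRUE))
  sig <- !is.na(e$p_adjusted) & e$p_adjusted < 0.05
  expect_true(all(e$call[!sig] == "ns"))
  expect_true(all(sign(e$log2_ratio[e$call == "over"]) == 1))
  expect_true(all(sign(e$log2_ratio[e$call == "under"]) == -1))

  # swapped contrast flips over/under exactly
  e2 <- enrichment_table(cnt, baseline = "B", contrast = "A",
                         condition_of = cond)
  expect_equal(e$p_value, e2$p_value, tolerance = 1e-10)
  expect_equal(e2$call[e$call == "over"],
               rep("under", sum(e$call == "over")))
  expect_equal(e2$call[e$call == "under"],
               rep("over", sum(e$call == "under")))

  expect_error(enrichment_table(cnt, baseline = "A", contrast = "C",
                                condition_of = cond), "not present")
})

test_that("sorted pools can be contrasted against the unsorted baseline", {
  ref <- default_reference()
  model <- default_effect_model(ref)
  plan <- data.frame(
    plasmid = rep("srna", 6),
    gate = rep(c("high", "unsorted"), each = 3),
    replicate = rep(1:3, 2))
  out <- file.path(tempfile(), "uns")
  on.exit(unlink(dirname(out), recursive = TRUE))
  sim <- simulate_experiment(ref, model, outdir = out, plan = plan,
                             n_clones = 2000, n_cells = 20000,
                             n_reads = 8000, indel_read_prob = 0, seed = 117)
  sheet <- sim$sample_sheet
  reads <- lapply(seq_len(nrow(sheet)), function(i) {
    process_sample(sheet$fastq_1[i], sheet$fastq_2[i], ref)$reads
  })
  names(reads) <- sheet$sample_id
  mcm <- build_count_matrix(reads, ref, samples = sheet)
  e <- enrichment_table(mcm, baseline = "srna_unsorted",
                        contrast = "srna_high")
  loss <- model$effects$label[model$effects$regulation_loss == 1]
  hits <- e$mutation[e$call == "over"]
  expect_gt(mean(loss %in% hits), 0.5)
})
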