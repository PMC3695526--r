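make_reads <- function(seqs, quals_int) {
  read_set(paste0("r", seq_along(seqs)), seqs,
           vapply(quals_int, function(v) intToUtf8(v + 33L), character(1)))
}

test_that("quality trimming follows the running-sum rule", {
  # all qualities at/above the threshold: unchanged
  r <- make_reads("ACGTAC", list(rep(30L, 6)))
  expect_equal(trim_quality(r, 30)$seq, "ACGTAC")
  # all below: trimmed to empty
  r <- make_reads("ACGTAC", list(rep(10L, 6)))
  expect_equal(trim_quality(r, 30)$seq, "")
  # hand-evaluated mixed case: removing the last four bases maximizes the
  # running sum (scores 28,56,46,74,64,54 for 1..6 removed)
  r <- make_reads("ACGTAC", list(c(40L, 40L, 2L, 40L, 2L, 2L)))
  expect_equal(trim_quality(r, 30)$seq, "AC")

  # property: agrees with brute-force enumeration of every cut position
  set.seed(31)
  for (i in 1:200) {
    L <- sample(1:40, 1)
    q <- sample(0:45, L, replace = TRUE)
    r <- make_reads(paste(sample(c("A", "C", "G", "T"), L, TRUE),
                          collapse = ""), list(q))
    thr <- sample(10:40, 1)
    expect_equal(nchar(trim_quality(r, thr)$seq),
                 oracle_trim_keep_length(q, thr))
  }
})

test_that("pair merging picks the best ungapped overlap", {
  set.seed(32)
  amp <- paste(sample(c("A", "C", "G", "T"), 160, TRUE), collapse = "")
  r1s <- substr(amp, 1, 100)
  r2s <- sortseqmap:::revcomp(substr(amp, 61, 160))
  q100 <- intToUtf8(rep(30L + 33L, 100))
  mg <- merge_pairs(read_set("a", r1s, q100), read_set("a", r2s, q100))
  expect_length(mg$merged, 1)
  expect_equal(nchar(mg$merged$seq), 160L)
  expect_equal(attr(mg$merged, "overlap_length"), 40L)
  expect_equal(mg$merged$seq, amp)

  # best possible overlap 20 < min_overlap 30: rejected with reason
  amp2 <- paste(sample(c("A", "C", "G", "T"), 180, TRUE), collapse = "")
  mg2 <- merge_pairs(read_set("b", substr(amp2, 1, 100), q100),
                     read_set("b", sortseqmap:::revcomp(substr(amp2, 81, 180)),
                              q100),
                     min_overlap = 30)
  rej <- mg2$rejected
  expect_true(length(mg2$merged) == 0 ||
                nchar(mg2$merged$seq) != 180)  # true merge impossible
  # a guaranteed no-overlap case: reads shorter than min_overlap
  mg3 <- merge_pairs(read_set("c", "ACGTACGT", intToUtf8(rep(63L, 8))),
                     read_set("c", "ACGTACGT", intToUtf8(rep(63L, 8))),
                     min_overlap = 30)
  expect_equal(mg3$rejected$reason, "no_overlap")
})

test_that("overlap mismatches resolve to the higher-quality base", {
  set.seed(33)
  amp <- paste(sample(c("A", "C", "G", "T"), 160, TRUE), collapse = "")
  r1s <- substr(amp, 1, 100)
  truth_base <- substr(amp, 70, 70)
  wrong <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  r1bad <- r1s
  substr(r1bad, 70, 70) <- wrong
  r2s <- sortseqmap:::revcomp(substr(amp, 61, 160))
  q1 <- rep(10L, 100); q1[70] <- 10L      # low-quality wrong base on read 1
  q2 <- rep(40L, 100)                     # high-quality correct base on read 2
  mg <- merge_pairs(make_reads(r1bad, list(q1)),
                    make_reads(r2s, list(q2)),
                    max_mismatch_fraction = 0.1)
  expect_equal(substr(mg$merged$seq, 70, 70), truth_base)
  # merged quality at the mismatch is the max of the two observations
  expect_equal(utf8ToInt(substr(mg$merged$qual, 70, 70)) - 33L, 40L)

  # reversed qualities: wrong base now has the higher quality and wins
  q1hi <- rep(40L, 100)
  q2lo <- rep(10L, 100)
  mg2 <- merge_pairs(make_reads(r1bad, list(q1hi)),
                     make_reads(r2s, list(q2lo)),
                     max_mismatch_fraction = 0.1)
  expect_equal(substr(mg2$merged$seq, 70, 70), wrong)

  # mismatch fraction above the cap: rejected with reason
  manybad <- r1s
  for (p in 65:75) substr(manybad, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(amp, p, p))[1]
  mg3 <- merge_pairs(make_reads(manybad, list(rep(30L, 100))),
                     make_reads(r2s, list(rep(30L, 100))))
  expect_true("too_many_mismatches" %in% mg3$rejected$reason ||
                nchar(mg3$merged$seq) != 160)
})

test_that("error-free merging reconstructs every clone exactly", {
  ref <- default_reference()
  lib <- generate_library(ref, 40, seed = 41)
  tmpl <- sortseqmap:::clone_sequences(lib, ref)
  sp <- sequence_pool(tmpl, 200, quality_profile = Inf, seed = 42)
  mg <- merge_pairs(sp$r1, sp$r2)
  expect_equal(length(mg$merged), 200)
  expect_identical(mg$merged$seq,
                   unname(tmpl[sp$truth$template_index]))
})

test_that("the exact-length filter removes all indel-bearing reads", {
  ref <- default_reference()
  lib <- generate_library(ref, 50, seed = 51)
  tmpl <- sortseqmap:::clone_sequences(lib, ref)
  sp <- sequence_pool(tmpl, 1000, quality_profile = Inf,
                      indel_read_prob = 0.05, seed = 52)
  expect_gt(sum(sp$truth$has_indel), 0)
  mg <- merge_pairs(sp$r1, sp$r2)
  kept <- length_filter(mg$merged, ref$length)
  indel_ids <- sp$truth$read_id[sp$truth$has_indel]
  clean_ids <- sp$truth$read_id[!sp$truth$has_indel]
  # every indel read is gone; every substitution-only read survives
  expect_length(intersect(kept$id, indel_ids), 0)
  expect_setequal(kept$id, clean_ids)
  expect_true(all(nchar(kept$seq) == ref$length))
})

test_that("process_sample tallies QC and returns reference-length reads", {
  ref <- default_reference()
  lib <- generate_library(ref, 30, seed = 61)
  tmpl <- sortseqmap:::clone_sequences(lib, ref)
  sp <- sequence_pool(tmpl, 300, quality_profile = 30, indel_read_prob = 0.02,
                      seed = 62)
  d <- tempfile(); dir.create(d); on.exit(unlink(d, recursive = TRUE))
  f1 <- file.path(d, "s_R1.fastq.gz")  # gzip-transparent IO
  f2 <- file.path(d, "s_R2.fastq.gz")
  write_fastq(sp$r1, f1)
  write_fastq(sp$r2, f2)
  ps <- process_sample(f1, f2, ref)
  expect_equal(ps$qc$input_pairs, 300)
  expect_equal(ps$qc$merged,
               ps$qc$input_pairs - ps$qc$rejected_no_overlap -
                 ps$qc$rejected_too_many_mismatches)
  expect_equal(ps$qc$kept,
               ps$qc$merged - ps$qc$wrong_length - ps$qc$containing_n)
  expect_true(all(nchar(ps$reads$seq) == ref$length))
  expect_length(intersect(ps$reads$id,
                          sp$truth$read_id[sp$truth$has_indel]), 0)
})
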