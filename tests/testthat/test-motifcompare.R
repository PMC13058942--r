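# PWM-PWM comparison, per-peak statistics, consolidated alignments and
# presence maps.

test_that("a query identical to a database motif is a perfect plus-strand match", {
  set.seed(50)
  target <- random_pwm(10)
  db <- motif_database(list(hit = list(pwm = target),
                            d1 = list(pwm = random_pwm(10)),
                            d2 = list(pwm = random_pwm(12))))
  set.seed(51)
  res <- compare_pwms(target, db, n_shuffle = 300L)
  hit <- res[res$db_motif == "hit", ]
  expect_equal(hit$offset, 0L)
  expect_equal(hit$orientation, "+")
  expect_equal(hit$score, 1, tolerance = 1e-9)
  expect_equal(hit$p_value, min(res$p_value))
  expect_equal(res$e_value, res$p_value * 3)
})

test_that("a reverse-complement query matches in minus orientation with equal score", {
  set.seed(52)
  target <- random_pwm(9, conc = 0.5)
  rc <- motifboot:::pwm_revcomp(target)
  db <- motif_database(list(hit = list(pwm = target)))
  set.seed(53); fwd <- compare_pwms(target, db, n_shuffle = 200L)
  set.seed(53); rev <- compare_pwms(rc, db, n_shuffle = 200L)
  expect_equal(fwd$orientation, "+")
  expect_equal(rev$orientation, "-")
  expect_equal(rev$score, 1, tolerance = 1e-9)
  expect_equal(fwd$score, rev$score, tolerance = 1e-9)
})

test_that("E-values scale linearly with database size for a fixed pair", {
  set.seed(54)
  q <- random_pwm(8)
  m <- random_pwm(10)
  decoys <- lapply(1:9, function(i) list(pwm = random_pwm(10)))
  db1 <- motif_database(list(m = list(pwm = m)))
  db10 <- motif_database(c(list(m = list(pwm = m)),
                           setNames(decoys, paste0("x", 1:9))))
  set.seed(55); r1 <- compare_pwms(q, db1, n_shuffle = 200L)
  set.seed(55); r10 <- compare_pwms(q, db10, n_shuffle = 200L)
  expect_equal(r1$p_value[1], r10$p_value[r10$db_motif == "m"])
  expect_equal(r10$e_value[r10$db_motif == "m"], 10 * r1$e_value[1] / 1)
  expect_true(all(r10$e_value >= r10$p_value))
})

test_that("uniform (N-padded) columns leave the comparison well-defined", {
  q <- rbind(matrix(0.25, 3, 4), word_pwm("ACGTA"))
  colnames(q) <- c("A", "C", "G", "T")
  db <- motif_database(list(m = list(pwm = word_pwm("ACGTACGT"))))
  set.seed(56)
  res <- compare_pwms(q, db, n_shuffle = 100L)
  expect_true(is.finite(res$score))
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("comparison guards empty databases and narrow queries", {
  expect_error(compare_pwms(random_pwm(8), motif_database(list())), "empty")
  db <- motif_database(list(m = list(pwm = random_pwm(8))))
  expect_error(compare_pwms(random_pwm(4), db, min_overlap = 5L), "min_overlap")
})

test_that("per-peak statistics compute top-candidate rates and significant fractions", {
  peaks <- data.frame(peak_id = 1L, start = 10L, end = 30L,
                      height = 25L, support_frac = 1)
  # 25 runs: TF A best in 18, TF B best in 7
  rows <- lapply(1:25, function(r) {
    ea <- if (r <= 18) 1e-4 else 0.5
    eb <- if (r <= 18) 0.2 else 1e-3
    data.frame(db_motif = c("A", "B"), offset = 0L, orientation = "+",
               score = 0.9, p_value = c(ea, eb) / 2, e_value = c(ea, eb),
               run_id = r, motif_id = 1L, target_start = 12L, target_end = 20L)
  })
  stats <- aggregate_peak_stats(do.call(rbind, rows), peaks, n_runs = 25L)
  a <- stats[stats$tf == "A", ]
  expect_equal(a$top_candidate_freq, 0.72)
  expect_equal(a$n, 25L)
  expect_equal(a$frac_significant, 18 / 25)
  b <- stats[stats$tf == "B", ]
  expect_equal(b$top_candidate_freq, 0.28)
  # top-candidate mass sums to at most 1 per peak
  expect_lte(sum(stats$top_candidate_freq), 1)

  # all insignificant
  rows2 <- data.frame(db_motif = "A", offset = 0L, orientation = "+", score = 0.1,
                      p_value = 0.4, e_value = 0.8, run_id = 1:4, motif_id = 1L,
                      target_start = 12L, target_end = 20L)
  s2 <- aggregate_peak_stats(rows2, peaks, n_runs = 4L)
  expect_equal(s2$frac_significant, 0)

  # single run: quartiles collapse onto the value
  rows3 <- rows2[1, ]
  s3 <- aggregate_peak_stats(rows3, peaks, n_runs = 1L)
  expect_equal(s3$e_median, 0.8)
  expect_equal(s3$e_q1, s3$e_q3)

  # a peak no run matched yields an n = 0 placeholder row
  peaks2 <- rbind(peaks, data.frame(peak_id = 2L, start = 60L, end = 80L,
                                    height = 20L, support_frac = 0.8))
  s4 <- aggregate_peak_stats(rows2, peaks2, n_runs = 4L)
  empty <- s4[s4$peak_id == 2L, ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$tf))
})

# A compact scenario with exactly known geometry: one motif of width 8
# detected at target position 20 and at position 3 in three orthologs.
consolidation_fixture <- function(extra_run = FALSE) {
  set.seed(60)
  seqs <- c(tgt = random_dna(60), o1 = random_dna(60), o2 = random_dna(60),
            o3 = random_dna(60), o4 = random_dna(60))
  recs <- make_records(seqs, target = "tgt")
  inst <- data.frame(promoter_id = c("tgt", "o1", "o2", "o3"),
                     start = c(20L, 3L, 3L, 3L), strand = "+")
  runs <- list(list(new_motif(inst, recs, 8L)))
  if (extra_run) {
    # two more runs place o1's site at 10; majority should override the 3
    inst2 <- data.frame(promoter_id = c("tgt", "o1"), start = c(20L, 10L),
                        strand = "+")
    runs <- c(runs, list(list(new_motif(inst2, recs, 8L)),
                         list(new_motif(inst2, recs, 8L))))
  }
  peak <- data.frame(peak_id = 1L, start = 18L, end = 30L, height = 1L,
                     support_frac = 1)
  list(recs = recs, runs = runs, peak = peak)
}

test_that("consolidated alignments stack re-anchored segments at peak width", {
  fx <- consolidation_fixture()
  ca <- build_consolidated_alignment(fx$peak, fx$runs, fx$recs, "tgt")
  expect_equal(nrow(ca$rows), 4L)  # target + 3 detected orthologs, o4 absent
  expect_false("o4" %in% ca$rows$promoter_id)
  expect_true(all(nchar(ca$rows$segment) == 12L))
  expect_equal(ca$rows$segment[1],
               substr(fx$recs[["tgt"]]$sequence, 19L, 30L))
  # ortholog anchor: instance start 3 aligned to target instance start 20,
  # peak starts at 18 -> segment starts at 3 - (20 - 18) = 1
  o1 <- ca$rows[ca$rows$promoter_id == "o1", ]
  expect_equal(o1$offset, 1L)
  expect_equal(o1$segment, substr(fx$recs[["o1"]]$sequence, 2L, 13L))
})

test_that("conflicting anchors resolve by majority across runs", {
  fx <- consolidation_fixture(extra_run = TRUE)
  ca <- build_consolidated_alignment(fx$peak, fx$runs, fx$recs, "tgt")
  o1 <- ca$rows[ca$rows$promoter_id == "o1", ]
  expect_equal(o1$offset, 8L)  # 10 - (20 - 18), the 2-vote anchor beats the 1-vote
})

test_that("out-of-bounds consolidated segments are N-padded and flagged", {
  set.seed(61)
  recs <- make_records(c(tgt = random_dna(60), o1 = random_dna(60)), target = "tgt")
  inst <- data.frame(promoter_id = c("tgt", "o1"), start = c(20L, 0L), strand = "+")
  runs <- list(list(new_motif(inst, recs, 8L)))
  peak <- data.frame(peak_id = 1L, start = 15L, end = 30L, height = 1L,
                     support_frac = 1)
  ca <- build_consolidated_alignment(peak, runs, recs, "tgt")
  o1 <- ca$rows[ca$rows$promoter_id == "o1", ]
  expect_true(o1$padded)
  expect_equal(substr(o1$segment, 1, 5), "NNNNN")  # anchor 0 - 5 = -5
  expect_equal(nchar(o1$segment), 15L)
})

test_that("a relative-minus instance is reverse-complemented into the stack", {
  set.seed(62)
  tgt <- random_dna(60)
  core <- substr(tgt, 21L, 28L)
  o1 <- paste0(random_dna(10), revcomp(core), random_dna(42))
  recs <- make_records(c(tgt = tgt, o1 = o1), target = "tgt")
  inst <- data.frame(promoter_id = c("tgt", "o1"), start = c(20L, 10L),
                     strand = c("+", "-"))
  runs <- list(list(new_motif(inst, recs, 8L)))
  peak <- data.frame(peak_id = 1L, start = 20L, end = 28L, height = 1L,
                     support_frac = 1)
  ca <- build_consolidated_alignment(peak, runs, recs, "tgt")
  o1row <- ca$rows[ca$rows$promoter_id == "o1", ]
  expect_equal(o1row$strand, "-")
  expect_equal(o1row$segment, core)  # RC of the minus-strand site = target core
})

test_that("scoring a consolidated alignment recovers its source motif", {
  set.seed(63)
  word <- "TTGACGTCAAGG"
  seqs <- setNames(rep(paste0(strrep("A", 10), word, strrep("C", 10)), 4),
                   c("tgt", "o1", "o2", "o3"))
  recs <- make_records(seqs, target = "tgt")
  inst <- data.frame(promoter_id = names(seqs), start = 10L, strand = "+")
  runs <- list(list(new_motif(inst, recs, 12L)))
  peak <- data.frame(peak_id = 1L, start = 10L, end = 22L, height = 1L,
                     support_frac = 1)
  ca <- build_consolidated_alignment(peak, runs, recs, "tgt")
  db <- motif_database(list(truth = list(pwm = word_pwm(word)),
                            decoy = list(pwm = word_pwm("ACACACACACAC"))))
  set.seed(64)
  sc <- score_consolidated(ca, db, n_shuffle = 200L)
  expect_equal(sc$db_motif[1], "truth")
  ca1 <- ca; ca1$rows <- ca1$rows[1, , drop = FALSE]
  expect_error(score_consolidated(ca1, db), ">= 2 rows")
})

test_that("presence maps distinguish detection, absence, and unsampled taxa", {
  fx <- consolidation_fixture()
  pm <- presence_map(fx$peak, fx$runs, fx$recs,
                     sampled_ids = c("o1", "o2", "o3"))
  expect_true(pm$present[pm$promoter_id == "tgt"])  # target always present
  expect_true(all(pm$present[pm$promoter_id %in% c("o1", "o2", "o3")]))
  o4 <- pm[pm$promoter_id == "o4", ]
  expect_false(o4$present)
  expect_false(o4$sampled)  # never entered a subset: absence of evidence
})
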