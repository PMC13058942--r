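# De novo finders and the voting combination.

test_that("information content behaves at the uniform and deterministic extremes", {
  W <- 7L
  expect_equal(pwm_ic(matrix(0.25, W, 4)), 0)
  det <- matrix(0, W, 4); det[cbind(1:W, rep(1:4, length.out = W))] <- 1
  # 0 * log(0) terms are dropped by convention
  det[det == 0] <- 1e-300
  expect_equal(pwm_ic(det), 2 * W, tolerance = 1e-6)
})

test_that("the Gibbs finder recovers an identical planted word", {
  set.seed(100)
  word <- "TTGATCAA"
  seqs <- vapply(1:10, function(i) {
    s <- strsplit(random_dna(100), "")[[1]]
    p <- sample(100 - 8 + 1, 1)
    s[p:(p + 7)] <- strsplit(word, "")[[1]]
    attr(s, "p") <- p
    paste(s, collapse = "")
  }, character(1))
  # recompute the planted positions from the sequences themselves
  planted <- vapply(seqs, function(s) regexpr(word, s, fixed = TRUE)[1], integer(1))
  recs <- make_records(seqs)
  set.seed(101)
  fr <- gibbs_finder(recs, 8L)
  expect_s3_class(fr, "finder_result")
  m <- fr$motifs[[1]]
  found <- m$instances$start[match(promoter_ids(recs), m$instances$promoter_id)]
  n_hit <- sum(found == planted - 1L)  # planted is 1-based
  expect_gte(n_hit, 9L)
})

test_that("the Gibbs finder is deterministic under a seed and validates width", {
  set.seed(3)
  recs <- make_records(vapply(1:5, function(i) random_dna(60), character(1)))
  set.seed(7); r1 <- gibbs_finder(recs, 8L)
  set.seed(7); r2 <- gibbs_finder(recs, 8L)
  expect_identical(r1$motifs[[1]]$instances, r2$motifs[[1]]$instances)
  short <- make_records(c(a = random_dna(60), b = random_dna(60), c = "ACGTA"))
  expect_error(gibbs_finder(short, 8L), "'c'.*shorter")
})

test_that("the word finder ranks a fully supported planted word first", {
  set.seed(15)
  word <- "GGATCCGT"
  seqs <- vapply(1:8, function(i) {
    s <- random_dna(80)
    p <- sample(80 - 8, 1)
    paste0(substr(s, 1, p), word, substr(s, p + 9, 80))
  }, character(1))
  recs <- make_records(seqs)
  fr <- consensus_finder(recs, 8L, cfg = finder_config(max_mismatch = 0L))
  m <- fr$motifs[[1]]
  expect_true(m$word %in% c(word, revcomp(word)))
  expect_equal(m$support, 8L)
  expect_equal(nrow(m$instances), 8L)
})

test_that("word-finder support equals brute-force counting at zero mismatches", {
  set.seed(16)
  for (rep in 1:5) {
    seqs <- vapply(1:6, function(i) random_dna(60), character(1))
    recs <- make_records(seqs)
    fr <- consensus_finder(recs, 5L,
                           cfg = finder_config(max_mismatch = 0L, n_best = 5L))
    for (m in fr$motifs) {
      o <- oracle_word_stats(seqs, m$word)
      expect_equal(m$support, o$support)
      expect_equal(m$occurrences, o$occurrences)
    }
    # and nothing with higher support was missed
    if (length(fr$motifs)) {
      best <- fr$motifs[[1]]
      all_words <- unique(unlist(lapply(seqs, function(s)
        vapply(seq_len(nchar(s) - 4L), function(p) substr(s, p, p + 4L), character(1)))))
      sup <- vapply(all_words, function(w) oracle_word_stats(seqs, w)$support, integer(1))
      expect_gte(best$support, max(sup))
    }
  }
})

test_that("word-finder ties break lexicographically and the width guard holds", {
  backbone <- paste(rep("T", 30), collapse = "")
  # both CAGGG and GAGGG occur once per sequence; identical support and
  # occurrence counts, so the lexicographically smaller word must win
  seqs <- c(paste0(backbone, "CAGGG", backbone, "GAGGG", backbone),
            paste0(backbone, "GAGGG", backbone, "CAGGG", backbone))
  recs <- make_records(seqs)
  fr <- consensus_finder(recs, 5L,
                         cfg = finder_config(max_mismatch = 0L, n_best = 50L))
  words <- vapply(fr$motifs, `[[`, character(1), "word")
  expect_true(which(words == "CAGGG") < which(words == "GAGGG"))
  expect_error(consensus_finder(recs, 13L), "enumeration guard")
})

make_fr <- function(name, inst_list, recs, width) {
  motifs <- lapply(inst_list, function(inst) new_motif(inst, recs, width))
  structure(list(finder_name = name, motifs = motifs), class = "finder_result")
}

test_that("voting merges identical reports and honors the quorum", {
  set.seed(20)
  recs <- make_records(vapply(1:4, function(i) random_dna(50), character(1)))
  inst <- data.frame(promoter_id = c("p1", "p2", "p3"), start = c(5L, 9L, 30L),
                     strand = "+")
  fr1 <- make_fr("f1", list(inst), recs, 8L)
  fr2 <- make_fr("f2", list(inst), recs, 8L)
  voted <- vote_combine(list(fr1, fr2), recs)
  expect_length(voted, 1L)
  expect_equal(voted[[1]]$instances[order(voted[[1]]$instances$promoter_id), ],
               inst, ignore_attr = TRUE)

  # a single finder: quorum auto-lowers to 1 and motifs pass through
  solo <- vote_combine(list(fr1), recs, quorum = 2L)
  expect_length(solo, 1L)
  expect_equal(sort(solo[[1]]$instances$start), sort(inst$start))
})

test_that("insufficient overlap keeps finder reports apart", {
  set.seed(21)
  recs <- make_records(vapply(1:3, function(i) random_dna(50), character(1)))
  a <- data.frame(promoter_id = c("p1", "p2"), start = c(10L, 10L), strand = "+")
  b <- data.frame(promoter_id = c("p1", "p2"), start = c(15L, 15L), strand = "+")
  fr1 <- make_fr("f1", list(a), recs, 8L)
  fr2 <- make_fr("f2", list(b), recs, 8L)
  # overlap 3 bp of width 8 = 0.375 < 0.5 -> two components, neither at quorum
  expect_length(vote_combine(list(fr1, fr2), recs, quorum = 2L), 0L)
  # at 4 bp (= 0.5) they merge
  b2 <- data.frame(promoter_id = c("p1", "p2"), start = c(14L, 14L), strand = "+")
  fr2b <- make_fr("f2", list(b2), recs, 8L)
  expect_length(vote_combine(list(fr1, fr2b), recs, quorum = 2L), 1L)
})

test_that("voting never fabricates instances on unseen promoters or strands", {
  set.seed(22)
  recs <- make_records(vapply(1:6, function(i) random_dna(60), character(1)))
  for (rep in 1:10) {
    mk <- function() {
      n <- sample(2:4, 1)
      pid <- sample(promoter_ids(recs), n)
      data.frame(promoter_id = pid,
                 start = sample(0:50, n, replace = TRUE),
                 strand = sample(c("+", "-"), n, replace = TRUE))
    }
    fr1 <- make_fr("f1", list(mk(), mk()), recs, 8L)
    fr2 <- make_fr("f2", list(mk()), recs, 8L)
    voted <- vote_combine(list(fr1, fr2), recs, quorum = 1L)
    input <- do.call(rbind, c(lapply(fr1$motifs, function(m) m$instances),
                              lapply(fr2$motifs, function(m) m$instances)))
    for (v in voted) for (r in seq_len(nrow(v$instances))) {
      vi <- v$instances[r, ]
      same <- input[input$promoter_id == vi$promoter_id & input$strand == vi$strand, ]
      overlaps <- any(pmin(same$start + 8L, vi$start + v$width) -
                      pmax(same$start, vi$start) > 0)
      expect_true(overlaps)
    }
  }
})

test_that("discover_motifs pools voted motifs across widths", {
  sim <- planted_sequences(8, 120, word_pwm("TTGACGTCAA"), seed = 30)
  recs <- make_records(sim$seqs)
  set.seed(30)
  motifs <- discover_motifs(recs, widths = c(8L, 10L), cfg = finder_config(restarts = 2L))
  expect_gte(length(motifs), 1L)
  expect_true(all(vapply(motifs, function(m) m$width %in% c(8L, 10L), logical(1))))
  # the top motif should sit on the implant in most sequences
  top <- motifs[[which.max(vapply(motifs, `[[`, numeric(1), "score"))]]
  hits <- abs(top$instances$start -
              sim$starts[match(top$instances$promoter_id, names(sim$seqs))])
  expect_gte(mean(hits <= 3), 0.7)
})
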