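# Format readers/writers: FASTA, Newick, MEME minimal, BedGraph.

test_that("FASTA parsing uppercases, round-trips, and rejects bad characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "acgt"), f)
  recs <- read_promoter_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "p1")
  expect_equal(recs[[1]]$sequence, "ACGT")

  set.seed(42)
  orig <- make_records(c(a = random_dna(80), b = random_dna(120), c = "ACGTN"))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_promoter_fasta(orig, f2)
  back <- read_promoter_fasta(f2)
  expect_equal(promoter_ids(back), promoter_ids(orig))
  expect_equal(vapply(back, `[[`, character(1), "sequence"),
               vapply(orig, `[[`, character(1), "sequence"))

  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACXT"), f3)
  expect_error(read_promoter_fasta(f3), "p1.*position 3")
})

test_that("empty FASTA yields an empty set and a duplicate id errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_length(read_promoter_fasta(f), 0L)
  expect_error(
    promoter_set(list(promoter_record("x", "ACGT"), promoter_record("x", "TTTT"))),
    "duplicate")
})

test_that("Newick parsing preserves structure and rejects malformed input", {
  t2 <- read_newick_text("(a:0.1,b:0.2);")
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_error(read_newick_text("(a:0.1,b:0.2"), "unbalanced|parse")
  expect_error(read_newick_text("(a:0.1,b:0.2);(x"), "unbalanced|parse")
  expect_error(read_newick_text("(a:0.1,(a:0.1,c:0.1):0.05);"), "duplicate")
  expect_error(read_newick_text("(a,b);"), "branch length")

  t3 <- read_newick_text("(a:0.1,(b:0.1,c:0.1):0.05);")
  expect_equal(length(t3$tip.label), 3L)
  # the internal edge of 0.05 shows up in all paths through it
  expect_equal(patristic_distance(t3, "a", "c"), 0.25)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t3, f)
  back <- read_newick(f)
  expect_equal(sort(back$tip.label), sort(t3$tip.label))
  expect_equal(patristic_distance(back, "b", "c"), patristic_distance(t3, "b", "c"))
})

test_that("MEME minimal motifs load with defaults and validation", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(meme_text_one_motif(), f)
  db <- read_meme_motifs(f)
  expect_length(db$motifs, 1L)
  expect_equal(nrow(db$motifs$toy1$pwm), 6L)
  expect_equal(db$motifs$toy1$nsites, 20L)
  # no Background block -> uniform
  expect_equal(db$background, rep(0.25, 4))

  dup <- c(meme_text_one_motif(), "", meme_text_one_motif()[5:12])
  f2 <- withr::local_tempfile(fileext = ".meme")
  writeLines(dup, f2)
  expect_error(read_meme_motifs(f2), "duplicate")

  bad <- meme_text_one_motif()
  bad[7] <- "0.8 0.1 0.05 0.2"  # sums to 1.15
  f3 <- withr::local_tempfile(fileext = ".meme")
  writeLines(bad, f3)
  expect_error(read_meme_motifs(f3), "sums to")

  noalpha <- meme_text_one_motif()[-3]
  f4 <- withr::local_tempfile(fileext = ".meme")
  writeLines(noalpha, f4)
  expect_error(read_meme_motifs(f4), "ALPHABET")
})

test_that("MEME write/read round-trips a database", {
  set.seed(7)
  db <- motif_database(list(m1 = list(pwm = random_pwm(8), nsites = 12L),
                            m2 = list(pwm = random_pwm(15), nsites = 30L)),
                       background = c(0.3, 0.2, 0.2, 0.3))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(db, f)
  back <- read_meme_motifs(f)
  expect_equal(names(back$motifs), c("m1", "m2"))
  expect_equal(back$background, db$background, tolerance = 1e-4)
  expect_equal(back$motifs$m1$pwm, db$motifs$m1$pwm, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(back$motifs$m2$nsites, 30L)
})

hist_obj <- function(counts, id = "tgt", n_runs = max(counts, 1L)) {
  accumulate_histogram(list(), length(counts), n_runs, id) |>
    (\(h) { h$counts <- as.integer(counts); h })()
}

read_bedgraph_lines <- function(path) {
  ln <- readLines(path)
  ln[!grepl("^track", ln)]
}

test_that("BedGraph merges equal-value runs, omits zeros, applies offsets", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(hist_obj(c(0, 0, 3, 3, 1)), f, chrom = "chr", chrom_offset = 100L)
  expect_equal(read_bedgraph_lines(f), c("chr\t102\t104\t3", "chr\t104\t105\t1"))

  write_bedgraph(hist_obj(c(0, 0, 0)), f, chrom = "chr")
  expect_length(read_bedgraph_lines(f), 0L)

  write_bedgraph(hist_obj(7L), f, chrom = "chr")
  expect_equal(read_bedgraph_lines(f), "chr\t0\t1\t7")

  expect_error(write_bedgraph(hist_obj(integer(0)), f, "chr"), "zero-length")
})

test_that("BedGraph intervals are disjoint, sorted, and conserve coverage", {
  set.seed(11)
  for (rep in 1:20) {
    counts <- sample(0:5, sample(5:80, 1), replace = TRUE)
    f <- withr::local_tempfile(fileext = ".bedgraph")
    write_bedgraph(hist_obj(counts), f, chrom = "c")
    ln <- read_bedgraph_lines(f)
    if (!length(ln)) { expect_equal(sum(counts), 0L); next }
    parts <- do.call(rbind, strsplit(ln, "\t"))
    start <- as.integer(parts[, 2]); end <- as.integer(parts[, 3])
    val <- as.numeric(parts[, 4])
    expect_true(all(end > start))
    expect_true(all(diff(start) > 0))
    expect_true(all(start[-1] >= end[-length(end)]))
    expect_equal(sum((end - start) * val), sum(counts))
  }
})
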