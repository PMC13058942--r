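# Fixtures are built in code at test time; nothing is stored on disk.

random_dna <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# Promoter set from a character vector of sequences (named or auto-named).
make_records <- function(seqs, target = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("p", seq_along(seqs))
  promoter_set(lapply(names(seqs), function(id)
    promoter_record(id, seqs[[id]], is_target = identical(id, target))))
}

# Synthetic stratified pool: a target plus subgroup members whose distances
# to the target fall in the three default bins; other pairwise distances are
# drawn well above the default diversity threshold.
make_pool <- function(sizes = c(30L, 30L, 60L), seed = 1L, target_id = "t") {
  set.seed(seed)
  ids <- c(target_id,
           sprintf("a%02d", seq_len(sizes[1])),
           sprintf("b%02d", seq_len(sizes[2])),
           sprintf("c%02d", seq_len(sizes[3])))
  n <- length(ids)
  d <- matrix(runif(n * n, 0.1, 0.7), n, n)
  d[upper.tri(d)] <- t(d)[upper.tri(d)]
  diag(d) <- 0
  to_target <- c(runif(sizes[1], 0.06, 0.30),
                 runif(sizes[2], 0.32, 0.54),
                 runif(sizes[3], 0.56, 0.72))
  d[1, -1] <- to_target; d[-1, 1] <- to_target
  dm <- distance_matrix(ids, d)
  list(dm = dm, groups = stratify(dm, target_id), target_id = target_id)
}

# Sequences with a site drawn from `pwm` implanted at a random position each.
planted_sequences <- function(n_seq, len, pwm, seed = 1L) {
  set.seed(seed)
  W <- nrow(pwm)
  starts <- sample.int(len - W + 1L, n_seq, replace = TRUE) - 1L
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- strsplit(random_dna(len), "")[[1]]
    site <- vapply(seq_len(W), function(w)
      sample(c("A", "C", "G", "T"), 1L, prob = pwm[w, ]), character(1))
    s[(starts[i] + 1L):(starts[i] + W)] <- site
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("p", seq_len(n_seq))
  list(seqs = seqs, starts = starts)
}

# Independent brute-force word statistics: overlap-aware occurrence counting
# on both strands, N-containing windows excluded.
oracle_word_stats <- function(seqs, word) {
  W <- nchar(word)
  rc <- revcomp(word)
  support <- 0L; occurrences <- 0L
  for (s in seqs) {
    hits <- 0L
    for (p in seq_len(nchar(s) - W + 1L)) {
      win <- substr(s, p, p + W - 1L)
      if (grepl("N", win, fixed = TRUE)) next
      if (win == word) hits <- hits + 1L
      if (win == rc) hits <- hits + 1L
    }
    occurrences <- occurrences + hits
    if (hits > 0L) support <- support + 1L
  }
  list(support = support, occurrences = occurrences)
}

# A sharp PWM whose consensus is the given word.
word_pwm <- function(word, dominance = 0.91) {
  ch <- strsplit(word, "")[[1]]
  pwm <- matrix((1 - dominance) / 3, nrow = length(ch), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(ch)) pwm[i, ch[i]] <- dominance
  pwm
}

# Random row-stochastic PWM (Dirichlet-ish via normalized gamma draws).
random_pwm <- function(width, conc = 1) {
  m <- matrix(rgamma(width * 4, shape = conc), nrow = width)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  m
}

meme_text_one_motif <- function() {
  c("MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF toy1",
    "letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0",
    "0.8 0.1 0.05 0.05",
    "0.1 0.8 0.05 0.05",
    "0.05 0.05 0.8 0.1",
    "0.05 0.05 0.1 0.8",
    "0.25 0.25 0.25 0.25",
    "0.97 0.01 0.01 0.01")
}
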