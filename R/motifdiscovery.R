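# De novo motif discovery: built-in finders behind a pluggable adapter
# interface, and the consensus ("voting") combination of their results.

#' Finder configuration
#'
#' @param max_iters maximum Gibbs sweeps per restart.
#' @param patience sweeps without information-content improvement before a
#'   restart stops.
#' @param restarts independent Gibbs restarts; the best configuration wins.
#' @param pseudocount added per PWM cell when normalizing counts.
#' @param background length-4 base frequency vector (uniform by default).
#' @param max_mismatch Hamming tolerance of the word-enumeration finder.
#' @param n_best motifs returned per finder invocation.
#' @return object of class `finder_config`.
#' @export
finder_config <- function(max_iters = 500L, patience = 50L, restarts = 5L,
                          pseudocount = 0.5, background = rep(0.25, 4),
                          max_mismatch = 1L, n_best = 1L) {
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6,
            pseudocount > 0)
  structure(list(max_iters = as.integer(max_iters), patience = as.integer(patience),
                 restarts = as.integer(restarts), pseudocount = pseudocount,
                 background = background, max_mismatch = as.integer(max_mismatch),
                 n_best = as.integer(n_best)),
            class = "finder_config")
}

# Extract the W-mer of an instance, reverse-complemented for minus strand.
instance_segment <- function(records, promoter_id, start, strand, width) {
  s <- substr(records[[promoter_id]]$sequence, start + 1L, start + width)
  if (strand == "-") revcomp(s) else s
}

#' Build a motif object from its instance list
#'
#' Counts are accumulated over the strand-adjusted instance segments (an N
#' base contributes 0.25 to every base), the PWM adds `pseudocount` per cell
#' and renormalizes rows, and the score is the information content in bits,
#' `IC = sum_w sum_b f_wb log2(f_wb / q_b)`.
#'
#' @param instances data frame with columns `promoter_id`, `start` (0-based),
#'   `strand` ("+"/"-").
#' @param records the `promoter_set` the instances index into.
#' @param width motif width W.
#' @param pseudocount per-cell pseudocount.
#' @param background length-4 base frequency vector.
#' @return object of class `motif`: `width`, `counts`, `pwm`, `instances`,
#'   `score`, `consensus`.
#' @export
new_motif <- function(instances, records, width, pseudocount = 0.5,
                      background = rep(0.25, 4)) {
  stopifnot(nrow(instances) >= 1L)
  counts <- matrix(0, nrow = width, ncol = 4, dimnames = list(NULL, DNA_BASES))
  for (r in seq_len(nrow(instances))) {
    pid <- instances$promoter_id[r]
    L <- nchar(records[[pid]]$sequence)
    if (instances$start[r] < 0 || instances$start[r] + width > L)
      stopf("instance on '%s' at %d exceeds promoter bounds (length %d, width %d)",
            pid, instances$start[r], L, width)
    seg <- strsplit(instance_segment(records, pid, instances$start[r],
                                     instances$strand[r], width), "")[[1]]
    for (w in seq_len(width)) {
      if (seg[w] == "N") counts[w, ] <- counts[w, ] + 0.25
      else counts[w, seg[w]] <- counts[w, seg[w]] + 1
    }
  }
  pwm <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  structure(list(width = width, counts = counts, pwm = pwm,
                 instances = instances,
                 score = pwm_ic(pwm, background),
                 consensus = paste(DNA_BASES[max.col(pwm)], collapse = "")),
            class = "motif")
}

#' Information content of a PWM in bits
#'
#' @param pwm W x 4 row-stochastic matrix.
#' @param background length-4 base frequency vector.
#' @return total IC over columns; 0 for a uniform PWM, 2W for a
#'   deterministic PWM under uniform background.
#' @export
pwm_ic <- function(pwm, background = rep(0.25, 4)) {
  sum(pwm * log2(sweep(pwm, 2, background, "/")))
}

finder_result <- function(finder_name, motifs) {
  ord <- order(vapply(motifs, `[[`, numeric(1), "score"), decreasing = TRUE)
  structure(list(finder_name = finder_name, motifs = motifs[ord]),
            class = "finder_result")
}

#' Gibbs site-sampler motif finder
#'
#' One-occurrence-per-sequence Gibbs sampling: site positions start uniform
#' at random; each sweep holds out one sequence, builds the PWM from the
#' remaining sites, and resamples the held-out site proportional to the
#' PWM/background likelihood ratio over both strands. The
#' best-information-content configuration across restarts is returned.
#' Deterministic under `set.seed()`.
#'
#' @param records a `promoter_set` with at least 3 sequences.
#' @param width motif width W; every sequence must be at least this long.
#' @param cfg a [finder_config()].
#' @return a `finder_result` with one motif.
#' @export
gibbs_finder <- function(records, width, cfg = finder_config()) {
  if (length(records) < 3L) stopf("gibbs_finder needs >= 3 sequences")
  ids <- promoter_ids(records)
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1))
  short <- which(lens < width)
  if (length(short))
    stopf("sequence '%s' (length %d) is shorter than motif width %d",
          ids[short[1]], lens[short[1]], width)
  enc <- lapply(records, function(r) encode_dna(r$sequence))
  res <- gibbs_sample_cpp(enc, as.integer(width), cfg$background,
                          cfg$max_iters, cfg$patience, cfg$restarts,
                          cfg$pseudocount)
  inst <- data.frame(promoter_id = ids,
                     start = res$positions,
                     strand = ifelse(res$strands == 0L, "+", "-"),
                     stringsAsFactors = FALSE)
  finder_result("gibbs", list(new_motif(inst, records, width,
                                        cfg$pseudocount, cfg$background)))
}

#' Word-enumeration motif finder
#'
#' Enumerates every W-mer present in the data on either strand, counts the
#' sequences containing an occurrence within Hamming distance
#' `max_mismatch`, and ranks candidate words by support, then total
#' occurrences, then lexicographic order. The motif is built from the best
#' occurrence per supporting sequence.
#'
#' @param records a `promoter_set` with at least 2 sequences.
#' @param width motif width W (at most 12; enumeration guard).
#' @param cfg a [finder_config()]; uses `max_mismatch` and `n_best`.
#' @return a `finder_result`; empty motif list when no word is supported by
#'   at least 2 sequences.
#' @export
consensus_finder <- function(records, width, cfg = finder_config()) {
  if (length(records) < 2L) stopf("consensus_finder needs >= 2 sequences")
  if (width > 12L) stopf("consensus_finder width %d exceeds enumeration guard (12)", width)
  ids <- promoter_ids(records)
  enc <- lapply(records, function(r) encode_dna(r$sequence))
  res <- consensus_count_cpp(enc, as.integer(width), cfg$max_mismatch, cfg$n_best)
  motifs <- lapply(res, function(cand) {
    inst <- data.frame(promoter_id = ids[cand$seq_idx + 1L],
                       start = cand$pos,
                       strand = ifelse(cand$strand == 0L, "+", "-"),
                       stringsAsFactors = FALSE)
    m <- new_motif(inst, records, width, cfg$pseudocount, cfg$background)
    m$word <- cand$word
    m$support <- cand$support
    m$occurrences <- cand$occurrences
    m
  })
  finder_result("consensus", motifs)
}

# Registry mapping finder names to functions; external adapters obeying the
# same contract (records, width, cfg) -> finder_result can be passed to
# discover_motifs() directly.
builtin_finders <- function() {
  list(gibbs = gibbs_finder, consensus = consensus_finder)
}

#' Combine finder results by voting
#'
#' Instances from different finders are grouped when, on the same promoter
#' and strand, their intervals overlap by at least `overlap_frac` of the
#' shorter width. Groups are linked into motif-level components through
#' their source motifs; a component is kept when it contains instances from
#' at least `quorum` distinct finders (automatically lowered to 1 when only
#' one finder ran). Each kept component yields one merged motif rebuilt from
#' its instance groups: per group the consensus interval is the intersection
#' extended to the component's modal width.
#'
#' @param results list of `finder_result`s from one subset.
#' @param records the `promoter_set` the instances index into.
#' @param quorum minimum number of distinct supporting finders.
#' @param overlap_frac minimum overlap as a fraction of the shorter width.
#' @param cfg a [finder_config()] (pseudocount/background for rebuilding).
#' @return list of merged `motif` objects ranked by information content.
#' @export
vote_combine <- function(results, records, quorum = 2L, overlap_frac = 0.5,
                         cfg = finder_config()) {
  stopifnot(length(results) >= 1L)
  n_finders <- length(unique(vapply(results, `[[`, character(1), "finder_name")))
  quorum <- min(quorum, n_finders)

  inst <- do.call(rbind, unlist(lapply(results, function(fr) {
    lapply(seq_along(fr$motifs), function(mi) {
      m <- fr$motifs[[mi]]
      if (nrow(m$instances) == 0L) return(NULL)
      data.frame(finder = fr$finder_name,
                 source = paste0(fr$finder_name, "#", mi),
                 promoter_id = m$instances$promoter_id,
                 start = m$instances$start,
                 end = m$instances$start + m$width,
                 strand = m$instances$strand,
                 width = m$width,
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  if (is.null(inst) || nrow(inst) == 0L) return(list())

  # Union-find over instances: link overlapping instances on the same
  # promoter and strand, then link instances sharing a source motif.
  parent <- seq_len(nrow(inst))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }

  key <- paste(inst$promoter_id, inst$strand)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-1L]) for (b in seq_len(a - 1L)) {
      i <- idx[a]; j <- idx[b]
      ov <- min(inst$end[i], inst$end[j]) - max(inst$start[i], inst$start[j])
      if (ov >= overlap_frac * min(inst$width[i], inst$width[j])) union_(i, j)
    }
  }
  # instance-group ids before source linking: these are the site-level groups
  site_group <- vapply(seq_len(nrow(inst)), find, integer(1))
  for (s in unique(inst$source)) {
    idx <- which(inst$source == s)
    for (a in seq_along(idx)[-1L]) union_(idx[1L], idx[a])
  }
  comp <- vapply(seq_len(nrow(inst)), find, integer(1))

  motifs <- list()
  for (cid in unique(comp)) {
    rows <- inst[comp == cid, , drop = FALSE]
    if (length(unique(rows$finder)) < quorum) next
    # modal width of the component (ties -> smaller)
    wt <- table(rows$width)
    W <- as.integer(names(wt)[which.max(wt)])
    sg <- site_group[comp == cid]
    merged <- do.call(rbind, lapply(unique(sg), function(g) {
      grp <- rows[sg == g, , drop = FALSE]
      is0 <- max(grp$start); ie0 <- min(grp$end)
      center <- if (ie0 > is0) floor((is0 + ie0) / 2) else
        floor(stats::median((grp$start + grp$end) / 2))
      L <- nchar(records[[grp$promoter_id[1]]]$sequence)
      start <- max(0L, min(L - W, center - W %/% 2L))
      st <- names(sort(table(grp$strand), decreasing = TRUE))[1]
      data.frame(promoter_id = grp$promoter_id[1], start = start, strand = st,
                 stringsAsFactors = FALSE)
    }))
    m <- new_motif(merged, records, W, cfg$pseudocount, cfg$background)
    m$finders <- sort(unique(rows$finder))
    motifs[[length(motifs) + 1L]] <- m
  }
  motifs[order(vapply(motifs, `[[`, numeric(1), "score"), decreasing = TRUE)]
}

#' Discover motifs in one promoter subset
#'
#' Runs every finder at every width, keeps the top motif per finder and
#' width, and combines results across finders by [vote_combine()] per width.
#'
#' @param records the subset's `promoter_set` (orthologs plus target).
#' @param widths motif widths to scan.
#' @param finders named list of finder functions, or character names of
#'   built-ins (`"gibbs"`, `"consensus"`).
#' @param cfg a [finder_config()].
#' @param quorum,overlap_frac voting parameters, see [vote_combine()].
#' @return list of voted `motif` objects (all widths pooled).
#' @export
discover_motifs <- function(records, widths = c(8L, 10L, 12L, 14L, 16L),
                            finders = c("gibbs", "consensus"),
                            cfg = finder_config(), quorum = 2L,
                            overlap_frac = 0.5) {
  if (is.character(finders)) {
    reg <- builtin_finders()
    unknown <- setdiff(finders, names(reg))
    if (length(unknown)) stopf("unknown finder: %s", paste(unknown, collapse = ", "))
    finders <- reg[finders]
  }
  out <- list()
  for (W in widths) {
    results <- list()
    for (fn in names(finders)) {
      if (identical(fn, "consensus") && W > 12L) next  # enumeration guard
      fr <- finders[[fn]](records, W, cfg)
      if (length(fr$motifs)) results[[length(results) + 1L]] <- fr
    }
    if (!length(results)) next
    out <- c(out, vote_combine(results, records, quorum, overlap_frac, cfg))
  }
  out
}

#' Export motif instance lists as TSV
#'
#' @param motifs_by_run list (by run) of lists of `motif` objects.
#' @param path TSV file with columns run_id, motif_id, finder(s),
#'   promoter_id, start, strand, width.
#' @export
write_motif_instances <- function(motifs_by_run, path) {
  rows <- do.call(rbind, unlist(lapply(seq_along(motifs_by_run), function(r) {
    lapply(seq_along(motifs_by_run[[r]]), function(mi) {
      m <- motifs_by_run[[r]][[mi]]
      data.frame(run_id = r, motif_id = mi,
                 finder = paste(m$finders %||% "NA", collapse = "+"),
                 promoter_id = m$instances$promoter_id,
                 start = m$instances$start, strand = m$instances$strand,
                 width = m$width, stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  if (is.null(rows))
    rows <- data.frame(run_id = integer(0), motif_id = integer(0),
                       finder = character(0), promoter_id = character(0),
                       start = integer(0), strand = character(0),
                       width = integer(0))
  write_tsv_file(rows, path)
}
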