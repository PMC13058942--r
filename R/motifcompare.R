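# Comparison of discovered motifs against a known-TFBS database with
# empirical p-values and E-values, per-peak statistics across runs,
# consolidated per-peak alignments, and taxonomic presence maps.

# Reverse complement of a PWM: reverse the positions, swap A<->T and C<->G.
pwm_revcomp <- function(pwm) {
  out <- pwm[rev(seq_len(nrow(pwm))), c(4, 3, 2, 1), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

# Row-wise z-scores of a PWM; a zero-variance (uniform) row becomes zeros,
# so its correlation with any column is 0 - well-defined for N padding.
pwm_zrows <- function(pwm) {
  t(apply(pwm, 1, function(x) {
    s <- stats::sd(x)
    if (s < 1e-12) rep(0, 4) else (x - mean(x)) / s
  }))
}

#' Compare a query motif against a known-motif database
#'
#' Tomtom-style ungapped PWM-PWM comparison: the column similarity is the
#' Pearson correlation of the two 4-vectors, the alignment score is the mean
#' column similarity over the overlap, every offset in both orientations
#' with overlap at least `min_overlap` is scanned, and the best alignment
#' per database motif is kept. Its p-value is the empirical fraction of
#' equally good or better best-alignment scores of the query against
#' `n_shuffle` column-shuffled versions of that database motif (all offsets
#' re-scanned per shuffle), with a +1/(K+1) correction; the E-value is the
#' p-value times the database size.
#'
#' @param query a `motif` object or W x 4 row-stochastic matrix (W >=
#'   `min_overlap`).
#' @param db a `motif_database`.
#' @param min_overlap minimum aligned columns.
#' @param n_shuffle shuffles K for the empirical null.
#' @return data frame with one row per database motif: `db_motif`, `offset`
#'   (position of the db motif start relative to the query start), `orientation`,
#'   `score`, `p_value`, `e_value`.
#' @export
compare_pwms <- function(query, db, min_overlap = 5L, n_shuffle = 1000L) {
  qpwm <- if (inherits(query, "motif")) query$pwm else query
  if (!length(db$motifs)) stopf("empty motif database")
  if (nrow(qpwm) < min_overlap)
    stopf("query width %d below min_overlap %d", nrow(qpwm), min_overlap)
  Zq <- pwm_zrows(qpwm)
  n_db <- length(db$motifs)
  out <- lapply(names(db$motifs), function(nm) {
    dpwm <- db$motifs[[nm]]$pwm
    eff_ov <- min(min_overlap, nrow(qpwm), nrow(dpwm))
    Zd <- pwm_zrows(dpwm)
    Zdrc <- pwm_zrows(pwm_revcomp(dpwm))
    C0 <- Zq %*% t(Zd) / 3
    C0rc <- Zq %*% t(Zdrc) / 3
    obs <- best_alignment_cpp(C0, C0rc, as.integer(eff_ov))
    null <- null_best_scores_cpp(C0, C0rc, as.integer(eff_ov),
                                 as.integer(n_shuffle))
    p <- (sum(null >= obs$score - 1e-12) + 1) / (n_shuffle + 1)
    data.frame(db_motif = nm, offset = obs$offset,
               orientation = obs$orientation,
               score = obs$score, p_value = p, e_value = p * n_db,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Match every run's motifs against the database
#'
#' @param motifs_by_run list (by run) of lists of `motif` objects.
#' @param db a `motif_database`.
#' @param target_id id of the target promoter (for peak assignment
#'   coordinates).
#' @param min_overlap,n_shuffle see [compare_pwms()].
#' @return data frame: `run_id`, `motif_id`, `target_start`, `target_end`,
#'   `db_motif`, `score`, `p_value`, `e_value` (one row per motif x db
#'   motif x target instance).
#' @export
match_runs_to_db <- function(motifs_by_run, db, target_id,
                             min_overlap = 5L, n_shuffle = 1000L) {
  rows <- list()
  for (r in seq_along(motifs_by_run)) {
    for (mi in seq_along(motifs_by_run[[r]])) {
      m <- motifs_by_run[[r]][[mi]]
      tgt <- m$instances[m$instances$promoter_id == target_id, , drop = FALSE]
      if (nrow(tgt) == 0L) next
      if (m$width < min_overlap) next
      sc <- compare_pwms(m, db, min_overlap, n_shuffle)
      for (ti in seq_len(nrow(tgt))) {
        sc2 <- sc
        sc2$run_id <- r; sc2$motif_id <- mi
        sc2$target_start <- tgt$start[ti]
        sc2$target_end <- tgt$start[ti] + m$width
        rows[[length(rows) + 1L]] <- sc2
      }
    }
  }
  if (!length(rows))
    return(data.frame(db_motif = character(0), offset = integer(0),
                      orientation = character(0), score = numeric(0),
                      p_value = numeric(0), e_value = numeric(0),
                      run_id = integer(0), motif_id = integer(0),
                      target_start = integer(0), target_end = integer(0)))
  do.call(rbind, rows)
}

#' Aggregate per-peak match statistics across runs
#'
#' Matches are assigned to peaks by interval overlap (>= 1 bp) of the
#' motif's target instance with the peak. One E-value per run enters the
#' statistics for each (peak, TF): the best (smallest) across that run's
#' matching motifs. `top_candidate_freq` is the fraction of all `n_runs`
#' runs in which the TF had the smallest E-value for that peak.
#'
#' @param matches data frame from [match_runs_to_db()].
#' @param peaks data frame from [call_peaks()].
#' @param n_runs total number of runs N.
#' @param alpha significance threshold on E-values.
#' @return data frame: `peak_id`, `tf`, `n` (runs with a match), `e_median`,
#'   `e_q1`, `e_q3`, `frac_significant`, `top_candidate_freq`. A peak with no
#'   matched run yields a single row with `n = 0` and no summary values.
#' @export
aggregate_peak_stats <- function(matches, peaks, n_runs, alpha = 0.05) {
  out <- list()
  for (pi in seq_len(nrow(peaks))) {
    pk <- peaks[pi, ]
    sel <- matches[matches$target_end > pk$start & matches$target_start < pk$end, ,
                   drop = FALSE]
    if (nrow(sel) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        peak_id = pk$peak_id, tf = NA_character_, n = 0L,
        e_median = NA_real_, e_q1 = NA_real_, e_q3 = NA_real_,
        frac_significant = NA_real_, top_candidate_freq = NA_real_)
      next
    }
    # best e-value per (run, TF); the alignment score rides along so that
    # ties on the discrete empirical p-value grid can be broken sensibly
    sel <- sel[order(sel$run_id, sel$db_motif, sel$e_value, -sel$score), ]
    key <- paste(sel$run_id, sel$db_motif, sep = "\r")
    per_run_tf <- sel[!duplicated(key), c("run_id", "db_motif", "e_value", "score")]
    names(per_run_tf)[2] <- "tf"
    # top candidate per run: smallest best e-value, ties -> higher score
    top_by_run <- vapply(split(per_run_tf, per_run_tf$run_id), function(d)
      d$tf[order(d$e_value, -d$score)[1]], character(1))
    for (tf in sort(unique(per_run_tf$tf))) {
      ev <- per_run_tf$e_value[per_run_tf$tf == tf]
      q <- stats::quantile(ev, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        peak_id = pk$peak_id, tf = tf, n = length(ev),
        e_median = q[2], e_q1 = q[1], e_q3 = q[3],
        frac_significant = mean(ev < alpha),
        top_candidate_freq = sum(top_by_run == tf) / n_runs)
    }
  }
  do.call(rbind, out)
}

# Map one ortholog instance of a motif into target/peak coordinates. The
# motif's target instance [t0, t0+W) anchors the mapping; for a
# relative-minus instance the orientation flips around the instance.
ortholog_segment_anchor <- function(peak_start, peak_end, t0, W, q0, rel_minus) {
  if (!rel_minus) {
    c(start = q0 + peak_start - t0, rel = 0L)
  } else {
    c(start = q0 + W + t0 - peak_end, rel = 1L)
  }
}

extract_segment <- function(records, pid, start, width, rel_minus) {
  L <- nchar(records[[pid]]$sequence)
  lo <- max(0L, start); hi <- min(L, start + width)
  core <- if (hi > lo) substr(records[[pid]]$sequence, lo + 1L, hi) else ""
  seg <- paste0(strrep("N", max(0L, lo - start)), core,
                strrep("N", max(0L, (start + width) - hi)))
  padded <- (start < 0L) || (start + width > L)
  if (rel_minus) seg <- revcomp(seg)
  list(segment = seg, padded = padded)
}

#' Build the consolidated alignment for one peak
#'
#' Stacks, at peak width, the target segment under the peak and one segment
#' per orthologous promoter in which a peak-overlapping motif was detected
#' in at least one run. Each ortholog segment is re-anchored so the motif
#' instance aligns with its target instance; when runs disagree on the
#' position, the most frequently detected anchor wins (ties: leftmost).
#' Relative-minus instances are reverse-complemented before stacking;
#' segments reaching beyond promoter bounds are padded with N and flagged.
#'
#' @param peak one row of the [call_peaks()] data frame.
#' @param motifs_by_run list (by run) of lists of `motif` objects.
#' @param records the full `promoter_set` (with target).
#' @param target_id id of the target promoter.
#' @param pseudocount per-cell pseudocount for the alignment PWM.
#' @return object of class `consolidated_alignment`: `peak_id`, `width`,
#'   `rows` (promoter_id, segment, offset, strand, padded), `pwm`.
#' @export
build_consolidated_alignment <- function(peak, motifs_by_run, records,
                                         target_id, pseudocount = 0.5) {
  pw <- peak$end - peak$start
  anchors <- list()  # per promoter: vector of "start:rel" keys
  for (run in motifs_by_run) for (m in run) {
    tgt <- m$instances[m$instances$promoter_id == target_id, , drop = FALSE]
    if (nrow(tgt) == 0L) next
    tgt <- tgt[tgt$start + m$width > peak$start & tgt$start < peak$end, ,
               drop = FALSE]
    if (nrow(tgt) == 0L) next
    orth <- m$instances[m$instances$promoter_id != target_id, , drop = FALSE]
    for (ti in seq_len(nrow(tgt))) {
      for (oi in seq_len(nrow(orth))) {
        rel_minus <- orth$strand[oi] != tgt$strand[ti]
        a <- ortholog_segment_anchor(peak$start, peak$end, tgt$start[ti],
                                     m$width, orth$start[oi], rel_minus)
        pid <- orth$promoter_id[oi]
        anchors[[pid]] <- c(anchors[[pid]], paste0(a[["start"]], ":", a[["rel"]]))
      }
    }
  }
  if (!length(anchors))
    stopf("peak %d has no supporting run; cannot build a consolidated alignment",
          peak$peak_id)

  tgt_seg <- substr(records[[target_id]]$sequence, peak$start + 1L, peak$end)
  rows <- data.frame(promoter_id = target_id, segment = tgt_seg,
                     offset = peak$start, strand = "+", padded = FALSE,
                     stringsAsFactors = FALSE)
  for (pid in sort(names(anchors))) {
    tab <- table(anchors[[pid]])
    best <- names(tab)[tab == max(tab)]
    # ties: leftmost anchor, plus orientation preferred at equal position
    parts <- do.call(rbind, strsplit(best, ":", fixed = TRUE))
    ord <- order(as.integer(parts[, 1]), as.integer(parts[, 2]))
    choice <- parts[ord[1], ]
    start <- as.integer(choice[1]); rel_minus <- choice[2] == "1"
    seg <- extract_segment(records, pid, start, pw, rel_minus)
    rows <- rbind(rows, data.frame(promoter_id = pid, segment = seg$segment,
                                   offset = start,
                                   strand = if (rel_minus) "-" else "+",
                                   padded = seg$padded, stringsAsFactors = FALSE))
  }
  structure(list(peak_id = peak$peak_id, width = pw, rows = rows,
                 pwm = alignment_pwm(rows$segment, pseudocount)),
            class = "consolidated_alignment")
}

# PWM from equal-length segments; N contributes 0.25 per base.
alignment_pwm <- function(segments, pseudocount = 0.5) {
  w <- nchar(segments[1])
  stopifnot(all(nchar(segments) == w))
  counts <- matrix(0, nrow = w, ncol = 4, dimnames = list(NULL, DNA_BASES))
  for (s in segments) {
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(w)) {
      if (ch[i] == "N") counts[i, ] <- counts[i, ] + 0.25
      else counts[i, ch[i]] <- counts[i, ch[i]] + 1
    }
  }
  (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
}

#' Score a consolidated alignment against the database
#'
#' @param alignment a `consolidated_alignment` with at least 2 rows.
#' @param db a `motif_database`.
#' @param min_overlap,n_shuffle see [compare_pwms()].
#' @return data frame as from [compare_pwms()], sorted by E-value.
#' @export
score_consolidated <- function(alignment, db, min_overlap = 5L,
                               n_shuffle = 1000L) {
  if (nrow(alignment$rows) < 2L)
    stopf("consolidated alignment needs >= 2 rows to score")
  res <- compare_pwms(alignment$pwm, db, min_overlap, n_shuffle)
  res[order(res$e_value, res$db_motif), ]
}

#' Write a consolidated alignment as FASTA
#' @param alignment a `consolidated_alignment`.
#' @param path output file.
#' @export
write_consolidated_fasta <- function(alignment, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in seq_len(nrow(alignment$rows))) {
    row <- alignment$rows[r, ]
    writeLines(sprintf(">%s offset=%d strand=%s%s", row$promoter_id, row$offset,
                       row$strand, if (row$padded) " padded" else ""), con)
    writeLines(row$segment, con)
  }
  invisible(path)
}

#' Map motif presence for a peak onto the analyzed taxa
#'
#' A taxon is present when any run's peak-overlapping motif has an instance
#' on that taxon's promoter. Taxa whose promoter was never sampled into a
#' subset are flagged separately (`sampled = FALSE`): absence of evidence,
#' not evidence of absence.
#'
#' @param peak one row of the [call_peaks()] data frame.
#' @param motifs_by_run list (by run) of lists of `motif` objects.
#' @param records the full `promoter_set`.
#' @param sampled_ids promoter ids that entered at least one subset
#'   (default: all).
#' @return data frame: `taxon`, `promoter_id`, `peak_id`, `present`, `sampled`.
#' @export
presence_map <- function(peak, motifs_by_run, records,
                         sampled_ids = promoter_ids(records)) {
  target_id <- target_id_of(records)
  hit <- character(0)
  for (run in motifs_by_run) for (m in run) {
    tgt <- m$instances[m$instances$promoter_id == target_id, , drop = FALSE]
    if (!any(tgt$start + m$width > peak$start & tgt$start < peak$end)) next
    hit <- union(hit, m$instances$promoter_id)
  }
  ids <- promoter_ids(records)
  data.frame(taxon = vapply(records, `[[`, character(1), "taxon"),
             promoter_id = ids, peak_id = peak$peak_id,
             present = ids %in% hit,
             sampled = ids %in% c(sampled_ids, target_id),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export presence maps as an annotated Newick tree
#'
#' Writes the guide tree with `[&present=1|0]` comments appended to each
#' leaf label for one peak.
#'
#' @param pmap data frame from [presence_map()].
#' @param tree `ape::phylo`.
#' @param path output file.
#' @export
write_presence_newick <- function(pmap, tree, path) {
  tr <- tree
  pres <- pmap$present[match(tr$tip.label, pmap$promoter_id)]
  tr$tip.label <- paste0(tr$tip.label, "[&present=", as.integer(pres %in% TRUE), "]")
  ape::write.tree(tr, file = path)
  invisible(path)
}
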