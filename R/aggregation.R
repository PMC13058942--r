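# Projection of per-run motifs onto the target promoter, the multi-run
# frequency histogram, and peak calling.

#' Project one run's motifs onto the target promoter
#'
#' A motif contributes its target interval(s) only when it is anchored on
#' the target (>= 1 instance there) and simultaneously detected in at least
#' `min_ortholog_support` distinct non-target promoters — the footprinting
#' requirement.
#'
#' @param run_motifs list of `motif` objects from one run.
#' @param target_id id of the target promoter.
#' @param min_ortholog_support minimum distinct ortholog promoters with an
#'   instance (default 6, half the default subset size).
#' @return data frame of 0-based half-open intervals (`start`, `end`) on the
#'   target, one row per emitted target instance.
#' @export
project_run <- function(run_motifs, target_id, min_ortholog_support = 6L) {
  out <- lapply(run_motifs, function(m) {
    on_target <- m$instances$promoter_id == target_id
    n_orth <- length(unique(m$instances$promoter_id[!on_target]))
    if (!any(on_target) || n_orth < min_ortholog_support) return(NULL)
    data.frame(start = m$instances$start[on_target],
               end = m$instances$start[on_target] + m$width)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(start = integer(0), end = integer(0)) else out
}

#' Accumulate the per-position run-support histogram
#'
#' `counts[i]` is the number of runs with at least one emitted interval
#' covering position i: a run votes 0/1 per position regardless of how many
#' of its motifs cover it, so `counts / n_runs` reads as a fraction of runs.
#'
#' @param per_run_intervals list over runs of interval data frames from
#'   [project_run()].
#' @param target_length length of the target promoter.
#' @param n_runs total number of runs N.
#' @param target_id id stored on the histogram.
#' @return object of class `position_histogram`: `target_id`, `length`,
#'   `counts`, `n_runs`.
#' @export
accumulate_histogram <- function(per_run_intervals, target_length, n_runs,
                                 target_id = "target") {
  counts <- integer(target_length)
  for (iv in per_run_intervals) {
    if (is.null(iv) || nrow(iv) == 0L) next
    if (any(iv$start < 0L) || any(iv$end > target_length))
      stopf("interval [%d,%d) outside target promoter [0,%d)",
            iv$start[which(iv$start < 0 | iv$end > target_length)][1],
            iv$end[which(iv$start < 0 | iv$end > target_length)][1],
            target_length)
    covered <- logical(target_length)
    for (r in seq_len(nrow(iv)))
      covered[(iv$start[r] + 1L):iv$end[r]] <- TRUE
    counts <- counts + covered
  }
  structure(list(target_id = target_id, length = target_length,
                 counts = as.integer(counts), n_runs = as.integer(n_runs)),
            class = "position_histogram")
}

#' Call peaks on a position histogram
#'
#' Positions with support of at least `ceil(min_support_frac * n_runs)` form
#' candidate intervals; candidates separated by fewer than `merge_gap`
#' positions are merged; merged candidates narrower than `min_width` are
#' discarded. Peaks are numbered left to right.
#'
#' @param hist a `position_histogram`.
#' @param min_support_frac threshold as a fraction of runs.
#' @param min_width minimum peak width in bp.
#' @param merge_gap merge candidates closer than this many positions.
#' @return data frame with columns `peak_id`, `start`, `end` (0-based
#'   half-open), `height`, `support_frac`; zero rows when nothing passes.
#' @export
call_peaks <- function(hist, min_support_frac = 0.25, min_width = 6L,
                       merge_gap = 5L) {
  if (hist$n_runs < 1L) stopf("cannot call peaks with n_runs < 1")
  t <- ceiling(min_support_frac * hist$n_runs)
  above <- hist$counts >= t
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  cand <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(cand) > 1L) {
    merged <- cand[1, , drop = FALSE]
    for (i in 2:nrow(cand)) {
      if (cand$start[i] - merged$end[nrow(merged)] < merge_gap)
        merged$end[nrow(merged)] <- cand$end[i]
      else merged <- rbind(merged, cand[i, ])
    }
    cand <- merged
  }
  cand <- cand[cand$end - cand$start >= min_width, , drop = FALSE]
  if (!nrow(cand))
    return(data.frame(peak_id = integer(0), start = integer(0), end = integer(0),
                      height = integer(0), support_frac = numeric(0)))
  data.frame(peak_id = seq_len(nrow(cand)),
             start = cand$start, end = cand$end,
             height = vapply(seq_len(nrow(cand)), function(i)
               max(hist$counts[(cand$start[i] + 1L):cand$end[i]]), integer(1)),
             support_frac = vapply(seq_len(nrow(cand)), function(i)
               max(hist$counts[(cand$start[i] + 1L):cand$end[i]]) / hist$n_runs,
               numeric(1)),
             row.names = NULL)
}
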