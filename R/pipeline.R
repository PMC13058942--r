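# End-to-end pipeline orchestration: distances -> stratification -> subset
# plan -> per-subset discovery -> histogram/peaks -> database comparison ->
# consolidated alignments and presence maps, with provenance artifacts.

PIPELINE_STAGES <- c("distances", "subsets", "discover", "aggregate",
                     "compare", "consolidate")

#' Pipeline configuration
#'
#' Bundles every stage's settings. All defaults are documented on the
#' stage constructors they feed ([stratification_config()],
#' [sampler_config()], [finder_config()], [call_peaks()], [compare_pwms()]).
#'
#' @param stratification a [stratification_config()].
#' @param sampler a [sampler_config()].
#' @param finder a [finder_config()].
#' @param widths motif widths scanned per finder.
#' @param finders built-in finder names (or named list of finder functions).
#' @param quorum,overlap_frac voting parameters ([vote_combine()]).
#' @param min_ortholog_support footprinting support threshold
#'   ([project_run()]).
#' @param min_support_frac,min_peak_width,merge_gap peak-calling parameters
#'   ([call_peaks()]).
#' @param min_overlap,n_shuffle comparison parameters ([compare_pwms()]).
#' @param alpha significance threshold on E-values.
#' @param chrom,chrom_offset track coordinates for BedGraph/BED output.
#' @param seed master seed; run r of discovery derives seed + r, so adding
#'   runs never reshuffles earlier ones.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stratification = stratification_config(),
                            sampler = sampler_config(),
                            finder = finder_config(),
                            widths = c(8L, 10L, 12L, 14L, 16L),
                            finders = c("gibbs", "consensus"),
                            quorum = 2L, overlap_frac = 0.5,
                            min_ortholog_support = 6L,
                            min_support_frac = 0.25, min_peak_width = 6L,
                            merge_gap = 5L,
                            min_overlap = 5L, n_shuffle = 1000L,
                            alpha = 0.05,
                            chrom = NULL, chrom_offset = 0L,
                            seed = 1L) {
  structure(list(stratification = stratification, sampler = sampler,
                 finder = finder, widths = as.integer(widths),
                 finders = finders, quorum = as.integer(quorum),
                 overlap_frac = overlap_frac,
                 min_ortholog_support = as.integer(min_ortholog_support),
                 min_support_frac = min_support_frac,
                 min_peak_width = as.integer(min_peak_width),
                 merge_gap = as.integer(merge_gap),
                 min_overlap = as.integer(min_overlap),
                 n_shuffle = as.integer(n_shuffle), alpha = alpha,
                 chrom = chrom, chrom_offset = as.integer(chrom_offset),
                 seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Any subset of the [pipeline_config()] fields may appear; nested blocks
#' `stratification`, `sampler`, `finder` override the corresponding
#' constructor arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (blk in c("stratification", "sampler", "finder")) {
    if (!is.null(y[[blk]])) {
      ctor <- switch(blk, stratification = stratification_config,
                     sampler = sampler_config, finder = finder_config)
      args[[blk]] <- do.call(ctor, y[[blk]])
      y[[blk]] <- NULL
    }
  }
  known <- setdiff(names(formals(pipeline_config)),
                   c("stratification", "sampler", "finder"))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, c(args, y[names(y) %in% known]))
}

#' Run the bootstrap footprinting pipeline
#'
#' Executes the stages in order (`distances`, `subsets`, `discover`,
#' `aggregate`, `compare`, `consolidate`), writing every artifact under
#' `outdir`: distance matrix, subgroup table, subset plan, per-run motifs
#' (MEME) and instance lists, histogram BedGraph (+ BigWig when a backend is
#' installed), peak BED, match/peak-statistics/top-candidate TSVs, per-peak
#' consolidated alignment FASTA + PWM, presence-map TSV, and a run manifest.
#' With a fixed seed and inputs, TSV/BED artifacts are byte-identical across
#' invocations.
#'
#' @param promoters a `promoter_set` containing exactly one target record.
#' @param outdir artifact directory (created if needed).
#' @param tree optional guide tree (`ape::phylo`); when absent, pairwise
#'   Jukes-Cantor distances are computed from the sequences.
#' @param motif_db optional `motif_database`; enables the `compare` and
#'   `consolidate` comparison outputs. Checked before discovery starts.
#' @param config a [pipeline_config()].
#' @param stop_after stop after this stage (one of
#'   `r paste(PIPELINE_STAGES, collapse = ", ")`).
#' @param verbose narrate stage progress with counts.
#' @return (invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(promoters, outdir, tree = NULL, motif_db = NULL,
                         config = pipeline_config(), stop_after = NULL,
                         verbose = TRUE) {
  if (!is.null(stop_after) && !stop_after %in% PIPELINE_STAGES)
    stopf("stop_after must be one of: %s", paste(PIPELINE_STAGES, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  target_id <- target_id_of(promoters)
  compare_enabled <- !is.null(motif_db)
  if (compare_enabled && !inherits(motif_db, "motif_database"))
    stopf("motif_db must be a motif_database (see read_meme_motifs)")
  res <- list(config = config, target_id = target_id)
  done <- function(stage) !is.null(stop_after) && stage == stop_after

  # distances
  dm <- if (!is.null(tree)) tree_distances(tree, promoter_ids(promoters))
        else sequence_distances(promoters)
  write_distance_tsv(dm, file.path(outdir, "distances.tsv"))
  groups <- stratify(dm, target_id, config$stratification)
  sizes <- subgroup_sizes(groups)
  msg("distances: %d promoters; subgroups %d/%d/%d, %d excluded",
      length(dm$ids), sizes[1], sizes[2], sizes[3], length(groups$excluded),
      verbose = verbose)
  write_tsv_file(data.frame(
    promoter_id = c(groups$g1, groups$g2, groups$g3, groups$excluded),
    subgroup = rep(c("g1", "g2", "g3", "excluded"),
                   c(sizes, length(groups$excluded)))),
    file.path(outdir, "subgroups.tsv"))
  res$dm <- dm; res$groups <- groups
  if (done("distances")) { write_manifest(res, outdir); return(invisible(res)) }

  # subsets (the sampler inherits the master seed)
  config$sampler$seed <- config$seed
  plan <- generate_subsets(groups, dm, config$sampler)
  msg("subsets: M = %d, N = %d (quota %s)", plan$M, plan$N,
      paste(config$sampler$quota, collapse = ":"), verbose = verbose)
  write_subset_plan(plan, file.path(outdir, "subset_plan.tsv"))
  res$plan <- plan
  if (done("subsets")) { write_manifest(res, outdir); return(invisible(res)) }

  # discover
  run_dir <- file.path(outdir, "runs")
  dir.create(run_dir, showWarnings = FALSE)
  motifs_by_run <- vector("list", plan$N)
  for (r in seq_len(plan$N)) {
    sub_recs <- promoter_set(promoters[plan$subsets[[r]]$member_ids])
    motifs_by_run[[r]] <- with_seed(config$seed + r, {
      discover_motifs(sub_recs, config$widths, config$finders, config$finder,
                      config$quorum, config$overlap_frac)
    })
    if (length(motifs_by_run[[r]])) {
      mm <- motifs_by_run[[r]]
      names(mm) <- sprintf("run%d_motif%d", r, seq_along(mm))
      write_meme_motifs(mm, file.path(run_dir, sprintf("run_%03d_motifs.meme", r)),
                        background = config$finder$background)
    }
  }
  msg("discover: %d runs, %.1f voted motifs per run on average", plan$N,
      mean(lengths(motifs_by_run)), verbose = verbose)
  write_motif_instances(motifs_by_run, file.path(outdir, "motif_instances.tsv"))
  res$motifs_by_run <- motifs_by_run
  if (done("discover")) { write_manifest(res, outdir); return(invisible(res)) }

  # aggregate
  target_len <- nchar(promoters[[target_id]]$sequence)
  per_run <- lapply(motifs_by_run, project_run, target_id = target_id,
                    min_ortholog_support = config$min_ortholog_support)
  hist <- accumulate_histogram(per_run, target_len, plan$N, target_id)
  chrom <- config$chrom %||% target_id
  write_bedgraph(hist, file.path(outdir, "histogram.bedgraph"), chrom,
                 config$chrom_offset)
  if (requireNamespace("rtracklayer", quietly = TRUE))
    write_bigwig(hist, file.path(outdir, "histogram.bw"), chrom,
                 config$chrom_offset)
  peaks <- call_peaks(hist, config$min_support_frac, config$min_peak_width,
                      config$merge_gap)
  msg("aggregate: %d peak(s) called at support >= %.0f%% of %d runs",
      nrow(peaks), 100 * config$min_support_frac, plan$N, verbose = verbose)
  write_peaks_bed(peaks, file.path(outdir, "peaks.bed"), chrom,
                  config$chrom_offset)
  res$histogram <- hist; res$peaks <- peaks
  if (done("aggregate") || !compare_enabled) {
    write_manifest(res, outdir); return(invisible(res))
  }

  # compare
  matches <- with_seed(config$seed + plan$N + 1L, {
    match_runs_to_db(motifs_by_run, motif_db, target_id,
                     config$min_overlap, config$n_shuffle)
  })
  write_tsv_file(matches, file.path(outdir, "matches.tsv"))
  stats <- aggregate_peak_stats(matches, peaks, plan$N, config$alpha)
  write_tsv_file(stats, file.path(outdir, "peak_stats.tsv"))
  top <- stats[!is.na(stats$tf), c("peak_id", "tf", "top_candidate_freq")]
  top <- top[order(top$peak_id, -top$top_candidate_freq), ]
  write_tsv_file(top, file.path(outdir, "top_candidates.tsv"))
  msg("compare: %d match rows against %d database motifs", nrow(matches),
      length(motif_db$motifs), verbose = verbose)
  res$matches <- matches; res$peak_stats <- stats
  if (done("compare")) { write_manifest(res, outdir); return(invisible(res)) }

  # consolidate
  cons_dir <- file.path(outdir, "consolidated")
  dir.create(cons_dir, showWarnings = FALSE)
  sampled <- unique(unlist(lapply(res$plan$subsets, `[[`, "member_ids")))
  res$consolidated <- list(); cons_scores <- list(); pmaps <- list()
  for (pi in seq_len(nrow(peaks))) {
    pk <- peaks[pi, ]
    ca <- tryCatch(build_consolidated_alignment(pk, motifs_by_run, promoters,
                                                target_id,
                                                config$finder$pseudocount),
                   error = function(e) NULL)
    if (is.null(ca)) next
    write_consolidated_fasta(ca, file.path(cons_dir, sprintf("peak_%d.fasta", pk$peak_id)))
    write_meme_motifs(stats::setNames(list(list(pwm = ca$pwm,
                                                nsites = nrow(ca$rows))),
                                      sprintf("peak_%d_consolidated", pk$peak_id)),
                      file.path(cons_dir, sprintf("peak_%d.meme", pk$peak_id)))
    if (nrow(ca$rows) >= 2L) {
      sc <- with_seed(config$seed + plan$N + 1L + pk$peak_id, {
        score_consolidated(ca, motif_db, config$min_overlap, config$n_shuffle)
      })
      sc$peak_id <- pk$peak_id
      cons_scores[[length(cons_scores) + 1L]] <- sc
    }
    pmaps[[length(pmaps) + 1L]] <-
      presence_map(pk, motifs_by_run, promoters, sampled)
    res$consolidated[[as.character(pk$peak_id)]] <- ca
  }
  if (length(cons_scores))
    write_tsv_file(do.call(rbind, cons_scores),
                   file.path(outdir, "consolidated_matches.tsv"))
  if (length(pmaps)) {
    pmap_all <- do.call(rbind, pmaps)
    write_tsv_file(pmap_all, file.path(outdir, "presence_map.tsv"))
    res$presence <- pmap_all
    if (!is.null(tree))
      for (pid in unique(pmap_all$peak_id))
        write_presence_newick(pmap_all[pmap_all$peak_id == pid, ], tree,
                              file.path(cons_dir, sprintf("peak_%d_presence.nwk", pid)))
  }
  res$consolidated_scores <- if (length(cons_scores)) do.call(rbind, cons_scores)
  msg("consolidate: %d alignment(s) built", length(res$consolidated),
      verbose = verbose)
  write_manifest(res, outdir)
  invisible(res)
}

# Run manifest: configuration, seed and package version for provenance.
write_manifest <- function(res, outdir) {
  cfg <- res$config
  manifest <- list(
    package = "motifboot",
    version = as.character(utils::packageVersion("motifboot")),
    seed = cfg$seed,
    target_id = res$target_id,
    n_promoters = if (!is.null(res$dm)) length(res$dm$ids),
    subgroup_sizes = if (!is.null(res$groups)) subgroup_sizes(res$groups),
    M = res$plan$M, N = res$plan$N,
    n_peaks = if (!is.null(res$peaks)) nrow(res$peaks),
    config = unclass_deep(cfg))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(NULL)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, unclass_deep)
  else if (is.function(x)) NULL
  else unclass(x)
}

#' Simulate a benchmark data set and write its artifacts
#'
#' Convenience wrapper around [simulate_tree()], [evolve_promoters()] and
#' [make_decoy_database()]: writes promoters FASTA, guide tree Newick,
#' ground-truth BED and a decoy motif database in MEME format.
#'
#' @param outdir output directory.
#' @param cfg a [sim_config()].
#' @param n_decoys decoys in the generated database.
#' @return (invisibly) list with `promoters`, `truth`, `tree`, `db` and the
#'   file paths.
#' @export
simulate_dataset <- function(outdir, cfg = sim_config(), n_decoys = 19L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- evolve_promoters(cfg)
  db <- make_decoy_database(cfg$implant_pwm, n_decoys, seed = cfg$seed)
  paths <- list(fasta = file.path(outdir, "promoters.fasta"),
                tree = file.path(outdir, "tree.nwk"),
                truth = file.path(outdir, "truth.bed"),
                db = file.path(outdir, "motif_db.meme"))
  write_promoter_fasta(sim$promoters, paths$fasta)
  write_newick(sim$truth$tree, paths$tree)
  write_truth_bed(sim$truth, paths$truth)
  write_meme_motifs(db, paths$db)
  invisible(list(promoters = sim$promoters, truth = sim$truth,
                 tree = sim$truth$tree, db = db, paths = paths))
}
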