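# Stratified bootstrap subset generation: N = rounds * M subsets of 12
# promoters in a fixed 3:3:6 quota across the three distance subgroups,
# with a within-subset diversity constraint.

#' Sampler configuration
#'
#' @param quota promoters drawn per subgroup (near, mid, far).
#' @param rounds sampling epochs r; the plan holds N = r * M subsets.
#'   Promoters are reused across epochs (the bootstrap-like replacement) but
#'   appear at most once per epoch.
#' @param min_intra_distance minimum pairwise distance between subset
#'   members; candidates closer than this to a current member are skipped
#'   and retried, then waived with a warning.
#' @param retry_budget candidates examined per slot before waiving the
#'   diversity constraint.
#' @param seed integer seed making the plan reproducible.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(quota = c(3L, 3L, 6L), rounds = 2L,
                           min_intra_distance = 0.02, retry_budget = 25L,
                           seed = 1L) {
  quota <- as.integer(quota)
  if (length(quota) != 3L || any(quota < 1L)) stopf("quota must be three integers >= 1")
  if (rounds < 1L) stopf("rounds must be >= 1")
  if (min_intra_distance < 0) stopf("min_intra_distance must be >= 0")
  structure(list(quota = quota, subset_size = sum(quota),
                 rounds = as.integer(rounds),
                 min_intra_distance = min_intra_distance,
                 retry_budget = as.integer(retry_budget),
                 seed = seed),
            class = "sampler_config")
}

#' Maximum number of complete quota-respecting subsets
#'
#' The largest M such that all three subgroups can supply M disjoint draws
#' of their quota: `M = min_k floor(sizes[k] / quota[k])`.
#'
#' @param sizes integer triple of subgroup sizes.
#' @param quota integer triple of per-subgroup quotas.
#' @return integer M (0 when any required subgroup is too small).
#' @export
max_subset_count <- function(sizes, quota = c(3L, 3L, 6L)) {
  stopifnot(length(sizes) == 3L, length(quota) == 3L,
            all(sizes >= 0), all(quota >= 1))
  as.integer(min(floor(sizes / quota)))
}

#' Generate the bootstrap subset plan
#'
#' Sampling proceeds in `cfg$rounds` epochs. Within an epoch each subgroup
#' is shuffled and consumed without replacement, so every usable promoter
#' appears at most once per epoch; across epochs promoters recur. A
#' candidate violating the diversity constraint against current subset
#' members is deferred and retried (up to `retry_budget` candidates), after
#' which the constraint is waived for that slot with a warning. The target
#' promoter is appended last to every subset and never counts toward quota
#' or diversity checks. Output is deterministic for a given seed.
#'
#' @param groups a `promoter_subgroups` from [stratify()].
#' @param dm the `distance_matrix` used for the diversity rule.
#' @param cfg a [sampler_config()].
#' @return object of class `subset_plan`: `M`, `N`, and `subsets`, a list of
#'   `subset_spec` entries (`run_id`, `member_ids`, `member_subgroups`,
#'   `target_id`).
#' @export
generate_subsets <- function(groups, dm, cfg = sampler_config()) {
  sizes <- subgroup_sizes(groups)
  M <- max_subset_count(sizes, cfg$quota)
  if (M < 1L)
    stopf(paste0("subgroup sizes (%s) cannot fill one subset with quota (%s); ",
                 "relax the stratification boundaries or lower the quota"),
          paste(sizes, collapse = ","), paste(cfg$quota, collapse = ","))
  pools_all <- list(groups$g1, groups$g2, groups$g3)
  n_waived <- 0L

  subsets <- with_seed(cfg$seed, {
    out <- vector("list", cfg$rounds * M)
    run <- 0L
    for (epoch in seq_len(cfg$rounds)) {
      pools <- lapply(pools_all, sample)  # reshuffle the full subgroup each epoch
      for (j in seq_len(M)) {
        run <- run + 1L
        members <- character(0); member_grp <- integer(0)
        for (k in 1:3) {
          for (slot in seq_len(cfg$quota[k])) {
            pool <- pools[[k]]
            pick <- NA_integer_
            n_try <- min(length(pool), cfg$retry_budget)
            for (ci in seq_len(n_try)) {
              cand <- pool[ci]
              if (!length(members) ||
                  all(dm$d[cand, members] >= cfg$min_intra_distance)) {
                pick <- ci; break
              }
            }
            if (is.na(pick)) {  # diversity unsatisfiable within budget: waive
              pick <- 1L
              n_waived <- n_waived + 1L
            }
            members <- c(members, pool[pick])
            member_grp <- c(member_grp, k)
            pools[[k]] <- pool[-pick]
          }
        }
        out[[run]] <- structure(
          list(run_id = run,
               member_ids = c(members, groups$target_id),
               member_subgroups = c(member_grp, NA_integer_),
               target_id = groups$target_id),
          class = "subset_spec")
      }
    }
    out
  })

  if (n_waived > 0L)
    warning(sprintf("diversity constraint (min_intra_distance = %g) waived for %d slot(s)",
                    cfg$min_intra_distance, n_waived), call. = FALSE)
  structure(list(M = M, N = cfg$rounds * M, subsets = subsets,
                 quota = cfg$quota, seed = cfg$seed),
            class = "subset_plan")
}

#' Export a subset plan as TSV (one row per subset member)
#'
#' @param plan a `subset_plan`.
#' @param path TSV file.
#' @export
write_subset_plan <- function(plan, path) {
  rows <- do.call(rbind, lapply(plan$subsets, function(s) {
    data.frame(run_id = s$run_id, member_id = s$member_ids,
               subgroup = ifelse(is.na(s$member_subgroups), "target",
                                 paste0("g", s$member_subgroups)))
  }))
  write_tsv_file(rows, path)
}
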