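# Pairwise evolutionary distances between promoters and stratification of
# the orthologous set by distance to the target.

#' Create a distance matrix object
#'
#' @param ids ordered promoter ids.
#' @param d symmetric nonnegative matrix with zero diagonal, dimnames = ids.
#' @return object of class `distance_matrix`.
#' @export
distance_matrix <- function(ids, d) {
  stopifnot(is.matrix(d), nrow(d) == length(ids), ncol(d) == length(ids))
  if (any(!is.finite(d))) stopf("distance matrix contains non-finite entries")
  if (max(abs(d - t(d))) > 1e-9) stopf("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stopf("distance matrix diagonal must be zero")
  if (any(d < 0)) stopf("distance matrix contains negative entries")
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "distance_matrix")
}

dm_lookup <- function(dm, a, b) {
  if (!all(c(a, b) %in% dm$ids)) stopf("id not present in distance matrix")
  dm$d[a, b]
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths on the unique tree path between leaves `a` and `b`.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param a,b leaf labels.
#' @return nonnegative distance.
#' @export
patristic_distance <- function(tree, a, b) {
  if (!(a %in% tree$tip.label)) stopf("unknown leaf: '%s'", a)
  if (!(b %in% tree$tip.label)) stopf("unknown leaf: '%s'", b)
  if (a == b) return(0)
  cm <- ape::cophenetic.phylo(tree)
  cm[a, b]
}

#' All pairwise patristic distances for a set of promoter ids
#'
#' @param tree `ape::phylo`; every id must resolve to exactly one leaf.
#' @param ids promoter ids (default: all leaves).
#' @return a `distance_matrix`.
#' @export
tree_distances <- function(tree, ids = tree$tip.label) {
  missing <- setdiff(ids, tree$tip.label)
  if (length(missing))
    stopf("promoter id(s) not found among tree leaves: %s",
          paste(missing, collapse = ", "))
  cm <- ape::cophenetic.phylo(tree)
  distance_matrix(ids, cm[ids, ids, drop = FALSE])
}

#' Jukes-Cantor distance from a pairwise alignment
#'
#' Globally aligns the two sequences with fixed scores (match +1,
#' mismatch -1, gap -2), computes the mismatch fraction p over aligned
#' non-gap columns (columns containing N are ignored), and applies the
#' Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3). Used as the documented
#' fallback when no guide tree is supplied.
#'
#' @param seqA,seqB DNA strings.
#' @return corrected distance.
#' @export
jc_distance <- function(seqA, seqB) {
  if (!nzchar(seqA) || !nzchar(seqB)) stopf("jc_distance: empty sequence")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    substitutionMatrix = submat, gapOpening = 0, gapExtension = 2,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  usable <- pa %in% DNA_BASES & sa %in% DNA_BASES
  n_cols <- sum(usable)
  if (n_cols == 0L) stopf("jc_distance: no comparable aligned columns")
  p <- sum(pa[usable] != sa[usable]) / n_cols
  jc_correct(p)
}

# Closed-form Jukes-Cantor correction of a mismatch fraction.
jc_correct <- function(p) {
  if (p >= 0.75)
    stopf("jc_distance: mismatch fraction p = %.3f >= 0.75, distance undefined (saturation)", p)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Jukes-Cantor distances for a promoter set
#'
#' @param records a `promoter_set`.
#' @return a `distance_matrix` over all record ids.
#' @export
sequence_distances <- function(records) {
  ids <- promoter_ids(records)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dij <- jc_distance(records[[i]]$sequence, records[[j]]$sequence)
      d[i, j] <- d[j, i] <- dij
    }
  }
  distance_matrix(ids, d)
}

#' Stratification boundaries for distance subgroups
#'
#' Promoters are binned by distance to the target: near `[lower_cut, b1)`,
#' mid `[b1, b2)`, far `[b2, upper_cut]`; anything outside
#' `[lower_cut, upper_cut]` is excluded as uninformative (too close) or out
#' of range (too far).
#'
#' @param lower_cut,b1,b2,upper_cut increasing distance boundaries.
#' @return object of class `stratification_config`.
#' @export
stratification_config <- function(lower_cut = 0.05, b1 = 0.31, b2 = 0.55,
                                  upper_cut = 0.73) {
  if (!(lower_cut < b1 && b1 < b2 && b2 < upper_cut))
    stopf("stratification boundaries must satisfy lower_cut < b1 < b2 < upper_cut")
  structure(list(lower_cut = lower_cut, b1 = b1, b2 = b2, upper_cut = upper_cut),
            class = "stratification_config")
}

#' Stratify promoters by distance to the target
#'
#' @param dm a `distance_matrix` containing the target.
#' @param target_id id of the target promoter.
#' @param cfg a [stratification_config()].
#' @return object of class `promoter_subgroups`: lists `g1`, `g2`, `g3`
#'   (near, mid, far), `excluded`, and `target_id`.
#' @export
stratify <- function(dm, target_id, cfg = stratification_config()) {
  if (!(target_id %in% dm$ids)) stopf("target id '%s' not in distance matrix", target_id)
  others <- setdiff(dm$ids, target_id)
  dist_to_target <- dm$d[others, target_id]
  bin <- ifelse(dist_to_target < cfg$lower_cut | dist_to_target > cfg$upper_cut, 0L,
         ifelse(dist_to_target < cfg$b1, 1L,
         ifelse(dist_to_target < cfg$b2, 2L, 3L)))
  structure(list(g1 = others[bin == 1L],
                 g2 = others[bin == 2L],
                 g3 = others[bin == 3L],
                 excluded = others[bin == 0L],
                 target_id = target_id),
            class = "promoter_subgroups")
}

#' Sizes of the three distance subgroups
#' @param groups a `promoter_subgroups` from [stratify()].
#' @return integer triple (near, mid, far).
#' @export
subgroup_sizes <- function(groups) {
  c(length(groups$g1), length(groups$g2), length(groups$g3))
}

#' Export / import a distance matrix as TSV
#'
#' Square matrix with an `id` header column, for caching.
#'
#' @param dm a `distance_matrix`.
#' @param path TSV file.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(id = dm$ids, dm$d, check.names = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read_tsv_file(path)
  ids <- df$id
  d <- as.matrix(df[, -1, drop = FALSE])
  distance_matrix(ids, unname(d))
}
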