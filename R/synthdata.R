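# Simulation of orthologous promoter sets with implanted conserved motifs
# and known ground truth: neutrally evolving Jukes-Cantor background with
# rate-scaled (conserved) motif columns.

#' Default implanted motif model
#'
#' A sharp 10-column PWM (dominant base probability `dominance`) with
#' consensus TTGACGTCAA; information content about 14 bits under a uniform
#' background.
#'
#' @param width motif width (consensus recycled/truncated to it).
#' @param dominance probability of the consensus base per column.
#' @return W x 4 row-stochastic matrix.
#' @export
default_implant_pwm <- function(width = 10L, dominance = 0.91) {
  consensus <- strsplit(strrep("TTGACGTCAA", ceiling(width / 10)), "")[[1]][seq_len(width)]
  pwm <- matrix((1 - dominance) / 3, nrow = width, ncol = 4,
                dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(width)) pwm[i, consensus[i]] <- dominance
  pwm
}

#' Simulation configuration
#'
#' @param n_taxa number of leaves including the target (>= 4).
#' @param promoter_length promoter length in bp.
#' @param background root base frequencies.
#' @param implant_pwm PWM the implanted motif is drawn from.
#' @param implant_positions 0-based starts of implants on the root promoter;
#'   intervals must lie within the promoter and not overlap.
#' @param conservation fraction c in `[0, 1]`: motif positions substitute at
#'   rate `c` times the background rate (0 = perfectly conserved).
#' @param depth_range distances from the target spanned by the leaves;
#'   the default covers all three stratification bins.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 30L, promoter_length = 250L,
                       background = rep(0.25, 4),
                       implant_pwm = default_implant_pwm(),
                       implant_positions = 100L, conservation = 0.1,
                       depth_range = c(0.05, 0.73), seed = 1L) {
  if (n_taxa < 4L) stopf("n_taxa must be >= 4")
  if (conservation < 0 || conservation > 1) stopf("conservation must be in [0, 1]")
  w <- nrow(implant_pwm)
  iv <- sort(as.integer(implant_positions))
  if (any(iv < 0L) || any(iv + w > promoter_length))
    stopf("implant interval outside the promoter")
  if (length(iv) > 1L && any(diff(iv) < w)) stopf("implant intervals overlap")
  stopifnot(length(depth_range) == 2L, depth_range[1] <= depth_range[2],
            depth_range[1] > 0)
  structure(list(n_taxa = as.integer(n_taxa),
                 promoter_length = as.integer(promoter_length),
                 background = background, implant_pwm = implant_pwm,
                 implant_positions = iv, conservation = conservation,
                 depth_range = depth_range, seed = seed),
            class = "sim_config")
}

# Jukes-Cantor substitution probability per site for branch length d.
jc_sub_prob <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Simulate a guide tree with controlled target distances
#'
#' Generates a pure-birth (Yule) topology for the non-target taxa, then
#' rewrites branch lengths so target-to-leaf distances are drawn from the
#' three stratification bins in a 1:1:2 round-robin (matching the 3:3:6
#' sampling quota), guaranteeing every bin is populated for n_taxa >= 13.
#' A collapsed `depth_range` yields equal (star-like) distances.
#'
#' @param n_taxa leaves including the target `t1` (>= 4).
#' @param depth_range span of target-to-leaf distances.
#' @param seed integer seed.
#' @return `ape::phylo` with leaves `t1` (target), `o1`, ..., `o<n-1>`.
#' @export
simulate_tree <- function(n_taxa, depth_range = c(0.05, 0.73), seed = 1L) {
  if (n_taxa < 4L) stopf("n_taxa must be >= 4")
  n_o <- n_taxa - 1L
  with_seed(seed, {
    lo <- depth_range[1]; hi <- depth_range[2]
    if (hi - lo < 1e-12) {
      d <- rep(lo, n_o)
    } else {
      # bin edges: the default stratification cuts, rescaled into depth_range
      rel <- (c(0.05, 0.31, 0.55, 0.73) - 0.05) / 0.68
      edges <- lo + (hi - lo) * rel
      bins <- rep(c(1L, 2L, 3L, 3L), length.out = n_o)
      eps <- (hi - lo) * 1e-4
      d <- stats::runif(n_o, edges[bins] + eps, edges[bins + 1L] - eps)
    }
    min_d <- min(d)
    t0 <- min_d / 4          # target pendant edge
    e0 <- min_d / 4          # edge joining the ortholog subtree
    if (n_o == 1L) {
      txt <- sprintf("(t1:%.10f,o1:%.10f);", t0, d[1] - t0)
      return(read_newick_text(txt))
    }
    sub <- ape::rphylo(n_o, birth = 1, death = 0)
    sub$tip.label <- paste0("o", seq_len(n_o))
    # internal edges get a small uniform length so no root-to-parent path
    # exceeds the depth budget; pendants absorb the per-leaf distance
    n_node <- sub$Nnode
    root <- n_o + 1L
    depth_edges <- integer(n_o + n_node)  # edge count root -> node
    ord <- reorder(sub, "cladewise")
    for (k in seq_len(nrow(ord$edge)))
      depth_edges[ord$edge[k, 2]] <- depth_edges[ord$edge[k, 1]] + 1L
    parent_of <- integer(n_o + n_node)
    parent_of[sub$edge[, 2]] <- sub$edge[, 1]
    max_int <- max(depth_edges[parent_of[seq_len(n_o)]], 1L)
    delta <- (min_d / 4) / max_int
    el <- rep(delta, nrow(sub$edge))
    is_pendant <- sub$edge[, 2] <= n_o
    leaf <- sub$edge[is_pendant, 2]
    el[is_pendant] <- d[leaf] - t0 - e0 - delta * depth_edges[parent_of[leaf]]
    sub$edge.length <- el
    sub_txt <- sub(";$", "", ape::write.tree(sub))
    read_newick_text(sprintf("(t1:%.10f,%s:%.10f);", t0, sub_txt, e0))
  })
}

#' Evolve promoter sequences down a tree
#'
#' The root promoter draws background positions i.i.d. from the background
#' frequencies and implant positions column-wise from the implant PWM. Along
#' each branch of length d, a background site substitutes with probability
#' `p(d) = (3/4)(1 - exp(-4d/3))` (uniformly among the three alternatives)
#' and a motif site with probability `p(c * d)`.
#'
#' @param cfg a [sim_config()].
#' @param tree optional `ape::phylo`; simulated via [simulate_tree()] when
#'   absent.
#' @return list with `promoters` (a `promoter_set`, target marked) and
#'   `truth` (per-taxon implant intervals, the tree, the root sequence).
#' @export
evolve_promoters <- function(cfg, tree = NULL) {
  if (is.null(tree))
    tree <- simulate_tree(cfg$n_taxa, cfg$depth_range, seed = cfg$seed)
  W <- nrow(cfg$implant_pwm)
  L <- cfg$promoter_length
  motif_mask <- logical(L)
  for (s in cfg$implant_positions) motif_mask[(s + 1L):(s + W)] <- TRUE

  with_seed(cfg$seed + 1L, {
    root_seq <- sample.int(4L, L, replace = TRUE, prob = cfg$background)
    for (s in cfg$implant_positions)
      for (w in seq_len(W))
        root_seq[s + w] <- sample.int(4L, 1L, prob = cfg$implant_pwm[w, ])

    n_tip <- length(tree$tip.label)
    node_seq <- vector("list", n_tip + tree$Nnode)
    root <- n_tip + 1L
    node_seq[[root]] <- root_seq
    ord <- reorder(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
      d <- ord$edge.length[k]
      s <- node_seq[[par]]
      p_bg <- jc_sub_prob(d)
      p_mot <- jc_sub_prob(cfg$conservation * d)
      p_site <- ifelse(motif_mask, p_mot, p_bg)
      mut <- stats::runif(L) < p_site
      if (any(mut)) {
        shift <- sample.int(3L, sum(mut), replace = TRUE)
        s[mut] <- ((s[mut] - 1L + shift) %% 4L) + 1L
      }
      node_seq[[child]] <- s
    }

    recs <- lapply(seq_len(n_tip), function(i) {
      promoter_record(tree$tip.label[i],
                      paste(DNA_BASES[node_seq[[i]]], collapse = ""),
                      is_target = tree$tip.label[i] == "t1")
    })
    truth_iv <- do.call(rbind, lapply(tree$tip.label, function(tx)
      data.frame(taxon = tx, start = cfg$implant_positions,
                 end = cfg$implant_positions + W, strand = "+",
                 stringsAsFactors = FALSE)))
    list(promoters = promoter_set(recs, require_target = TRUE),
         truth = list(intervals = truth_iv, tree = tree,
                      root_sequence = paste(DNA_BASES[root_seq], collapse = "")))
  })
}

#' Write ground-truth implant intervals as BED
#'
#' @param truth the `truth` element of [evolve_promoters()] output.
#' @param path BED file (taxon as chrom, 0-based half-open intervals).
#' @export
write_truth_bed <- function(truth, path) {
  iv <- truth$intervals
  writeLines(sprintf("%s\t%d\t%d\timplant\t0\t%s",
                     iv$taxon, iv$start, iv$end, iv$strand), path)
  invisible(path)
}

#' Generate a decoy motif database around an implant PWM
#'
#' The implant PWM is included under `name`; decoys are equally sharp PWMs
#' built on independent random consensus words of the same width, giving a
#' database in which only the implant should match the recovered motif.
#'
#' @param pwm implant PWM.
#' @param n_decoys number of decoy motifs.
#' @param seed integer seed.
#' @param name database name of the implant motif.
#' @param dominance per-column probability of each decoy's consensus base.
#' @return a `motif_database` of size `n_decoys + 1`.
#' @export
make_decoy_database <- function(pwm, n_decoys = 19L, seed = 1L,
                                name = "implant", dominance = 0.91) {
  W <- nrow(pwm)
  with_seed(seed, {
    motifs <- list()
    motifs[[name]] <- list(pwm = pwm, nsites = 20L)
    for (i in seq_len(n_decoys)) {
      cons <- sample.int(4L, W, replace = TRUE)
      dp <- matrix((1 - dominance) / 3, nrow = W, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
      for (w in seq_len(W)) dp[w, cons[w]] <- dominance
      motifs[[sprintf("decoy_%02d", i)]] <- list(pwm = dp, nsites = 20L)
    }
    motif_database(motifs)
  })
}
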