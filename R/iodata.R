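# I/O for the external formats the pipeline touches (FASTA, Newick, MEME
# minimal motif format, BedGraph/BigWig, TSV) and the shared record types.

#' Create a promoter record
#'
#' One orthologous promoter sequence with its taxon identity. Sequences are
#' uppercased; only A/C/G/T/N are allowed.
#'
#' @param id unique identifier (matched to tree leaves by exact equality).
#' @param sequence DNA string.
#' @param taxon taxon label; defaults to `id`.
#' @param source_offset 0-based genomic start of the promoter, or `NA`.
#' @param is_target logical; exactly one record per analysis set is the
#'   target promoter.
#' @return an object of class `promoter_record`.
#' @export
promoter_record <- function(id, sequence, taxon = id, source_offset = NA_integer_,
                            is_target = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stopf("record '%s': invalid character '%s' at position %d",
          id, substr(sequence, bad, bad), bad)
  if (nchar(sequence) < 1L) stopf("record '%s': empty sequence", id)
  structure(list(id = id, taxon = taxon, sequence = sequence,
                 source_offset = source_offset, is_target = isTRUE(is_target)),
            class = "promoter_record")
}

#' Bundle promoter records into an analysis set
#'
#' @param records list of [promoter_record()] objects.
#' @param require_target if `TRUE`, validates that exactly one record has
#'   `is_target = TRUE`.
#' @return list of records with class `promoter_set`.
#' @export
promoter_set <- function(records, require_target = FALSE) {
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("duplicate promoter id: '%s'", ids[duplicated(ids)][1])
  if (require_target) {
    nt <- sum(vapply(records, `[[`, logical(1), "is_target"))
    if (nt != 1L) stopf("analysis set must contain exactly one target promoter (found %d)", nt)
  }
  names(records) <- ids
  structure(records, class = "promoter_set")
}

promoter_ids <- function(records) vapply(records, `[[`, character(1), "id")

target_id_of <- function(records) {
  tid <- promoter_ids(records)[vapply(records, `[[`, logical(1), "is_target")]
  if (length(tid) != 1L) stopf("expected exactly one target promoter, found %d", length(tid))
  tid
}

#' Read promoter sequences from FASTA
#'
#' The header token before the first whitespace becomes the record id.
#' Sequences are uppercased; any character outside A/C/G/T/N is an error
#' naming the record and position.
#'
#' @param path FASTA file.
#' @param target_id optional id to mark as the target promoter.
#' @return a `promoter_set` (possibly empty).
#' @export
read_promoter_fasta <- function(path, target_id = NULL) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  recs <- lapply(seq_along(ss), function(i) {
    id <- sub("\\s.*$", "", names(ss)[i])
    promoter_record(id, as.character(ss[[i]]),
                    is_target = !is.null(target_id) && id == target_id)
  })
  promoter_set(recs)
}

#' Write promoter records to FASTA
#' @param records a `promoter_set` or list of promoter records.
#' @param path output file.
#' @export
write_promoter_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- promoter_ids(records)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a guide tree from a Newick file
#'
#' Branch lengths are required on every edge (evolutionary distances are the
#' method's input, not optional); leaf labels must be unique.
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("Newick file not found: %s", path)
  read_newick_text(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname read_newick
#' @param text Newick string.
#' @export
read_newick_text <- function(text) {
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stopf("Newick parse error: unbalanced parentheses")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree)) stopf("Newick parse error: %s", substr(text, 1, 60))
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate leaf label in tree: '%s'",
          tree$tip.label[duplicated(tree$tip.label)][1])
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stopf("tree is missing branch lengths; distances require them")
  if (any(tree$edge.length < 0)) stopf("negative branch length in tree")
  tree
}

#' Write a guide tree to Newick
#' @param tree `ape::phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct a known-motif database
#'
#' @param motifs named list; each element a list with `pwm` (W x 4 matrix,
#'   rows summing to 1, columns A,C,G,T) and `nsites`.
#' @param background length-4 base frequency vector summing to 1.
#' @return object of class `motif_database`.
#' @export
motif_database <- function(motifs, background = rep(0.25, 4)) {
  if (length(motifs) && (is.null(names(motifs)) || any(!nzchar(names(motifs)))))
    stopf("every database motif must be named")
  if (anyDuplicated(names(motifs)))
    stopf("duplicate motif name in database: '%s'",
          names(motifs)[duplicated(names(motifs))][1])
  for (nm in names(motifs)) {
    pwm <- motifs[[nm]]$pwm
    if (!is.matrix(pwm) || ncol(pwm) != 4L)
      stopf("motif '%s': PWM must be a W x 4 matrix", nm)
    if (nrow(pwm) < 4L) stopf("motif '%s': width %d < 4", nm, nrow(pwm))
    if (any(abs(rowSums(pwm) - 1) > 1e-3))
      stopf("motif '%s': probability matrix row does not sum to 1", nm)
    motifs[[nm]]$pwm <- pwm / rowSums(pwm)
    motifs[[nm]]$nsites <- motifs[[nm]]$nsites %||% 20L
  }
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  structure(list(motifs = motifs, background = background),
            class = "motif_database")
}

#' Read motifs in MEME minimal format
#'
#' Supports the minimal format: `MEME version`, `ALPHABET= ACGT`, optional
#' `Background letter frequencies`, and per-motif
#' `letter-probability matrix` blocks. Background defaults to uniform when
#' absent from the file.
#'
#' @param path MEME-format file.
#' @return a `motif_database`.
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) stopf("MEME file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines)))
    stopf("not a MEME minimal motif file (missing 'MEME version'): %s", path)
  alpha_i <- grep("^ALPHABET", lines)
  if (!length(alpha_i)) stopf("MEME file missing ALPHABET line: %s", path)
  alpha <- gsub("\\s", "", sub("^ALPHABET=?", "", lines[alpha_i[1]]))
  if (alpha != "ACGT") stopf("unsupported alphabet '%s' (only ACGT)", alpha)

  background <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toks[seq(1, 7, by = 2)]
      background <- unname(vals[DNA_BASES])
      if (anyNA(background) || abs(sum(background) - 1) > 1e-3)
        stopf("malformed background frequencies in %s", path)
      background <- background / sum(background)
    }
  }

  motif_starts <- grep("^MOTIF\\s", lines)
  motifs <- list()
  for (s in motif_starts) {
    name <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[s])), "\\s+")[[1]][1]
    lp_rel <- grep("^letter-probability matrix", lines[s:length(lines)])[1]
    if (is.na(lp_rel)) stopf("motif '%s': missing letter-probability matrix", name)
    lp <- s + lp_rel - 1L
    w <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[lp])))
    nsites <- suppressWarnings(as.integer(sub(".*\\bnsites=\\s*(\\d+).*", "\\1", lines[lp])))
    if (is.na(nsites)) nsites <- 20L
    rows <- list(); i <- lp + 1L
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (!nzchar(tl) || grepl("^(MOTIF|letter-probability|URL)", tl)) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) != 4L)
        stopf("motif '%s': malformed matrix row %d", name, length(rows) + 1L)
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    pwm <- do.call(rbind, rows)
    if (!is.na(w) && nrow(pwm) != w)
      stopf("motif '%s': declared w=%d but %d matrix rows", name, w, nrow(pwm))
    bad <- which(abs(rowSums(pwm) - 1) > 1e-3)
    if (length(bad))
      stopf("motif '%s': matrix row %d sums to %.4f (not 1)",
            name, bad[1], rowSums(pwm)[bad[1]])
    colnames(pwm) <- DNA_BASES
    if (name %in% names(motifs)) stopf("duplicate motif name in database: '%s'", name)
    motifs[[name]] <- list(pwm = pwm, nsites = nsites)
  }
  motif_database(motifs, background)
}

#' Write motifs in MEME minimal format
#'
#' @param motifs a `motif_database`, or a list of motif objects (each with
#'   `$pwm` and optionally `$nsites`); unnamed lists are named motif_1, ...
#' @param path output file.
#' @param background length-4 base frequency vector.
#' @export
write_meme_motifs <- function(motifs, path, background = NULL) {
  if (inherits(motifs, "motif_database")) {
    background <- background %||% motifs$background
    motifs <- motifs$motifs
  }
  background <- background %||% rep(0.25, 4)
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    names(motifs) <- sprintf("motif_%d", seq_along(motifs))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3], background[4]),
               ""), con)
  for (nm in names(motifs)) {
    m <- motifs[[nm]]
    pwm <- m$pwm
    nsites <- m$nsites %||% (if (!is.null(m$instances)) nrow(m$instances) else 20L)
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       nrow(pwm), nsites), con)
    writeLines(apply(pwm, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a position histogram as BedGraph
#'
#' Intervals are 0-based half-open; runs of equal value are merged into a
#' single line and zero runs are omitted. Values are raw run-support counts.
#'
#' @param histogram a `position_histogram` (see [accumulate_histogram()]).
#' @param path output file.
#' @param chrom chromosome/sequence name for column 1.
#' @param chrom_offset integer added to positions (0 keeps promoter-local
#'   coordinates; the promoter's genomic start gives genomic coordinates).
#' @export
write_bedgraph <- function(histogram, path, chrom = histogram$target_id,
                           chrom_offset = 0L) {
  counts <- histogram$counts
  if (length(counts) < 1L) stopf("cannot write BedGraph for a zero-length histogram")
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = rep(chrom, sum(keep)),
                   start = starts[keep] + chrom_offset,
                   end = ends[keep] + chrom_offset,
                   value = r$values[keep], row.names = NULL)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", chrom), con)
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%g", df$chrom, df$start, df$end, df$value), con)
  invisible(path)
}

#' Write a position histogram as BigWig (optional backend)
#'
#' BedGraph is the canonical artifact; BigWig is emitted additionally when
#' the `rtracklayer` backend is installed.
#'
#' @inheritParams write_bedgraph
#' @param chrom_length total length of `chrom` (defaults to offset + length).
#' @return the path, or `NULL` (with a message) when no backend is available.
#' @export
write_bigwig <- function(histogram, path, chrom = histogram$target_id,
                         chrom_offset = 0L, chrom_length = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    message("rtracklayer not installed; skipping BigWig output (BedGraph is canonical)")
    return(invisible(NULL))
  }
  counts <- histogram$counts
  if (length(counts) < 1L) stopf("cannot write BigWig for a zero-length histogram")
  r <- rle(counts)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values != 0
  chrom_length <- chrom_length %||% (chrom_offset + length(counts))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts[keep] + chrom_offset + 1L,
                              end = ends[keep] + chrom_offset),
    score = as.numeric(r$values[keep]))
  GenomeInfoDb::seqlengths(gr) <- chrom_length
  rtracklayer::export.bw(gr, path)
  invisible(path)
}

#' Write called peaks as BED6
#'
#' Name is `peak_<k>`; score is `round(1000 * support_frac)` capped at 1000.
#'
#' @param peaks data frame from [call_peaks()].
#' @param path output file.
#' @param chrom sequence name.
#' @param chrom_offset coordinate offset as in [write_bedgraph()].
#' @export
write_peaks_bed <- function(peaks, path, chrom, chrom_offset = 0L) {
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(peaks))
    writeLines(sprintf("%s\t%d\t%d\tpeak_%d\t%d\t.",
                       chrom, peaks$start + chrom_offset, peaks$end + chrom_offset,
                       peaks$peak_id, pmin(1000L, round(1000 * peaks$support_frac))),
               con)
  invisible(path)
}
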