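# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Accepts uppercase A/C/G/T/N; N maps to N.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Encode A,C,G,T,N -> 0,1,2,3,4 for the compiled finders.
encode_dna <- function(s) {
  m <- match(strsplit(s, "", fixed = TRUE)[[1]], c(DNA_BASES, "N")) - 1L
  if (anyNA(m)) stop("sequence contains characters outside {A,C,G,T,N}")
  m
}

decode_dna <- function(v) paste(c(DNA_BASES, "N")[v + 1L], collapse = "")

# Run `code` under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Consistent TSV writing: tab-separated, no quoting, no row names.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msg <- function(fmt, ..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}
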