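# Internal helpers shared across modules.

.fam_env <- new.env(parent = emptyenv())

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA4 <- c("A", "C", "G", "T")

#' @importFrom utils data
.blosum62 <- function() {
  if (is.null(.fam_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .fam_env$blosum62 <- e$BLOSUM62
  }
  .fam_env$blosum62
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_token <- function(x) {
  is.character(x) && length(x) == 1L && nzchar(x) && !grepl("[[:space:]]", x)
}

# residues -> 0-based indices into a scoring matrix with given row names
.encode_residues <- function(s, alphabet) {
  idx <- match(strsplit(s, "")[[1]], alphabet) - 1L
  if (anyNA(idx))
    .stopf("sequence contains characters outside alphabet: %s",
           paste(setdiff(strsplit(s, "")[[1]], alphabet), collapse = ""))
  idx
}

.seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
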