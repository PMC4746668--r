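#' PROSITE patterns
#'
#' `read_prosite()` parses a PROSITE pattern string (elements separated by
#' `-`: residue letters, `[...]` allowed sets, `{...}` excluded sets, `x`
#' wildcards, `(n)`/`(n,m)` repeats, `<`/`>` anchors; an optional trailing
#' `.` is tolerated) into a matcher; `match_prosite()` returns all
#' leftmost non-overlapping matches as 1-based inclusive coordinates.
#'
#' @param pattern PROSITE pattern string, e.g. `"R-x(2)-K"`.
#' @return `read_prosite()`: a `prosite_pattern` object (carries the
#'   translated regular expression).
#' @export
read_prosite <- function(pattern) {
  raw <- pattern
  p <- sub("\\.$", "", trimws(pattern))
  if (!nzchar(p)) .stopf("empty PROSITE pattern")
  anchor_start <- grepl("^<", p)
  anchor_end <- grepl(">$", p)
  p <- sub("^<", "", p)
  p <- sub(">$", "", p)
  elements <- strsplit(p, "-", fixed = TRUE)[[1]]
  rx <- character(0)
  for (k in seq_along(elements)) {
    el <- elements[k]
    if (!nzchar(el)) .stopf("empty element at position %d in '%s'", k, raw)
    m <- regmatches(el, regexec("^(\\[[A-Z]+\\]|\\{[A-Z]+\\}|[A-Zx])(\\((\\d+)(,(\\d+))?\\))?$", el))[[1]]
    if (!length(m)) .stopf("malformed PROSITE element '%s' at position %d", el, k)
    core <- m[2]
    body <- if (core == "x") "." else if (startsWith(core, "[")) core
      else if (startsWith(core, "{")) paste0("[^", substr(core, 2, nchar(core) - 1), "]")
      else core
    if (nzchar(m[3])) {
      body <- if (nzchar(m[5])) sprintf("%s{%s,%s}", body, m[4], m[6])
              else sprintf("%s{%s}", body, m[4])
    }
    rx <- c(rx, body)
  }
  regex <- paste0(if (anchor_start) "^" else "", paste(rx, collapse = ""),
                  if (anchor_end) "$" else "")
  structure(list(pattern = raw, regex = regex), class = "prosite_pattern")
}

#' @rdname read_prosite
#' @param seq protein sequence string.
#' @return `match_prosite()`: data.frame with columns `start`, `end`
#'   (1-based inclusive), zero rows if no match.
#' @export
match_prosite <- function(pattern, seq) {
  if (is.character(pattern)) pattern <- read_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  m <- gregexpr(pattern$regex, toupper(seq))[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}
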