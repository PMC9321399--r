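# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., call. = FALSE) stop(sprintf(fmt, ...), call. = call.)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a seed without disturbing the caller's RNG stream
#'
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Detect the field separator of a text table (comma or tab) from its header.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stopf("file '%s' is empty", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_comma <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_comma && n_tab > 0L) "\t" else ","
}

# Read a CSV/TSV with auto-detected separator; report the offending line on
# ragged input instead of utils' opaque error.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  sep <- detect_sep(path)
  nf <- tryCatch(
    utils::count.fields(path, sep = sep, quote = "\"", comment.char = ""),
    error = function(e) stopf("cannot parse '%s': %s", path, conditionMessage(e))
  )
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stopf("malformed file '%s': line %d has %d fields, expected %d",
          path, bad, nf[bad], nf[1L])
  }
  out <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           strip.white = TRUE, comment.char = "", quote = "\"")
  names(out) <- trimws(names(out))
  out
}

is_binary01 <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x %in% c(0, 1))
}

assert_binary_labels <- function(y, what = "labels") {
  if (!is_binary01(as.numeric(y))) {
    stopf("%s must be binary 0/1 with no missing values", what)
  }
  if (length(unique(y)) < 2L) stopf("%s contain a single class", what)
  invisible(as.numeric(y))
}
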