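BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == trunc(x) && x >= 1

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T; any other
#' character becomes `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  .revcomp_cpp(as.character(x))
}

#' Pack k-mers into numeric codes
#'
#' Encodes each k-mer as `sum(code[i] * 4^(k-1-i))` with A=0, C=1, G=2, T=3,
#' stored in a double (exact for `k <= 26`). Numeric order of codes equals
#' lexicographic order of the k-mer strings, so sorted joins on codes are
#' sorted joins on sequences.
#'
#' @param x character vector of equal-length k-mers.
#' @param k k-mer length; defaults to the length of the first element.
#' @return numeric vector of codes (`NA` for k-mers with non-ACGT bases).
#' @seealso [decode_kmers()]
#' @export
encode_kmers <- function(x, k = nchar(x[1])) {
  if (length(x) == 0L) return(numeric(0))
  if (any(nchar(x) != k)) stopf("all k-mers must have length %d", k)
  .encode_at_cpp(as.character(x), 1L, as.integer(k))
}

#' Unpack numeric k-mer codes into strings
#'
#' @param codes numeric vector of packed k-mer codes.
#' @param k k-mer length.
#' @return character vector of k-mers.
#' @seealso [encode_kmers()]
#' @export
decode_kmers <- function(codes, k) {
  .decode_codes_cpp(as.numeric(codes), as.integer(k))
}

## byte-lexicographic (C locale) sort, the total order used across all modules
lex_sort <- function(x) sort(x, method = "radix")

## base <-> code helpers
base_to_code <- function(b) match(b, BASES) - 1L
code_to_base <- function(code) BASES[code + 1L]

## open a file connection, transparently handling gzip (by magic bytes)
open_maybe_gz <- function(path, mode = "rt") {
  magic <- tryCatch(readBin(path, "raw", n = 2L), error = function(e) raw(0))
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    gzfile(path, mode)
  else
    file(path, mode)
}

read_lines_fast <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  scan(con, what = character(), sep = "\n", quiet = TRUE,
       quote = "", comment.char = "", blank.lines.skip = FALSE)
}

## run code with a private RNG stream seeded by `seed`, restoring global state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
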