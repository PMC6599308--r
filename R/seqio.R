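## seqio: sequence I/O and the sorted-unique ("sort_uniq") read set that the
## whole pipeline consumes.

#' Construct a genome object
#'
#' A genome is a named character vector of uppercase chromosome sequences
#' over A/C/G/T/N, with unique non-empty names.
#'
#' @param sequences named character vector of chromosome sequences.
#' @return a `ped_genome` object.
#' @export
genome <- function(sequences) {
  if (length(sequences) == 0L) stopf("genome needs at least one chromosome")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stopf("all chromosomes must be named")
  if (anyDuplicated(nm)) stopf("duplicate chromosome names: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(!nzchar(sequences))) stopf("chromosome sequences must be non-empty")
  sequences <- toupper(sequences)
  structure(sequences, class = c("ped_genome", "character"))
}

#' @export
print.ped_genome <- function(x, ...) {
  cat(sprintf("ped_genome: %d chromosome(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (i in seq_along(x))
    cat(sprintf("  %s  %s bp\n", names(x)[i], format(nchar(x[i]), big.mark = ",")))
  invisible(x)
}

#' Read a FASTA file as a genome
#'
#' Sequences are uppercased; the chromosome name is the header token before
#' the first whitespace. Wrapped and unwrapped FASTA and gzip compression are
#' supported.
#'
#' @param path FASTA file path.
#' @return a [genome()] object with chromosomes in file order.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) stopf("duplicate chromosome names in %s", path)
  genome(setNames(as.character(dss), nm))
}

#' Write a genome to FASTA
#'
#' @param x a [genome()] object or named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records (qualities are ignored), optionally
#' gzip-compressed, and returns the uppercased read sequences in file order.
#' A structurally malformed record raises an error naming the record index.
#'
#' @param path FASTQ file path.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- read_lines_fast(path)
  n <- length(lines)
  if (n == 0L) return(character(0))
  if (n %% 4L != 0L)
    stopf("malformed FASTQ record %d in %s: truncated record", n %/% 4L + 1L, path)
  hd <- lines[seq.int(1L, n, by = 4L)]
  sq <- lines[seq.int(2L, n, by = 4L)]
  pl <- lines[seq.int(3L, n, by = 4L)]
  qu <- lines[seq.int(4L, n, by = 4L)]
  bad <- !startsWith(hd, "@") | !startsWith(pl, "+") | nchar(sq) != nchar(qu)
  if (any(bad))
    stopf("malformed FASTQ record %d in %s", which(bad)[1], path)
  toupper(sq)
}

#' Write reads to FASTQ
#'
#' Writes 4-line records with constant `I` quality strings. Compression is
#' chosen from the file extension (`.gz`).
#'
#' @param reads character vector of read sequences.
#' @param path output path.
#' @param ids optional record identifiers (default `read1`, `read2`, ...).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  n <- length(reads)
  ids <- ids %||% paste0("read", seq_len(n))
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (n > 0L) {
    rec <- paste0("@", ids, "\n", reads, "\n+\n",
                  strrep("I", nchar(reads)), "\n")
    writeLines(paste(rec, collapse = ""), con, sep = "")
  }
  invisible(path)
}

#' Build the sorted unique read set
#'
#' Removes reads containing any non-ACGT character (PCR-duplicate and
#' error-tail control per the pipeline's design), adds the reverse complement
#' of every surviving read, deduplicates and sorts byte-lexicographically.
#' The result ("sort_uniq" reads) is closed under reverse complement and is
#' the input to all counting and verification stages.
#'
#' @param reads character vector of read sequences (uppercase).
#' @return a sorted character vector of class `ped_readset`.
#' @export
sort_unique_reads <- function(reads) {
  reads <- as.character(reads)
  if (length(reads)) {
    keep <- !grepl("[^ACGT]", reads)
    reads <- reads[keep]
  }
  out <- if (length(reads)) lex_sort(unique(c(reads, .revcomp_cpp(reads))))
         else character(0)
  structure(out, class = c("ped_readset", "character"))
}

#' @export
print.ped_readset <- function(x, ...) {
  lens <- if (length(x)) range(nchar(x)) else c(0L, 0L)
  cat(sprintf("ped_readset: %s reads (complement-closed, sorted), length %d..%d\n",
              format(length(x), big.mark = ","), lens[1], lens[2]))
  invisible(x)
}

#' Read/write a sorted read set as plain text
#'
#' One read per line, in sorted order (the "sort_uniq" file format).
#'
#' @param reads a `ped_readset`.
#' @param path file path.
#' @return `write_read_set`: `path` invisibly; `read_read_set`: a
#'   `ped_readset`.
#' @export
write_read_set <- function(reads, path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(reads, con)
  invisible(path)
}

#' @rdname write_read_set
#' @export
read_read_set <- function(path) {
  x <- read_lines_fast(path)
  if (!identical(x, lex_sort(x))) stopf("%s is not a sorted read set", path)
  structure(x, class = c("ped_readset", "character"))
}
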