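## ref_index: genome-unique k-mer index and exact-match anchoring of read
## ends by sorted merge-join ("mapping by join").

#' Build a genome-unique k-mer index
#'
#' Enumerates every k-mer window of every chromosome on the forward strand
#' and its reverse complement (recorded at the same forward-strand start
#' position, strand `-`). Windows containing non-ACGT bases are skipped. Any
#' k-mer occurring more than once in the combined enumeration is removed
#' entirely, so every retained k-mer identifies a single genomic locus and
#' strand.
#'
#' @param genome a [genome()] object.
#' @param k k-mer length (2..26).
#' @return a `data.table` keyed by packed k-mer `code` with columns `chrom`
#'   (integer chromosome index), `pos` (1-based forward-strand start) and
#'   `strand` (+1/-1); attributes `k` and `chrom_names`.
#' @export
build_reference_index <- function(genome, k = 20L) {
  k <- as.integer(k)
  if (k < 2L || k > 26L) stopf("k must be in 2..26")
  enc <- .encode_windows_cpp(unclass(genome), k)
  nwin <- enc$n
  fwd <- data.table(
    code = enc$codes,
    chrom = rep(seq_along(genome), nwin),
    pos = unlist(lapply(nwin, seq_len), use.names = FALSE),
    strand = 1L)
  fwd <- fwd[!is.na(code)]
  rev <- data.table(code = .revcomp_codes_cpp(fwd$code, k),
                    chrom = fwd$chrom, pos = fwd$pos, strand = -1L)
  idx <- rbindlist(list(fwd, rev))
  setkey(idx, code)
  dup <- duplicated(idx, by = "code") | duplicated(idx, by = "code", fromLast = TRUE)
  idx <- idx[!dup]
  setattr(idx, "k", k)
  setattr(idx, "chrom_names", names(genome))
  setattr(idx, "class", c("ped_ref_index", class(idx)))
  idx[]
}

#' @export
print.ped_ref_index <- function(x, ...) {
  cat(sprintf("ped_ref_index: %s genome-unique %d-mers on %d chromosome(s)\n",
              format(nrow(x), big.mark = ","), attr(x, "k"),
              length(attr(x, "chrom_names"))))
  invisible(x)
}

#' Serialize a reference index as sorted TSV
#'
#' Columns: kmer sequence, chromosome name, 1-based position, strand (+/-).
#'
#' @param index a [build_reference_index()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_index <- function(index, path) {
  k <- attr(index, "k")
  out <- data.table(kmer = decode_kmers(index$code, k),
                    chrom = attr(index, "chrom_names")[index$chrom],
                    pos = index$pos,
                    strand = ifelse(index$strand > 0L, "+", "-"))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Anchor both ends of reads on the reference
#'
#' The 5' anchor is the k-mer starting `margin` bases inside the read's 5'
#' end; the 3' anchor is the k-mer ending `margin` bases before the 3' end
#' (read ends tend to have lower quality, hence the inset). Anchors are
#' looked up in the genome-unique index as one sorted merge-join over all
#' reads; an anchor is absent when its k-mer is not genome-unique (or the
#' read is shorter than `k + margin`, which is also logged).
#'
#' @param reads character vector of reads.
#' @param index a [build_reference_index()] result.
#' @param margin anchor offset from the read ends (bases).
#' @return `data.table` with one row per read: `read_id`, `len`, and
#'   `chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`, `strand3` (`NA` where the
#'   anchor is absent); attributes `k`, `margin`, `chrom_names`.
#' @export
map_read_ends <- function(reads, index, margin = 5L) {
  k <- attr(index, "k")
  margin <- as.integer(margin)
  lens <- nchar(reads)
  n_short <- sum(lens < k + margin)
  if (n_short > 0L)
    message(sprintf("map_read_ends: %d read(s) shorter than k + margin = %d skipped",
                    n_short, k + margin))
  code5 <- .encode_at_cpp(reads, margin + 1L, k)
  code3 <- .encode_at_cpp(reads, pmax(lens - margin - k + 1L, 1L), k)
  code3[lens < k + margin] <- NA_real_

  lookup <- function(codes) {
    q <- data.table(code = codes)
    index[q, on = "code", .(chrom, pos, strand)]
  }
  a5 <- lookup(code5)
  a3 <- lookup(code3)
  out <- data.table(read_id = seq_along(reads), len = lens,
                    chrom5 = a5$chrom, pos5 = a5$pos, strand5 = a5$strand,
                    chrom3 = a3$chrom, pos3 = a3$pos, strand3 = a3$strand)
  setattr(out, "k", k)
  setattr(out, "margin", margin)
  setattr(out, "chrom_names", attr(index, "chrom_names"))
  out[]
}
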