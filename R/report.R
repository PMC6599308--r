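## report_cli: bin classification (graphical-genotype data), VCF/TSV writers
## and the end-to-end pipeline driver.

#' Classify genome bins by shared vs sample-specific SNPs
#'
#' The genome is partitioned into consecutive bins of `bin_span` bp. Within
#' each bin the verified homozygous SNPs of two samples (against a common
#' reference) are counted; SNPs identical in chromosome, position, reference
#' and alternative base are shared. A bin is `common` when the shared
#' fraction of the union of SNPs exceeds `share_threshold`, `specific_a` /
#' `specific_b` when SNPs exist but sharing is at or below the threshold
#' (labelled by the sample with more SNPs; ties go to `a`), and `empty`
#' when the bin holds no SNPs.
#'
#' @param snps_a,snps_b SNP tables (`chrom`, `pos`, `ref`, `alt`), sorted by
#'   chromosome and position.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param bin_span bin width in bp.
#' @param share_threshold shared fraction above which a bin is `common`.
#' @return `data.table`: `chrom`, `bin_index` (1-based), `start`, `end`,
#'   `n_snps_a`, `n_snps_b`, `n_shared`, `label`.
#' @export
classify_bins <- function(snps_a, snps_b, chrom_lengths, bin_span = 50562L,
                          share_threshold = 0.30) {
  for (s in list(snps_a, snps_b)) {
    s <- as.data.table(s)
    if (nrow(s) && !identical(order(s$chrom, s$pos), seq_len(nrow(s))))
      stopf("SNP tables must be sorted by chromosome and position")
  }
  bins <- rbindlist(lapply(names(chrom_lengths), function(cn) {
    nb <- max(1L, ceiling(chrom_lengths[[cn]] / bin_span))
    data.table(chrom = cn, bin_index = seq_len(nb),
               start = (seq_len(nb) - 1L) * bin_span + 1L,
               end = pmin(seq_len(nb) * bin_span, chrom_lengths[[cn]]))
  }))
  cnt <- function(s) {
    s <- as.data.table(s)
    if (nrow(s) == 0L)
      return(data.table(chrom = character(0), bin_index = integer(0),
                        n = integer(0)))
    s[, .(n = .N), by = .(chrom, bin_index = (pos - 1L) %/% bin_span + 1L)]
  }
  a <- cnt(snps_a); b <- cnt(snps_b)
  sh <- merge(as.data.table(snps_a)[, .(chrom, pos, ref, alt)],
              as.data.table(snps_b)[, .(chrom, pos, ref, alt)],
              by = c("chrom", "pos", "ref", "alt"))
  s <- cnt(sh[, .(chrom, pos)])
  out <- merge(bins, a, by = c("chrom", "bin_index"), all.x = TRUE)
  setnames(out, "n", "n_snps_a")
  out <- merge(out, b, by = c("chrom", "bin_index"), all.x = TRUE)
  setnames(out, "n", "n_snps_b")
  out <- merge(out, s, by = c("chrom", "bin_index"), all.x = TRUE)
  setnames(out, "n", "n_shared")
  for (col in c("n_snps_a", "n_snps_b", "n_shared"))
    set(out, which(is.na(out[[col]])), col, 0L)
  out[, label := {
    union_n <- n_snps_a + n_snps_b - n_shared
    fifelse(union_n == 0L, "empty",
            fifelse(n_shared / union_n > share_threshold, "common",
                    fifelse(n_snps_a >= n_snps_b, "specific_a", "specific_b")))
  }]
  setorder(out, chrom, bin_index)
  out[]
}

vcf_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write calls as VCF 4.2
#'
#' SNPs are written as plain ref/alt records. Deletions and insertions with
#' size at most `max_seq_len` carry full sequences (anchored at the last
#' matching base); larger ones use symbolic alleles (`<DEL>`) with `END` and
#' `SVLEN`. Inversions are `<INV>` with `END`; translocations are `<TRA>`
#' with `CHR2`/`END2`. The genotype column maps verification marks `M` to
#' `1/1` and `H` to `0/1` (`./.` otherwise).
#'
#' @param calls call table ([call_variants()] / [verify_candidates()]).
#' @param genome the reference [genome()] (for anchor/deleted sequences and
#'   contig headers).
#' @param path output path.
#' @param max_seq_len size limit for writing full indel sequences.
#' @param sample sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, genome, path, max_seq_len = 100L,
                      sample = "sample") {
  calls <- as.data.table(calls)
  if (anyDuplicated(calls, by = c("chrom", "pos", "type", "ref", "alt",
                                  "size", "chrom2", "pos2")))
    stopf("duplicate call records")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pedr",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end or junction partner position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Partner chromosome of a translocation\">",
    "##INFO=<ID=END2,Number=1,Type=Integer,Description=\"Partner position of a translocation\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Distinct supporting reads\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  seqs <- unclass(genome)
  n <- nrow(calls)
  gt <- if ("genotype" %in% names(calls))
    c(M = "1/1", H = "0/1", none = "./.")[calls$genotype] else rep("./.", n)
  gt[is.na(gt)] <- "./."
  sup <- if ("support" %in% names(calls)) calls$support else rep(NA_integer_, n)

  rows <- character(n)
  for (i in seq_len(n)) {
    cl <- calls[i]
    info <- if (!is.na(sup[i])) sprintf("SUPPORT=%d", sup[i]) else "."
    if (cl$type == "SNP") {
      rows[i] <- paste(cl$chrom, vcf_num(cl$pos), ".", cl$ref, cl$alt, ".",
                       "PASS", info, "GT", gt[i], sep = "\t")
      next
    }
    anchor <- substr(seqs[[cl$chrom]], cl$pos, cl$pos)
    if (cl$type == "DEL" && cl$size <= max_seq_len) {
      ref <- substr(seqs[[cl$chrom]], cl$pos, cl$pos + cl$size)
      alt <- anchor
    } else if (cl$type == "INS" && cl$size <= max_seq_len) {
      ref <- anchor
      alt <- paste0(anchor, cl$alt)
    } else {
      ref <- anchor
      alt <- sprintf("<%s>", c(DEL = "DEL", INS = "INS", INV = "INV",
                               TRL = "TRA")[cl$type])
      info <- paste0(info, sprintf(";SVTYPE=%s",
                                   c(DEL = "DEL", INS = "INS", INV = "INV",
                                     TRL = "TRA")[cl$type]))
      if (cl$type == "TRL") {
        info <- paste0(info, sprintf(";CHR2=%s;END2=%s", cl$chrom2,
                                     vcf_num(cl$pos2)))
      } else if (!is.na(cl$pos2)) {
        info <- paste0(info, sprintf(";END=%s", vcf_num(cl$pos2)))
      }
      if (!is.na(cl$size))
        info <- paste0(info, sprintf(";SVLEN=%s",
                                     vcf_num(if (cl$type == "DEL") -cl$size
                                             else cl$size)))
    }
    rows[i] <- paste(cl$chrom, vcf_num(cl$pos), ".", ref, alt, ".", "PASS",
                     info, "GT", gt[i], sep = "\t")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Locate k-mer SNP edge calls on a reference
#'
#' The control k-mer (prefix plus control base) of each call is looked up in
#' the genome-unique index; a hit places the SNP at the base following the
#' prefix (strand-normalised to the forward strand).
#'
#' @param calls k-mer SNP edge calls ([kmer_call_snps()]).
#' @param index a [build_reference_index()] result.
#' @return `calls` plus `chrom`, `pos`, `ref`, `alt` columns (`NA` where the
#'   k-mer is not genome-unique).
#' @export
locate_kmer_calls <- function(calls, index) {
  calls <- copy(as.data.table(calls))
  k <- attr(index, "k")
  if (nrow(calls) == 0L) {
    calls[, `:=`(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))]
    return(calls[])
  }
  codes <- encode_kmers(paste0(calls$prefix, calls$control_base), k)
  hit <- index[data.table(code = codes), on = "code"]
  comp <- function(b) chartr("ACGT", "TGCA", b)
  fwd <- hit$strand == 1L
  calls[, chrom := attr(index, "chrom_names")[hit$chrom]]
  calls[, pos := fifelse(fwd, hit$pos + k - 1L, hit$pos)]
  calls[, ref := fifelse(fwd, control_base, comp(control_base))]
  calls[, alt := fifelse(fwd, target_base, comp(target_base))]
  calls[]
}

## flat key=value config parser; later keys override earlier ones
read_pipeline_config <- function(path) {
  lines <- read_lines_fast(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2L) stopf("bad config line: %s", paste(p, collapse = "="))
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the detection pipeline end to end
#'
#' Reads the inputs, builds sorted unique read sets, runs the selected
#' method(s), verifies candidates, and writes TSV/VCF outputs plus a
#' machine-readable summary. The k-mer method requires a control; the
#' bidirectional method and verification require a reference.
#'
#' @param target target reads: FASTQ path(s) or a character vector.
#' @param control optional control reads (FASTQ path(s) or character
#'   vector); when absent, verification uses reference-derived control
#'   reads.
#' @param reference reference genome: FASTA path or [genome()] object
#'   (required unless `method = "kmer"`).
#' @param method `"bidir"`, `"kmer"` or `"both"`.
#' @param out_dir output directory (created); `NULL` writes no files.
#' @param k,margin,min_depth,max_noise,min_support tuning parameters (see
#'   [kmer_config()], [bidir_config()]).
#' @param het_low,het_high heterozygous allele-fraction window.
#' @param verify verify candidates and filter to genotyped calls.
#' @return list: `calls` (bidirectional calls), `kmer_calls`, `verified`,
#'   `summary` (named counts), and output `paths`.
#' @export
run_pipeline <- function(target, control = NULL, reference = NULL,
                         method = c("bidir", "kmer", "both"),
                         out_dir = NULL, k = 20L, margin = 5L,
                         min_depth = 5L, max_noise = 1L, min_support = 2L,
                         het_low = 0.30, het_high = 0.70, verify = TRUE) {
  method <- match.arg(method)
  as_reads <- function(x) {
    if (inherits(x, "ped_readset")) return(x)
    if (is.character(x) && length(x) < 10L && all(nchar(x) < 500) &&
        all(file.exists(x)))
      x <- unlist(lapply(x, read_fastq), use.names = FALSE)
    sort_unique_reads(x)
  }
  if (method %in% c("kmer", "both") && is.null(control))
    stopf("the k-mer method needs a control read set")
  if (method %in% c("bidir", "both") || verify) {
    if (is.null(reference)) stopf("a reference is required")
    if (!inherits(reference, "ped_genome")) {
      if (!(is.character(reference) && length(reference) == 1L &&
            file.exists(reference)))
        stopf("reference must be a genome object or a FASTA path")
      reference <- read_fasta(reference)
    }
  }
  tgt <- as_reads(target)
  ctl <- if (!is.null(control)) as_reads(control)
  read_length <- if (length(tgt)) max(nchar(tgt)) else 100L

  kcfg <- kmer_config(k, min_depth, max_noise, het_low, het_high)
  bcfg <- bidir_config(k, margin, min_support)

  kmer_calls <- NULL
  if (method %in% c("kmer", "both"))
    kmer_calls <- kmer_call_snps(tgt, ctl, kcfg)

  calls <- NULL; verified <- NULL
  if (method %in% c("bidir", "both")) {
    calls <- call_variants(tgt, reference, cfg = bcfg)
    if (verify)
      verified <- verify_candidates(calls, reference, tgt, ctl,
                                    read_length, het_low, het_high)
  }

  summary <- c(
    n_target_reads = length(tgt),
    n_control_reads = length(ctl %||% character(0)),
    n_kmer_calls = if (is.null(kmer_calls)) NA_integer_ else nrow(kmer_calls),
    n_bidir_calls = if (is.null(calls)) NA_integer_ else nrow(calls),
    n_verified = if (is.null(verified)) NA_integer_
                 else sum(verified$genotype != "none"))
  if (!is.null(verified))
    for (tp in c("SNP", "DEL", "INS", "INV", "TRL"))
      summary[paste0("n_verified_", tp)] <-
        sum(verified$type == tp & verified$genotype != "none")

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(kmer_calls)) {
      paths$kmer_tsv <- file.path(out_dir, "kmer_calls.tsv")
      fwrite(kmer_calls, paths$kmer_tsv, sep = "\t")
    }
    if (!is.null(calls)) {
      paths$calls_tsv <- file.path(out_dir, "bidir_calls.tsv")
      write_calls_tsv(calls, paths$calls_tsv)
    }
    if (!is.null(verified)) {
      paths$verified_tsv <- file.path(out_dir, "verified.tsv")
      write_verified_tsv(verified, paths$verified_tsv)
      paths$vcf <- file.path(out_dir, "calls.vcf")
      write_vcf(verified[verified$genotype != "none"], reference, paths$vcf,
                max_seq_len = read_length)
    }
    paths$summary <- file.path(out_dir, "summary.tsv")
    fwrite(data.table(metric = names(summary), value = unlist(summary)),
           paths$summary, sep = "\t")
  }
  list(calls = calls, kmer_calls = kmer_calls, verified = verified,
       summary = summary, paths = paths)
}
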