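## kmer_edge: reference-free SNP-edge detection by comparing (k-1)-mer
## last-base count tables between target and control read sets.

#' Parameters of the k-mer edge caller
#'
#' @param k k-mer length. The caller compares the counts of the last base
#'   following each (k-1)-mer prefix.
#' @param min_depth minimum k-mer count for a base to be considered present.
#' @param max_noise maximum count tolerated for a base considered absent
#'   (sequencing-error allowance).
#' @param het_low,het_high inclusive allele-fraction window for a
#'   heterozygous call (alternative count over reference+alternative counts
#'   in the target).
#' @return a `ped_kmer_config` list.
#' @export
kmer_config <- function(k = 20L, min_depth = 5L, max_noise = 1L,
                        het_low = 0.30, het_high = 0.70) {
  k <- as.integer(k)
  if (k < 2L || k > 26L) stopf("k must be in 2..26 (k-mers are packed into doubles)")
  if (!(max_noise >= 0 && max_noise < min_depth))
    stopf("need 0 <= max_noise < min_depth")
  if (!(het_low > 0 && het_low < het_high && het_high < 1))
    stopf("need 0 < het_low < het_high < 1")
  structure(list(k = k, min_depth = as.integer(min_depth),
                 max_noise = as.integer(max_noise),
                 het_low = het_low, het_high = het_high),
            class = "ped_kmer_config")
}

#' Extract all k-mers from reads
#'
#' Every read of length `L >= k` contributes its `L - k + 1` k-mers (one per
#' start offset). Shorter reads are skipped (a message reports how many).
#'
#' @param reads character vector of reads.
#' @param k k-mer length.
#' @param codes return packed numeric codes instead of strings (fast path).
#' @return character (or numeric) vector: the k-mer multiset.
#' @export
extract_kmers <- function(reads, k, codes = FALSE) {
  enc <- .encode_windows_cpp(as.character(reads), as.integer(k))
  n_short <- sum(enc$n == 0L & length(reads) > 0L)
  if (n_short > 0L)
    message(sprintf("extract_kmers: skipped %d read(s) shorter than k = %d",
                    n_short, k))
  out <- enc$codes
  if (anyNA(out)) out <- out[!is.na(out)]
  if (codes) out else decode_kmers(out, k)
}

#' Count a k-mer multiset
#'
#' @param kmers k-mer multiset as strings or packed codes (from
#'   [extract_kmers()]).
#' @param k k-mer length (required for packed codes).
#' @return a `data.table` with columns `kmer` and `count`, sorted by k-mer;
#'   attribute `k` carries the k-mer length.
#' @export
count_kmers <- function(kmers, k = NULL) {
  if (is.character(kmers)) {
    k <- k %||% (if (length(kmers)) nchar(kmers[1]) else NA_integer_)
    dt <- data.table(kmer = kmers)
  } else {
    if (is.null(k)) stopf("k is required when counting packed k-mer codes")
    dt <- data.table(kmer = as.numeric(kmers))
  }
  out <- dt[, .(count = .N), by = kmer]
  setkey(out, kmer)  # byte-lexicographic == numeric code order
  setattr(out, "k", as.integer(k))
  out[]
}

#' Convert a k-mer count table to a last-base count table
#'
#' Each k-mer is split into its (k-1)-mer prefix and last base; the k-mer
#' count becomes the count of that base following the prefix. One row per
#' distinct prefix with columns `A`, `C`, `G`, `T`.
#'
#' @param counts a k-mer count table from [count_kmers()] (string or packed
#'   `kmer` column).
#' @param k k-mer length (default: the table's `k` attribute).
#' @return a sorted `data.table` with columns `prefix`, `A`, `C`, `G`, `T`;
#'   attribute `k` is the original k-mer length.
#' @export
to_last_base_table <- function(counts, k = attr(counts, "k")) {
  if (is.null(k) || is.na(k)) stopf("k-mer length unknown; pass k")
  k <- as.integer(k)
  if (nrow(counts) == 0L) {
    out <- data.table(prefix = if (is.character(counts$kmer)) character(0) else numeric(0),
                      A = integer(0), C = integer(0), G = integer(0), T = integer(0))
    setkey(out, prefix); setattr(out, "k", k)
    return(out[])
  }
  if (is.character(counts$kmer)) {
    dt <- data.table(prefix = substr(counts$kmer, 1L, k - 1L),
                     b = substr(counts$kmer, k, k),
                     count = counts$count)
    dt[, b := factor(b, levels = BASES)]
  } else {
    dt <- data.table(prefix = floor(counts$kmer / 4),
                     b = factor(code_to_base(as.integer(counts$kmer %% 4)),
                                levels = BASES),
                     count = counts$count)
  }
  out <- dcast(dt, prefix ~ b, value.var = "count", fill = 0L, drop = c(TRUE, FALSE))
  for (col in BASES) set(out, j = col, value = as.integer(out[[col]]))
  setkey(out, prefix)
  setattr(out, "k", k)
  out[]
}

#' Last-base count table straight from reads
#'
#' Fast chunked path equivalent to
#' `to_last_base_table(count_kmers(extract_kmers(reads, k, codes = TRUE), k))`.
#' Prefixes are kept as packed codes; use [write_last_base_table()] or
#' [decode_kmers()] for the sequence form.
#'
#' @param reads character vector of reads (a `ped_readset` in the pipeline).
#' @param k k-mer length.
#' @param chunk_reads reads per counting chunk (memory/speed trade-off).
#' @return sorted `data.table` (`prefix` packed code, `A`, `C`, `G`, `T`).
#' @export
last_base_table <- function(reads, k = 20L, chunk_reads = 25e4L) {
  k <- as.integer(k)
  n <- length(reads)
  acc <- NULL
  starts <- seq.int(1L, max(n, 1L), by = chunk_reads)
  for (s in starts) {
    if (n == 0L) break
    idx <- s:min(n, s + chunk_reads - 1L)
    codes <- .encode_windows_cpp(reads[idx], k)$codes
    if (anyNA(codes)) codes <- codes[!is.na(codes)]
    part <- .count_codes_cpp(codes)   # sorted (code, count); consumes codes
    rm(codes)
    acc <- if (is.null(acc)) part
           else .merge_counts_cpp(acc$code, acc$count, part$code, part$count)
  }
  if (is.null(acc)) acc <- list(code = numeric(0), count = integer(0))
  out <- setDT(.last_base_from_counts_cpp(acc$code, acc$count))
  rm(acc)
  setkey(out, prefix)
  setattr(out, "k", k)
  out[]
}

#' Join control and target last-base tables
#'
#' Sorted merge-join on the (k-1)-mer prefix; only prefixes present in both
#' tables are kept. Control counts become `cA..cT`, target counts `tA..tT`.
#'
#' @param control,target last-base tables with the same `k` (both sorted).
#' @return joined `data.table` keyed by `prefix`.
#' @export
join_last_base_tables <- function(control, target) {
  for (tb in list(control, target))
    if (!identical(key(tb), "prefix"))
      stopf("last-base tables must be sorted (keyed) by prefix")
  kc <- attr(control, "k"); kt <- attr(target, "k")
  if (!is.null(kc) && !is.null(kt) && kc != kt)
    stopf("control and target tables use different k (%d vs %d)", kc, kt)
  out <- control[target, on = "prefix", nomatch = NULL][
    , .(prefix, cA = A, cC = C, cG = G, cT = T,
        tA = i.A, tC = i.C, tG = i.G, tT = i.T)]
  setkey(out, prefix)
  setattr(out, "k", kc %||% kt)
  out[]
}

#' Call SNP edges from a joined last-base table
#'
#' For each prefix, a base is *present* when its count is at least
#' `min_depth` and *absent* when at most `max_noise`. A homozygous edge is
#' called when control and target each have exactly one present base, the
#' bases differ, and each is absent in the other sample. A heterozygous edge
#' is called when the control has one present base `r`, the target has `r`
#' and exactly one other base `a` present, `a` is absent in the control, and
#' the target fraction `a/(r+a)` lies inside the heterozygous window.
#' Ambiguous rows (several present bases in the control, ties, under-covered
#' controls) yield no call.
#'
#' @param joined output of [join_last_base_tables()].
#' @param cfg a [kmer_config()].
#' @return `data.table` of SNP edge calls: `prefix` (sequence), control and
#'   target base, both count quadruples, `zygosity` (`hom`/`het`), target
#'   allele fraction `af`, and a `reciprocal` placeholder (`NA` until
#'   [reciprocal_confirm()]).
#' @export
call_snp_edges <- function(joined, cfg = kmer_config()) {
  k <- attr(joined, "k")
  cmx <- as.matrix(joined[, .(cA, cC, cG, cT)])
  tmx <- as.matrix(joined[, .(tA, tC, tG, tT)])
  pc <- cmx >= cfg$min_depth; ac <- cmx <= cfg$max_noise
  pt <- tmx >= cfg$min_depth; at <- tmx <= cfg$max_noise
  npc <- rowSums(pc); npt <- rowSums(pt)

  ## control base index (only meaningful where npc == 1)
  cb <- as.integer(pc %*% seq_len(4L))
  one_c <- npc == 1L

  ## homozygous: one present base each side, different, absent in the other
  tb_hom <- as.integer(pt %*% seq_len(4L))   # valid only where npt == 1
  idx <- seq_len(nrow(joined))
  cb_cl <- pmin(pmax(cb, 1L), 4L)
  tb_cl <- pmin(pmax(tb_hom, 1L), 4L)
  hom <- one_c & npt == 1L & cb != tb_hom &
    at[cbind(idx, cb_cl)] & ac[cbind(idx, tb_cl)]

  ## heterozygous: target carries control base plus exactly one other
  tb_het <- as.integer(pt %*% seq_len(4L)) - cb       # the "other" base index
  het_shape <- one_c & npt == 2L & pt[cbind(idx, cb_cl)] &
    tb_het >= 1L & tb_het <= 4L
  het_shape[het_shape] <- ac[cbind(idx[het_shape], tb_het[het_shape])]
  af <- rep(NA_real_, length(idx))
  ok <- which(het_shape)
  if (length(ok)) {
    ra <- tmx[cbind(ok, cb[ok])]
    aa <- tmx[cbind(ok, tb_het[ok])]
    af[ok] <- aa / (ra + aa)
  }
  het <- het_shape & !is.na(af) & af >= cfg$het_low & af <= cfg$het_high

  sel <- hom | het
  if (!any(sel)) {
    return(data.table(prefix = character(0), control_base = character(0),
                      target_base = character(0),
                      cA = integer(0), cC = integer(0), cG = integer(0), cT = integer(0),
                      tA = integer(0), tC = integer(0), tG = integer(0), tT = integer(0),
                      zygosity = character(0), af = numeric(0),
                      reciprocal = logical(0)))
  }
  tb <- ifelse(hom, tb_hom, tb_het)[sel]
  pfx <- joined$prefix[sel]
  if (is.numeric(pfx)) pfx <- decode_kmers(pfx, k - 1L)
  out <- data.table(
    prefix = pfx,
    control_base = BASES[cb[sel]],
    target_base = BASES[tb],
    joined[sel, .(cA, cC, cG, cT, tA, tC, tG, tT)],
    zygosity = ifelse(hom[sel], "hom", "het"),
    af = ifelse(hom[sel],
                tmx[cbind(which(sel), tb)] / pmax(rowSums(tmx)[sel], 1L),
                af[sel]),
    reciprocal = NA)
  setorder(out, prefix)
  out[]
}

## Walk the target last-base table rightward from a k-mer: at each step the
## next base must be the unique present base after the current prefix.
## Returns the extended sequence (stops early at ambiguity or dead end).
walk_target <- function(kmer_codes, table_codes, counts, k, min_depth, steps) {
  top <- 4^(k - 1)
  vapply(kmer_codes, function(code) {
    s <- decode_kmers(code, k)
    for (i in seq_len(steps)) {
      pfx <- code %% top
      row <- findInterval(pfx, table_codes)   # tables are sorted by prefix
      if (row == 0L || table_codes[row] != pfx) break
      present <- which(counts[row, ] >= min_depth)
      if (length(present) != 1L) break
      b <- present - 1L
      s <- paste0(s, BASES[present])
      code <- pfx * 4 + b
    }
    s
  }, character(1))
}

#' Mark SNP edge calls confirmed on both strands
#'
#' Because read sets are complement-closed, a genuine SNP edge appears twice:
#' once with the left flank as prefix (forward k-mers) and once with the
#' reverse-complemented right flank (complementary k-mers). The call object
#' only carries the left flank, so the right flank is recovered by walking
#' the target last-base table rightward from the call's k-mer (following the
#' unique present base, up to `k` steps). Two calls are reciprocal when one
#' call's reverse-complemented k-mer is a substring of the other's extension;
#' both members of such a pair are marked. The walk stops at ambiguous
#' prefixes, so edges in repetitive or mixed contexts may remain unconfirmed.
#'
#' @param calls output of [call_snp_edges()].
#' @param target_table the target last-base table (packed prefixes, from
#'   [last_base_table()]).
#' @param cfg the [kmer_config()] used for calling.
#' @return `calls` with the logical `reciprocal` column filled.
#' @export
reciprocal_confirm <- function(calls, target_table, cfg = kmer_config()) {
  calls <- copy(calls)
  if (nrow(calls) == 0L) { calls[, reciprocal := logical(0)]; return(calls[]) }
  k <- attr(target_table, "k") %||% cfg$k
  kmers <- paste0(calls$prefix, calls$target_base)
  if (!is.numeric(target_table$prefix))
    stopf("target_table must carry packed prefixes (use last_base_table())")
  counts <- as.matrix(target_table[, .(A, C, G, T)])
  ext <- walk_target(encode_kmers(kmers, k), target_table$prefix, counts,
                     k, cfg$min_depth, steps = k)
  rc <- .revcomp_cpp(kmers)
  n <- length(kmers)
  rec <- logical(n)
  for (i in seq_len(n)) {
    if (rec[i]) next
    hits <- which(vapply(seq_len(n), function(j)
      j != i && grepl(rc[j], ext[i], fixed = TRUE), logical(1)))
    if (length(hits)) { rec[i] <- TRUE; rec[hits] <- TRUE }
  }
  calls[, reciprocal := rec]
  calls[]
}

#' Reference-free SNP calling between two read sets (k-mer method)
#'
#' Runs the full k-mer pipeline: last-base count tables for target and
#' control, sorted join on the (k-1)-mer prefix, edge calling, and
#' both-strand confirmation.
#'
#' @param target_reads,control_reads sorted unique read sets
#'   ([sort_unique_reads()]).
#' @param cfg a [kmer_config()].
#' @param target_table,control_table optional precomputed last-base tables.
#' @return SNP edge calls (see [call_snp_edges()]) with `reciprocal` filled.
#' @export
kmer_call_snps <- function(target_reads, control_reads, cfg = kmer_config(),
                           target_table = NULL, control_table = NULL) {
  if (is.null(target_table))  target_table  <- last_base_table(target_reads, cfg$k)
  if (is.null(control_table)) control_table <- last_base_table(control_reads, cfg$k)
  joined <- join_last_base_tables(control_table, target_table)
  calls <- call_snp_edges(joined, cfg)
  reciprocal_confirm(calls, target_table, cfg)
}

#' Serialize a last-base table as sorted TSV
#'
#' Columns: prefix sequence, count_A, count_C, count_G, count_T.
#'
#' @param tbl a last-base table (packed or sequence prefixes).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_last_base_table <- function(tbl, path) {
  k <- attr(tbl, "k")
  out <- tbl[, .(prefix, A, C, G, T)]
  if (is.numeric(out$prefix)) {
    if (is.null(k)) stopf("packed table without k attribute")
    out[, prefix := decode_kmers(prefix, k - 1L)]
  }
  fwrite(out, path, sep = "\t")
  invisible(path)
}
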