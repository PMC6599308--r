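## bidir_align: anchor both read ends on the genome-unique index, scan inward
## from each end to the polymorphic edges, and classify the variant.

#' Parameters of the bidirectional alignment caller
#'
#' @param k anchor k-mer length (must match the reference index).
#' @param margin anchor offset from the read ends.
#' @param min_support minimum number of distinct reads asserting a call for
#'   it to be reported (applied before verification).
#' @param lookahead number of bases compared in-register after the first
#'   mismatch to distinguish a point mismatch from an indel/SV edge.
#' @param lookahead_min_mm minimum mismatches among the lookahead bases for
#'   the edge to be treated as a non-point (gap) edge.
#' @param max_reps representative reads stored per merged call (used by the
#'   verification stage to validate junction reconstruction).
#' @return a `ped_bidir_config` list.
#' @export
bidir_config <- function(k = 20L, margin = 5L, min_support = 2L,
                         lookahead = 5L, lookahead_min_mm = 2L,
                         max_reps = 5L) {
  structure(list(k = as.integer(k), margin = as.integer(margin),
                 min_support = as.integer(min_support),
                 lookahead = as.integer(lookahead),
                 lookahead_min_mm = as.integer(lookahead_min_mm),
                 max_reps = as.integer(max_reps)),
            class = "ped_bidir_config")
}

## orientation symbols for breakends: ">" = the matching block extends
## leftward from pos (junction on its right side), "<" = extends rightward.
orient_sym <- function(d) ifelse(d > 0L, ">", "<")

#' Scan one read inward from an anchored end
#'
#' Base-by-base comparison of the read against the reference in the anchor's
#' frame (reverse-complementing for `-` anchors), from the chosen end inward.
#' At the first mismatch the following `lookahead` bases are compared
#' in-register; with fewer than `lookahead_min_mm` of them mismatching the
#' edge is flagged as a point mismatch (SNP-like), otherwise as a gap edge.
#'
#' @param read a single read sequence.
#' @param genome a [genome()] object.
#' @param anchor list with `chrom` (name), `pos` (1-based k-mer start on the
#'   forward strand) and `strand` (`"+"`/`"-"`).
#' @param direction `"5"` or `"3"`: which read end to scan from.
#' @param cfg a [bidir_config()].
#' @return `NULL` when the read matches the reference over its full scanned
#'   extent; otherwise a list with `ref` (edge reference position), `offset`
#'   (read offset), `point`, `oob`, `ref_base`, `alt_base` (genome-frame).
#' @export
scan_edge <- function(read, genome, anchor, direction = c("5", "3"),
                      cfg = bidir_config()) {
  direction <- match.arg(direction)
  ci <- match(anchor$chrom, names(genome))
  if (is.na(ci)) stopf("unknown chromosome %s", anchor$chrom)
  s <- if (identical(anchor$strand, "-") || identical(anchor$strand, -1L)) -1L else 1L
  none <- 0L
  res <- .scan_reads_cpp(read, unclass(genome),
                         if (direction == "5") ci else none,
                         as.integer(anchor$pos), s,
                         if (direction == "3") ci else none,
                         as.integer(anchor$pos), s,
                         cfg$k, cfg$margin, cfg$lookahead, cfg$lookahead_min_mm)
  p <- if (direction == "5") "5" else "3"
  g <- function(nm) res[[paste0(nm, p)]][1]
  if (g("ob") == 1L)
    return(list(ref = NA_integer_, offset = NA_integer_, point = FALSE,
                oob = TRUE, ref_base = NA_character_, alt_base = NA_character_))
  if (g("f") == 0L) return(NULL)
  list(ref = g("r"), offset = g("o"), point = g("pt") == 1L, oob = FALSE,
       ref_base = code_to_base(g("rb")), alt_base = code_to_base(g("ab")))
}

## Vectorised classification of anchored+scanned reads into raw call rows.
## `anchors` from map_read_ends(); `scans` the list returned by
## .scan_reads_cpp for the same reads. Returns one row per (read, call).
classify_scans <- function(reads, anchors, scans, cfg) {
  k <- attr(anchors, "k"); m <- attr(anchors, "margin")
  A <- anchors; S <- scans
  L <- A$len
  has5 <- !is.na(A$chrom5); has3 <- !is.na(A$chrom3)
  oob <- (S$ob5 == 1L) | (S$ob3 == 1L)
  usable <- (has5 | has3) & !oob

  empty <- data.table(read_id = integer(0), type = character(0),
                      chrom = integer(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      size = integer(0), chrom2 = integer(0),
                      pos2 = integer(0), orient = character(0))
  out <- list(empty)

  both <- usable & has5 & has3
  one5 <- usable & has5 & !has3
  one3 <- usable & !has5 & has3

  ## ---- single-anchor reads: SNP edge from the surviving direction only
  snp_one <- function(sel, side) {
    f  <- S[[paste0("f",  side)]]; pt <- S[[paste0("pt", side)]]
    r  <- S[[paste0("r",  side)]]; rb <- S[[paste0("rb", side)]]
    ab <- S[[paste0("ab", side)]]
    w <- which(sel & f == 1L & pt == 1L & rb >= 0L & ab >= 0L & rb != ab)
    if (!length(w)) return(NULL)
    ch <- if (side == "5") A$chrom5[w] else A$chrom3[w]
    data.table(read_id = w, type = "SNP", chrom = ch, pos = r[w],
               ref = code_to_base(rb[w]), alt = code_to_base(ab[w]),
               size = 0L, chrom2 = NA_integer_, pos2 = NA_integer_,
               orient = NA_character_)
  }
  out <- c(out, list(snp_one(one5, "5"), snp_one(one3, "3")))

  if (any(both)) {
    c5 <- A$chrom5; c3 <- A$chrom3; s5 <- A$strand5; s3 <- A$strand3
    p5 <- A$pos5; p3 <- A$pos3

    ## ---- inter-chromosomal / inverted: breakend pair from both edges
    sv_bk <- both & (c5 != c3 | s5 != s3) & S$f5 == 1L & S$f3 == 1L
    w <- which(sv_bk)
    if (length(w)) {
      j5 <- S$r5[w] - s5[w]          # last matching base of the 5' block
      j3 <- S$r3[w] + s3[w]          # first matching base of the 3' block
      d1 <- s5[w]; d2 <- -s3[w]
      b1c <- c5[w]; b2c <- c3[w]
      swap <- b2c < b1c | (b2c == b1c & (j3 < j5 | (j3 == j5 & d2 < d1)))
      dt <- data.table(read_id = w, type = ifelse(b1c == b2c, "INV", "TRL"),
                       chrom = ifelse(swap, b2c, b1c),
                       pos = ifelse(swap, j3, j5),
                       ref = NA_character_, alt = NA_character_,
                       size = NA_integer_,
                       chrom2 = ifelse(swap, b1c, b2c),
                       pos2 = ifelse(swap, j5, j3),
                       orient = paste0(orient_sym(ifelse(swap, d2, d1)),
                                       orient_sym(ifelse(swap, d1, d2))))
      out <- c(out, list(dt))
    }

    ## ---- same chromosome, same strand: span arithmetic
    ss <- both & c5 == c3 & s5 == s3
    w <- which(ss)
    if (length(w)) {
      sw <- s5[w]
      refstart5 <- ifelse(sw == 1L, p5[w] - m, p5[w] + k + m - 1L)
      refstart3 <- ifelse(sw == 1L, p3[w] - (L[w] - m - k), p3[w] + L[w] - m - 1L)
      delta <- ifelse(sw == 1L, refstart3 - refstart5, refstart5 - refstart3)

      ## SNPs: each directional point edge (coincident edges emit once)
      wz <- w[delta == 0L]
      if (length(wz)) {
        v5 <- S$f5[wz] == 1L & S$pt5[wz] == 1L & S$rb5[wz] >= 0L &
          S$ab5[wz] >= 0L & S$rb5[wz] != S$ab5[wz]
        v3 <- S$f3[wz] == 1L & S$pt3[wz] == 1L & S$rb3[wz] >= 0L &
          S$ab3[wz] >= 0L & S$rb3[wz] != S$ab3[wz]
        dup <- v5 & v3 & S$r5[wz] == S$r3[wz]
        mk <- function(sel, side) {
          ww <- wz[sel]
          if (!length(ww)) return(NULL)
          r  <- S[[paste0("r",  side)]][ww]
          rb <- S[[paste0("rb", side)]][ww]
          ab <- S[[paste0("ab", side)]][ww]
          data.table(read_id = ww, type = "SNP", chrom = c5[ww], pos = r,
                     ref = code_to_base(rb), alt = code_to_base(ab),
                     size = 0L, chrom2 = NA_integer_, pos2 = NA_integer_,
                     orient = NA_character_)
        }
        out <- c(out, list(mk(v5, "5"), mk(v3 & !dup, "3")))
      }

      ## indels: genome-left scan is the 5' scan on '+' reads, 3' on '-'
      wi <- w[delta != 0L]
      if (length(wi)) {
        di <- delta[delta != 0L]
        swi <- s5[wi]
        fL <- ifelse(swi == 1L, S$f5[wi], S$f3[wi])
        rL <- ifelse(swi == 1L, S$r5[wi], S$r3[wi])
        oL <- ifelse(swi == 1L, S$o5[wi], S$o3[wi])
        ok <- fL == 1L
        if (any(ok)) {
          wi <- wi[ok]; di <- di[ok]; rL <- rL[ok]; oL <- oL[ok]; swi <- swi[ok]
          isdel <- di > 0L
          ## deletions
          if (any(isdel)) {
            wd <- wi[isdel]
            out <- c(out, list(data.table(
              read_id = wd, type = "DEL", chrom = c5[wd],
              pos = rL[isdel] - 1L, ref = NA_character_, alt = NA_character_,
              size = di[isdel], chrom2 = c5[wd],
              pos2 = rL[isdel] - 1L + di[isdel] + 1L, orient = "><")))
          }
          ## insertions: captured inserted bases in genome orientation
          if (any(!isdel)) {
            wn <- wi[!isdel]; sz <- -di[!isdel]
            gl_off <- ifelse(swi[!isdel] == 1L, oL[!isdel],
                             L[wn] - oL[!isdel] + 1L)
            gread <- ifelse(swi[!isdel] == 1L, reads[wn],
                            .revcomp_cpp(reads[wn]))
            fits <- gl_off + sz - 1L <= L[wn]
            if (any(fits)) {
              wn <- wn[fits]
              out <- c(out, list(data.table(
                read_id = wn, type = "INS", chrom = c5[wn],
                pos = (rL[!isdel] - 1L)[fits], ref = NA_character_,
                alt = substr(gread[fits], gl_off[fits],
                             gl_off[fits] + sz[fits] - 1L),
                size = sz[fits], chrom2 = c5[wn],
                pos2 = (rL[!isdel] - 1L)[fits] + 1L, orient = "><")))
            }
          }
        }
      }
    }
  }
  rbindlist(out, use.names = TRUE)
}

#' Call variants by bidirectional alignment
#'
#' For every read: both ends are anchored on the genome-unique k-mer index
#' ([map_read_ends()]); the read is scanned base-by-base inward from each
#' anchored end to its polymorphic edge; the anchor geometry and edge pair
#' classify the read as wild type, SNP, insertion, deletion (reference span
#' minus read span), inversion (opposite-strand anchors) or translocation
#' (anchors on different chromosomes). Identical calls are merged with
#' `support` = number of distinct read molecules (a read and its
#' complement-closure partner count once), and calls below `min_support`
#' are dropped. Reads with one anchor contribute SNP edges from the surviving
#' direction only; reads with no anchors, or whose scan runs outside a
#' chromosome, are dropped.
#'
#' Deletions and insertions are reported at the reference position of the
#' last matching base on the 5' (genome-left) side; `pos2` is the first
#' matching base on the 3' side. Inversions and translocations are reported
#' as the canonicalised pair of edge coordinates with an `orient` code
#' (`>` = matching block extends left of the coordinate, `<` = right).
#'
#' @param reads a sorted unique read set ([sort_unique_reads()]).
#' @param genome a [genome()] object.
#' @param index optional precomputed [build_reference_index()] (built from
#'   `genome` when `NULL`).
#' @param cfg a [bidir_config()].
#' @return a `data.table` of merged calls sorted by chromosome and position:
#'   `chrom`, `pos`, `type`, `ref`, `alt`, `size`, `chrom2`, `pos2`,
#'   `orient`, `support`, and `reps` (list column of up to `max_reps`
#'   representative reads).
#' @export
call_variants <- function(reads, genome, index = NULL, cfg = bidir_config(),
                          chunk_reads = 2e6L) {
  if (is.null(index)) index <- build_reference_index(genome, cfg$k)
  n <- length(reads)
  parts <- list()
  starts <- seq.int(1L, max(n, 1L), by = chunk_reads)
  for (s in starts) {
    if (n == 0L) break
    idx <- s:min(n, s + chunk_reads - 1L)
    chunk <- reads[idx]
    anchors <- map_read_ends(chunk, index, cfg$margin)
    scans <- .scan_reads_cpp(
      chunk, unclass(genome),
      fifelse(is.na(anchors$chrom5), 0L, anchors$chrom5),
      fifelse(is.na(anchors$pos5), 0L, anchors$pos5),
      fifelse(is.na(anchors$strand5), 0L, anchors$strand5),
      fifelse(is.na(anchors$chrom3), 0L, anchors$chrom3),
      fifelse(is.na(anchors$pos3), 0L, anchors$pos3),
      fifelse(is.na(anchors$strand3), 0L, anchors$strand3),
      cfg$k, cfg$margin, cfg$lookahead, cfg$lookahead_min_mm)
    raw <- classify_scans(chunk, anchors, scans, cfg)
    raw[, read_id := read_id + (s - 1L)]
    parts[[length(parts) + 1L]] <- raw
    rm(anchors, scans, chunk)
  }
  raw <- if (length(parts)) rbindlist(parts)
  else data.table(read_id = integer(0), type = character(0),
                  chrom = integer(0), pos = integer(0), ref = character(0),
                  alt = character(0), size = integer(0), chrom2 = integer(0),
                  pos2 = integer(0), orient = character(0))
  merge_calls(raw, reads, names(genome), cfg)
}

## merge identical raw call rows; attach support and representative reads.
## Support counts read *molecules*: a read and its reverse complement (added
## by complement closure) are the same observation and count once.
merge_calls <- function(raw, reads, chrom_names, cfg) {
  if (nrow(raw) == 0L) {
    out <- data.table(chrom = character(0), pos = integer(0), type = character(0),
                      ref = character(0), alt = character(0), size = integer(0),
                      chrom2 = character(0), pos2 = integer(0),
                      orient = character(0), support = integer(0),
                      reps = list())
    return(out)
  }
  uid <- unique(raw$read_id)
  partner <- chmatch(.revcomp_cpp(as.character(reads[uid])), as.character(reads))
  raw[, canon := pmin(uid, partner, na.rm = TRUE)[match(read_id, uid)]]
  merged <- raw[, .(support = uniqueN(canon),
                    reps = list(head(reads[read_id], cfg$max_reps))),
                by = .(type, chrom, pos, ref, alt, size, chrom2, pos2, orient)]
  merged <- merged[support >= cfg$min_support]
  merged[, chrom := chrom_names[chrom]]
  merged[, chrom2 := chrom_names[chrom2]]
  setorder(merged, chrom, pos, type, na.last = TRUE)
  setcolorder(merged, c("chrom", "pos", "type", "ref", "alt", "size",
                        "chrom2", "pos2", "orient", "support", "reps"))
  merged[]
}

#' Write variant calls as TSV
#'
#' @param calls output of [call_variants()] or [verify_candidates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- copy(calls)
  if ("reps" %in% names(out)) out[, reps := NULL]
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
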