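## simulate: artificial genomes with planted mutations, sliced reads, truth
## tables and the call evaluator.

#' IRGSP-1.0 chromosome lengths
#'
#' Lengths (bp) of the 12 chromosomes of the Os-Nipponbare-Reference-IRGSP-1.0
#' rice genome assembly (RAP-DB), used to plan mutation schemes at real
#' chromosome scale without downloading sequence.
#'
#' @format named integer vector of length 12.
#' @export
irgsp1_chrom_lengths <- c(
  chr01 = 43270923L, chr02 = 35937250L, chr03 = 36413819L, chr04 = 35502694L,
  chr05 = 29958434L, chr06 = 31248787L, chr07 = 29697621L, chr08 = 28443022L,
  chr09 = 23012720L, chr10 = 23207287L, chr11 = 29021106L, chr12 = 27531856L)

#' Planted-mutation scheme
#'
#' The default scheme plants, per chromosome: a substitution SNP every
#' `snp_interval` bases (at every multiple of the interval strictly inside
#' the chromosome), a pair of adjacent substitutions at `pair_pos` and
#' `pair_pos + 1`, and a nine-event structural-variant battery (1/10/100 bp
#' deletions, 1/10/20 bp insertions, a 100 bp inversion, a 100 bp
#' translocation, and a large deletion of `100000/scale` bp) at nine fixed
#' positions. `scale` divides all positions and intervals so the same design
#' runs at desk scale. The translocated segment is moved (cut and paste) to
#' the next chromosome, `trl_dest_offset` bases before its end, so that its
#' junction reads carry anchors on two different chromosomes.
#'
#' @param scale positive divisor applied to positions, intervals and the
#'   large-deletion size; must divide them exactly.
#' @param snp_interval,pair_pos,sv_positions,trl_dest_offset see above
#'   (values are given on the unscaled coordinate system and divided by
#'   `scale`).
#' @return a `ped_scheme` list with the scaled scheme, including
#'   `sv_battery` (list of `type`/`size` pairs).
#' @export
mutation_scheme <- function(scale = 1L, snp_interval = 1e7, pair_pos = 10010000,
                            sv_positions = seq(1e6, 9e6, by = 1e6) + 1,
                            trl_dest_offset = 10000L) {
  if (!is_count(scale)) stopf("scale must be a positive integer")
  sc <- function(x, off = 0) {
    v <- (x - off) / scale + off
    if (any(v != trunc(v))) stopf("scale %d does not divide the scheme positions", scale)
    as.integer(v)
  }
  battery <- list(
    list(type = "DEL", size = 1L), list(type = "DEL", size = 10L),
    list(type = "DEL", size = 100L), list(type = "INS", size = 1L),
    list(type = "INS", size = 10L), list(type = "INS", size = 20L),
    list(type = "INV", size = 100L), list(type = "TRL", size = 100L),
    list(type = "DEL", size = sc(1e5)))
  structure(list(
    snp_interval = sc(snp_interval),
    pair_pos = sc(pair_pos),
    sv_positions = sc(sv_positions, off = 1),
    sv_battery = battery,
    trl_dest_offset = as.integer(trl_dest_offset),
    scale = as.integer(scale)), class = "ped_scheme")
}

#' Random genome
#'
#' I.i.d. uniform A/C/G/T chromosomes, deterministic for a given seed. An
#' optional repeat injection copies a segment to a second locus to create a
#' known repetitive region.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length (bp), recycled across chromosomes.
#' @param seed RNG seed.
#' @param repeat_inject optional list `(chrom, from, length, to_chrom, to)`:
#'   copy `length` bases starting at `from` of chromosome `chrom` over the
#'   bases starting at `to` of `to_chrom`.
#' @return a [genome()] object with chromosomes `chr01`, `chr02`, ...
#' @export
random_genome <- function(n_chrom, chrom_length, seed = 1L,
                          repeat_inject = NULL) {
  lens <- rep_len(as.integer(chrom_length), n_chrom)
  seqs <- with_seed(seed, {
    vapply(lens, function(L)
      intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, L, replace = TRUE)]),
      character(1))
  })
  names(seqs) <- sprintf("chr%02d", seq_len(n_chrom))
  if (!is.null(repeat_inject)) {
    ri <- repeat_inject
    seg <- substr(seqs[[ri$chrom]], ri$from, ri$from + ri$length - 1L)
    tgt <- seqs[[ri$to_chrom]]
    seqs[[ri$to_chrom]] <- paste0(substr(tgt, 1L, ri$to - 1L), seg,
                                  substr(tgt, ri$to + ri$length,
                                         nchar(tgt)))
  }
  genome(seqs)
}

## deterministic transversion map, so planted substitutions need no RNG
transversion <- function(b) chartr("ACGT", "CATG", b)

#' Plan planted mutations for given chromosome lengths
#'
#' Computes the truth-table skeleton (positions, types, sizes) of a
#' [mutation_scheme()] applied to chromosomes of the given lengths; sequence
#' content (`ref`/`alt`) is filled in by [apply_mutations()]. The adjacent
#' mismatch pair is recorded as two SNP records.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param scheme a [mutation_scheme()].
#' @return `data.table`: `chrom`, `pos` (original reference coordinates),
#'   `type`, `ref`, `alt`, `size`, `chrom2`, `pos2`, `origin` (one of
#'   `interval_snp`, `pair_snp`, `sv`).
#' @export
plan_mutations <- function(chrom_lengths, scheme = mutation_scheme()) {
  nms <- names(chrom_lengths)
  if (is.null(nms)) stopf("chrom_lengths must be named")
  nc <- length(chrom_lengths)
  recs <- vector("list", nc)
  for (i in seq_len(nc)) {
    L <- chrom_lengths[[i]]
    need <- max(scheme$pair_pos + 1L,
                scheme$sv_positions[9] + scheme$sv_battery[[9]]$size)
    if (L <= need)
      stopf("chromosome %s (%d bp) too short for the scheme (needs > %d bp)",
            nms[i], L, need)
    p_int <- seq.int(scheme$snp_interval, L - 1L, by = scheme$snp_interval)
    snps <- data.table(
      chrom = nms[i],
      pos = c(p_int, scheme$pair_pos, scheme$pair_pos + 1L),
      type = "SNP", ref = NA_character_, alt = NA_character_, size = 0L,
      chrom2 = NA_character_, pos2 = NA_integer_,
      origin = c(rep("interval_snp", length(p_int)), "pair_snp", "pair_snp"))
    dest <- if (nc == 1L) i else (i %% nc) + 1L
    svs <- data.table(
      chrom = nms[i],
      pos = scheme$sv_positions,
      type = vapply(scheme$sv_battery, `[[`, character(1), "type"),
      ref = NA_character_, alt = NA_character_,
      size = vapply(scheme$sv_battery, `[[`, integer(1), "size"),
      chrom2 = NA_character_, pos2 = NA_integer_, origin = "sv")
    svs[type == "TRL", `:=`(
      chrom2 = nms[dest],
      pos2 = chrom_lengths[[dest]] - scheme$trl_dest_offset)]
    recs[[i]] <- rbind(snps, svs)
  }
  truth <- rbindlist(recs)
  ## overlap check on origin-chromosome footprints
  foot <- truth[, .(chrom, s = pos, e = pos + pmax(size - 1L, 0L))]
  setorder(foot, chrom, s)
  bad <- foot[, any(s[-1] <= e[-.N]), by = chrom][V1 == TRUE]
  if (nrow(bad)) stopf("scheme events overlap on %s", bad$chrom[1])
  setorder(truth, chrom, pos)
  truth[]
}

#' Apply a mutation scheme to a genome
#'
#' Plants the scheme's SNPs and structural variants into the genome and
#' returns the mutated genome plus the truth table (in original reference
#' coordinates). Substituted bases use a deterministic transversion map
#' (A<->C, G<->T), inserted bases are the transversion image of the
#' reference bases at the insertion point, inversions reverse-complement in
#' place, and the translocated segment is cut from its origin and pasted
#' into the destination chromosome after `pos2`.
#'
#' @param genome a [genome()] object.
#' @param scheme a [mutation_scheme()].
#' @return list with elements `genome` (mutated [genome()]) and `truth`
#'   (`data.table`, see [plan_mutations()]).
#' @export
apply_mutations <- function(genome, scheme = mutation_scheme()) {
  lens <- setNames(nchar(genome), names(genome))
  truth <- plan_mutations(lens, scheme)
  seqs <- unclass(genome)

  ## fill sequence content (substring: vectorised over start/stop)
  truth[type == "SNP", ref := substring(seqs[chrom], pos, pos)]
  truth[type == "SNP", alt := transversion(ref)]
  truth[type == "INS",
        alt := transversion(substring(seqs[chrom], pos, pos + size - 1L))]

  ## edit lists per chromosome: TRL adds an insertion on the destination
  edits <- truth[, .(chrom, pos, type, alt, size)]
  trl <- truth[type == "TRL"]
  if (nrow(trl)) {
    trl_seg <- trl[, substring(seqs[chrom], pos, pos + size - 1L)]
    edits <- rbind(edits,
                   data.table(chrom = trl$chrom2, pos = trl$pos2 + 1L,
                              type = "INS", alt = trl_seg, size = trl$size))
  }
  setorder(edits, chrom, pos)

  mut <- vapply(names(seqs), function(cn) {
    ch <- seqs[[cn]]
    ev <- edits[chrom == cn]
    if (nrow(ev) == 0L) return(ch)
    parts <- character(0)
    cur <- 1L
    for (r in seq_len(nrow(ev))) {
      p <- ev$pos[r]; tp <- ev$type[r]; sz <- ev$size[r]
      parts <- c(parts, substr(ch, cur, p - 1L))
      if (tp == "SNP") { parts <- c(parts, ev$alt[r]); cur <- p + 1L }
      else if (tp == "DEL" || tp == "TRL") { cur <- p + sz }
      else if (tp == "INS") { parts <- c(parts, ev$alt[r]); cur <- p }
      else if (tp == "INV") {
        parts <- c(parts, .revcomp_cpp(substr(ch, p, p + sz - 1L)))
        cur <- p + sz
      }
    }
    parts <- c(parts, substr(ch, cur, nchar(ch)))
    paste(parts, collapse = "")
  }, character(1))

  list(genome = genome(mut), truth = truth)
}

#' Read-slicing configuration
#'
#' @param read_length read length (bp).
#' @param step interval between slice start positions.
#' @param mate_offset distance from the R1 start to the (reverse-complement)
#'   R2 window start.
#' @param error_rate per-base substitution error probability.
#' @param seed RNG seed for error injection.
#' @return a `ped_readsim_config` list.
#' @export
read_sim_config <- function(read_length = 100L, step = 2L, mate_offset = 231L,
                            error_rate = 0.001, seed = 1L) {
  if (!(error_rate >= 0 && error_rate < 1)) stopf("need 0 <= error_rate < 1")
  structure(list(read_length = as.integer(read_length),
                 step = as.integer(step),
                 mate_offset = as.integer(mate_offset),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "ped_readsim_config")
}

#' Slice paired reads from a genome
#'
#' R1 reads are genome windows of `read_length` starting every `step` bases;
#' the R2 mate is the reverse complement of the window starting
#' `mate_offset` bases downstream. Pairs are emitted only where both windows
#' fit. Each base is substituted independently with probability
#' `error_rate` (uniformly among the three other bases), deterministically
#' for a given seed.
#'
#' @param genome a [genome()] object.
#' @param cfg a [read_sim_config()].
#' @param out_prefix optional path prefix; when given, reads are written to
#'   `<prefix>_1.fastq` / `<prefix>_2.fastq` (add `.gz` via `gz = TRUE`).
#' @param gz write gzip-compressed FASTQ.
#' @return invisible list with `r1`, `r2` (character vectors), `ids`, and
#'   `paths` (when written).
#' @export
slice_reads <- function(genome, cfg = read_sim_config(), out_prefix = NULL,
                        gz = FALSE) {
  rl <- cfg$read_length; off <- cfg$mate_offset
  pieces <- lapply(seq_along(genome), function(i) {
    ch <- unclass(genome)[[i]]
    L <- nchar(ch)
    if (L < rl + off) return(NULL)
    s <- seq.int(1L, L - (rl + off) + 1L, by = cfg$step)
    list(r1 = substring(ch, s, s + rl - 1L),
         r2 = .revcomp_cpp(substring(ch, s + off, s + off + rl - 1L)),
         ids = sprintf("%s_%d", names(genome)[i], s))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  r1 <- unlist(lapply(pieces, `[[`, "r1"), use.names = FALSE)
  r2 <- unlist(lapply(pieces, `[[`, "r2"), use.names = FALSE)
  ids <- unlist(lapply(pieces, `[[`, "ids"), use.names = FALSE)

  if (cfg$error_rate > 0 && length(r1)) {
    both <- c(r1, r2)
    nb <- length(both) * rl
    both <- with_seed(cfg$seed, {
      ne <- rbinom(1L, nb, cfg$error_rate)
      if (ne > 0L) {
        at <- sort(sample.int(nb, ne))
        ridx <- (at - 1L) %/% rl + 1L
        roff <- (at - 1L) %% rl + 1L
        old <- substr(both[ridx], roff, roff)
        shift <- sample.int(3L, ne, replace = TRUE)
        new <- BASES[(base_to_code(old) + shift) %% 4L + 1L]
        .apply_subs_cpp(both, ridx, roff, new)
      } else both
    })
    r1 <- both[seq_along(r1)]
    r2 <- both[seq_along(r2) + length(r1)]
  }

  paths <- NULL
  if (!is.null(out_prefix)) {
    ext <- if (gz) ".fastq.gz" else ".fastq"
    paths <- paste0(out_prefix, c("_1", "_2"), ext)
    write_fastq(r1, paths[1], ids = paste0(ids, "/1"))
    write_fastq(r2, paths[2], ids = paste0(ids, "/2"))
  }
  invisible(list(r1 = r1, r2 = r2, ids = ids, paths = paths))
}

#' Flag planted mutations as unique or repetitive
#'
#' For each truth record, the 200 bp reference window centred on the
#' mutation (clipped at chromosome ends) is marked `unique` when every one
#' of its k-mers occurs exactly once in the genome counting both strands —
#' an exact-match surrogate for a single-hit BLAST criterion — and
#' `repetitive` otherwise.
#'
#' @param genome the original reference [genome()].
#' @param truth truth table from [apply_mutations()].
#' @param flank half-window (bp).
#' @param k k-mer length for the occurrence scan.
#' @return `truth` with a `uniqueness` column (`unique`/`repetitive`).
#' @export
classify_uniqueness <- function(genome, truth, flank = 100L, k = 20L) {
  enc <- .encode_windows_cpp(unclass(genome), as.integer(k))
  codes <- enc$codes[!is.na(enc$codes)]
  cnt <- data.table(code = c(codes, .revcomp_codes_cpp(codes, k)))[
    , .(n = .N), by = code]
  setkey(cnt, code)
  truth <- copy(truth)
  lens <- setNames(nchar(genome), names(genome))
  wins <- truth[, .(id = .I, chrom, s = pmax(1L, pos - flank),
                    e = pmin(lens[chrom], pos + flank - 1L))]
  wseq <- substring(unclass(genome)[wins$chrom], wins$s, wins$e)
  wenc <- .encode_windows_cpp(wseq, as.integer(k))
  q <- data.table(id = rep(wins$id, wenc$n), code = wenc$codes)
  q <- cnt[q, on = "code"]
  flag <- q[, .(uni = !anyNA(n) && all(n == 1L) && .N > 0L), by = id]
  truth[, uniqueness := "repetitive"]
  truth[flag$id[flag$uni], uniqueness := "unique"]
  truth[]
}

#' Evaluate calls against a truth table
#'
#' A truth record is recovered when a call of the same type lies within
#' `tol_snp` (SNPs, also matching ref/alt) or `tol_sv` (SV edges) of its
#' breakpoints, with exact size for insertions and deletions. Independently,
#' any call with a breakend inside a planted event's genomic footprint
#' (within `tol_sv`) is *attributed* to that event — the excision scar of a
#' cut-and-paste translocation, shadow edges from junction-crossing reads,
#' or error calls on top of a planted allele are artifacts of the event, not
#' of the method — but attribution never recovers a record; only a
#' correctly-typed call does. Calls matching no truth record at all are
#' counted and returned.
#'
#' @param calls call table ([call_variants()] / [verify_candidates()]).
#' @param truth truth table (optionally with `uniqueness` from
#'   [classify_uniqueness()]).
#' @param tol_snp,tol_sv position tolerances (bp).
#' @return list: `truth` (with `recovered`), `calls` (with `matched`),
#'   `recall_by` (`data.table` by type and uniqueness), `n_unmatched`,
#'   `unmatched` (the unmatched calls).
#' @export
evaluate_calls <- function(calls, truth, tol_snp = 0L, tol_sv = 5L) {
  truth <- copy(as.data.table(truth))
  calls <- copy(as.data.table(calls))
  if (!"uniqueness" %in% names(truth)) truth[, uniqueness := NA_character_]
  truth[, recovered := FALSE]
  calls[, matched := FALSE]
  for (r in seq_len(nrow(truth))) {
    t <- truth[r]
    hit <- switch(
      t$type,
      SNP = calls$type == "SNP" & calls$chrom == t$chrom &
        abs(calls$pos - t$pos) <= tol_snp &
        calls$ref == t$ref & calls$alt == t$alt,
      DEL = calls$type == "DEL" & calls$chrom == t$chrom &
        calls$size == t$size & abs(calls$pos - (t$pos - 1L)) <= tol_sv,
      INS = calls$type == "INS" & calls$chrom == t$chrom &
        calls$size == t$size & abs(calls$pos - (t$pos - 1L)) <= tol_sv,
      INV = {
        e <- t$pos + t$size - 1L
        calls$type == "INV" & calls$chrom == t$chrom &
          calls$pos >= t$pos - 1L - tol_sv & calls$pos <= t$pos + tol_sv &
          calls$pos2 >= e - tol_sv & calls$pos2 <= e + 1L + tol_sv
      },
      TRL = {
        lo_o <- t$pos - 1L - tol_sv; hi_o <- t$pos + t$size + tol_sv
        lo_d <- t$pos2 - tol_sv;     hi_d <- t$pos2 + 1L + tol_sv
        fwd <- calls$chrom == t$chrom & calls$pos >= lo_o & calls$pos <= hi_o &
          calls$chrom2 == t$chrom2 & calls$pos2 >= lo_d & calls$pos2 <= hi_d
        rev <- calls$chrom == t$chrom2 & calls$pos >= lo_d & calls$pos <= hi_d &
          calls$chrom2 == t$chrom & calls$pos2 >= lo_o & calls$pos2 <= hi_o
        calls$type == "TRL" & (fwd | rev)
      })
    hit[is.na(hit)] <- FALSE
    if (any(hit)) {
      truth[r, recovered := TRUE]
      calls[hit, matched := TRUE]
    }
    ## footprint attribution: any call with a breakend inside the event's
    ## genomic footprint (+/- tol_sv) is attributed to the event — e.g. the
    ## excision scar of a cut-and-paste translocation, shadow edges that
    ## junction-crossing reads emit, or error calls on top of a planted
    ## allele, where the event itself removed the wild-type context. An
    ## attributed call does not recover the record unless correctly typed
    ## above.
    inwin <- function(cc, pp, w_chrom, lo, hi)
      !is.na(cc) & cc == w_chrom & !is.na(pp) & pp >= lo & pp <= hi
    art <- inwin(calls$chrom, calls$pos, t$chrom,
                 t$pos - 1L - tol_sv, t$pos + max(t$size, 1L) + tol_sv) |
      inwin(calls$chrom2, calls$pos2, t$chrom,
            t$pos - 1L - tol_sv, t$pos + max(t$size, 1L) + tol_sv)
    if (t$type == "TRL") {
      art <- art |
        inwin(calls$chrom, calls$pos, t$chrom2,
              t$pos2 - tol_sv, t$pos2 + t$size + 1L + tol_sv) |
        inwin(calls$chrom2, calls$pos2, t$chrom2,
              t$pos2 - tol_sv, t$pos2 + t$size + 1L + tol_sv)
    }
    if (any(art)) calls[art, matched := TRUE]
  }
  recall_by <- truth[, .(n = .N, recovered = sum(recovered),
                         recall = mean(recovered)),
                     by = .(type, uniqueness)]
  list(truth = truth[], calls = calls[],
       recall_by = recall_by[],
       n_unmatched = sum(!calls$matched),
       unmatched = calls[matched == FALSE])
}

#' Match k-mer SNP edge calls against planted SNPs
#'
#' For each truth SNP the two expected edge calls are derived from the
#' reference: the forward call (prefix = the (k-1)-mer left flank, bases
#' ref -> alt) and the complementary call (prefix = reverse complement of
#' the right flank, bases comp(ref) -> comp(alt)). A truth SNP is matched
#' when either call is present; `reciprocal_ok` reports whether a matching
#' call is confirmed on both strands.
#'
#' @param calls k-mer SNP edge calls ([kmer_call_snps()]).
#' @param truth truth table (SNP records are used).
#' @param genome the original reference [genome()].
#' @param k k-mer length used by the caller.
#' @return `data.table` of truth SNPs with `matched`, `zygosity_called` and
#'   `reciprocal_ok`; attribute `n_extra_calls` counts calls matching no
#'   truth SNP.
#' @export
match_kmer_calls <- function(calls, truth, genome, k = 20L) {
  tsnp <- as.data.table(truth)[type == "SNP"]
  seqs <- unclass(genome)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  fwd_pfx <- substring(seqs[tsnp$chrom], tsnp$pos - (k - 1L), tsnp$pos - 1L)
  rev_pfx <- .revcomp_cpp(substring(seqs[tsnp$chrom], tsnp$pos + 1L,
                                    tsnp$pos + k - 1L))
  key_call <- paste(calls$prefix, calls$control_base, calls$target_base)
  key_fwd <- paste(fwd_pfx, tsnp$ref, tsnp$alt)
  key_rev <- paste(rev_pfx, comp(tsnp$ref), comp(tsnp$alt))
  i_fwd <- match(key_fwd, key_call)
  i_rev <- match(key_rev, key_call)
  hit <- ifelse(!is.na(i_fwd), i_fwd, i_rev)
  out <- copy(tsnp)
  out[, matched := !is.na(hit)]
  out[, zygosity_called := ifelse(is.na(hit), NA_character_,
                                  calls$zygosity[hit])]
  out[, reciprocal_ok := !is.na(hit) & calls$reciprocal[hit]]
  setattr(out, "n_extra_calls",
          sum(!seq_len(nrow(calls)) %in% stats::na.omit(c(i_fwd, i_rev))))
  out[]
}
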