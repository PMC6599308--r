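## verify: confirm candidate mutations by counting reads that carry the
## wild-type vs the mutant sequence context, and assign genotypes.

#' Control reads sliced from the reference
#'
#' When no control sample exists, control reads are made from the reference:
#' windows of `read_length` starting at every odd position of every
#' chromosome, complement-closed, deduplicated and sorted. Windows containing
#' non-ACGT bases are dropped.
#'
#' @param genome a [genome()] object.
#' @param read_length window length (the target read length).
#' @return a `ped_readset`.
#' @export
make_control_reads <- function(genome, read_length = 100L) {
  rl <- as.integer(read_length)
  if (rl < 1L) stopf("read_length must be positive")
  win <- unlist(lapply(unclass(genome), function(ch) {
    L <- nchar(ch)
    if (L < rl) return(character(0))
    s <- seq.int(1L, L - rl + 1L, by = 2L)
    substring(ch, s, s + rl - 1L)
  }), use.names = FALSE)
  sort_unique_reads(win)
}

#' Validation sequences for a SNP candidate
#'
#' Every window of `read_length` covering the SNP position (one per offset,
#' truncated at chromosome bounds) is emitted twice: the reference window
#' (tag `w`) and the window with the base substituted by the alternative
#' (tag `m`). Both read orientations are covered implicitly because read
#' sets are complement-closed.
#'
#' @param candidate list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param genome a [genome()] object.
#' @param read_length target read length.
#' @return `data.table` with columns `sequence`, `chrom`, `pos`, `ref`,
#'   `alt`, `tag`, sorted by sequence.
#' @export
build_validation_sequences <- function(candidate, genome, read_length = 100L) {
  rl <- as.integer(read_length)
  ch <- unclass(genome)[[candidate$chrom]]
  if (is.null(ch)) stopf("unknown chromosome %s", candidate$chrom)
  L <- nchar(ch)
  pos <- as.integer(candidate$pos)
  if (pos < 1L || pos > L) stopf("position %d outside chromosome %s", pos,
                                 candidate$chrom)
  s <- max(1L, pos - rl + 1L):min(pos, L - rl + 1L)
  s <- s[s >= 1L & s + rl - 1L <= L]
  wild <- substring(ch, s, s + rl - 1L)
  off <- pos - s + 1L
  mut <- paste0(substr(wild, 1L, off - 1L), candidate$alt,
                substr(wild, off + 1L, rl))
  out <- data.table(
    sequence = c(wild, mut),
    chrom = candidate$chrom, pos = pos,
    ref = candidate$ref, alt = candidate$alt,
    tag = rep(c("w", "m"), each = length(s)))
  setorder(out, sequence)
  out[]
}

#' Count read support for validation sequences
#'
#' Joins validation sequences against a sorted unique read set; the count of
#' a tag is the number of *distinct* validation sequences found verbatim in
#' the read set (the read set is deduplicated, so counts are over distinct
#' sequence contexts).
#'
#' @param records validation records ([build_validation_sequences()]).
#' @param reads a `ped_readset`.
#' @return named integer vector `c(wild = ..., mutant = ...)`.
#' @export
count_support <- function(records, reads) {
  found <- records$sequence %chin% as.character(reads)
  u <- !duplicated(records, by = c("sequence", "tag"))
  c(wild = sum(found & u & records$tag == "w"),
    mutant = sum(found & u & records$tag == "m"))
}

#' Genotype from verification counts
#'
#' `M` (homozygous mutation) requires at most 1 mutant-supporting control
#' read, at most 1 wild-supporting target read, and at least one
#' mutant-supporting target read. `H` (heterozygous) requires at most 1
#' mutant-supporting control read and both target fractions
#' `tw/(tw+tm)` and `tm/(tw+tm)` inside `[het_low, het_high]` (inclusive).
#' Everything else is `none`.
#'
#' @param cw,cm,tw,tm verification counts (control/target x wild/mutant);
#'   vectors are recycled to a common length.
#' @param het_low,het_high heterozygous allele-fraction window.
#' @return character vector of `"M"`, `"H"`, `"none"`.
#' @export
call_genotype <- function(cw, cm, tw, tm, het_low = 0.30, het_high = 0.70) {
  n <- max(length(cw), length(cm), length(tw), length(tm))
  cw <- rep_len(cw, n); cm <- rep_len(cm, n)
  tw <- rep_len(tw, n); tm <- rep_len(tm, n)
  m <- cm <= 1L & tw <= 1L & tm >= 1L
  tot <- tw + tm
  frac <- ifelse(tot > 0L, tm / tot, NA_real_)
  h <- cm <= 1L & tot > 0L & !is.na(frac) &
    frac >= het_low & frac <= het_high &
    (1 - frac) >= het_low & (1 - frac) <= het_high
  ifelse(m, "M", ifelse(h, "H", "none"))
}

## ---- SNP verification via read location -----------------------------------
## Locate every read of a sample on the reference (probe k-mers at the read's
## first and last offsets against the genome-unique index, then one full
## comparison). Forward-strand reads that equal a reference window give exact
## locations; reads one substitution away give (pos, alt, start) triples.
## Validation-window counts then reduce to cumulative sums (wild) and a keyed
## join (mutant): a wild validation window is present in the sample iff the
## window itself occurs as a read, and a mutant window iff a read equals the
## reference window with the single substitution pos -> alt.
locate_sample_reads <- function(reads, genome, index, rl) {
  k <- attr(index, "k")
  reads <- as.character(reads)
  lens <- nchar(reads)
  use <- lens == rl
  rd <- reads[use]
  a5 <- .encode_at_cpp(rd, 1L, k)
  hit5 <- index[data.table(code = a5), on = "code", .(chrom, pos, strand)]
  ## implied forward-strand window start from the 5' probe
  start <- fifelse(hit5$strand == 1L, hit5$pos, NA_integer_)
  chrom <- fifelse(hit5$strand == 1L, hit5$chrom, NA_integer_)
  miss <- is.na(start)
  if (any(miss)) {   # fall back to the 3' probe (error in the first k bases)
    a3 <- .encode_at_cpp(rd[miss], rl - k + 1L, k)
    hit3 <- index[data.table(code = a3), on = "code", .(chrom, pos, strand)]
    start[miss] <- fifelse(hit3$strand == 1L, hit3$pos - (rl - k), NA_integer_)
    chrom[miss] <- fifelse(hit3$strand == 1L, hit3$chrom, NA_integer_)
  }
  located <- !is.na(start)
  cmp <- .compare_at_cpp(rd[located], unclass(genome),
                         chrom[located], start[located], 2L)
  lchrom <- chrom[located]; lstart <- start[located]
  exact <- data.table(chrom = lchrom[cmp$mm == 0L],
                      start = lstart[cmp$mm == 0L])
  one <- cmp$mm == 1L & cmp$base >= 0L
  mm1 <- data.table(chrom = lchrom[one],
                    pos = lstart[one] + cmp$off[one] - 1L,
                    alt = cmp$base[one],   # 0..3 base code
                    start = lstart[one])
  setkey(exact, chrom, start)
  setkey(mm1, chrom, pos, alt)
  list(exact = exact, mm1 = mm1)
}

## per-candidate counts from located reads; cand: chrom (int), pos, alt
snp_counts_mapped <- function(cand, loc, chrom_lens, rl) {
  n <- nrow(cand)
  lo <- pmax(1L, cand$pos - rl + 1L)
  hi <- pmin(cand$pos, chrom_lens[cand$chrom] - rl + 1L)
  ## wild windows present: exact read starts within [lo, hi]
  wild <- integer(n)
  ex <- loc$exact
  if (nrow(ex)) {
    i1 <- ex[data.table(chrom = cand$chrom, start = lo), on = c("chrom", "start"),
             roll = -Inf, which = TRUE]
    i2 <- ex[data.table(chrom = cand$chrom, start = hi), on = c("chrom", "start"),
             roll = Inf, which = TRUE]
    ## rows i1..i2 are the exact windows of this chromosome within [lo, hi]
    ok <- !is.na(i1) & !is.na(i2) & i2 >= i1
    wild[ok] <- i2[ok] - i1[ok] + 1L
  }
  mut <- integer(n)
  if (nrow(loc$mm1)) {
    cnt <- loc$mm1[, .(nm = .N), by = .(chrom, pos, alt)]
    m <- cnt[data.table(chrom = cand$chrom, pos = cand$pos, alt = cand$alt),
             on = c("chrom", "pos", "alt")]
    mut <- fifelse(is.na(m$nm), 0L, m$nm)
  }
  list(wild = wild, mut = mut)
}

## ---- SNP verification, vectorised over many candidates -------------------

snp_verification_counts <- function(cand, genome, rl, target, control,
                                    chunk = 25000L) {
  seqs <- unclass(genome)
  lens <- nchar(seqs)
  n <- nrow(cand)
  res <- vector("list", ceiling(n / chunk))
  for (ci in seq_along(res)) {
    rows <- ((ci - 1L) * chunk + 1L):min(n, ci * chunk)
    cc <- cand[rows]
    m <- nrow(cc)
    Lc <- lens[cc$chrom]
    ids <- rep(seq_len(m), each = rl)
    starts <- rep(cc$pos, each = rl) + (-(rl - 1L)):0L
    keep <- starts >= 1L & starts <= rep(Lc, each = rl) - rl + 1L &
      starts + rl - 1L >= rep(cc$pos, each = rl)
    ids <- ids[keep]; starts <- starts[keep]
    txt <- seqs[cc$chrom[ids]]
    wild <- substring(txt, starts, starts + rl - 1L)
    offp <- cc$pos[ids] - starts + 1L
    mut <- .apply_subs_cpp(wild, seq_along(wild), offp, cc$alt[ids])
    dt <- data.table(id = ids, wild = wild, mut = mut)
    dtw <- unique(dt[, .(id, s = wild)], by = c("id", "s"))
    dtw[, `:=`(t = s %chin% target, ctl = s %chin% control)]
    cnt1 <- dtw[, .(tw = sum(t), cw = sum(ctl)), by = id]
    dtm <- unique(dt[, .(id, s = mut)], by = c("id", "s"))
    dtm[, `:=`(t = s %chin% target, ctl = s %chin% control)]
    cnt2 <- dtm[, .(tm = sum(t), cm = sum(ctl)), by = id]
    part <- merge(cnt1, cnt2, by = "id", all = TRUE)
    for (col in c("tw", "cw", "tm", "cm"))
      set(part, which(is.na(part[[col]])), col, 0L)
    part[, id := rows[id]]
    res[[ci]] <- part
  }
  out <- rbindlist(res)
  setkey(out, id)
  ## candidates whose windows were all out of bounds
  miss <- setdiff(seq_len(n), out$id)
  if (length(miss))
    out <- rbind(out, data.table(id = miss, tw = 0L, cw = 0L, tm = 0L, cm = 0L))
  setkey(out, id)
  out
}

## ---- SV verification: junction validation windows -------------------------

## breakend segment extraction; d = +1: block extends left of pos (junction
## at its right), d = -1: block extends right of pos
bk_seg1 <- function(ch, p, d, w) {
  L <- nchar(ch)
  if (d > 0L) substr(ch, max(1L, p - w + 1L), min(p, L))
  else .revcomp_cpp(substr(ch, max(1L, p), min(p + w - 1L, L)))
}
bk_seg2 <- function(ch, p, d, w) {
  L <- nchar(ch)
  if (d < 0L) substr(ch, max(1L, p), min(p + w - 1L, L))
  else .revcomp_cpp(substr(ch, max(1L, p - w + 1L), min(p, L)))
}

## local mutant haplotype around an SV junction; returns list(seq, joff)
## where joff is the offset of the last base before the junction
sv_local <- function(call, seqs, w) {
  ch1 <- seqs[[call$chrom]]
  type <- call$type
  if (type == "DEL") {
    left <- substr(ch1, max(1L, call$pos - w + 1L), call$pos)
    right <- substr(ch1, call$pos + call$size + 1L,
                    min(call$pos + call$size + w, nchar(ch1)))
    return(list(seq = paste0(left, right), joff = nchar(left),
                span = nchar(left) + 1L))
  }
  if (type == "INS") {
    left <- substr(ch1, max(1L, call$pos - w + 1L), call$pos)
    right <- substr(ch1, call$pos + 1L, min(call$pos + w, nchar(ch1)))
    return(list(seq = paste0(left, call$alt, right), joff = nchar(left),
                span = nchar(left) + call$size + 1L))
  }
  ## INV / TRL: generic breakend junction
  d <- c(if (substr(call$orient, 1, 1) == ">") 1L else -1L,
         if (substr(call$orient, 2, 2) == ">") 1L else -1L)
  ch2 <- seqs[[call$chrom2]]
  s1 <- bk_seg1(ch1, call$pos, d[1], w)
  s2 <- bk_seg2(ch2, call$pos2, d[2], w)
  list(seq = paste0(s1, s2), joff = nchar(s1), span = nchar(s1) + 1L)
}

## candidate breakpoint adjustments for INV/TRL junctions whose edge
## positions carry independent micro-homology slip; the shift that best
## reproduces the representative reads is used
sv_refine <- function(call, seqs, rl, max_shift = 8L) {
  reps <- call$reps[[1]]
  if (is.null(reps) || !length(reps)) return(call)
  reps <- unique(c(reps, .revcomp_cpp(reps)))
  shifts <- c(0L, as.vector(rbind(seq_len(max_shift), -seq_len(max_shift))))
  cand <- unique(rbindlist(list(
    data.table(d1 = shifts, d2 = 0L),
    data.table(d1 = 0L, d2 = shifts),
    data.table(d1 = shifts, d2 = -shifts),
    data.table(d1 = shifts, d2 = shifts))))
  best <- NULL; best_n <- -1L
  for (i in seq_len(nrow(cand))) {
    trial <- call
    trial$pos <- call$pos + cand$d1[i]
    trial$pos2 <- call$pos2 + cand$d2[i]
    loc <- sv_local(trial, seqs, rl + 10L)
    nhit <- sum(vapply(reps, function(r) grepl(r, loc$seq, fixed = TRUE),
                       logical(1)))
    if (nhit > best_n) { best <- trial; best_n <- nhit }
    if (best_n >= length(reps)) break
  }
  best
}

## reference windows crossing the breakpoint base pair (p, p+1 for d = +1;
## p-1, p for d = -1) of one chromosome
breakpoint_wild_windows <- function(ch, p, d, rl) {
  pr <- if (d > 0L) c(p, p + 1L) else c(p - 1L, p)
  L <- nchar(ch)
  sw <- max(1L, pr[2] - rl + 1L):min(pr[1], L - rl + 1L)
  sw <- sw[sw >= 1L & sw + rl - 1L <= L]
  if (length(sw)) unique(substring(ch, sw, sw + rl - 1L)) else character(0)
}

## wild and mutant validation windows for one SV call. Mutant windows whose
## junction overlap lies within the breakpoint micro-homology are identical
## to reference windows of one side; they carry no mutant information and
## are excluded (they would otherwise count wild-type reads as mutant
## support).
sv_windows <- function(call, seqs, rl) {
  w <- rl - 1L
  if (call$type %in% c("INV", "TRL")) call <- sv_refine(call, seqs, rl)
  loc <- sv_local(call, seqs, w)
  n <- nchar(loc$seq)
  ## mutant windows: every read-length window covering the junction span
  s <- max(1L, loc$span - rl + 1L):min(loc$joff, n - rl + 1L)
  s <- s[s >= 1L & s + rl - 1L <= n]
  mut <- if (length(s)) unique(substring(loc$seq, s, s + rl - 1L)) else character(0)
  ## side-1 breakpoint orientation
  d1 <- if (call$type %in% c("DEL", "INS")) 1L
        else if (substr(call$orient, 1, 1) == ">") 1L else -1L
  wild <- breakpoint_wild_windows(seqs[[call$chrom]], call$pos, d1, rl)
  ## side-2 reference windows (junction partner locus)
  p2 <- switch(call$type, DEL = call$pos + call$size + 1L,
               INS = call$pos + 1L, call$pos2)
  ch2 <- seqs[[if (call$type %in% c("DEL", "INS")) call$chrom else call$chrom2]]
  d2 <- if (call$type %in% c("DEL", "INS")) -1L
        else if (substr(call$orient, 2, 2) == ">") 1L else -1L
  wild2 <- breakpoint_wild_windows(ch2, p2, d2, rl)
  allw <- c(wild, wild2)
  mut <- mut[!(mut %chin% allw) & !(.revcomp_cpp(mut) %chin% allw)]
  ## symmetrically, wild windows whose junction overlap lies within the
  ## breakpoint micro-homology also occur on the mutant haplotype and carry
  ## no wild-type information
  amb <- vapply(wild, function(x) grepl(x, loc$seq, fixed = TRUE), logical(1)) |
    vapply(.revcomp_cpp(wild), function(x) grepl(x, loc$seq, fixed = TRUE),
           logical(1))
  wild <- wild[!amb]
  list(wild = wild, mut = mut)
}

#' Verify candidate mutations against target and control reads
#'
#' For every candidate, validation sequences (read-length windows carrying
#' the wild-type or the mutant context) are counted in the target and
#' control read sets and a genotype is assigned with [call_genotype()].
#' SNPs use all windows covering the variant base
#' ([build_validation_sequences()]). SVs — an extension of the same
#' procedure — use windows over the mutant junction, reconstructed by
#' splicing the reference at the call's breakpoints; for inversion and
#' translocation junctions the splice is first refined against the call's
#' representative reads so that micro-homology slip cannot shift the
#' windows. When no control read set is supplied, control reads are made
#' from the reference ([make_control_reads()]).
#'
#' @param candidates calls from [call_variants()] (or any table with
#'   `chrom`, `pos`, `type`, `ref`, `alt`, `size`, `chrom2`, `pos2`,
#'   `orient`, optionally `support` and `reps`).
#' @param genome a [genome()] object.
#' @param target_reads sorted unique target read set.
#' @param control_reads optional sorted unique control read set.
#' @param read_length read length used for validation windows.
#' @param het_low,het_high heterozygous allele-fraction window.
#' @param method SNP counting strategy. `"mapped"` (default) locates every
#'   read once on the genome-unique index and derives all window counts from
#'   the located reads; `"join"` materialises every validation window and
#'   joins it against the read sets (the literal construction; slower, and
#'   the reference for cross-checks). The two agree wherever reads anchor
#'   uniquely; in heavily repetitive regions `"mapped"` can undercount.
#' @param index optional precomputed [build_reference_index()] for
#'   `method = "mapped"`.
#' @return the candidate table plus `cw`, `cm`, `tw`, `tm` and `genotype`
#'   (`M`, `H` or `none`) columns.
#' @export
verify_candidates <- function(candidates, genome, target_reads,
                              control_reads = NULL, read_length = 100L,
                              het_low = 0.30, het_high = 0.70,
                              method = c("mapped", "join"), index = NULL) {
  method <- match.arg(method)
  rl <- as.integer(read_length)
  if (is.null(control_reads)) control_reads <- make_control_reads(genome, rl)
  target <- as.character(target_reads)
  control <- as.character(control_reads)
  out <- as.data.table(copy(candidates))
  if (nrow(out) == 0L) {
    out[, `:=`(cw = integer(0), cm = integer(0), tw = integer(0),
               tm = integer(0), genotype = character(0))]
    return(out[])
  }
  if (!"type" %in% names(out)) out[, type := "SNP"]
  out[, `:=`(cw = NA_integer_, cm = NA_integer_, tw = NA_integer_,
             tm = NA_integer_)]

  is_snp <- out$type == "SNP"
  if (any(is_snp) && method == "mapped") {
    if (is.null(index)) index <- build_reference_index(genome, min(20L, rl %/% 2L))
    loc_t <- locate_sample_reads(target, genome, index, rl)
    loc_c <- locate_sample_reads(control, genome, index, rl)
    lens <- nchar(genome)
    cand <- data.table(chrom = match(out$chrom[is_snp], names(genome)),
                       pos = out$pos[is_snp],
                       alt = base_to_code(out$alt[is_snp]))
    ct <- snp_counts_mapped(cand, loc_t, lens, rl)
    cc <- snp_counts_mapped(cand, loc_c, lens, rl)
    out[which(is_snp), `:=`(tw = ct$wild, tm = ct$mut,
                            cw = cc$wild, cm = cc$mut)]
  } else if (any(is_snp)) {
    cand <- out[is_snp, .(chrom, pos, ref, alt)]
    cnt <- snp_verification_counts(cand, genome, rl, target, control)
    out[which(is_snp)[cnt$id], `:=`(cw = cnt$cw, cm = cnt$cm,
                                    tw = cnt$tw, tm = cnt$tm)]
  }
  if (any(!is_snp)) {
    seqs <- as.list(unclass(genome))
    svs <- which(!is_snp)
    wins <- lapply(svs, function(i) sv_windows(as.list(out[i]), seqs, rl))
    pool <- data.table(
      i = rep(svs, times = vapply(wins, function(x)
        length(x$wild) + length(x$mut), integer(1))),
      s = unlist(lapply(wins, function(x) c(x$wild, x$mut)), use.names = FALSE),
      tag = unlist(lapply(wins, function(x)
        rep(c("w", "m"), c(length(x$wild), length(x$mut)))), use.names = FALSE))
    pool[, `:=`(t = s %chin% target, ctl = s %chin% control)]
    agg <- pool[, .(cw = sum(ctl[tag == "w"]), cm = sum(ctl[tag == "m"]),
                    tw = sum(t[tag == "w"]), tm = sum(t[tag == "m"])), by = i]
    out[agg$i, `:=`(cw = agg$cw, cm = agg$cm, tw = agg$tw, tm = agg$tm)]
    for (col in c("cw", "cm", "tw", "tm"))
      set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, genotype := call_genotype(cw, cm, tw, tm, het_low, het_high)]
  out[]
}

#' Write verified calls as TSV
#'
#' Mirrors the verification output format: chromosome, position, reference
#' base, alternative base, detection support, cw, cm, tw, tm, genotype
#' (plus SV columns for non-SNP calls).
#'
#' @param verified output of [verify_candidates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_verified_tsv <- function(verified, path) {
  out <- copy(as.data.table(verified))
  if ("reps" %in% names(out)) out[, reps := NULL]
  keep <- intersect(c("chrom", "pos", "type", "ref", "alt", "size", "chrom2",
                      "pos2", "orient", "support", "cw", "cm", "tw", "tm",
                      "genotype"), names(out))
  fwrite(out[, ..keep], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
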