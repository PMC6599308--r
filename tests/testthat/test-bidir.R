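## A controllable toy locus: random background with doctored bases around a
## planted 2 bp deletion so edge positions are exact (no homology slip).
del2_toy <- function() {
  g <- random_genome(1, 3000, seed = 101)
  ch <- unclass(g)[[1]]
  d <- 1500L
  substr(ch, d - 1, d + 2) <- "GAAC"   # ref[d-1]=G, ref[d]=A, ref[d+1]=A, ref[d+2]=C
  g <- genome(c(chr01 = ch))
  mut <- genome(c(chr01 = paste0(substr(ch, 1, d - 1),
                                 substr(ch, d + 2, nchar(ch)))))
  list(genome = g, mutated = mut, d = d)
}

test_that("scan_edge: identical read has no edge; point mismatch is symmetric", {
  g <- random_genome(1, 2000, seed = 77)
  s <- 600
  read <- substr(g[[1]], s, s + 79)
  cfg <- bidir_config()
  a5 <- list(chrom = "chr01", pos = s + cfg$margin, strand = "+")
  a3 <- list(chrom = "chr01", pos = s + 80 - cfg$margin - cfg$k, strand = "+")
  expect_null(scan_edge(read, g, a5, "5"))
  expect_null(scan_edge(read, g, a3, "3"))

  ## single substitution mid-read: same edge coordinate from both directions
  p <- as.integer(s + 40)
  ref <- substr(g[[1]], p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  substr(read, 41, 41) <- alt
  e5 <- scan_edge(read, g, a5, "5")
  e3 <- scan_edge(read, g, a3, "3")
  expect_identical(e5$ref, p)
  expect_identical(e3$ref, p)
  expect_true(e5$point && e3$point)
  expect_identical(e5$alt_base, alt)
  expect_identical(e5$ref_base, ref)
})

test_that("scan_edge locates the two edges of a 2 bp deletion junction", {
  toy <- del2_toy()
  d <- toy$d
  s <- d - 40                           # mutant-coordinate read start
  read <- substr(toy$mutated[[1]], s, s + 79)
  cfg <- bidir_config()
  d <- as.integer(d)
  e5 <- scan_edge(read, toy$genome,
                  list(chrom = "chr01", pos = s + cfg$margin, strand = "+"), "5")
  ## 3' anchor: read end maps 2 bp further right on the reference
  a3pos <- s + 80 - cfg$margin - cfg$k + 2
  e3 <- scan_edge(read, toy$genome,
                  list(chrom = "chr01", pos = a3pos, strand = "+"), "3")
  expect_identical(e5$ref, d)           # first base after the junction
  expect_identical(e3$ref, d + 1L)      # 2 bp away on the reference
  expect_false(e5$point)                # gap edge, not a point mismatch
})

test_that("classify arithmetic: reference span exceeding read span gives a DEL of that size", {
  toy <- del2_toy()
  cfg <- bidir_config(min_support = 1L)
  ## starts chosen so both anchor k-mers clear the junction
  s <- seq(toy$d - 54, toy$d - 26, by = 2)
  reads <- sort_unique_reads(substring(toy$mutated[[1]], s, s + 79))
  calls <- call_variants(reads, toy$genome, cfg = cfg)
  del <- calls[calls$type == "DEL", ]
  expect_identical(nrow(del), 1L)
  expect_identical(del$size, 2L)
  expect_identical(del$pos, toy$d - 1L)  # last matching base, 5' side
  expect_identical(del$pos2, toy$d + 2L) # first matching base, 3' side
  ## support counts molecules: a read and its closure complement are one
  expect_identical(del$support, length(reads) %/% 2L)
})

test_that("anchors on different chromosomes classify as TRL; opposite strands as INV", {
  g <- random_genome(2, 3000, seed = 88)
  cfg <- bidir_config(min_support = 1L)
  trl_read <- paste0(substr(g[[1]], 1000, 1049), substr(g[[2]], 2000, 2049))
  calls <- call_variants(sort_unique_reads(trl_read), g, cfg = cfg)
  expect_identical(unique(calls$type), "TRL")
  expect_setequal(c(calls$chrom[1], calls$chrom2[1]), c("chr01", "chr02"))

  inv_read <- paste0(substr(g[[1]], 500, 549),
                     brute_revcomp(substr(g[[1]], 1200, 1249)))
  calls <- call_variants(sort_unique_reads(inv_read), g, cfg = cfg)
  expect_identical(unique(calls$type), "INV")
})

test_that("insertions carry the inserted sequence and exact size", {
  g <- random_genome(1, 3000, seed = 99)
  ch <- unclass(g)[[1]]
  ## 10 bp insert after position 1400; first base differs from ref[1401] so
  ## the call is exactly left-aligned
  first <- setdiff(c("A", "C", "G", "T"), substr(ch, 1401, 1401))[1]
  ins <- paste0(first, "TGACCAATG")
  mut <- paste0(substr(ch, 1, 1400), ins, substr(ch, 1401, nchar(ch)))
  s <- seq(1340, 1390, by = 2)
  reads <- sort_unique_reads(substring(mut, s, s + 79))
  calls <- call_variants(reads, g, cfg = bidir_config(min_support = 1L))
  insc <- calls[calls$type == "INS", ]
  expect_identical(nrow(insc), 1L)
  expect_identical(insc$size, 10L)
  expect_identical(insc$pos, 1400L)
  expect_identical(insc$alt, ins)
})

test_that("error-free reads from an unmutated genome give zero calls", {
  g <- random_genome(2, 5000, seed = 123)
  reads <- sort_unique_reads(unlist(lapply(unclass(g), function(ch) {
    s <- seq(1, nchar(ch) - 59, by = 3)
    substring(ch, s, s + 59)
  })))
  calls <- call_variants(reads, g, cfg = bidir_config(min_support = 1L))
  expect_identical(nrow(calls), 0L)
})

test_that("calling a read and its reverse complement yields the same variant", {
  toy <- del2_toy()
  cfg <- bidir_config(min_support = 1L)
  read <- substr(toy$mutated[[1]], toy$d - 40, toy$d + 39)
  for (r in list(read, brute_revcomp(read))) {
    calls <- call_variants(structure(r, class = c("ped_readset", "character")),
                           toy$genome, cfg = cfg)
    del <- calls[calls$type == "DEL", ]
    expect_identical(del$pos, toy$d - 1L)
    expect_identical(del$size, 2L)
  }
})

test_that("planted battery is recovered with exact types and sizes (error-free)", {
  g <- random_genome(2, 120000, seed = 202)
  mut <- apply_mutations(g, mutation_scheme(scale = 100))
  reads <- slice_reads(mut$genome, read_sim_config(error_rate = 0, seed = 1))
  rs <- sort_unique_reads(c(reads$r1, reads$r2))
  calls <- call_variants(rs, g)
  truth <- classify_uniqueness(g, mut$truth)
  ev <- evaluate_calls(calls, truth)
  utruth <- ev$truth[ev$truth$uniqueness == "unique", ]
  expect_true(all(utruth$recovered))
  ## every DEL/INS call that matches truth has the exact planted size
  sizes <- ev$calls[ev$calls$matched & ev$calls$type %in% c("DEL", "INS"), ]
  expect_true(all(sizes$size %in% c(1L, 10L, 20L, 100L, 1000L)))
})

test_that("one-anchor reads still support SNP edges (margin-masked anchor)", {
  g <- random_genome(1, 4000, seed = 303)
  p <- 2000L
  ref <- substr(g[[1]], p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mut <- unclass(g)[[1]]
  substr(mut, p, p) <- alt
  ## reads whose 3' anchor k-mer covers the SNP: anchor absent, 5' scan calls
  s <- p - 85
  read <- substr(mut, s, s + 99)
  calls <- call_variants(structure(read, class = c("ped_readset", "character")),
                         g, cfg = bidir_config(min_support = 1L))
  snp <- calls[calls$type == "SNP", ]
  expect_identical(snp$pos, p)
  expect_identical(snp$alt, alt)
})
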