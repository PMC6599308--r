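test_that("extract_kmers enumerates every window", {
  expect_identical(sort(extract_kmers("ACGTACGT", 4)),
                   sort(c("ACGT", "ACGT", "CGTA", "GTAC", "TACG")))
  expect_identical(extract_kmers("ACGTA", 5), "ACGTA")
  expect_message(out <- extract_kmers(c("ACG", "ACGT"), 4), "skipped 1")
  expect_identical(out, "ACGT")
})

test_that("extract_kmers count matches the brute-force loop on random reads", {
  reads <- random_reads(1000, 50, seed = 1)
  km <- extract_kmers(reads, 20)
  expect_length(km, 31000)   # 1000 * (50 - 20 + 1)
  expect_length(km, length(brute_kmers(reads[1:20], 20)) * 50)
})

test_that("count_kmers matches a brute-force table and keeps totals", {
  expect_equal(
    as.data.frame(count_kmers(c("ACGT", "ACGT", "CGTA"))),
    data.frame(kmer = c("ACGT", "CGTA"), count = c(2L, 1L)),
    ignore_attr = TRUE)
  expect_identical(nrow(count_kmers(character(0))), 0L)
  for (seed in 1:3) {
    reads <- random_reads(50, 18, seed = seed)
    km <- extract_kmers(reads, 6)
    tb <- count_kmers(km)
    bf <- brute_count(brute_kmers(reads, 6))
    expect_identical(tb$kmer, bf$kmer)
    expect_identical(tb$count, bf$count)
    expect_identical(sum(tb$count), length(km))
  }
})

test_that("packed-code counting equals string counting", {
  reads <- random_reads(200, 40, seed = 7)
  k <- 20
  tb_str <- count_kmers(extract_kmers(reads, k))
  tb_cod <- count_kmers(extract_kmers(reads, k, codes = TRUE), k)
  expect_identical(decode_kmers(tb_cod$kmer, k), tb_str$kmer)
  expect_identical(tb_cod$count, tb_str$count)
})

test_that("to_last_base_table splits prefix and last base", {
  tb <- count_kmers(c(rep("AAAC", 3), rep("AAAT", 2)))
  lb <- to_last_base_table(tb)
  expect_equal(as.data.frame(lb),
               data.frame(prefix = "AAA", A = 0L, C = 3L, G = 0L, T = 2L),
               ignore_attr = TRUE)
  lb2 <- to_last_base_table(count_kmers(rep("AAAA", 7)))
  expect_equal(as.data.frame(lb2),
               data.frame(prefix = "AAA", A = 7L, C = 0L, G = 0L, T = 0L),
               ignore_attr = TRUE)
})

test_that("last-base row sums equal prefix-grouped totals on random tables", {
  reads <- random_reads(80, 25, seed = 11)
  k <- 8
  km <- extract_kmers(reads, k)
  lb <- to_last_base_table(count_kmers(km))
  expect_identical(sum(lb$A + lb$C + lb$G + lb$T), length(km))
  grp <- table(substr(km, 1, k - 1))
  expect_identical(as.integer(grp[lb$prefix]), lb$A + lb$C + lb$G + lb$T)
})

test_that("last_base_table fast path equals the step-by-step path", {
  reads <- sort_unique_reads(random_reads(150, 30, seed = 13))
  k <- 12
  fast <- last_base_table(reads, k, chunk_reads = 40L)
  slow <- to_last_base_table(count_kmers(extract_kmers(reads, k)))
  expect_identical(decode_kmers(fast$prefix, k - 1), slow$prefix)
  expect_identical(fast[, c("A", "C", "G", "T")], slow[, c("A", "C", "G", "T")])
})

test_that("join keeps only shared prefixes", {
  mk <- function(reads, k) last_base_table(sort_unique_reads(reads), k)
  ctl <- mk(c("AAAC"), 4)   # prefixes AAA (+ complements)
  tgt <- mk(c("AAAC", "CCCG"), 4)
  j <- join_last_base_tables(ctl, tgt)
  expect_identical(decode_kmers(j$prefix, 3), sort(c("AAA", "GTT")))
  tgt2 <- mk("GGGT", 4)
  expect_identical(nrow(join_last_base_tables(ctl, tgt2)), 0L)
})

test_that("joined prefix set equals the brute-force intersection", {
  a <- sort_unique_reads(random_reads(60, 20, seed = 17))
  b <- sort_unique_reads(random_reads(60, 20, seed = 18))
  k <- 7
  ja <- last_base_table(a, k); jb <- last_base_table(b, k)
  j <- join_last_base_tables(ja, jb)
  expect_setequal(decode_kmers(j$prefix, k - 1),
                  intersect(decode_kmers(ja$prefix, k - 1),
                            decode_kmers(jb$prefix, k - 1)))
})

test_that("call_snp_edges applies the stated presence/absence rules", {
  mkjoin <- function(ctl, tgt) {
    j <- data.table::data.table(
      prefix = encode_kmers("ACGTACGTACGTACGTACG"),
      cA = ctl[1], cC = ctl[2], cG = ctl[3], cT = ctl[4],
      tA = tgt[1], tC = tgt[2], tG = tgt[3], tT = tgt[4])
    data.table::setattr(j, "k", 20L)
    j
  }
  hom <- call_snp_edges(mkjoin(c(0, 30, 0, 0), c(0, 0, 0, 28)))
  expect_identical(hom$zygosity, "hom")
  expect_identical(hom$control_base, "C")
  expect_identical(hom$target_base, "T")

  het <- call_snp_edges(mkjoin(c(0, 30, 0, 0), c(0, 14, 0, 16)))
  expect_identical(het$zygosity, "het")
  expect_identical(het$target_base, "T")
  expect_equal(het$af, 16 / 30, tolerance = 1e-12)

  ## alternative below min_depth: no call
  expect_identical(nrow(call_snp_edges(mkjoin(c(0, 30, 0, 0), c(0, 29, 0, 1)))), 0L)
  ## ambiguous control (two present bases): no call
  expect_identical(nrow(call_snp_edges(mkjoin(c(0, 15, 15, 0), c(0, 0, 0, 28)))), 0L)
  ## under-covered control: no call
  expect_identical(nrow(call_snp_edges(mkjoin(c(0, 2, 0, 0), c(0, 0, 0, 28)))), 0L)
})

test_that("k-mer pipeline recovers a planted hom SNP on both strands, and nothing else", {
  sim <- tiny_snp_sim(len = 4000, snp_pos = 2000, seed = 5)
  calls <- kmer_call_snps(sim$target, sim$control)
  expect_identical(nrow(calls), 2L)   # forward and complementary edge
  expect_true(all(calls$zygosity == "hom"))
  expect_true(all(calls$reciprocal))
  fwd <- calls[calls$control_base == sim$ref & calls$target_base == sim$alt]
  expect_identical(fwd$prefix,
                   substr(sim$genome[[1]], sim$pos - 19, sim$pos - 1))
})

test_that("heterozygous mixtures are called het within the allele-fraction window", {
  sim <- tiny_snp_sim(len = 4000, snp_pos = 2000, seed = 6)
  pooled <- sort_unique_reads(c(as.character(sim$target),
                                as.character(sim$control)))
  calls <- kmer_call_snps(pooled, sim$control)
  expect_gte(nrow(calls), 2L)
  expect_true(all(calls$zygosity == "het"))
  expect_true(all(calls$af >= 0.3 & calls$af <= 0.7))
})

test_that("no polymorphism means no calls (target = control)", {
  sim <- tiny_snp_sim(len = 3000, seed = 8)
  calls <- kmer_call_snps(sim$control, sim$control)
  expect_identical(nrow(calls), 0L)
})

test_that("reciprocal marking is symmetric and FALSE without a mirror", {
  sim <- tiny_snp_sim(len = 4000, snp_pos = 2000, seed = 5)
  tt <- last_base_table(sim$target, 20)
  ct <- last_base_table(sim$control, 20)
  calls <- call_snp_edges(join_last_base_tables(ct, tt))
  conf <- reciprocal_confirm(calls, tt)
  expect_true(all(conf$reciprocal))   # both mirrors present -> both marked
  one <- reciprocal_confirm(calls[1], tt)
  expect_false(any(one$reciprocal))   # mirror removed from the call list
})

test_that("complement closure makes the k-mer count table strand symmetric", {
  reads <- sort_unique_reads(random_reads(100, 30, seed = 21))
  k <- 10
  tb <- count_kmers(extract_kmers(reads, k))
  rc <- brute_revcomp(tb$kmer)
  m <- match(rc, tb$kmer)
  expect_false(anyNA(m))
  expect_identical(tb$count[m], tb$count)
})
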