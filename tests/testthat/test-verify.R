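test_that("make_control_reads slices odd positions, complement-closed", {
  g <- genome(c(c1 = "ACGTACGTAC"))     # length 10
  cr <- make_control_reads(g, 4)
  win <- substring("ACGTACGTAC", c(1, 3, 5, 7), c(4, 6, 8, 10))
  expect_setequal(as.character(cr), unique(c(win, brute_revcomp(win))))
  ## all-distinct windows -> 2x window count
  g2 <- random_genome(1, 301, seed = 2)
  cr2 <- make_control_reads(g2, 40)
  expect_identical(length(cr2), 2L * length(seq(1, 301 - 39, by = 2)))
  ## chromosome shorter than the read length contributes nothing
  expect_identical(length(make_control_reads(genome(c(c1 = "ACG")), 10)), 0L)
})

test_that("control window multiset equals brute-force slicing", {
  g <- random_genome(1, 1000, seed = 31)
  rl <- 30
  cr <- make_control_reads(g, rl)
  brute <- character(0)
  ch <- unclass(g)[[1]]
  for (s in seq(1, nchar(ch) - rl + 1, by = 2))
    brute <- c(brute, substr(ch, s, s + rl - 1))
  expect_setequal(as.character(cr), unique(c(brute, brute_revcomp(brute))))
})

test_that("build_validation_sequences emits one wild/mutant pair per offset", {
  g <- random_genome(1, 500, seed = 41)
  ref250 <- substr(g[[1]], 250, 250)
  cand <- list(chrom = "chr01", pos = 250L, ref = ref250,
               alt = setdiff(c("A", "C", "G", "T"), ref250)[1])
  v <- build_validation_sequences(cand, g, 100)
  expect_identical(sum(v$tag == "w"), 100L)
  expect_identical(sum(v$tag == "m"), 100L)
  ## wild windows are genome substrings; mutant windows are not
  expect_true(all(vapply(v$sequence[v$tag == "w"],
                         function(s) grepl(s, g[[1]], fixed = TRUE), logical(1))))
  expect_false(any(vapply(v$sequence[v$tag == "m"],
                          function(s) grepl(s, g[[1]], fixed = TRUE), logical(1))))
  ## boundary SNP: one valid window each
  v1 <- build_validation_sequences(list(chrom = "chr01", pos = 1L,
                                        ref = substr(g[[1]], 1, 1), alt = "A"),
                                   g, 100)
  expect_identical(nrow(v1), 2L)
  expect_error(build_validation_sequences(list(chrom = "chr01", pos = 900L,
                                               ref = "A", alt = "C"), g, 100),
               "outside")
})

test_that("count_support equals brute-force substring-set membership", {
  g <- random_genome(1, 800, seed = 51)
  reads <- sort_unique_reads(substring(g[[1]], seq(1, 750, 3), seq(1, 750, 3) + 49))
  cand <- list(chrom = "chr01", pos = 400L,
               ref = substr(g[[1]], 400, 400), alt = "A")
  v <- build_validation_sequences(cand, g, 50)
  cs <- count_support(v, reads)
  brute <- c(wild = length(unique(v$sequence[v$tag == "w" &
                                             v$sequence %in% as.character(reads)])),
             mutant = length(unique(v$sequence[v$tag == "m" &
                                               v$sequence %in% as.character(reads)])))
  expect_identical(cs, brute)
  expect_identical(unname(cs["mutant"]), 0L)  # mutant absent from wild reads
})

test_that("count_support never decreases when reads are added", {
  g <- random_genome(1, 600, seed = 61)
  cand <- list(chrom = "chr01", pos = 300L,
               ref = substr(g[[1]], 300, 300), alt = "C")
  v <- build_validation_sequences(cand, g, 40)
  some <- sort_unique_reads(substring(g[[1]], seq(260, 300, 4), seq(260, 300, 4) + 39))
  more <- sort_unique_reads(c(as.character(some),
                              substring(g[[1]], seq(261, 299, 2), seq(261, 299, 2) + 39)))
  c1 <- count_support(v, some); c2 <- count_support(v, more)
  expect_true(all(c2 >= c1))
})

test_that("call_genotype reproduces the printed M/H rules", {
  expect_identical(call_genotype(30, 0, 0, 28), "M")
  expect_identical(call_genotype(30, 0, 17, 25), "H")    # 17/42, 25/42
  expect_identical(call_genotype(30, 5, 10, 10), "none") # contaminated control
  expect_identical(call_genotype(30, 0, 0, 0), "none")   # no mutant support
  ## inclusive window bounds
  expect_identical(call_genotype(0, 0, 3, 7), "H")       # exactly 0.30 / 0.70
  expect_identical(call_genotype(0, 0, 2, 8), "none")
})

test_that("verification genotypes a planted hom SNP as M and a false candidate as none", {
  sim <- tiny_snp_sim(len = 4000, snp_pos = 2000, seed = 71)
  cand <- data.table::data.table(chrom = "chr01", pos = 2000L, type = "SNP",
                                 ref = sim$ref, alt = sim$alt,
                                 size = 0L, chrom2 = NA_character_,
                                 pos2 = NA_integer_, orient = NA_character_)
  v <- verify_candidates(cand, sim$genome, sim$target, sim$control, 50)
  expect_identical(v$genotype, "M")
  expect_lte(v$tw, 1L)
  expect_gte(v$tm, 2L)

  ## candidate at an unmutated site: no mutant support
  ref2 <- substr(sim$genome[[1]], 1000, 1000)
  false_cand <- data.table::data.table(chrom = "chr01", pos = 1000L,
                                       type = "SNP", ref = ref2,
                                       alt = setdiff(c("A","C","G","T"), ref2)[1],
                                       size = 0L, chrom2 = NA_character_,
                                       pos2 = NA_integer_, orient = NA_character_)
  v2 <- verify_candidates(false_cand, sim$genome, sim$target, sim$control, 50)
  expect_identical(v2$genotype, "none")
  expect_identical(v2$tm, 0L)
})

test_that("1:1 pooled reads verify as H at planted sites, never M", {
  sim <- tiny_snp_sim(len = 4000, snp_pos = 2000, seed = 81)
  pooled <- sort_unique_reads(c(as.character(sim$target),
                                as.character(sim$control)))
  cand <- data.table::data.table(chrom = "chr01", pos = 2000L, type = "SNP",
                                 ref = sim$ref, alt = sim$alt, size = 0L,
                                 chrom2 = NA_character_, pos2 = NA_integer_,
                                 orient = NA_character_)
  v <- verify_candidates(cand, sim$genome, pooled, sim$control, 50)
  expect_identical(v$genotype, "H")
})

test_that("reference-derived control is used when no control reads are given", {
  sim <- tiny_snp_sim(len = 3000, snp_pos = 1500, seed = 91, read_length = 50)
  cand <- data.table::data.table(chrom = "chr01", pos = 1500L, type = "SNP",
                                 ref = sim$ref, alt = sim$alt, size = 0L,
                                 chrom2 = NA_character_, pos2 = NA_integer_,
                                 orient = NA_character_)
  v <- verify_candidates(cand, sim$genome, sim$target, NULL, 50)
  expect_identical(v$genotype, "M")
  expect_gte(v$cw, 1L)
  expect_identical(v$cm, 0L)
})

test_that("SV junction verification marks true deletions M and rejects shifted junctions", {
  g <- random_genome(1, 6000, seed = 105)
  ch <- unclass(g)[[1]]
  d <- 3000; sz <- 100L
  mut <- paste0(substr(ch, 1, d - 1), substr(ch, d + sz, nchar(ch)))
  s <- seq(1, nchar(mut) - 49, by = 2)
  target <- sort_unique_reads(substring(mut, s, s + 49))
  call <- data.table::data.table(chrom = "chr01", pos = d - 1L, type = "DEL",
                                 ref = NA_character_, alt = NA_character_,
                                 size = sz, chrom2 = "chr01",
                                 pos2 = d + sz, orient = "><",
                                 support = 10L, reps = list(character(0)))
  v <- verify_candidates(call, g, target, NULL, 50)
  expect_identical(v$genotype, "M")
  ## same deletion size at a shifted position: windows don't match target
  wrong <- data.table::copy(call)[, pos := pos - 500L][, pos2 := pos2 - 500L]
  v2 <- verify_candidates(wrong, g, target, NULL, 50)
  expect_identical(v2$genotype, "none")
})
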