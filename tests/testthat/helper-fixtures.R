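## Small in-code fixtures shared across test files.

## brute-force k-mer multiset by explicit substring loop
brute_kmers <- function(reads, k) {
  out <- character(0)
  for (r in reads) {
    L <- nchar(r)
    if (L < k) next
    for (s in seq_len(L - k + 1)) out <- c(out, substr(r, s, s + k - 1))
  }
  out
}

## brute-force k-mer counter (independent of the package path)
brute_count <- function(kmers) {
  tb <- table(kmers)
  data.frame(kmer = names(tb), count = as.integer(tb),
             stringsAsFactors = FALSE)[order(names(tb)), ]
}

## pure-R reverse complement, independent of the compiled path
brute_revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(rev(chartr("ACGT", "TGCA", ch)), collapse = ""), character(1))
}

## random reads over ACGT
random_reads <- function(n, len, seed) {
  with_seed_test(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## a tiny simulated dataset: genome + one planted hom SNP, error-free tiled
## reads from both strands
tiny_snp_sim <- function(len = 4000, snp_pos = 2000, seed = 5,
                         read_length = 50, step = 2) {
  g <- random_genome(1, len, seed = seed)
  ref <- substr(g[[1]], snp_pos, snp_pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mut <- g
  substr(mut[[1]], snp_pos, snp_pos) <- alt
  mut <- genome(setNames(unclass(mut), names(g)))
  slice <- function(gn) {
    s <- seq(1, nchar(gn[[1]]) - read_length + 1, by = step)
    sort_unique_reads(substring(gn[[1]], s, s + read_length - 1))
  }
  list(genome = g, mutated = mut, ref = ref, alt = alt, pos = snp_pos,
       target = slice(mut), control = slice(g))
}
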