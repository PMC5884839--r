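# Independent brute-force oracles, deliberately written with different
# machinery (Biostrings reverse complement, R substring scans) than the
# package's C++ engine.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oracle_canonical <- function(w) {
  rc <- oracle_revcomp(w)
  ifelse(w <= rc, w, rc)
}

# All valid canonical k-mer windows of one sequence, in positional order.
oracle_windows <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  w <- substring(s, 1:(n - k + 1), k:n)
  w <- w[grepl("^[ACGT]+$", w)]
  if (!length(w)) return(character(0))
  oracle_canonical(w)
}

# Naive per-read substring-scan counts of list k-mers, both modes.
oracle_count_sample <- function(reads, lists, mode = "occurrences") {
  k <- lists$k
  wins <- unlist(lapply(reads, oracle_windows, k = k), use.names = FALSE)
  vapply(lists$lists, function(s) {
    if (mode == "occurrences") sum(wins %in% s$kmer)
    else sum(s$kmer %in% wins)
  }, 0)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Tiny random chromosome lists + read sets for oracle-equivalence checks.
random_read_case <- function(k, n_chrom = 2, chrom_len = 120, n_reads = 6,
                             read_len = 40, n_frac = 0.05) {
  genome <- setNames(vapply(seq_len(n_chrom), function(i)
    random_dna_str(chrom_len), ""), paste0("c", seq_len(n_chrom)))
  lists <- lapply(genome, function(s) {
    km <- unique(oracle_windows(s, k))
    kmer_set(sample(km, max(1, length(km) %/% 2)), k)
  })
  obj <- structure(list(k = as.integer(k), lists = lists,
                        L_c = vapply(lists, function(x) length(x$kmer), 0L),
                        params = list(), control_ids = character(0)),
                   class = "chrom_kmer_lists")
  obj$digest <- "test"
  reads <- vapply(seq_len(n_reads), function(i) {
    src <- genome[[sample(n_chrom, 1)]]
    a <- sample.int(nchar(src) - read_len + 1L, 1)
    r <- substr(src, a, a + read_len - 1L)
    if (runif(1) < 0.5) r <- oracle_revcomp(r)
    # sprinkle Ns to exercise window voiding
    nn <- rbinom(1, read_len, n_frac)
    if (nn > 0) for (p in sample.int(read_len, nn)) substr(r, p, p) <- "N"
    r
  }, "")
  list(lists = obj, reads = reads)
}

# Explicit normal-equation OLS, the regression oracle.
oracle_ols <- function(X, y) drop(solve(t(X) %*% X) %*% t(X) %*% y)

# Term-by-term Poisson CDF quantile: smallest x with sum(pmf) >= p.
oracle_poisson_quantile <- function(p, lambda, x_max = 10000) {
  cdf <- 0
  for (x in 0:x_max) {
    cdf <- cdf + exp(-lambda) * lambda^x / factorial(x)
    if (cdf >= p) return(x)
  }
  stop("x_max exceeded")
}
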