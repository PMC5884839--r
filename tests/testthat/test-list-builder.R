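test_that("initial lists enumerate each chromosome", {
  set.seed(21)
  g <- c(chrA = random_dna_str(100), chrB = random_dna_str(100))
  lists <- build_initial_lists(g, 25)
  expect_named(lists, c("chrA", "chrB"))
  expect_true(all(vapply(lists, function(x) length(x$kmer), 0L) <= 76))
  expect_equal(sum(lists$chrA$count), 76)  # all windows valid

  rep_g <- c(chrR = strrep("ACGTACGT", 20))
  rl <- build_initial_lists(rep_g, 25)$chrR
  tab <- table(oracle_windows(rep_g[[1]], 25))
  expect_identical(rl$kmer, sort(names(tab)))
  expect_equal(rl$count, as.numeric(tab[rl$kmer]))

  expect_identical(build_initial_lists(c(chrN = strrep("N", 100)), 25)$chrN$kmer,
                   character(0))
  expect_error(build_initial_lists(character(0), 25), "empty genome")
})

test_that("uniqueness filter removes genome-wide multi-copy k-mers", {
  set.seed(22)
  k <- 25
  block <- random_dna_str(60)
  chrA <- paste0(random_dna_str(50), block, random_dna_str(120))
  chrB <- paste0(random_dna_str(100), block, random_dna_str(80))
  g <- c(chrA = chrA, chrB = chrB)
  uniq <- filter_nonunique(build_initial_lists(g, k))

  # oracle: global canonical multiplicity over both chromosomes
  wins <- c(oracle_windows(chrA, k), oracle_windows(chrB, k))
  tab <- table(wins)
  singletons <- names(tab)[tab == 1]
  expect_identical(uniq$chrA$kmer,
                   sort(intersect(unique(oracle_windows(chrA, k)), singletons)))
  expect_identical(uniq$chrB$kmer,
                   sort(intersect(unique(oracle_windows(chrB, k)), singletons)))

  # every k-mer fully inside the duplicated block is gone from both lists
  block_kmers <- oracle_windows(block, k)
  expect_length(intersect(block_kmers, uniq$chrA$kmer), 0)
  expect_length(intersect(block_kmers, uniq$chrB$kmer), 0)
  # flanking junction k-mers are retained
  expect_gt(length(uniq$chrA$kmer), 0)

  # a within-chromosome duplicate is removed too
  g2 <- c(chrC = paste0("ACGTACGTACGT", random_dna_str(30), "ACGTACGTACGT"))
  u2 <- filter_nonunique(build_initial_lists(g2, 12))
  expect_false("ACGTACGTACGT" %in% u2$chrC$kmer)
})

test_that("polymorphic k-mers cover all haplotype windows of qualifying variants", {
  g <- c(chrT = "ACGTACGTAC")
  v <- data.frame(chrom = "chrT", pos = 5, ref = "A", alt = "G", af = 0.3)
  got <- polymorphic_kmers(g, v, k = 3)
  # hand-derived: ref slice GTACG -> {GTA, GTA, ACG}; alt slice GTGCG ->
  # {CAC, GCA, CGC}
  expect_identical(got$kmer, c("ACG", "CAC", "CGC", "GCA", "GTA"))

  # below-threshold and absent variants contribute nothing
  v_rare <- transform(v, af = 0.005)
  expect_length(polymorphic_kmers(g, v_rare, k = 3)$kmer, 0)
  expect_length(polymorphic_kmers(g, v[0, ], k = 3)$kmer, 0)
  # missing AF treated as above threshold (conservative)
  v_na <- transform(v, af = NA_real_)
  expect_identical(polymorphic_kmers(g, v_na, k = 3)$kmer, got$kmer)

  # ref-allele inconsistency is reported with the variant
  v_bad <- transform(v, ref = "C")
  expect_error(polymorphic_kmers(g, v_bad, k = 3), "chrT:5")

  # dense cluster beyond the cap falls back to reference window k-mers
  v2 <- data.frame(chrom = "chrT", pos = c(4, 5, 6), ref = c("T", "A", "C"),
                   alt = c("A", "G", "T"), af = 0.3)
  capped <- polymorphic_kmers(g, v2, k = 3, max_haplotypes = 2)
  ref_only <- kmer_set(oracle_windows(substr(g[[1]], 2, 8), 3), 3)
  expect_true(all(ref_only$kmer %in% capped$kmer))

  # an indel substitutes allele strings and keeps k-1 flanks
  v3 <- data.frame(chrom = "chrT", pos = 4, ref = "TA", alt = "T", af = 0.2)
  del <- polymorphic_kmers(g, v3, k = 3)
  # haplotype with deletion around pos 4: ...CGT|CGT...
  expect_true(all(oracle_windows("ACGTCGTAC", 3) %in% del$kmer))
})

test_that("region k-mers are exactly the windows overlapping by >= 1 base", {
  set.seed(23)
  g <- c(chrQ = random_dna_str(100))
  k <- 5
  reg <- data.frame(chrom = "chrQ", start = 40, end = 50)
  got <- region_kmers(g, reg, k)
  # positional oracle: 0-based window starts overlapping [40, 50)
  starts0 <- 0:(100 - k)
  overlap <- starts0 < 50 & (starts0 + k) > 40
  expect_equal(sum(overlap), 14)
  wins <- oracle_canonical(substring(g[[1]], starts0 + 1, starts0 + k))
  expect_identical(got$kmer, sort(unique(wins[overlap])))

  whole <- region_kmers(g, data.frame(chrom = "chrQ", start = 0, end = 100), k)
  expect_identical(whole$kmer, sort(unique(wins)))
  expect_length(region_kmers(g, reg[0, ], k)$kmer, 0)
  expect_error(region_kmers(g, data.frame(chrom = "nope", start = 0, end = 5), k),
               "unknown chromosome")
  expect_error(region_kmers(g, data.frame(chrom = "chrQ", start = 5, end = 5), k),
               "start < end")
})

test_that("poisson bounds match term-by-term CDF summation and are monotone", {
  for (lambda in c(0.5, 1, 4, 13, 25)) {
    b <- poisson_bounds(lambda, 0.01, 0.99)
    expect_identical(unname(b["low"]),
                     oracle_poisson_quantile(0.01, lambda))
    expect_identical(unname(b["high"]),
                     oracle_poisson_quantile(0.99, lambda))
  }
  expect_identical(unname(poisson_bounds(4, 1e-12, 0.99)["low"]), 0L)
  grid <- seq(0.5, 40, by = 0.5)
  bounds <- vapply(grid, function(l) poisson_bounds(l), integer(2))
  expect_true(all(diff(bounds[1, ]) >= 0))
  expect_true(all(diff(bounds[2, ]) >= 0))
  expect_error(poisson_bounds(-1), "positive")
  expect_error(poisson_bounds(4, 0.99, 0.01), "p_low")
})

test_that("stability filter keeps in-interval candidates and rejects absent ones", {
  cand <- kmer_set(c("AAAAA", "AACCA", "ACACA", "AGGGA"), 5)
  ctl <- kmer_counts(c("AAAAA", "AACCA", "ACACA"), c(10, 11, 30), 5)
  s <- stable_kmers_for_control(ctl, cand, lambda = 10)
  b <- attr(s, "bounds")
  expect_true(b["low"] >= 1)
  # AGGGA has count 0 -> rejected; ACACA at 30 is far above high
  expect_identical(s$kmer, c("AAAAA", "AACCA"))
  expect_error(stable_kmers_for_control(ctl, kmer_set(character(0), 5)),
               "empty")
})

test_that("a planted homozygous duplication in a control is rejected by the filter", {
  set.seed(24)
  cfg <- sim_config(chrom_lengths = c(chr1 = 9000, chr2 = 8000),
                    sex_chroms = character(0), telomere_length = 0,
                    centromere_length = 0, par_length = 0,
                    repeat_fraction = 0, snp_density = 0, n_controls = 1)
  sim <- simulate_genome(cfg, seed = 301)
  ind <- simulate_individual(sim, NULL, sex = "female", seed = 302,
                             cnv = list(chrom = "chr1", start = 2001,
                                        length = 1000))
  reads <- simulate_reads(list(list(individual = ind, weight = 1)),
                          n_reads = round(30 * 17000 / 50), read_length = 50,
                          error_rate = 0, seed = 303)$reads
  uniq <- filter_nonunique(build_initial_lists(sim$genome, 25))
  cand <- kmer_union(uniq$chr1, uniq$chr2)
  s <- stable_kmers_for_control(reads, cand, k = 25)
  lam <- attr(s, "lambda")
  b <- attr(s, "bounds")
  cnv_kmers <- oracle_windows(substr(sim$genome[["chr1"]], 2001, 3000), 25)
  cnv_kmers <- intersect(cnv_kmers, cand$kmer)
  rej <- mean(!(cnv_kmers %in% s$kmer))
  # doubled copy number: counts ~ Poisson(2*lambda_true); expected rejection
  # evaluated at the filter's own interval, clustered SE (windows within a
  # read are correlated)
  lam_true <- lam / (1 + length(cnv_kmers) / length(cand$kmer))
  p_rej <- 1 - (ppois(b["high"], 2 * lam_true) - ppois(b["low"] - 1, 2 * lam_true))
  se <- sqrt(p_rej * (1 - p_rej) / (length(cnv_kmers) / 26))
  expect_lt(abs(rej - p_rej), 3 * se + 0.02)
  expect_gt(rej, 0.5)
})

test_that("finalize combines stages, errors on empty lists, and shrinks monotonically", {
  set.seed(25)
  k <- 11
  g <- c(chrA = random_dna_str(4000), chrB = random_dna_str(4000))
  uniq <- filter_nonunique(build_initial_lists(g, k))
  poly <- kmer_set(sample(uniq$chrA$kmer, 50), k)
  regs <- kmer_set(sample(uniq$chrB$kmer, 50), k)

  # subtraction stages commute
  f1 <- kmer_subtract(kmer_subtract(uniq$chrA, poly), regs)
  f2 <- kmer_subtract(kmer_subtract(uniq$chrA, regs), poly)
  expect_identical(f1$kmer, f2$kmer)

  expect_error(finalize_lists(uniq, poly, regs, list()), "control")
  expect_message(
    final0 <- finalize_lists(uniq, poly, regs, list(), strict = FALSE),
    "skipped")
  expect_identical(final0$chrA$kmer, f1$kmer)
  expect_false(any(poly$kmer %in% final0$chrA$kmer))
  expect_false(any(regs$kmer %in% final0$chrB$kmer))

  cand <- kmer_union(final0$chrA, final0$chrB)
  stab1 <- kmer_set(sample(cand$kmer, round(0.9 * length(cand$kmer))), k)
  stab2 <- kmer_set(sample(cand$kmer, round(0.9 * length(cand$kmer))), k)
  final1 <- finalize_lists(uniq, poly, regs, list(stab1))
  final12 <- finalize_lists(uniq, poly, regs, list(stab1, stab2))
  # adding a control never grows a list
  expect_true(all(final12$chrA$kmer %in% final1$chrA$kmer))
  expect_true(all(final12$chrB$kmer %in% final1$chrB$kmer))

  empty_stab <- kmer_set(cand$kmer[1], k)  # leaves chrB empty
  expect_error(finalize_lists(uniq, poly, regs, list(empty_stab)), "empty")
})

test_that("built lists are disjoint, unique genome-wide, and carry a manifest", {
  lists <- small_lists()
  sc <- small_scenario()
  members <- lapply(lists$lists, `[[`, "kmer")
  all_members <- unlist(members, use.names = FALSE)
  expect_identical(anyDuplicated(all_members), 0L)  # pairwise disjoint
  expect_identical(unname(lists$L_c), unname(lengths(members)))

  # genome-wide multiplicity exactly 1 (oracle recount)
  k <- lists$k
  tab <- table(unlist(lapply(sc$sim$genome, oracle_windows, k = k)))
  expect_true(all(tab[all_members] == 1))

  expect_identical(lists$control_ids, names(sc$controls))
  expect_match(lists$digest, "^[0-9a-f]{32}$")

  # directory round-trip preserves membership and digest
  d <- tempfile()
  write_chromosome_lists(lists, d)
  back <- read_chromosome_lists(d)
  expect_identical(back$digest, lists$digest)
  expect_identical(back$lists$chr1$kmer, lists$lists$chr1$kmer)
})
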