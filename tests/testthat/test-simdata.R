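micro_cfg <- function(...) {
  sim_config(chrom_lengths = c(chr1 = 6000, chr2 = 5000, chr3 = 4000,
                               chrX = 3000, chrY = 2000),
             telomere_length = 100, centromere_length = 200, par_length = 300,
             repeat_block = 150, sample_depth = 4, control_depth = 15,
             n_controls = 1, n_reference = 12, n_euploid_test = 2,
             n_trisomic_test = 1, trisomy_chrom = "chr3", ...)
}

test_that("generators are fully deterministic under a fixed seed", {
  cfg <- micro_cfg()
  g1 <- simulate_genome(cfg, seed = 501)
  g2 <- simulate_genome(cfg, seed = 501)
  expect_identical(g1$genome, g2$genome)          # byte-identical
  expect_identical(g1$regions, g2$regions)
  expect_identical(g1$repeats, g2$repeats)
  expect_false(identical(g1$genome, simulate_genome(cfg, seed = 502)$genome))

  v1 <- simulate_variants(g1, seed = 503)
  expect_identical(v1, simulate_variants(g1, seed = 503))

  i1 <- simulate_individual(g1, v1, sex = "male", seed = 504)
  expect_identical(i1, simulate_individual(g1, v1, sex = "male", seed = 504))

  r1 <- simulate_reads(list(list(individual = i1, weight = 1)), 500,
                       seed = 505)
  r2 <- simulate_reads(list(list(individual = i1, weight = 1)), 500,
                       seed = 505)
  expect_identical(r1$reads, r2$reads)

  s1 <- simulate_scenario(cfg, seed = 506)
  s2 <- simulate_scenario(cfg, seed = 506)
  expect_identical(s1$plan, s2$plan)
  expect_identical(s1$controls, s2$controls)
})

test_that("planted genome features match their truth records", {
  cfg <- micro_cfg()
  g <- simulate_genome(cfg, seed = 507)
  # every planted duplication occurs at exactly 2 genomic positions
  for (i in seq_len(nrow(g$repeats))) {
    r <- g$repeats[i, ]
    block <- substr(g$genome[[r$chrom_src]], r$start_src,
                    r$start_src + r$length - 1L)
    hits <- sum(vapply(g$genome, function(s) {
      m <- gregexpr(block, s, fixed = TRUE)[[1]]
      if (m[1] == -1) 0L else length(m)
    }, 0L))
    expect_identical(hits, 2L)
  }
  # exclusion regions lie within bounds and the PAR is X/Y-identical
  expect_true(all(g$regions$start < g$regions$end))
  par <- g$regions[g$regions$type == "PAR", ]
  expect_identical(substr(g$genome[["chrX"]], par$start[1] + 1, par$end[1]),
                   substr(g$genome[["chrY"]], par$start[2] + 1, par$end[2]))

  norep <- simulate_genome(micro_cfg(repeat_fraction = 0), seed = 508)
  expect_null(norep$repeats)
})

test_that("individual haplotypes follow the variant model", {
  cfg <- micro_cfg()
  g <- simulate_genome(cfg, seed = 509)
  v <- simulate_variants(g, seed = 510)
  expect_true(all(v$af >= 0 & v$af <= 1))
  expect_true(all(toupper(substring(g$genome[v$chrom], v$pos, v$pos)) == v$ref))

  # MAF 0 -> reference haplotypes; MAF 1 -> always the alternate allele
  v0 <- transform(v, af = 0)
  i0 <- simulate_individual(g, v0, sex = "female", seed = 511)
  expect_identical(i0$haplotypes$chr1[1], g$genome[["chr1"]])
  v1 <- transform(v, af = 1)
  i1 <- simulate_individual(g, v1, sex = "female", seed = 512)
  v1c <- v1[v1$chrom == "chr1", ]
  expect_identical(substring(i1$haplotypes$chr1[1], v1c$pos, v1c$pos), v1c$alt)

  # sex determines the X/Y copy structure
  f <- simulate_individual(g, v, sex = "female", seed = 513)
  m <- simulate_individual(g, v, sex = "male", seed = 514)
  expect_length(f$haplotypes$chrX, 2)
  expect_null(f$haplotypes$chrY)
  expect_length(m$haplotypes$chrX, 1)
  expect_length(m$haplotypes$chrY, 1)

  # pooled genotype frequencies match Hardy-Weinberg within 3 SE
  set.seed(515)
  n_ind <- 150
  het <- 0
  for (s in seq_len(n_ind)) {
    ind <- simulate_individual(g, v, sex = "female", seed = 20000 + s)
    gt <- do.call(cbind, ind$genotypes[setdiff(names(ind$genotypes), "chrY")])
    vv <- do.call(rbind, lapply(setdiff(unique(v$chrom), "chrY"),
                                function(ch) v[v$chrom == ch, ]))
    het <- het + sum(colSums(gt) == 1)
  }
  p_het <- 2 * vv$af * (1 - vv$af)
  expected <- n_ind * sum(p_het)
  se <- sqrt(n_ind * sum(p_het * (1 - p_het)))
  expect_lt(abs(het - expected), 3 * se)
})

test_that("read simulation respects counts, shares and error settings", {
  cfg <- micro_cfg()
  g <- simulate_genome(cfg, seed = 516)
  ind <- simulate_individual(g, NULL, sex = "female", seed = 517)
  rs <- simulate_reads(list(list(individual = ind, weight = 1)), 100,
                       read_length = 50, error_rate = 0, seed = 518)
  expect_length(rs$reads, 100)
  # with no errors every read is an exact substring of a haplotype (either strand)
  ok <- vapply(seq_along(rs$reads), function(i) {
    hs <- ind$haplotypes[[rs$origin$chrom[i]]]
    any(vapply(hs, function(h)
      grepl(rs$reads[i], h, fixed = TRUE) ||
        grepl(oracle_revcomp(rs$reads[i]), h, fixed = TRUE), TRUE))
  }, TRUE)
  expect_true(all(ok))

  # chromosome shares follow copy length within 3 SE (multinomial oracle)
  big <- simulate_reads(list(list(individual = ind, weight = 1)), 20000,
                        read_length = 50, error_rate = 0, seed = 519)
  lens <- vapply(ind$haplotypes, function(h) sum(nchar(h)), 0)
  p <- lens / sum(lens)
  obs <- table(factor(big$origin$chrom, names(p)))
  for (ch in names(p)) {
    se <- sqrt(20000 * p[ch] * (1 - p[ch]))
    expect_lt(abs(obs[[ch]] - 20000 * p[ch]), 3 * se + 1)
  }

  # error injection perturbs roughly error_rate of bases
  err <- simulate_reads(list(list(individual = ind, weight = 1)), 2000,
                        read_length = 50, error_rate = 0.01, seed = 520)
  exact <- vapply(seq_along(err$reads), function(i) {
    hs <- ind$haplotypes[[err$origin$chrom[i]]]
    any(vapply(hs, function(h)
      grepl(err$reads[i], h, fixed = TRUE) ||
        grepl(oracle_revcomp(err$reads[i]), h, fixed = TRUE), TRUE))
  }, TRUE)
  p_clean <- (1 - 0.01)^50
  expect_lt(abs(mean(exact) - p_clean), 3 * sqrt(p_clean * (1 - p_clean) / 2000))

  expect_error(simulate_reads(list(list(individual = ind, weight = 0.5)), 10),
               "sum to 1")
  expect_error(simulate_reads(list(list(individual = ind, weight = 1)), 10,
                              read_length = 5000),
               "read_length")
})

test_that("NIPT mixtures place fetal reads at the fetal fraction", {
  cfg <- micro_cfg()
  g <- simulate_genome(cfg, seed = 521)
  v <- simulate_variants(g, seed = 522)
  mother <- simulate_individual(g, v, sex = "female", seed = 523)
  father <- simulate_individual(g, v, sex = "male", seed = 524)

  pure <- simulate_nipt_sample(mother, father, g, fetal_fraction = 0,
                               seed = 525)
  expect_true(all(pure$origin$source == 1))
  expect_identical(pure$truth$fetal_fraction, 0)

  # n = 100 with a trisomy: affected chromosome's read share elevated ~50%
  tri <- simulate_nipt_sample(mother, father, g, fetal_sex = "female",
                              fetal_fraction = 100, trisomy = "chr3",
                              depth = 8, seed = 526)
  lens <- cfg$chrom_lengths
  n_reads <- length(tri$reads)
  copy_len <- c(2 * lens[c("chr1", "chr2")], 3 * lens["chr3"],
                2 * lens["chrX"])
  p3 <- copy_len[["chr3"]] / sum(copy_len)
  obs3 <- sum(tri$origin$chrom == "chr3")
  expect_lt(abs(obs3 - n_reads * p3), 3 * sqrt(n_reads * p3 * (1 - p3)))
  # ~1.5x the euploid share expectation
  p3_eu <- lens[["chr3"]] / (sum(lens) - lens[["chrY"]])
  expect_gt(obs3 / n_reads, 1.3 * p3_eu)

  # a male fetus contributes Y reads; mother alone cannot
  male <- simulate_nipt_sample(mother, father, g, fetal_sex = "male",
                               fetal_fraction = 30, depth = 6, seed = 527)
  expect_gt(sum(male$origin$chrom == "chrY"), 0)
  expect_false(any(pure$origin$chrom == "chrY"))

  expect_error(simulate_nipt_sample(mother, father, g, fetal_fraction = 150),
               "\\[0, 100\\]")
})

test_that("the mixture-arithmetic shift matches brute-force read simulation", {
  cfg <- micro_cfg(error_rate = 0)
  g <- simulate_genome(cfg, seed = 528)
  mother <- simulate_individual(g, NULL, sex = "female", seed = 529)
  father <- simulate_individual(g, NULL, sex = "male", seed = 530)
  ff <- 40
  smp <- simulate_nipt_sample(mother, father, g, fetal_sex = "female",
                              fetal_fraction = ff, trisomy = "chr3",
                              depth = 40, seed = 531)
  lens <- cfg$chrom_lengths
  # empirical per-unit-length rate ratio of affected vs euploid autosomes
  n_t <- sum(smp$origin$chrom == "chr3") / lens[["chr3"]]
  others <- c("chr1", "chr2")
  n_o <- sum(smp$origin$chrom %in% others) / sum(lens[others])
  got <- n_t / n_o - 1
  want <- expected_sim_shift(cfg, trisomy = "chr3", fetal_fraction = ff,
                             fetal_sex = "female")
  n_reads <- length(smp$reads)
  se <- sqrt(1 / (n_reads * lens[["chr3"]] / sum(lens)) +
               1 / (n_reads * sum(lens[others]) / sum(lens)))
  expect_lt(abs(got - want), 3 * se)
  # in the small-chromosome limit the read-share parametrization
  # approaches 0.5 n / 100 (the fixed-total formula gives 0.5 n / (100 + n))
  wide <- sim_config(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6,
                                       chr4 = 1e6, chr5 = 1e6, chr6 = 1e6,
                                       chr7 = 1e6, chr8 = 1e6, chr9 = 1e6,
                                       chr10 = 2000),
                     sex_chroms = character(0), trisomy_chrom = "chr10")
  expect_equal(expected_sim_shift(wide, fetal_fraction = 10),
               0.5 * 10 / 100, tolerance = 1e-3)
})

test_that("scenario files round-trip through the standard formats", {
  cfg <- micro_cfg()
  sc <- simulate_scenario(cfg, seed = 532)
  d <- tempfile()
  write_scenario(sc, d)
  expect_true(all(file.exists(file.path(d, c("genome.fa", "variants.vcf",
                                             "exclude.bed", "truth.json",
                                             "control01.fastq.gz")))))
  g_back <- as_genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_identical(as.character(g_back), sc$sim$genome)

  v_back <- read_variants(file.path(d, "variants.vcf"))
  expect_identical(v_back$pos, sc$variants$pos)
  expect_equal(v_back$af, sc$variants$af, tolerance = 1e-6)

  r_back <- read_regions(file.path(d, "exclude.bed"))
  expect_identical(r_back$start, as.integer(sc$sim$regions$start))
  expect_identical(r_back$end, as.integer(sc$sim$regions$end))

  reads_back <- count_fastq(file.path(d, "control01.fastq.gz"), 25)
  direct <- count_fastq(sc$controls[[1]], 25)
  expect_identical(reads_back$kmer, direct$kmer)
  expect_equal(reads_back$count, direct$count)
})
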