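#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' emulate the study conditions at toy scale: 50 bp single-end reads with a
#' 0.2% substitution error rate, deep (25x) control individuals, shallow
#' cfDNA samples whose per-chromosome read counts carry comparable
#' information to low-coverage human NIPT sequencing, a 10% fetal fraction,
#' common SNPs at 1 per 500 bp, and a genome of six autosomes plus X and Y
#' carrying planted duplications, low-complexity telomere/centromere
#' regions, and a shared pseudoautosomal block.
#'
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param sex_chroms Names of the X- and Y-like chromosomes.
#' @param k K-mer length.
#' @param repeat_fraction Fraction of the genome covered by planted
#'   duplicated block pairs.
#' @param repeat_block Length of each duplicated block (bp).
#' @param telomere_length,centromere_length,par_length Sizes of the
#'   low-complexity end caps, the mid-chromosome low-complexity region, and
#'   the X/Y-shared pseudoautosomal block (bp).
#' @param snp_density Variants per bp.
#' @param low_maf_fraction Fraction of variants drawn below the 1%
#'   list-filter threshold (the rest are common, MAF 0.01--0.5).
#' @param read_length Single-end read length (bp).
#' @param error_rate Per-base substitution error probability.
#' @param gc_bias_strength Logistic GC acceptance-bias strength (0 = off).
#' @param control_depth,n_controls Sequencing depth and number of control
#'   individuals for list building.
#' @param sample_depth Mean cfDNA sample depth (x); per-sample depths are
#'   drawn from `depth_jitter` times this value.
#' @param depth_jitter Range of the per-sample uniform depth multiplier.
#' @param fetal_fraction Default fetal fraction in percent.
#' @param ff_range Range of fetal fractions (percent) drawn for cohort
#'   reference and euploid test pregnancies.
#' @param trisomy_chrom Chromosome gained in trisomic samples.
#' @param n_reference,n_euploid_test,n_trisomic_test Cohort composition.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 110000, chr2 = 105000,
                                         chr3 = 100000, chr4 = 100000,
                                         chr5 = 95000, chr6 = 90000,
                                         chrX = 60000, chrY = 40000),
                       sex_chroms = c("chrX", "chrY"),
                       k = 25,
                       repeat_fraction = 0.04,
                       repeat_block = 500,
                       telomere_length = 1000,
                       centromere_length = 2000,
                       par_length = 3000,
                       snp_density = 0.002,
                       low_maf_fraction = 0.2,
                       read_length = 50,
                       error_rate = 0.002,
                       gc_bias_strength = 0,
                       control_depth = 25,
                       n_controls = 3,
                       sample_depth = 13,
                       depth_jitter = c(0.6, 1.4),
                       fetal_fraction = 10,
                       ff_range = c(6, 16),
                       trisomy_chrom = "chr6",
                       n_reference = 60,
                       n_euploid_test = 10,
                       n_trisomic_test = 5) {
  cfg <- as.list(environment())
  cfg$chrom_lengths <- unlist(cfg$chrom_lengths)  # tolerate YAML lists
  if (any(cfg$chrom_lengths < cfg$k))
    stop("chromosome lengths must be at least k")
  if (cfg$fetal_fraction < 0 || cfg$fetal_fraction > 100)
    stop("fetal_fraction must be in [0, 100]")
  structure(cfg, class = "sim_config")
}

str_overwrite <- function(s, start, value) {
  paste0(substr(s, 1L, start - 1L), value,
         substr(s, start + nchar(value), nchar(s)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

lowcomplex_dna <- function(n) {
  unit <- paste(sample(c("A", "C", "G", "T"), 2), collapse = "")
  substr(strrep(unit, ceiling(n / 2)), 1, n)
}

intervals_overlap <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2

#' Simulate a toy reference genome
#'
#' Random multi-chromosome genome with planted duplicated blocks (to
#' exercise the uniqueness filter), low-complexity telomere and centromere
#' regions (emitted as exclusion-BED truth), and a pseudoautosomal block
#' shared between the X and Y chromosomes.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return List of class `sim_genome`: `genome` (named character vector),
#'   `regions` (exclusion truth: `chrom`, `start` 0-based, `end`, `type`),
#'   `repeats` (planted duplications: source/destination coordinates,
#'   1-based), `config`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  lens <- config$chrom_lengths
  genome <- vapply(lens, random_dna, "")
  regions <- list()
  occupied <- lapply(lens, function(...) NULL)  # per-chrom matrix of (start,end) 1-based
  mark <- function(chrom, a, b) {
    occupied[[chrom]] <<- rbind(occupied[[chrom]], c(a, b))
  }
  add_region <- function(chrom, a, b, type) {   # 1-based inclusive
    regions[[length(regions) + 1]] <<- data.frame(
      chrom = chrom, start = a - 1L, end = b, type = type,
      stringsAsFactors = FALSE)
    mark(chrom, a, b)
  }
  tl <- config$telomere_length
  cl <- config$centromere_length
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    if (tl > 0) {
      genome[[chrom]] <- str_overwrite(genome[[chrom]], 1L, lowcomplex_dna(tl))
      genome[[chrom]] <- str_overwrite(genome[[chrom]], L - tl + 1L,
                                       lowcomplex_dna(tl))
      add_region(chrom, 1L, tl, "telomere")
      add_region(chrom, L - tl + 1L, L, "telomere")
    }
    if (cl > 0) {
      a <- as.integer(L / 2)
      genome[[chrom]] <- str_overwrite(genome[[chrom]], a, lowcomplex_dna(cl))
      add_region(chrom, a, a + cl - 1L, "centromere")
    }
  }
  sx <- intersect(config$sex_chroms, names(lens))
  if (length(sx) == 2 && config$par_length > 0) {
    a <- tl + 1L
    b <- tl + config$par_length
    genome[[sx[2]]] <- str_overwrite(genome[[sx[2]]], a,
                                     substr(genome[[sx[1]]], a, b))
    add_region(sx[1], a, b, "PAR")
    add_region(sx[2], a, b, "PAR")
  }
  repeats <- NULL
  if (config$repeat_fraction > 0) {
    bl <- config$repeat_block
    n_dup <- max(1L, round(config$repeat_fraction * sum(lens) / (2 * bl)))
    pick_free <- function() {
      for (try in 1:200) {
        chrom <- sample(names(lens), 1, prob = lens)
        a <- sample.int(lens[[chrom]] - bl + 1L, 1)
        occ <- occupied[[chrom]]
        if (is.null(occ) ||
            !any(intervals_overlap(a, a + bl - 1L, occ[, 1], occ[, 2])))
          return(list(chrom = chrom, start = a))
      }
      stop("could not place duplication block; genome too crowded")
    }
    for (i in seq_len(n_dup)) {
      src <- pick_free(); mark(src$chrom, src$start, src$start + bl - 1L)
      dst <- pick_free(); mark(dst$chrom, dst$start, dst$start + bl - 1L)
      genome[[dst$chrom]] <- str_overwrite(
        genome[[dst$chrom]], dst$start,
        substr(genome[[src$chrom]], src$start, src$start + bl - 1L))
      repeats <- rbind(repeats, data.frame(
        chrom_src = src$chrom, start_src = src$start,
        chrom_dst = dst$chrom, start_dst = dst$start, length = bl,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(genome = genome,
                 regions = do.call(rbind, regions),
                 repeats = repeats, config = config, seed = seed),
            class = "sim_genome")
}

#' Simulate a set of known polymorphisms
#'
#' Draws SNV positions uniformly at the configured density; minor allele
#' frequencies are a mixture of common (0.01--0.5) and rare (below the 1%
#' filter threshold) variants.
#'
#' @param sim A `sim_genome`.
#' @param seed Integer seed.
#' @return `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`, `af`.
#' @export
simulate_variants <- function(sim, seed = 2) {
  stopifnot(inherits(sim, "sim_genome"))
  set.seed(seed)
  cfg <- sim$config
  out <- list()
  for (chrom in names(sim$genome)) {
    L <- nchar(sim$genome[[chrom]])
    n <- round(L * cfg$snp_density)
    if (n == 0) next
    pos <- sort(sample.int(L, n))
    ref <- toupper(substring(sim$genome[[chrom]], pos, pos))
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  "")
    rare <- runif(n) < cfg$low_maf_fraction
    af <- ifelse(rare, runif(n, 0.001, 0.01), runif(n, 0.01, 0.5))
    out[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                               alt = unname(alt), af = af,
                               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

apply_alleles <- function(refseq, pos, alt) {
  if (length(pos) == 0) return(refseq)
  v <- strsplit(refseq, "", fixed = TRUE)[[1]]
  v[pos] <- alt
  paste(v, collapse = "")
}

#' Simulate a diploid individual
#'
#' Draws each haplotype's alleles independently as Bernoulli(MAF) per
#' variant (Hardy-Weinberg), producing two haplotype sequences per autosome.
#' Females carry two X haplotypes and no Y; males one X and one Y.  An
#' optional homozygous duplication (`cnv`) appends a copy of a segment to
#' both haplotypes of a chromosome, giving its k-mers twice the expected
#' copy count.
#'
#' @param sim A `sim_genome`.
#' @param variants Variant table from [simulate_variants()] (or `NULL`).
#' @param sex `"female"` or `"male"`.
#' @param seed Integer seed.
#' @param cnv Optional `list(chrom=, start=, length=)` duplication (1-based).
#' @return List of class `sim_individual`: `haplotypes` (named list,
#'   chromosome to character vector of copy sequences), `sex`, `genotypes`
#'   (per chromosome, copies x variants 0/1 matrix), `cnv`.
#' @export
simulate_individual <- function(sim, variants = NULL, sex = "female",
                                seed = 3, cnv = NULL) {
  stopifnot(inherits(sim, "sim_genome"), sex %in% c("female", "male"))
  set.seed(seed)
  sx <- intersect(sim$config$sex_chroms, names(sim$genome))
  x_chrom <- if (length(sx)) sx[1] else NA
  y_chrom <- if (length(sx) > 1) sx[2] else NA
  haplotypes <- list()
  genotypes <- list()
  for (chrom in names(sim$genome)) {
    n_copies <- if (identical(chrom, y_chrom)) {
      if (sex == "male") 1L else 0L
    } else if (identical(chrom, x_chrom)) {
      if (sex == "male") 1L else 2L
    } else 2L
    if (n_copies == 0L) next
    vs <- if (is.null(variants)) NULL
          else variants[variants$chrom == chrom, , drop = FALSE]
    haps <- character(n_copies)
    geno <- matrix(0L, n_copies, if (is.null(vs)) 0 else nrow(vs))
    for (cp in seq_len(n_copies)) {
      if (!is.null(vs) && nrow(vs)) {
        has_alt <- runif(nrow(vs)) < vs$af
        geno[cp, ] <- as.integer(has_alt)
        haps[cp] <- apply_alleles(sim$genome[[chrom]], vs$pos[has_alt],
                                  vs$alt[has_alt])
      } else haps[cp] <- sim$genome[[chrom]]
    }
    haplotypes[[chrom]] <- haps
    genotypes[[chrom]] <- geno
  }
  if (!is.null(cnv)) {
    seg <- substr(sim$genome[[cnv$chrom]], cnv$start,
                  cnv$start + cnv$length - 1L)
    haplotypes[[cnv$chrom]] <- paste0(haplotypes[[cnv$chrom]], seg)
  }
  structure(list(haplotypes = haplotypes, sex = sex, genotypes = genotypes,
                 cnv = cnv),
            class = "sim_individual")
}

revcomp_reads <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  rl <- nchar(reads)
  nerr <- rbinom(length(reads), rl, error_rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(rl[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  reads
}

#' Simulate single-end sequencing reads from a genome mixture
#'
#' Each read picks a source genome by its mixture weight, then a chromosome
#' copy proportional to its length within that source, then a uniform start
#' position and a random strand; per-base substitution errors are applied at
#' `error_rate`.  With `gc_bias_strength > 0` fragments are accepted with
#' logistic probability in their GC content (biased resampling keeps the
#' read count fixed).
#'
#' @param sources List of `list(individual = <sim_individual>, weight = w)`;
#'   weights must be non-negative and sum to 1.
#' @param n_reads Number of reads (typically
#'   `round(depth * genome_length / read_length)`).
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution probability.
#' @param gc_bias_strength Logistic GC-acceptance strength (0 = off).
#' @param seed Integer seed.
#' @return List: `reads` (character vector), `origin` (`data.frame` with
#'   per-read `source` index and `chrom`).
#' @export
simulate_reads <- function(sources, n_reads, read_length = 50,
                           error_rate = 0.002, gc_bias_strength = 0,
                           seed = 4) {
  set.seed(seed)
  w <- vapply(sources, `[[`, 0, "weight")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("mixture weights must be non-negative and sum to 1")
  copies <- do.call(rbind, lapply(seq_along(sources), function(si) {
    ind <- sources[[si]]$individual
    do.call(rbind, lapply(names(ind$haplotypes), function(chrom)
      data.frame(source = si, chrom = chrom,
                 copy = seq_along(ind$haplotypes[[chrom]]),
                 len = nchar(ind$haplotypes[[chrom]]),
                 stringsAsFactors = FALSE)))
  }))
  if (any(copies$len < read_length))
    stop("read_length exceeds the shortest chromosome copy")
  src_total <- tapply(copies$len, copies$source, sum)
  copies$prob <- w[copies$source] * copies$len / src_total[copies$source]

  draw <- function(n) {
    idx <- sample.int(nrow(copies), n, replace = TRUE, prob = copies$prob)
    starts <- floor(runif(n) * (copies$len[idx] - read_length + 1)) + 1L
    reads <- character(n)
    for (g in unique(idx)) {
      sel <- idx == g
      hap <- sources[[copies$source[g]]]$individual$haplotypes[[
        copies$chrom[g]]][copies$copy[g]]
      reads[sel] <- substring(hap, starts[sel],
                              starts[sel] + read_length - 1L)
    }
    minus <- runif(n) < 0.5
    if (any(minus)) reads[minus] <- revcomp_reads(reads[minus])
    list(reads = reads, idx = idx)
  }

  if (gc_bias_strength > 0) {
    acc_reads <- character(0); acc_idx <- integer(0)
    while (length(acc_reads) < n_reads) {
      batch <- draw(max(n_reads, 1000L))
      gc <- vapply(gregexpr("[GCgc]", batch$reads), function(m)
        if (m[1] == -1) 0L else length(m), 0L) / read_length
      keep <- runif(length(gc)) < stats::plogis(gc_bias_strength * (gc - 0.5))
      acc_reads <- c(acc_reads, batch$reads[keep])
      acc_idx <- c(acc_idx, batch$idx[keep])
    }
    reads <- acc_reads[seq_len(n_reads)]
    idx <- acc_idx[seq_len(n_reads)]
  } else {
    b <- draw(n_reads)
    reads <- b$reads
    idx <- b$idx
  }
  reads <- inject_errors(reads, error_rate)
  names(reads) <- sprintf("r%07d", seq_len(n_reads))
  list(reads = reads,
       origin = data.frame(source = copies$source[idx],
                           chrom = copies$chrom[idx],
                           stringsAsFactors = FALSE))
}

make_fetus <- function(mother, father, sim, fetal_sex, trisomy = NULL) {
  cfg <- sim$config
  sx <- intersect(cfg$sex_chroms, names(sim$genome))
  x_chrom <- if (length(sx)) sx[1] else NA
  y_chrom <- if (length(sx) > 1) sx[2] else NA
  haplotypes <- list()
  for (chrom in names(sim$genome)) {
    if (identical(chrom, y_chrom)) {
      if (fetal_sex == "male")
        haplotypes[[chrom]] <- father$haplotypes[[chrom]][1]
      next
    }
    maternal <- sample(mother$haplotypes[[chrom]], 1)
    if (identical(chrom, x_chrom)) {
      haplotypes[[chrom]] <-
        if (fetal_sex == "male") maternal
        else c(maternal, father$haplotypes[[chrom]][1])
    } else {
      paternal <- sample(father$haplotypes[[chrom]], 1)
      haplotypes[[chrom]] <- c(maternal, paternal)
    }
  }
  if (!is.null(trisomy)) {
    if (!trisomy %in% names(haplotypes))
      stop("trisomy chromosome not present in fetus: ", trisomy)
    extra <- sample(haplotypes[[trisomy]], 1)
    haplotypes[[trisomy]] <- c(haplotypes[[trisomy]], extra)
  }
  structure(list(haplotypes = haplotypes, sex = fetal_sex,
                 genotypes = NULL, cnv = NULL),
            class = "sim_individual")
}

#' Simulate a cfDNA NIPT sample
#'
#' Builds a fetus from one maternal haplotype per chromosome plus a paternal
#' haplotype (an extra copy of one chromosome for trisomies; X/Y composition
#' per fetal sex), then draws reads from the maternal genome with weight
#' `(100 - n)/100` and the fetal genome with weight `n/100` — the fetal
#' fraction is the expected share of reads of fetal origin.
#'
#' @param mother,father `sim_individual` objects (mother female; father male
#'   when a Y is needed).
#' @param sim The `sim_genome` both derive from.
#' @param fetal_sex `"female"` or `"male"`.
#' @param fetal_fraction Fetal fraction in percent (0--100).
#' @param trisomy Chromosome name gained in the fetus, or `NULL`.
#' @param depth Sample sequencing depth (x over the haploid genome).
#' @param seed Integer seed.
#' @return List: `reads`, `origin`, and `truth`
#'   (`fetal_sex`, `trisomy`, `fetal_fraction`, `depth`).
#' @export
simulate_nipt_sample <- function(mother, father, sim, fetal_sex = "female",
                                 fetal_fraction = 10, trisomy = NULL,
                                 depth = NULL, seed = 5) {
  stopifnot(inherits(sim, "sim_genome"))
  cfg <- sim$config
  if (fetal_fraction < 0 || fetal_fraction > 100)
    stop("fetal_fraction must be in [0, 100]")
  if (is.null(depth)) depth <- cfg$sample_depth
  set.seed(seed)
  fetus <- make_fetus(mother, father, sim, fetal_sex, trisomy)
  f <- fetal_fraction / 100
  sources <- if (f == 0) list(list(individual = mother, weight = 1))
             else if (f == 1) list(list(individual = fetus, weight = 1))
             else list(list(individual = mother, weight = 1 - f),
                       list(individual = fetus, weight = f))
  n_reads <- round(depth * sum(cfg$chrom_lengths) / cfg$read_length)
  rs <- simulate_reads(sources, n_reads, cfg$read_length, cfg$error_rate,
                       cfg$gc_bias_strength, seed = seed + 1L)
  list(reads = rs$reads, origin = rs$origin,
       truth = list(fetal_sex = fetal_sex, trisomy = trisomy,
                    fetal_fraction = fetal_fraction, depth = depth))
}

#' Exact expected trisomic coverage shift under the simulator's mixture
#'
#' The simulator fixes the fetal read share at `n`% of the total; the
#' affected chromosome's expected normalized difference `D` relative to the
#' euploid-calibrated prediction follows from the per-chromosome read-rate
#' ratios of the maternal/fetal copy-length mixture.  For an affected
#' chromosome that is a vanishing fraction of the genome this tends to
#' `0.5 n / 100`; the fixed-total-material algebra of [expected_shift()]
#' gives `0.5 n / (100 + n)` instead.  Both parametrizations are discussed
#' in the methods vignette.
#'
#' @param config A [sim_config()].
#' @param trisomy Affected chromosome.
#' @param fetal_fraction Fetal fraction in percent.
#' @param fetal_sex Fetal sex (affects the fetal genome size via X/Y).
#' @return Expected `D` of the affected chromosome.
#' @export
expected_sim_shift <- function(config, trisomy = config$trisomy_chrom,
                               fetal_fraction = config$fetal_fraction,
                               fetal_sex = "female") {
  lens <- config$chrom_lengths
  sx <- intersect(config$sex_chroms, names(lens))
  autosomes <- setdiff(names(lens), sx)
  if (!trisomy %in% autosomes) stop("trisomy must be an autosome")
  f <- fetal_fraction / 100
  A <- sum(lens[autosomes]); X <- if (length(sx)) lens[[sx[1]]] else 0
  Y <- if (length(sx) > 1) lens[[sx[2]]] else 0
  M <- 2 * (A + X)                                   # maternal copy length
  F_eu <- if (fetal_sex == "male") 2 * A + X + Y else 2 * (A + X)
  F_tri <- F_eu + lens[[trisomy]]
  # per-unit-length read rate of a chromosome with `copies` fetal copies;
  # in euploid samples this rate is identical for every autosome, so the
  # regression's prediction for the affected chromosome equals the euploid
  # autosomes' common rate in the same sample.
  rate <- function(copies) (1 - f) * 2 / M + f * copies / F_tri
  rate(3) / rate(2) - 1
}

#' Simulate a complete NIPT scenario
#'
#' Generates the reference genome with its truth records, the variant set,
#' deep-coverage male control individuals for list building, and a cohort
#' plan (reference, euploid test and trisomic test pregnancies with their
#' fetal sexes, fetal fractions and per-sample depths).  Control reads are
#' materialized; cohort sample reads are generated lazily by
#' [simulate_cohort_counts()] to bound memory.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; all derived seeds are deterministic
#'   functions of it.
#' @return List of class `sim_scenario`: `sim` (genome truth), `variants`,
#'   `controls` (list of read vectors), `plan` (per-sample `data.frame`),
#'   `config`, `seed`.
#' @export
simulate_scenario <- function(config = sim_config(), seed = 1) {
  seed <- as.integer(seed)
  sim <- simulate_genome(config, seed = seed)
  variants <- simulate_variants(sim, seed = seed + 1L)
  n_ctl <- config$n_controls
  controls <- lapply(seq_len(n_ctl), function(i) {
    ind <- simulate_individual(sim, variants, sex = "male",
                               seed = seed + 10L + i)
    n_reads <- round(config$control_depth * sum(config$chrom_lengths) /
                       config$read_length)
    simulate_reads(list(list(individual = ind, weight = 1)), n_reads,
                   config$read_length, config$error_rate,
                   config$gc_bias_strength, seed = seed + 40L + i)$reads
  })
  names(controls) <- sprintf("control%02d", seq_len(n_ctl))

  set.seed(seed + 100L)
  n_ref <- config$n_reference
  n_eu <- config$n_euploid_test
  n_tri <- config$n_trisomic_test
  n <- n_ref + n_eu + n_tri
  role <- c(rep("reference", n_ref), rep("euploid_test", n_eu),
            rep("trisomic_test", n_tri))
  # alternate reference sexes so both sex-model strata are well populated
  sex <- character(n)
  sex[role == "reference"] <- rep_len(c("female", "male"), n_ref)
  sex[role != "reference"] <- sample(c("female", "male"), n_eu + n_tri,
                                     replace = TRUE)
  ff <- runif(n, config$ff_range[1], config$ff_range[2])
  ff[role == "trisomic_test"] <- config$fetal_fraction
  depth <- config$sample_depth * runif(n, config$depth_jitter[1],
                                       config$depth_jitter[2])
  plan <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)), role = role, fetal_sex = sex,
    fetal_fraction = ff, depth = depth,
    trisomy = ifelse(role == "trisomic_test", config$trisomy_chrom, NA),
    seed = seed + 1000L + 7L * seq_len(n), stringsAsFactors = FALSE)
  structure(list(sim = sim, variants = variants, controls = controls,
                 plan = plan, config = config, seed = seed),
            class = "sim_scenario")
}

#' Generate and count every cohort sample of a scenario
#'
#' For each planned sample: simulate fresh parents, draw the cfDNA read
#' mixture, count it against the chromosome k-mer lists, and discard the
#' reads.
#'
#' @param scenario A [simulate_scenario()] result.
#' @param lists `chrom_kmer_lists` built from the scenario's genome.
#' @param mode Counting mode for [count_sample()].
#' @return List of `sample_counts`, named by sample id.
#' @export
simulate_cohort_counts <- function(scenario, lists,
                                   mode = c("occurrences", "distinct")) {
  mode <- match.arg(mode)
  plan <- scenario$plan
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    mother <- simulate_individual(scenario$sim, scenario$variants,
                                  sex = "female", seed = p$seed)
    father <- simulate_individual(scenario$sim, scenario$variants,
                                  sex = "male", seed = p$seed + 1L)
    smp <- simulate_nipt_sample(
      mother, father, scenario$sim, fetal_sex = p$fetal_sex,
      fetal_fraction = p$fetal_fraction,
      trisomy = if (is.na(p$trisomy)) NULL else p$trisomy,
      depth = p$depth, seed = p$seed + 2L)
    out[[i]] <- count_sample(smp$reads, lists, mode = mode,
                             sample_id = p$sample_id)
  }
  names(out) <- plan$sample_id
  out
}

#' Run the full pipeline on a simulated scenario
#'
#' List building, cohort counting, model fitting on the reference samples,
#' and calling of every sample.
#'
#' @param scenario A [simulate_scenario()] result.
#' @param mode Counting mode.
#' @return List: `lists`, `matrix`, `model`, `calls`, `plan`.
#' @export
run_scenario <- function(scenario, mode = "occurrences") {
  cfg <- scenario$config
  regions <- scenario$sim$regions
  if (!is.null(regions)) regions <- regions[, c("chrom", "start", "end")]
  lists <- build_chromosome_lists(
    scenario$sim$genome, variants = scenario$variants,
    regions = regions, controls = scenario$controls, k = cfg$k)
  counts <- simulate_cohort_counts(scenario, lists, mode = mode)
  mat <- build_nipt_matrix(counts, lists)
  plan <- scenario$plan
  ref_ids <- plan$sample_id[plan$role == "reference"]
  fetal_sex <- setNames(plan$fetal_sex, plan$sample_id)
  model <- nipt_model(mat, reference = ref_ids, fetal_sex = fetal_sex,
                      sex_chroms = cfg$sex_chroms)
  calls <- predict(model, mat)
  list(lists = lists, matrix = mat, model = model, calls = calls,
       plan = plan)
}

#' Write scenario inputs to disk
#'
#' Emits the FASTA reference, VCF variants, exclusion BED, gzipped control
#' FASTQs and a truth JSON for a scenario, as a CLI-runnable input set.
#'
#' @param scenario A [simulate_scenario()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(scenario$sim$genome, file.path(dir, "genome.fa"))
  write_sim_vcf(scenario$variants, scenario$sim,
                file.path(dir, "variants.vcf"))
  write_bed(scenario$sim$regions, file.path(dir, "exclude.bed"))
  for (id in names(scenario$controls))
    write_fastq(scenario$controls[[id]],
                file.path(dir, paste0(id, ".fastq.gz")))
  truth <- list(seed = scenario$seed, plan = scenario$plan,
                repeats = scenario$sim$repeats,
                regions = scenario$sim$regions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write sequences / reads / intervals in standard formats
#'
#' @param genome Named character vector of sequences.
#' @param path Output path (FASTA; gzip if ending in `.gz`).
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, compress = endsWith(path, ".gz"))
  invisible(path)
}

#' @rdname write_fasta
#' @param reads Named character vector of reads (constant quality written).
#' @export
write_fastq <- function(reads, path) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("r%07d", seq_along(reads))
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, compress = endsWith(path, ".gz"),
                              format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fasta
#' @param regions `data.frame` with `chrom`, `start` (0-based), `end`.
#' @export
write_bed <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fasta
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`, `af`).
#' @param sim The `sim_genome` (for contig headers).
#' @export
write_sim_vcf <- function(variants, sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(sim$genome),
            nchar(sim$genome)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (!is.null(variants) && nrow(variants))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s",
                       variants$chrom, variants$pos, variants$ref,
                       variants$alt,
                       format(variants$af, scientific = FALSE, trim = TRUE)),
               con)
  invisible(path)
}
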