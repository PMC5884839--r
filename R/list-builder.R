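#' @title Building filtered per-chromosome k-mer lists
#' @description Stage functions implementing the multi-stage construction of
#'   the final per-chromosome unique k-mer lists: per-chromosome enumeration,
#'   genome-wide uniqueness, polymorphism expansion and subtraction, region
#'   exclusion, and the Poisson population-stability filter over deep-coverage
#'   control individuals.
#' @name list_builder
NULL

# Accept a genome as a named character vector, DNAStringSet, or FASTA path.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- as.character(genome)
    names(genome) <- nm
  }
  if (!is.character(genome) ||
      (length(genome) && (is.null(names(genome)) ||
                          any(!nzchar(names(genome))))))
    stop("genome must be a named character vector, DNAStringSet or FASTA path")
  genome
}

#' Read variants from a VCF file
#'
#' Parses a VCF into the variant table used by [polymorphic_kmers()].  The
#' minor/alternate allele frequency is read from an INFO field (default
#' `AF`); multi-allelic records are expanded to one row per alternate allele.
#' Records lacking the frequency field get `NA`, which downstream is treated
#' as above any threshold (conservative exclusion).
#'
#' @param path VCF file (plain or gzip).
#' @param af_key INFO key holding the allele frequency.
#' @return `data.frame` with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `af`, sorted by chromosome and position.
#' @export
read_variants <- function(path, af_key = "AF") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- vcfR::extract.info(v, element = af_key)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    af = af, stringsAsFactors = FALSE)
  # expand multi-allelic rows
  alts <- strsplit(out$alt, ",", fixed = TRUE)
  afs <- strsplit(ifelse(is.na(out$af), "", out$af), ",", fixed = TRUE)
  n <- lengths(alts)
  idx <- rep(seq_len(nrow(out)), n)
  within_idx <- sequence(n)
  af_num <- mapply(function(a, j) {
    if (length(a) >= j) suppressWarnings(as.numeric(a[j])) else NA_real_
  }, afs[idx], within_idx)
  out <- data.frame(chrom = out$chrom[idx], pos = out$pos[idx],
                    ref = out$ref[idx], alt = unlist(alts),
                    af = as.numeric(af_num), stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Read exclusion regions from a BED file
#'
#' @param path BED file (0-based half-open intervals).
#' @return `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive).
#' @export
read_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Per-chromosome raw k-mer count lists of a genome
#'
#' @param genome Named character vector of chromosome sequences,
#'   `DNAStringSet`, or FASTA path.
#' @param k K-mer length.
#' @return Named list of [kmer_counts], one per chromosome.
#' @export
build_initial_lists <- function(genome, k = 25) {
  genome <- as_genome(genome)
  if (length(genome) == 0) stop("empty genome")
  lists <- lapply(names(genome), function(chrom)
    enumerate_kmers(genome[[chrom]], k, source = chrom))
  names(lists) <- names(genome)
  lists
}

#' Keep only genome-wide unique k-mers
#'
#' A k-mer survives on chromosome `c` iff its total canonical count summed
#' over the whole genome is exactly 1.  A k-mer occurring once each on two
#' chromosomes is removed from both.
#'
#' @param lists Named list of per-chromosome [kmer_counts] sharing `k`.
#' @return Named list of [kmer_set] objects.
#' @export
filter_nonunique <- function(lists) {
  ks <- vapply(lists, `[[`, 0L, "k")
  if (length(unique(ks)) > 1) stop("k mismatch across chromosome lists")
  all_kmers <- unlist(lapply(lists, `[[`, "kmer"), use.names = FALSE)
  all_counts <- unlist(lapply(lists, `[[`, "count"), use.names = FALSE)
  u <- sort(unique(all_kmers), method = "radix")
  tot <- as.vector(rowsum(all_counts, match(all_kmers, u)))
  unique_set <- u[tot == 1]
  lapply(lists, function(x)
    kmer_set(x$kmer[x$kmer %in% unique_set], x$k))
}

check_variants <- function(genome, variants) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns chrom, pos, ref, alt (and optionally af)")
  bad <- !(variants$chrom %in% names(genome))
  if (any(bad))
    stop("variant on unknown chromosome: ", variants$chrom[which(bad)[1]], ":",
         variants$pos[which(bad)[1]])
  for (i in seq_len(nrow(variants))) {
    ref <- toupper(variants$ref[i])
    obs <- toupper(substr(genome[[variants$chrom[i]]], variants$pos[i],
                          variants$pos[i] + nchar(ref) - 1L))
    if (obs != ref)
      stop(sprintf("variant %s:%d ref allele '%s' does not match genome '%s'",
                   variants$chrom[i], variants$pos[i], variants$ref[i], obs))
  }
  invisible(TRUE)
}

# All haplotype sequences of a reference slice [a, b] (1-based inclusive)
# with every allele combination of `vars` substituted; NULL if combinations
# exceed `cap`.
haplotype_sequences <- function(refseq, a, b, vars, cap) {
  alleles <- lapply(seq_len(nrow(vars)), function(i)
    c(vars$ref[i], vars$alt[i]))
  n_comb <- prod(lengths(alleles))
  if (n_comb > cap) return(NULL)
  base <- substr(refseq, a, b)
  combos <- expand.grid(alleles, stringsAsFactors = FALSE)
  vapply(seq_len(nrow(combos)), function(ci) {
    pieces <- character(0)
    cursor <- a
    for (i in seq_len(nrow(vars))) {
      p <- vars$pos[i]
      pieces <- c(pieces, substr(refseq, cursor, p - 1L),
                  as.character(combos[ci, i]))
      cursor <- p + nchar(vars$ref[i])
    }
    paste0(paste(pieces, collapse = ""), substr(refseq, cursor, b))
  }, "")
}

#' K-mers affected by known polymorphisms
#'
#' For every variant at or above the frequency threshold, all canonical
#' k-mers of every haplotype sequence over the window `pos +/- (k-1)`
#' (extended to preserve `k-1` flanks around indels) are collected, covering
#' the reference and each alternate allele of every qualifying variant inside
#' the window.  If the allele combinations in a window exceed
#' `max_haplotypes`, all reference k-mers overlapping the window are returned
#' instead (conservative: biases toward exclusion).  Variants with missing
#' frequency are treated as above the threshold.
#'
#' @param genome Genome as in [build_initial_lists()].
#' @param variants `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   and optionally `af`; see [read_variants()].
#' @param k K-mer length.
#' @param maf_min Minimum allele frequency for a variant to count
#'   (default 0.01).
#' @param max_haplotypes Combination cap per window (default 4096).
#' @return A [kmer_set] of k-mers to exclude from every chromosome list.
#' @export
polymorphic_kmers <- function(genome, variants, k = 25, maf_min = 0.01,
                              max_haplotypes = 4096) {
  genome <- as_genome(genome)
  if (is.null(variants) || nrow(variants) == 0) return(kmer_set(character(), k))
  if (is.null(variants$af)) variants$af <- NA_real_
  keep <- is.na(variants$af) | variants$af >= maf_min
  variants <- variants[keep, , drop = FALSE]
  if (nrow(variants) == 0) return(kmer_set(character(), k))
  check_variants(genome, variants)
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  out <- character(0)
  for (chrom in unique(variants$chrom)) {
    vs <- variants[variants$chrom == chrom, , drop = FALSE]
    refseq <- genome[[chrom]]
    L <- nchar(refseq)
    for (i in seq_len(nrow(vs))) {
      del_slack <- sum(pmax(nchar(vs$ref) - nchar(vs$alt), 0))
      a <- max(1L, vs$pos[i] - (k - 1L) - del_slack)
      b <- min(L, vs$pos[i] + nchar(vs$ref[i]) - 1L + (k - 1L) + del_slack)
      inside <- vs$pos >= a & (vs$pos + nchar(vs$ref) - 1L) <= b
      haps <- haplotype_sequences(refseq, a, b, vs[inside, , drop = FALSE],
                                  max_haplotypes)
      kmers <- if (is.null(haps)) enumerate_kmers(substr(refseq, a, b), k)$kmer
               else enumerate_kmers(haps, k)$kmer
      out <- c(out, kmers)
    }
  }
  kmer_set(out, k)
}

#' K-mers overlapping excluded regions
#'
#' Returns every canonical k-mer whose window overlaps an exclusion region by
#' at least one base (low-complexity repeats, telomeres/centromeres,
#' pseudoautosomal regions, ...).
#'
#' @param genome Genome as in [build_initial_lists()].
#' @param regions `data.frame` with `chrom`, `start` (0-based), `end`
#'   (exclusive); see [read_regions()].
#' @param k K-mer length.
#' @return A [kmer_set].
#' @export
region_kmers <- function(genome, regions, k = 25) {
  genome <- as_genome(genome)
  if (is.null(regions) || nrow(regions) == 0) return(kmer_set(character(), k))
  bad <- !(regions$chrom %in% names(genome))
  if (any(bad))
    stop("region on unknown chromosome: ", regions$chrom[which(bad)[1]])
  if (any(regions$start >= regions$end))
    stop("regions must satisfy start < end (0-based half-open)")
  out <- character(0)
  for (i in seq_len(nrow(regions))) {
    refseq <- genome[[regions$chrom[i]]]
    a <- max(1L, regions$start[i] - k + 2L)      # 1-based slice bounds
    b <- min(nchar(refseq), regions$end[i] + k - 1L)
    out <- c(out, enumerate_kmers(substr(refseq, a, b), k)$kmer)
  }
  kmer_set(out, k)
}

#' Poisson count cut-offs for the stability filter
#'
#' The observed copy count of a genome-wide unique k-mer in a deep-coverage
#' control is approximated as Poisson with the sequencing coverage as mean.
#' The bounds are the smallest integers whose cumulative probability reaches
#' `p_low` and `p_high`.
#'
#' @param lambda Positive Poisson mean (per-k-mer expected count).
#' @param p_low,p_high Probability cut-offs, `0 < p_low < p_high < 1`
#'   (defaults 0.01 and 0.99).
#' @return Integer vector `c(low, high)`; the acceptance interval is
#'   inclusive at both ends.
#' @export
poisson_bounds <- function(lambda, p_low = 0.01, p_high = 0.99) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  if (!(p_low > 0 && p_low < p_high && p_high < 1))
    stop("need 0 < p_low < p_high < 1")
  c(low = as.integer(qpois(p_low, lambda)),
    high = as.integer(qpois(p_high, lambda)))
}

#' Stable k-mers of one control individual
#'
#' Members of the candidate set whose count in the control's reads falls
#' inside the Poisson acceptance interval.  K-mers absent, depleted (e.g. not
#' present in exactly two copies in that genome) or enriched (duplications,
#' sequencing bias) are rejected.
#'
#' @param control A [kmer_counts] object (full raw k-mer list of the
#'   control), a FASTQ path, or a character vector of reads.
#' @param candidate A [kmer_set] of genome-wide unique candidate k-mers.
#' @param p_low,p_high Probability cut-offs (defaults 0.01 / 0.99).
#' @param lambda Poisson mean; if `NULL` (default), estimated as the mean
#'   count of candidate k-mers present (count >= 1) in this control, which is
#'   nearly unbiased at the deep coverage (20-30x) expected of controls.
#' @param k K-mer length; required when `control` is reads.
#' @return A [kmer_set] with attributes `lambda` and `bounds`.
#' @export
stable_kmers_for_control <- function(control, candidate, p_low = 0.01,
                                     p_high = 0.99, lambda = NULL, k = NULL) {
  stopifnot(inherits(candidate, "kmer_set"))
  if (length(candidate$kmer) == 0) stop("candidate k-mer set is empty")
  if (inherits(control, "kmer_counts")) {
    check_same_k(control, candidate)
    counts <- control$count[match(candidate$kmer, control$kmer)]
    counts[is.na(counts)] <- 0
  } else {
    if (is.null(k)) k <- candidate$k
    if (k != candidate$k) stop("k mismatch: ", k, " vs ", candidate$k)
    counts <- cpp_count_in_set(as_reads(control), candidate$kmer, k)
  }
  if (is.null(lambda)) {
    present <- counts >= 1
    if (!any(present)) stop("no candidate k-mer observed in control")
    lambda <- mean(counts[present])
  }
  b <- poisson_bounds(lambda, p_low, p_high)
  out <- kmer_set(candidate$kmer[counts >= b["low"] & counts <= b["high"]],
                  candidate$k)
  attr(out, "lambda") <- lambda
  attr(out, "bounds") <- b
  out
}

kmer_set_intersect <- function(a, b) {
  check_same_k(a, b)
  kmer_set(a$kmer[a$kmer %in% kmer_members(b)], a$k)
}

#' Combine filter stages into final per-chromosome lists
#'
#' `final(c) = (unique(c) \ polymorphic \ regions)` intersected with every
#' control's stable set.  Polymorphic and region k-mers are subtracted
#' genome-wide (an alternate-allele k-mer may coincide with reference
#' sequence on any chromosome).  The subtraction stages commute.
#'
#' @param unique_lists Named list of per-chromosome [kmer_set] objects from
#'   [filter_nonunique()].
#' @param polymorphic,regions [kmer_set] objects to subtract (may be empty).
#' @param stable List of per-control [kmer_set] objects; may be empty only
#'   when `strict = FALSE` (the stability stage is then skipped with a
#'   message).
#' @param strict Require at least one control (default `TRUE`).
#' @return Named list of per-chromosome [kmer_set] objects; errors if any
#'   final list is empty (toy genome too small or filters too strict).
#' @export
finalize_lists <- function(unique_lists, polymorphic = NULL, regions = NULL,
                           stable = list(), strict = TRUE) {
  if (length(stable) == 0) {
    if (strict)
      stop("at least one control individual is required (strict = TRUE)")
    message("no control individuals: Poisson stability stage skipped")
  }
  final <- lapply(unique_lists, function(x) {
    if (!is.null(polymorphic)) x <- kmer_subtract(x, polymorphic)
    if (!is.null(regions)) x <- kmer_subtract(x, regions)
    for (s in stable) x <- kmer_set_intersect(x, s)
    x
  })
  sizes <- vapply(final, function(x) length(x$kmer), 0L)
  if (any(sizes == 0))
    stop("final k-mer list empty for chromosome(s): ",
         paste(names(sizes)[sizes == 0], collapse = ", "),
         " (genome too small or filters too strict)")
  final
}

#' Build final filtered per-chromosome k-mer lists
#'
#' Runs the complete list-construction stage: per-chromosome enumeration,
#' genome-wide uniqueness filtering, subtraction of polymorphic and
#' excluded-region k-mers, and intersection with the Poisson-stable k-mer set
#' of each control individual.
#'
#' @param genome Named character vector, `DNAStringSet`, or FASTA path.
#' @param variants Variant table (see [read_variants()]), VCF path, or `NULL`.
#' @param regions Region table (see [read_regions()]), BED path, or `NULL`.
#' @param controls List of controls (FASTQ paths, read vectors, or
#'   [kmer_counts]); names become control ids.
#' @param k K-mer length (default 25).
#' @param p_low,p_high Poisson probability cut-offs (defaults 0.01 / 0.99).
#' @param maf_min Allele-frequency threshold for polymorphism exclusion
#'   (default 0.01).
#' @param max_haplotypes Haplotype-combination cap (default 4096).
#' @param lambda Optional fixed Poisson mean for every control; estimated per
#'   control from its counts when `NULL`.
#' @param strict Require at least one control (default `TRUE`).
#' @return An object of class `chrom_kmer_lists`: fields `k`, `lists` (named
#'   per-chromosome [kmer_set]s), `L_c` (list sizes), `params`,
#'   `control_ids`, `digest` (content hash tying downstream matrices to
#'   these lists).
#' @export
build_chromosome_lists <- function(genome, variants = NULL, regions = NULL,
                                   controls = list(), k = 25, p_low = 0.01,
                                   p_high = 0.99, maf_min = 0.01,
                                   max_haplotypes = 4096, lambda = NULL,
                                   strict = TRUE) {
  genome <- as_genome(genome)
  if (is.character(variants) && length(variants) == 1L)
    variants <- read_variants(variants)
  if (is.character(regions) && length(regions) == 1L)
    regions <- read_regions(regions)
  initial <- build_initial_lists(genome, k)
  uniq <- filter_nonunique(initial)
  poly <- polymorphic_kmers(genome, variants, k, maf_min, max_haplotypes)
  regk <- region_kmers(genome, regions, k)
  pre <- lapply(uniq, function(x)
    kmer_subtract(kmer_subtract(x, poly), regk))
  candidate <- kmer_set(unlist(lapply(pre, `[[`, "kmer"), use.names = FALSE), k)
  if (is.null(names(controls)) && length(controls))
    names(controls) <- sprintf("control%02d", seq_along(controls))
  stable <- lapply(controls, function(ctl)
    stable_kmers_for_control(ctl, candidate, p_low, p_high, lambda, k))
  final <- finalize_lists(uniq, poly, regk, stable, strict = strict)
  res <- structure(
    list(k = as.integer(k), lists = final,
         L_c = vapply(final, function(x) length(x$kmer), 0L),
         params = list(p_low = p_low, p_high = p_high, maf_min = maf_min,
                       max_haplotypes = max_haplotypes,
                       lambda = lapply(stable, attr, "lambda")),
         control_ids = names(controls)),
    class = "chrom_kmer_lists")
  res$digest <- kmer_lists_digest(res)
  res
}

#' @export
print.chrom_kmer_lists <- function(x, ...) {
  cat(sprintf("chrom_kmer_lists: %d chromosomes, k = %d, %d control(s)\n",
              length(x$lists), x$k, length(x$control_ids)))
  print(x$L_c)
  invisible(x)
}

# Content hash of the final lists (k, chromosome names, members), used to tie
# count matrices to the exact lists they were counted against.
kmer_lists_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  writeLines(c(as.character(x$k), names(x$lists),
               unlist(lapply(x$lists, `[[`, "kmer"), use.names = FALSE)), con)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Write per-chromosome lists and manifest to a directory
#'
#' One k-mer list file per chromosome (see [write_kmer_list()]) plus a
#' `manifest.json` recording k, list sizes, filter parameters, control ids
#' and the content digest.
#'
#' @param x A `chrom_kmer_lists` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chromosome_lists <- function(x, dir) {
  stopifnot(inherits(x, "chrom_kmer_lists"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (chrom in names(x$lists)) {
    s <- x$lists[[chrom]]
    write_kmer_list(kmer_counts(s$kmer, rep(1, length(s$kmer)), s$k,
                                source = chrom),
                    file.path(dir, paste0(chrom, ".kmers.gz")))
  }
  manifest <- list(k = x$k, chromosomes = names(x$lists),
                   L_c = as.list(x$L_c), params = x$params,
                   control_ids = x$control_ids, digest = x$digest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read per-chromosome lists written by [write_chromosome_lists()]
#'
#' @param dir Directory containing `manifest.json` and the per-chromosome
#'   list files.
#' @return A `chrom_kmer_lists` object (digest recomputed and checked).
#' @export
read_chromosome_lists <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lists <- lapply(manifest$chromosomes, function(chrom) {
    x <- read_kmer_list(file.path(dir, paste0(chrom, ".kmers.gz")))
    kmer_set(x$kmer, x$k)
  })
  names(lists) <- manifest$chromosomes
  res <- structure(
    list(k = as.integer(manifest$k), lists = lists,
         L_c = vapply(lists, function(x) length(x$kmer), 0L),
         params = manifest$params, control_ids = manifest$control_ids),
    class = "chrom_kmer_lists")
  res$digest <- kmer_lists_digest(res)
  if (!identical(res$digest, manifest$digest))
    warning("list content digest differs from manifest (files modified?)")
  res
}
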