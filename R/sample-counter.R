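#' Count chromosome-specific k-mers in a sample
#'
#' Scans every read window once and tallies hits against the final
#' per-chromosome k-mer lists, yielding the per-chromosome counts `K_sc` and
#' the sample GC content `GC_S`.  In `occurrences` mode (default) every
#' window hit counts, so `K_sc` grows linearly with sequencing depth; in
#' `distinct` mode each list k-mer is counted at most once (saturates with
#' depth).
#'
#' @param reads FASTQ path (plain or gzip) or character vector of read
#'   sequences.
#' @param lists A `chrom_kmer_lists` object (see [build_chromosome_lists()]).
#' @param mode `"occurrences"` or `"distinct"`.
#' @param sample_id Identifier stored on the result.
#' @return An object of class `sample_counts`: fields `sample_id`, `K_sc`
#'   (named per-chromosome counts), `gc` (fraction of called bases that are
#'   G/C), `total_bases`, `total_reads`, `n_windows`, `mode`, `k`, `digest`.
#' @export
count_sample <- function(reads, lists, mode = c("occurrences", "distinct"),
                         sample_id = "sample") {
  stopifnot(inherits(lists, "chrom_kmer_lists"))
  mode <- match.arg(mode)
  seqs <- as_reads(reads)
  if (length(seqs) == 0) stop("no reads supplied for sample '", sample_id, "'")
  keys <- unlist(lapply(lists$lists, `[[`, "kmer"), use.names = FALSE)
  group <- rep(seq_along(lists$lists), times = lists$L_c)
  res <- cpp_count_by_group(seqs, keys, group, length(lists$lists),
                            lists$k, mode == "distinct")
  K_sc <- res$count
  names(K_sc) <- names(lists$lists)
  bs <- cpp_base_stats(seqs)
  structure(
    list(sample_id = sample_id, K_sc = K_sc,
         gc = if (bs[["called"]] > 0) bs[["gc"]] / bs[["called"]] else NA_real_,
         gc_bases = bs[["gc"]], total_bases = bs[["called"]],
         total_reads = length(seqs), n_windows = res$n_windows,
         mode = mode, k = lists$k, digest = lists$digest),
    class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("sample_counts '%s': %s reads, GC %.4f, mode %s\n",
              x$sample_id, format(x$total_reads, big.mark = ","), x$gc,
              x$mode))
  print(x$K_sc)
  invisible(x)
}

#' Assemble the cohort data matrix
#'
#' Stacks per-sample counts into the cohort matrix: one row per sample, one
#' column per chromosome (in list-manifest order) plus the sample GC
#' fraction.  All samples must have been counted against the same lists
#' (checked via the content digest).
#'
#' @param samples List of [count_sample()] results.
#' @param lists The `chrom_kmer_lists` the samples were counted against.
#' @return A `data.frame` of class `nipt_matrix` with columns `sample_id`,
#'   one per chromosome, and `gc`; attributes `L_c`, `k`, `digest`, `mode`.
#' @export
build_nipt_matrix <- function(samples, lists) {
  stopifnot(inherits(lists, "chrom_kmer_lists"), length(samples) > 0)
  chroms <- names(lists$lists)
  rows <- lapply(samples, function(s) {
    stopifnot(inherits(s, "sample_counts"))
    if (!identical(s$digest, lists$digest))
      stop("sample '", s$sample_id,
           "' was counted against different k-mer lists (digest mismatch)")
    c(s$K_sc[chroms], gc = s$gc)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(sample_id = vapply(samples, `[[`, "", "sample_id"), m,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample ids in matrix")
  structure(out, L_c = lists$L_c, k = lists$k, digest = lists$digest,
            mode = samples[[1]]$mode,
            class = c("nipt_matrix", "data.frame"))
}

#' Write / read a cohort data matrix
#'
#' The matrix is a TSV with header `sample_id <chromosomes...> gc`; a
#' companion JSON manifest (`<path>.manifest.json`) stores the per-chromosome
#' list sizes `L_c`, `k`, the counting mode and the list content digest,
#' tying the matrix to the lists it was counted against.  Values round-trip
#' losslessly.
#'
#' @param x A `nipt_matrix`.
#' @param path Output TSV path.
#' @return `path` (write) or the `nipt_matrix` (read).
#' @export
write_nipt_matrix <- function(x, path) {
  stopifnot(inherits(x, "nipt_matrix"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v)
    format(v, digits = 17, scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(k = attr(x, "k"), L_c = as.list(attr(x, "L_c")),
                   digest = attr(x, "digest"), mode = attr(x, "mode"))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nipt_matrix
#' @param manifest Optional explicit manifest path (default
#'   `<path>.manifest.json`).
#' @export
read_nipt_matrix <- function(path, manifest = paste0(path, ".manifest.json")) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  L_c <- unlist(man$L_c)
  structure(df, L_c = L_c, k = man$k, digest = man$digest, mode = man$mode,
            class = c("nipt_matrix", "data.frame"))
}
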