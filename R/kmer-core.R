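#' Canonical form of k-mers
#'
#' A canonical k-mer is the lexicographically smaller of a k-mer and its
#' reverse complement.  Sequencing reads originate from either strand, so all
#' k-mer bookkeeping in this package is strand-collapsed.
#'
#' @param kmers Character vector of k-mers (A/C/G/T, case-insensitive).
#' @param k Expected k-mer length; defaults to the length of the first
#'   element.  Elements of a different length are an error.
#' @return Character vector of canonical k-mers, upper case.
#' @examples
#' canonicalize(c("AAAA", "TTTT"))  # both "AAAA"
#' canonicalize("GTA")              # "GTA" (revcomp "TAC" is larger)
#' @export
canonicalize <- function(kmers, k = nchar(kmers[1])) {
  if (length(kmers) == 0L) return(character())
  k <- as.integer(k)
  if (any(nchar(kmers) != k))
    stop("all k-mers must have length k = ", k)
  out <- cpp_canonicalize(kmers, k)
  if (anyNA(out))
    stop("k-mer contains a non-ACGT character: ",
         kmers[which(is.na(out))[1]])
  out
}

#' Construct a k-mer count list
#'
#' The central container of the package: a mapping from canonical k-mers to
#' positive occurrence counts, with `k` and a source label recorded.
#'
#' @param kmers Character vector of canonical k-mers (all length `k`).
#' @param counts Numeric vector of positive counts, same length.
#' @param k K-mer length.
#' @param source Free-text label of where the counts came from.
#' @param n_windows Total number of A/C/G/T windows scanned (count mass plus
#'   windows of k-mers not retained, if any); defaults to `sum(counts)`.
#' @return An object of class `kmer_counts` with fields `k`, `kmer`
#'   (sorted ascending), `count`, `source`, `n_windows`.
#' @export
kmer_counts <- function(kmers, counts, k, source = "", n_windows = sum(counts)) {
  k <- as.integer(k)
  stopifnot(length(kmers) == length(counts))
  if (length(kmers) && any(counts < 1))
    stop("all counts must be >= 1")
  kmers <- canonicalize(as.character(kmers), k)
  counts <- as.numeric(counts)
  if (anyDuplicated(kmers)) {       # strand-mates collapse onto one key
    u <- sort(unique(kmers), method = "radix")
    counts <- as.vector(rowsum(counts, match(kmers, u)))
    kmers <- u
  } else {
    o <- order(kmers, method = "radix")
    kmers <- kmers[o]
    counts <- counts[o]
  }
  structure(
    list(k = k, kmer = kmers, count = counts,
         source = source, n_windows = n_windows),
    class = "kmer_counts"
  )
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("kmer_counts: %d distinct %d-mers, total count %s%s\n",
              length(x$kmer), x$k, format(sum(x$count), big.mark = ","),
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Construct a k-mer set
#'
#' @param kmers Character vector of canonical k-mers.
#' @param k K-mer length.
#' @return An object of class `kmer_set` with sorted unique members.
#' @export
kmer_set <- function(kmers, k) {
  structure(list(k = as.integer(k),
                 kmer = sort(unique(canonicalize(as.character(kmers),
                                                 as.integer(k))),
                             method = "radix")),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %d distinct %d-mers\n", length(x$kmer), x$k))
  invisible(x)
}

kmer_members <- function(x) {
  if (inherits(x, "kmer_counts") || inherits(x, "kmer_set")) x$kmer
  else as.character(x)
}

kmer_k <- function(x) {
  if (inherits(x, "kmer_counts") || inherits(x, "kmer_set")) x$k
  else if (length(x)) nchar(x[1]) else NA_integer_
}

check_same_k <- function(a, b) {
  ka <- kmer_k(a); kb <- kmer_k(b)
  if (!is.na(ka) && !is.na(kb) && ka != kb)
    stop("k mismatch: ", ka, " vs ", kb)
  invisible(TRUE)
}

#' Enumerate canonical k-mers of a sequence
#'
#' Counts canonical k-mers over every window consisting only of A/C/G/T
#' (case-folded).  Windows overlapping any other symbol (e.g. `N`) are
#' skipped; only the windows covering the offending base are lost, not the
#' whole sequence.
#'
#' @param sequence Character vector of one or more DNA sequences (counts are
#'   aggregated), or a [Biostrings::DNAStringSet].
#' @param k K-mer length (1--31).
#' @param source Label stored on the result.
#' @return A [kmer_counts] object.  Sequences shorter than `k` contribute
#'   nothing.
#' @examples
#' enumerate_kmers("ACGTA", 3)  # ACG x2 (CGT collapses to ACG), GTA x1
#' @export
enumerate_kmers <- function(sequence, k, source = "") {
  if (inherits(sequence, "DNAStringSet") || inherits(sequence, "DNAString"))
    sequence <- as.character(sequence)
  res <- cpp_count_kmers(as.character(sequence), as.integer(k))
  kmer_counts(res$kmer, res$count, k, source = source,
              n_windows = res$n_windows)
}

read_fastq_reads <- function(fastq) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", fastq, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  as.character(reads)
}

# Accept a FASTQ path or an already-materialized character vector of reads.
as_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L) {
    if (file.exists(reads)) return(read_fastq_reads(reads))
    if (grepl("[/\\\\]", reads) || grepl("\\.(fastq|fq)(\\.gz)?$", reads))
      stop("FASTQ file not found: ", reads)
  }
  as.character(reads)
}

#' Count canonical k-mers in sequencing reads
#'
#' Converts the reads of a sample into a canonical k-mer count list and
#' records base statistics for the sample GC content (G+C called bases over
#' all called bases; `N` bases enter neither numerator nor denominator).
#'
#' @param reads Path to a FASTQ file (plain or gzip) or a character vector of
#'   read sequences.
#' @param k K-mer length.
#' @param source Label stored on the result.
#' @return A [kmer_counts] object with attributes `total_bases` (called
#'   bases), `gc_bases`, `gc` (fraction, `NA` if no called bases) and
#'   `n_reads`.
#' @export
count_fastq <- function(reads, k, source = "") {
  seqs <- as_reads(reads)
  out <- enumerate_kmers(seqs, k, source = source)
  bs <- cpp_base_stats(seqs)
  attr(out, "total_bases") <- unname(bs["called"])
  attr(out, "gc_bases") <- unname(bs["gc"])
  attr(out, "gc") <- if (bs["called"] > 0) unname(bs["gc"] / bs["called"]) else NA_real_
  attr(out, "n_reads") <- length(seqs)
  out
}

#' Intersect a k-mer count list with a k-mer set
#'
#' Keeps the entries of `a` whose k-mer is a member of `b`; counts are
#' preserved from `a`.
#'
#' @param a A [kmer_counts] object.
#' @param b A [kmer_set], [kmer_counts], or character vector of k-mers.
#' @return A [kmer_counts] object.
#' @export
kmer_intersect <- function(a, b) {
  stopifnot(inherits(a, "kmer_counts"))
  check_same_k(a, b)
  keep <- a$kmer %in% kmer_members(b)
  kmer_counts(a$kmer[keep], a$count[keep], a$k, source = a$source,
              n_windows = sum(a$count[keep]))
}

#' Subtract one k-mer set from another
#'
#' @param a,b [kmer_set] objects (or [kmer_counts]/character vectors); the
#'   result has the members of `a` not in `b`.
#' @return A [kmer_set] with the k of `a`.
#' @export
kmer_subtract <- function(a, b) {
  check_same_k(a, b)
  ka <- kmer_k(a)
  m <- kmer_members(a)
  kmer_set(m[!(m %in% kmer_members(b))], ka)
}

#' Union of k-mer sets
#'
#' @param ... [kmer_set]/[kmer_counts] objects or character vectors sharing k.
#' @return A [kmer_set].
#' @export
kmer_union <- function(...) {
  xs <- list(...)
  ks <- unlist(lapply(xs, kmer_k))
  ks <- ks[!is.na(ks)]
  if (length(unique(ks)) > 1) stop("k mismatch in union")
  kmer_set(unlist(lapply(xs, kmer_members)), ks[1])
}

list_format_tag <- "#niptkmer-kmerlist"

#' Write a k-mer list file
#'
#' File format: gzip-compressed text with a single header line
#' `#niptkmer-kmerlist<TAB>k=<k><TAB>source=<label>` followed by one
#' `<canonical-kmer><TAB><count>` line per entry, sorted ascending
#' lexicographically.  A pure set is written with count 1.
#'
#' @param x A [kmer_counts] or [kmer_set] object.
#' @param path Output path (written gzip-compressed regardless of extension).
#' @return `path`, invisibly.
#' @export
write_kmer_list <- function(x, path) {
  if (inherits(x, "kmer_set"))
    x <- if (length(x$kmer)) kmer_counts(x$kmer, rep(1, length(x$kmer)), x$k)
         else structure(list(k = x$k, kmer = character(), count = numeric(),
                             source = "", n_windows = 0),
                        class = "kmer_counts")
  stopifnot(inherits(x, "kmer_counts"))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  header <- paste(list_format_tag, paste0("k=", x$k),
                  paste0("source=", x$source), sep = "\t")
  writeLines(c(header, if (length(x$kmer))
    paste(x$kmer, format(x$count, scientific = FALSE, trim = TRUE),
          sep = "\t")), con)
  invisible(path)
}

#' Read a k-mer list file
#'
#' @param path Path written by [write_kmer_list()].
#' @return A [kmer_counts] object.
#' @export
read_kmer_list <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0 || !startsWith(lines[1], list_format_tag))
    stop("not a k-mer list file (missing '", list_format_tag, "' header): ",
         path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  k <- as.integer(sub("^k=", "", hdr[2]))
  source <- sub("^source=", "", hdr[3])
  body <- lines[-1]
  if (!length(body))
    return(kmer_counts(character(), numeric(), k, source = source))
  parts <- strsplit(body, "\t", fixed = TRUE)
  kmer_counts(vapply(parts, `[[`, "", 1L),
              as.numeric(vapply(parts, `[[`, "", 2L)),
              k, source = source)
}
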