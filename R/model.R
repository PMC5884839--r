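#' Per-chromosome relative coverage
#'
#' `C_sc = K_sc / L_c`: the raw chromosome-specific k-mer count of a sample
#' divided by the size of that chromosome's k-mer list, a proxy for the
#' sequencing depth of the chromosome.
#'
#' @param K Non-negative k-mer count(s).
#' @param L Positive list size(s).
#' @return `K / L`.
#' @export
kmer_coverage <- function(K, L) {
  if (any(!is.finite(L)) || any(L <= 0)) stop("list size L must be positive")
  if (any(K < 0)) stop("counts must be non-negative")
  K / L
}

#' Normalized coverage difference
#'
#' `D_sc = (C_sc - C'_sc) / C'_sc`: relative difference between observed and
#' predicted coverage.  The denominator is the predicted coverage.
#'
#' @param C Observed coverage.
#' @param C_pred Predicted coverage (must be positive).
#' @return Relative difference.
#' @export
coverage_diff <- function(C, C_pred) {
  if (any(!is.finite(C_pred)) || any(C_pred <= 0))
    stop("predicted coverage must be positive (sample flagged for QC)")
  (C - C_pred) / C_pred
}

#' Standardize a coverage difference against the reference population
#'
#' `Z_sc = (D_sc - mean(D_ref)) / sd(D_ref)` with the sample (n-1) standard
#' deviation of the reference differences.
#'
#' @param D Normalized difference(s).
#' @param ref_mean,ref_sd Reference mean and standard deviation of `D`.
#' @return Z-score(s).
#' @export
coverage_zscore <- function(D, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0)
    stop("degenerate reference SD; cannot standardize")
  (D - ref_mean) / ref_sd
}

#' Call chromosome gains from z-scores
#'
#' One-sided calling of coverage gains (trisomies): `elevated` iff
#' `Z > cutoff` (strict inequality; a z-score exactly at the cut-off is
#' `normal`).  Losses are never called.
#'
#' @param z Z-score(s).
#' @param cutoff Calling threshold in standard deviations (default 3.5, at
#'   which the one-sided normal tail is about 0.023%).
#' @return Character vector, `"elevated"` or `"normal"`.
#' @export
call_aneuploidy <- function(z, cutoff = 3.5) {
  ifelse(is.finite(z) & z > cutoff, "elevated", "normal")
}

#' Expected relative coverage shift of a trisomic chromosome
#'
#' If `n`% of the cell-free DNA is of fetal origin, a full non-mosaic
#' trisomy changes the relative coverage of the affected chromosome by
#' `(100 + 3/2 n) / (100 + n) - 1`, i.e. `0.5 n / (100 + n)`.
#'
#' @param n Fetal fraction in percent, `0 <= n <= 100`.
#' @return Relative coverage change (fraction; monotone increasing in `n`).
#' @examples
#' expected_shift(10)  # 5/110
#' @export
expected_shift <- function(n) {
  if (any(!is.finite(n)) || any(n < 0 | n > 100))
    stop("fetal fraction n must be in [0, 100]")
  (100 + 1.5 * n) / (100 + n) - 1
}

#' Mahalanobis distance from a reference population
#'
#' `sqrt((x - mu)' S^-1 (x - mu))`.  If the covariance matrix is
#' ill-conditioned it is regularized by a small ridge
#' (`1e-8 * trace(S)/dim` on the diagonal), with a message.
#'
#' @param x Numeric vector or matrix of row vectors.
#' @param center Reference mean vector.
#' @param cov Reference covariance matrix.
#' @return Non-negative distance(s).
#' @export
mahalanobis_distance <- function(x, center, cov) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(center) || !all(dim(cov) == length(center)))
    stop("dimension mismatch between sample vector, center and covariance")
  if (!is.finite(rcond(cov)) || rcond(cov) < 1e-12) {
    message("covariance near-singular: applying ridge regularization")
    cov <- cov + diag(1e-8 * sum(diag(cov)) / ncol(cov), ncol(cov))
  }
  sqrt(stats::mahalanobis(x, center, cov))
}

ols_fit <- function(X, y, what) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular regression for ", what,
         ": add more reference samples or drop predictors")
  beta <- qr.coef(qrX, y)
  names(beta) <- colnames(X)
  beta
}

cov_matrix_of <- function(x) {
  stopifnot(inherits(x, "nipt_matrix") || is.data.frame(x))
  L_c <- attr(x, "L_c")
  chroms <- names(L_c)
  if (is.null(chroms) || !all(chroms %in% names(x)))
    stop("matrix lacks chromosome columns matching its L_c manifest")
  C <- as.matrix(x[, chroms, drop = FALSE])
  C <- sweep(C, 2, L_c[chroms], "/")
  cbind(C, gc = x$gc)
}

#' Fit the per-chromosome coverage regression model
#'
#' Fits, on a declared euploid reference cohort, one ordinary
#' least-squares model per autosome predicting its relative coverage
#' `C_sc = K_sc / L_c` from the coverages of the other autosomes and the
#' sample GC content (`beta = (X'X)^-1 X'y`; no intercept by default), and
#' stores the reference mean and (n-1) standard deviation of the normalized
#' differences `D_sc = (C - C')/C'` for later z-scoring.  When fetal sexes
#' are declared for the reference pregnancies and sex chromosomes are
#' present, four additional sex-stratified models (X|female, X|male,
#' Y|female, Y|male) are fitted with all autosomes plus GC as predictors.
#' Sex chromosomes are never predictors for autosomes.  The reference
#' mean/covariance of `(D_autosomes, GC)` is stored for Mahalanobis quality
#' control.
#'
#' @param x A `nipt_matrix` (see [build_nipt_matrix()]).
#' @param reference Character vector of reference sample ids (euploid by
#'   declaration); a test sample must not be its own reference.  At least
#'   `predictors + 5` reference samples are required per model.
#' @param fetal_sex Optional named character vector (`"female"`/`"male"`)
#'   giving the fetal sex of reference samples; required for sex models.
#' @param sex_chroms Names of the X- and Y-like chromosomes (default
#'   `c("chrX", "chrY")`); entries absent from the matrix are ignored.
#' @param cutoff Default z-score calling cut-off stored with the model
#'   (default 3.5; cohort-specific cut-offs must be determined
#'   experimentally).
#' @param intercept Include an intercept term (default `FALSE`, matching the
#'   no-intercept prediction equation).
#' @return An object of class `nipt_model`.
#' @seealso [predict.nipt_model()]
#' @export
nipt_model <- function(x, reference, fetal_sex = NULL,
                       sex_chroms = c("chrX", "chrY"), cutoff = 3.5,
                       intercept = FALSE) {
  stopifnot(inherits(x, "nipt_matrix"))
  missing_ids <- setdiff(reference, x$sample_id)
  if (length(missing_ids))
    stop("reference ids absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  ref_rows <- match(reference, x$sample_id)
  covm <- cov_matrix_of(x)
  rownames(covm) <- x$sample_id
  chroms <- setdiff(colnames(covm), "gc")
  sex_chroms <- intersect(sex_chroms, chroms)
  autosomes <- setdiff(chroms, sex_chroms)
  if (length(autosomes) < 2)
    stop("need at least two autosomes to fit coverage models")
  R <- covm[ref_rows, , drop = FALSE]

  fit_one <- function(rows, target, predictors, what,
                      require_positive = TRUE) {
    Xp <- R[rows, predictors, drop = FALSE]
    if (intercept) Xp <- cbind(`(Intercept)` = 1, Xp)
    if (length(rows) < ncol(Xp) + 5)
      stop("too few reference samples for ", what, ": need at least ",
           ncol(Xp) + 5, ", got ", length(rows))
    y <- R[rows, target]
    beta <- ols_fit(Xp, y, what)
    pred <- drop(Xp %*% beta)
    res <- list(target = target, predictors = colnames(Xp), beta = beta,
                resid_sd = sd(y - pred))
    if (all(pred > 0)) {
      D <- (y - pred) / pred
      res$d_mean <- mean(D)
      res$d_sd <- sd(D)
      res$D_ref <- D
      res$degenerate <- !is.finite(res$d_sd) || res$d_sd < 1e-10
      if (res$degenerate)
        warning("reference SD of D is degenerate (~0) for ", what,
                "; z-scores unavailable", call. = FALSE)
    } else {
      if (require_positive)
        stop("non-positive predicted coverage for ", what,
             " in the reference cohort; add more reference samples")
      res$d_mean <- NA_real_
      res$d_sd <- NA_real_
      res$D_ref <- rep(NA_real_, length(rows))
      res$degenerate <- TRUE
    }
    res
  }

  targets <- lapply(autosomes, function(t)
    fit_one(seq_len(nrow(R)), t, c(setdiff(autosomes, t), "gc"),
            paste0("chromosome ", t)))
  names(targets) <- autosomes

  sex_models <- NULL
  ref_sex <- NULL
  if (!is.null(fetal_sex) && length(sex_chroms)) {
    ref_sex <- fetal_sex[reference]
    if (anyNA(ref_sex))
      stop("fetal_sex must name every reference sample")
    if (!all(ref_sex %in% c("female", "male")))
      stop("fetal_sex values must be 'female' or 'male'")
    sex_models <- lapply(c(female = "female", male = "male"), function(h) {
      rows <- which(ref_sex == h)
      ms <- lapply(sex_chroms, function(sx)
        suppressWarnings(fit_one(rows, sx, c(autosomes, "gc"),
                                 paste0(sx, "|", h),
                                 require_positive = FALSE)))
      names(ms) <- sex_chroms
      ms
    })
  }

  D_ref <- vapply(targets, `[[`, numeric(nrow(R)), "D_ref")
  qc_ref <- cbind(D_ref, gc = R[, "gc"])
  obj <- structure(
    list(targets = targets, sex_models = sex_models,
         autosomes = autosomes, sex_chroms = sex_chroms,
         chroms = chroms, L_c = attr(x, "L_c"), k = attr(x, "k"),
         digest = attr(x, "digest"), mode = attr(x, "mode"),
         cutoff = cutoff, intercept = intercept,
         reference = x$sample_id[ref_rows], ref_sex = ref_sex,
         D_ref = D_ref, gc_ref = unname(R[, "gc"]),
         qc_center = colMeans(qc_ref), qc_cov = cov(qc_ref),
         coverage_scale = mean(R[, autosomes])),
    class = "nipt_model")
  obj
}

#' @export
print.nipt_model <- function(x, ...) {
  cat(sprintf(
    "nipt_model: %d autosome model(s)%s, %d reference sample(s), cutoff %.2f\n",
    length(x$targets),
    if (!is.null(x$sex_models))
      sprintf(" + 4 sex models (%s)", paste(x$sex_chroms, collapse = "/"))
    else "", length(x$reference), x$cutoff))
  invisible(x)
}

#' @export
summary.nipt_model <- function(object, ...) {
  tab <- data.frame(
    target = names(object$targets),
    n_predictors = vapply(object$targets, function(t) length(t$beta), 0L),
    d_ref_mean = vapply(object$targets, `[[`, 0, "d_mean"),
    d_ref_sd = vapply(object$targets, `[[`, 0, "d_sd"),
    row.names = NULL)
  structure(list(table = tab, n_reference = length(object$reference),
                 cutoff = object$cutoff,
                 has_sex_models = !is.null(object$sex_models)),
            class = "summary.nipt_model")
}

#' @export
print.summary.nipt_model <- function(x, ...) {
  cat(sprintf("Coverage regression model on %d reference samples (cutoff %.2f)\n",
              x$n_reference, x$cutoff))
  print(x$table, digits = 4)
  if (x$has_sex_models) cat("Sex-stratified X/Y models fitted.\n")
  invisible(x)
}

#' @export
coef.nipt_model <- function(object, ...) {
  out <- lapply(object$targets, `[[`, "beta")
  if (!is.null(object$sex_models))
    for (h in names(object$sex_models))
      for (sx in names(object$sex_models[[h]]))
        out[[paste0(sx, "|", h)]] <- object$sex_models[[h]][[sx]]$beta
  out
}

#' @export
residuals.nipt_model <- function(object, ...) object$D_ref

#' Determine fetal sex of samples
#'
#' Scores each sex hypothesis by the squared standardized residuals of the
#' observed X and Y coverages under that hypothesis's models
#' (`z = (C - C') / sd(resid)`); the hypothesis with the smaller
#' `z_X^2 + z_Y^2` wins.  An exact tie is reported as `"ambiguous"` rather
#' than silently resolved.
#'
#' @param object A fitted [nipt_model()] with sex models.
#' @param newdata A `nipt_matrix` (or coverage-compatible data frame).
#' @return `data.frame` with the per-hypothesis z-scores, fit scores and the
#'   chosen `sex`.
#' @export
determine_sex <- function(object, newdata) {
  if (is.null(object$sex_models))
    stop("model has no sex models (fit with fetal_sex declared)")
  covm <- cov_matrix_of(newdata)
  # Residual SDs of clean simulated strata can be ~0 (e.g. Y coverage under
  # the female hypothesis); coverage differences below ~1% of the autosome
  # scale are beneath the method's resolution, so standardization is floored
  # there.  Keeps a handful of stray k-mer hits from dominating the score.
  sd_floor <- 0.01 * object$coverage_scale
  out <- data.frame(sample_id = newdata$sample_id, stringsAsFactors = FALSE)
  scores <- matrix(0, nrow(covm), 2,
                   dimnames = list(NULL, c("female", "male")))
  for (h in c("female", "male")) {
    for (sx in object$sex_chroms) {
      m <- object$sex_models[[h]][[sx]]
      pred <- drop(covm[, setdiff(m$predictors, "(Intercept)"),
                        drop = FALSE] %*%
                     m$beta[setdiff(names(m$beta), "(Intercept)")])
      if (object$intercept) pred <- pred + m$beta["(Intercept)"]
      z <- (covm[, m$target] - pred) / max(m$resid_sd, sd_floor)
      out[[paste0("z_", sub("chr", "", tolower(sx)), "_", h)]] <- z
      scores[, h] <- scores[, h] + z^2
    }
    out[[paste0("score_", h)]] <- scores[, h]
  }
  out$sex <- ifelse(scores[, "female"] == scores[, "male"], "ambiguous",
                    ifelse(scores[, "female"] < scores[, "male"],
                           "female", "male"))
  out
}

#' Call aneuploidies and fetal sex on new samples
#'
#' Applies the fitted coverage models to new samples: predicts each
#' autosome's coverage, forms the normalized difference `D` and z-score `Z`
#' against the reference statistics, calls `elevated` for `Z > cutoff`
#' (one-sided, gains only), determines fetal sex from the four sex models,
#' and computes the Mahalanobis distance of `(D_autosomes, GC)` from the
#' reference population as a quality-control metric.  A sample whose
#' predicted coverage is non-positive is flagged for QC with `NA` scores
#' rather than called.
#'
#' @param object A [nipt_model()].
#' @param newdata A `nipt_matrix` of samples to score.  Must derive from the
#'   same k-mer lists as the training matrix (content digest checked).
#' @param cutoff Calling cut-off; defaults to the model's.
#' @param ... Unused.
#' @return An object of class `nipt_calls` with elements `calls` (one row
#'   per sample per chromosome: `K`, `L`, `C`, `C_pred`, `D`, `Z`, `call`)
#'   and `samples` (per sample: `sex`, per-hypothesis z-scores and fit
#'   scores, Mahalanobis `d_m`, `qc_flag`, `cutoff_used`).
#' @export
predict.nipt_model <- function(object, newdata, cutoff = object$cutoff, ...) {
  stopifnot(inherits(newdata, "nipt_matrix") || is.data.frame(newdata))
  nd_digest <- attr(newdata, "digest")
  if (!is.null(nd_digest) && !is.null(object$digest) &&
      !identical(nd_digest, object$digest))
    stop("newdata was counted against different k-mer lists than the model")
  covm <- cov_matrix_of(newdata)
  missing_cols <- setdiff(c(object$autosomes, "gc"), colnames(covm))
  if (length(missing_cols))
    stop("newdata lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(covm)
  ids <- newdata$sample_id
  L_c <- object$L_c

  sample_sex <- NULL
  if (!is.null(object$sex_models)) sample_sex <- determine_sex(object, newdata)

  call_rows <- list()
  qc_flag <- rep("", n)
  D_auto <- matrix(NA_real_, n, length(object$autosomes),
                   dimnames = list(NULL, object$autosomes))
  for (t in object$autosomes) {
    m <- object$targets[[t]]
    pred <- drop(covm[, setdiff(m$predictors, "(Intercept)"),
                      drop = FALSE] %*%
                   m$beta[setdiff(names(m$beta), "(Intercept)")])
    if (object$intercept) pred <- pred + m$beta["(Intercept)"]
    C <- covm[, t]
    D <- ifelse(pred > 0, (C - pred) / pred, NA_real_)
    bad <- pred <= 0
    if (any(bad))
      qc_flag[bad] <- paste0(qc_flag[bad], "nonpositive_prediction:", t, ";")
    Z <- if (m$degenerate) rep(NA_real_, n) else (D - m$d_mean) / m$d_sd
    D_auto[, t] <- D
    call_rows[[t]] <- data.frame(
      sample_id = ids, chrom = t,
      K = as.numeric(newdata[[t]]), L = unname(L_c[t]),
      C = unname(C), C_pred = unname(pred), D = unname(D), Z = unname(Z),
      call = call_aneuploidy(Z, cutoff), stringsAsFactors = FALSE)
  }

  # sex chromosomes under the chosen hypothesis, where defined
  if (!is.null(sample_sex)) {
    for (sx in object$sex_chroms) {
      pred <- D <- Z <- rep(NA_real_, n)
      for (h in c("female", "male")) {
        rows <- which(sample_sex$sex == h)
        if (!length(rows)) next
        m <- object$sex_models[[h]][[sx]]
        p <- drop(covm[rows, setdiff(m$predictors, "(Intercept)"),
                       drop = FALSE] %*%
                    m$beta[setdiff(names(m$beta), "(Intercept)")])
        if (object$intercept) p <- p + m$beta["(Intercept)"]
        pred[rows] <- p
        ok <- p > 0
        D[rows][ok] <- (covm[rows, sx][ok] - p[ok]) / p[ok]
        if (!m$degenerate) Z[rows] <- (D[rows] - m$d_mean) / m$d_sd
      }
      call_rows[[sx]] <- data.frame(
        sample_id = ids, chrom = sx,
        K = as.numeric(newdata[[sx]]), L = unname(L_c[sx]),
        C = unname(covm[, sx]), C_pred = pred, D = D, Z = Z,
        call = call_aneuploidy(Z, cutoff), stringsAsFactors = FALSE)
    }
  }

  d_m <- rep(NA_real_, n)
  ok <- !apply(D_auto, 1, anyNA)
  if (any(ok))
    d_m[ok] <- mahalanobis_distance(cbind(D_auto, gc = covm[, "gc"])[ok, ,
                                                                     drop = FALSE],
                                    object$qc_center, object$qc_cov)

  samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (!is.null(sample_sex))
    samples <- cbind(samples, sample_sex[, setdiff(names(sample_sex),
                                                   "sample_id"),
                                         drop = FALSE])
  else samples$sex <- NA_character_
  samples$d_m <- d_m
  samples$qc_flag <- qc_flag
  samples$cutoff_used <- cutoff

  calls <- do.call(rbind, call_rows)
  rownames(calls) <- NULL
  structure(list(calls = calls, samples = samples, cutoff = cutoff,
                 digest = object$digest),
            class = "nipt_calls")
}

#' @export
print.nipt_calls <- function(x, ...) {
  el <- x$calls[x$calls$call == "elevated", , drop = FALSE]
  cat(sprintf("nipt_calls: %d sample(s), cutoff %.2f; %d elevated call(s)\n",
              nrow(x$samples), x$cutoff, nrow(el)))
  if (nrow(el)) print(el[, c("sample_id", "chrom", "Z", "call")], digits = 3)
  invisible(x)
}

#' @export
summary.nipt_calls <- function(object, ...) {
  z <- object$calls
  cat(sprintf("Samples: %d  Chromosome calls: %d  Elevated: %d\n",
              nrow(object$samples), nrow(z), sum(z$call == "elevated")))
  cat("Z-score range by chromosome:\n")
  print(do.call(rbind, lapply(split(z$Z, z$chrom), function(v)
    c(min = suppressWarnings(min(v, na.rm = TRUE)),
      max = suppressWarnings(max(v, na.rm = TRUE))))), digits = 3)
  invisible(object)
}

#' @export
plot.nipt_calls <- function(x, ...) {
  z <- x$calls[is.finite(x$calls$Z), , drop = FALSE]
  f <- factor(z$chrom, levels = unique(x$calls$chrom))
  graphics::plot(as.integer(f), z$Z, xaxt = "n", xlab = "chromosome",
                 ylab = "Z score",
                 col = ifelse(z$call == "elevated", "red", "grey40"),
                 pch = 19, ...)
  graphics::axis(1, at = seq_along(levels(f)), labels = levels(f))
  graphics::abline(h = x$cutoff, lty = 2)
  invisible(x)
}

#' Write calls to TSV files
#'
#' Writes the per-sample-per-chromosome table to `path` and the per-sample
#' table (sex, sex-model z-scores, Mahalanobis distance, QC flags) to
#' `<path>.samples.tsv`.
#'
#' @param x A `nipt_calls` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(x, path) {
  stopifnot(inherits(x, "nipt_calls"))
  write.table(x$calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, paste0(path, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a fitted model as JSON
#'
#' Stores coefficients, reference statistics and QC covariance so the model
#' can be reused on new samples without refitting.
#'
#' @param object A `nipt_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `nipt_model` (read).
#' @export
write_nipt_model <- function(object, path) {
  stopifnot(inherits(object, "nipt_model"))
  ser <- unclass(object)
  # jsonlite drops names of atomic vectors; store name-carrying fields as
  # lists / explicit name arrays
  ser$qc_cov <- list(values = as.vector(object$qc_cov),
                     names = colnames(object$qc_cov))
  ser$qc_center <- as.list(object$qc_center)
  ser$L_c <- as.list(object$L_c)
  ser$ref_sex <- if (is.null(object$ref_sex)) NULL else as.list(object$ref_sex)
  ser$D_ref <- NULL  # reconstructed from the per-target residuals
  fit_ser <- function(m) {
    m$beta <- as.list(m$beta)
    m
  }
  ser$targets <- lapply(ser$targets, fit_ser)
  if (!is.null(ser$sex_models))
    ser$sex_models <- lapply(ser$sex_models, function(h) lapply(h, fit_ser))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_nipt_model
#' @export
read_nipt_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- ser$qc_cov$names
  ser$qc_cov <- matrix(ser$qc_cov$values, length(nm), length(nm),
                       dimnames = list(nm, nm))
  ser$qc_center <- unlist(ser$qc_center)
  ser$L_c <- unlist(ser$L_c)
  ser$ref_sex <- if (length(ser$ref_sex)) unlist(ser$ref_sex) else NULL
  fix_fit <- function(m) {
    m$beta <- unlist(m$beta)
    m
  }
  ser$targets <- lapply(ser$targets, fix_fit)
  if (!is.null(ser$sex_models) && length(ser$sex_models))
    ser$sex_models <- lapply(ser$sex_models, function(h) lapply(h, fix_fit))
  else ser$sex_models <- NULL
  ser$D_ref <- vapply(ser$targets, function(t) unlist(t$D_ref),
                      numeric(length(ser$targets[[1]]$D_ref)))
  colnames(ser$D_ref) <- names(ser$targets)
  structure(ser, class = "nipt_model")
}
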