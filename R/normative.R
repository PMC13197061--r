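# ROI-level normative scoring: per-ROI means, the abnormality z-score of a
# subject against its personalized reference set, the age-matched template
# baseline, and SVM cross-validated classification of the score vectors.

#' Per-ROI means of a vertex map
#'
#' Unweighted arithmetic mean of the map within each parcellation region.
#' Empty ROIs (possible with externally supplied parcellations) yield `NaN`.
#'
#' @param map Per-vertex numeric vector (or single-column matrix).
#' @param parcellation A `parcellation`.
#' @return Numeric vector of length `n_rois` (names from the parcellation).
#' @export
roi_means <- function(map, parcellation) {
  map <- as.numeric(map)
  if (length(map) != length(parcellation$labels))
    stop("map length must match the parcellation's vertex count")
  out <- rep(NaN, parcellation$n_rois)
  agg <- rowsum(map, parcellation$labels)
  cnt <- tabulate(parcellation$labels + 1L, nbins = parcellation$n_rois)
  ids <- as.integer(rownames(agg)) + 1L
  out[ids] <- agg[, 1] / cnt[ids]
  names(out) <- parcellation$names
  out
}

#' ROI abnormality z-scores against a reference set
#'
#' For each ROI `i`, computes
#' \eqn{Z_i = (x_i - \mathrm{mean}_j\, x_{i,j}) / \mathrm{std}_j\, x_{i,j}}
#' where \eqn{x_i} is the subject's ROI mean and \eqn{x_{i,j}} the ROI means
#' of the `N` reference maps (generated reconstructions or age-matched
#' template subjects). The std uses the unbiased `N - 1` denominator; set
#' `unbiased = FALSE` for the population form. ROIs whose reference spread is
#' zero get a signed infinite sentinel and are flagged in the `degenerate`
#' attribute.
#'
#' @param subject_map Per-vertex values for the test subject (the scored
#'   channel, cortical thickness by default in the wrappers).
#' @param sample_maps List of `N >= 2` reference per-vertex maps.
#' @param parcellation A `parcellation`.
#' @param unbiased Use the `N - 1` std denominator (default TRUE).
#' @return Numeric vector of z-scores (length `n_rois`), with attributes
#'   `n_reference` and `degenerate` (indices of zero-spread ROIs).
#' @export
abnormal_scores <- function(subject_map, sample_maps, parcellation,
                            unbiased = TRUE) {
  n <- length(sample_maps)
  if (n < 2) stop("at least 2 reference maps are required")
  x <- roi_means(subject_map, parcellation)
  ref <- vapply(sample_maps, roi_means, numeric(parcellation$n_rois),
                parcellation = parcellation)
  dim(ref) <- c(parcellation$n_rois, n)   # keep matrix shape when n_rois = 1
  mu <- rowMeans(ref)
  if (unbiased) {
    sd_ <- apply(ref, 1, stats::sd)
  } else {
    sd_ <- sqrt(rowMeans((ref - mu)^2))
  }
  z <- (x - mu) / sd_
  degen <- unname(which(sd_ == 0))
  if (length(degen) > 0) {
    z[degen] <- sign(x[degen] - mu[degen]) * Inf
    z[degen][x[degen] == mu[degen]] <- 0
  }
  attr(z, "n_reference") <- n
  attr(z, "degenerate") <- degen
  z
}

#' Age-matched template reference set
#'
#' Selects the `k` training subjects whose ages are closest to the test age
#' (ties broken by position in the cohort, i.e. subject-id order).
#'
#' @param train_cohort A `cortex_cohort` or list of `cortex_subject`.
#' @param test_age Age of the test subject in years.
#' @param k Reference-set size (default 10).
#' @return List of `k` `cortex_subject`s.
#' @export
template_reference <- function(train_cohort, test_age, k = 10L) {
  subjects <- if (inherits(train_cohort, "cortex_cohort"))
    train_cohort$subjects else train_cohort
  if (length(subjects) < k)
    stop(sprintf("cohort of %d subjects cannot supply k = %d references",
                 length(subjects), k))
  ages <- vapply(subjects, `[[`, 0, "age")
  ord <- order(abs(ages - test_age))   # stable: ties keep cohort order
  subjects[ord[seq_len(k)]]
}

#' Abnormality score table for a set of subjects
#'
#' Convenience wrapper producing the per-subject, per-ROI z-score table used
#' as classification features. With `reference = "ddpm"` the reference set is
#' the model's `n` pseudo-healthy reconstructions of each subject; with
#' `reference = "template"` it is the `n` age-closest training subjects.
#'
#' @param fit A fitted `surface_ddpm` (required for `reference = "ddpm"`).
#' @param subjects Test subjects (list or `cortex_cohort`).
#' @param parcellation A `parcellation` (defaults to the one stored in `fit`).
#' @param reference `"ddpm"` or `"template"`.
#' @param channel Scored feature channel (default `"ct"`, cortical thickness,
#'   the accepted atrophy biomarker).
#' @param n Reference-set size.
#' @param t_start Noising depth for the reconstructions (default `T/2`).
#' @param train_cohort Training cohort (required for `reference = "template"`).
#' @param seed Integer seed for the reconstructions.
#' @return Object of class `abnormality_table`: data frame with one row per
#'   subject x ROI (`subject_id`, `group`, `roi`, `roi_name`, `z`), plus a
#'   `zmat` attribute (subjects x ROIs matrix).
#' @export
abnormality_scores <- function(fit = NULL, subjects, parcellation = NULL,
                               reference = c("ddpm", "template"),
                               channel = "ct", n = 10L, t_start = NULL,
                               train_cohort = NULL, seed = 1L) {
  reference <- match.arg(reference)
  subjects <- if (inherits(subjects, "cortex_cohort")) subjects$subjects
              else subjects
  if (is.null(parcellation))
    parcellation <- fit$parcellation %||%
      stop("a parcellation is required")
  refs <- switch(reference,
    ddpm = {
      stopifnot(inherits(fit, "surface_ddpm"))
      recon <- predict(fit, subjects, t_start = t_start, n = n, seed = seed)
      lapply(recon, function(per_subj)
        lapply(per_subj, function(m) m[, channel]))
    },
    template = {
      if (is.null(train_cohort))
        stop("'train_cohort' is required for the template reference")
      lapply(subjects, function(s) {
        tmpl <- template_reference(train_cohort, s$age, k = n)
        lapply(tmpl, function(ts) ts$features[, channel])
      })
    })
  zmat <- t(vapply(seq_along(subjects), function(i) {
    as.numeric(abnormal_scores(subjects[[i]]$features[, channel],
                               refs[[i]], parcellation))
  }, numeric(parcellation$n_rois)))
  rownames(zmat) <- vapply(subjects, `[[`, "", "subject_id")
  colnames(zmat) <- parcellation$names
  df <- data.frame(
    subject_id = rep(rownames(zmat), each = parcellation$n_rois),
    group = rep(vapply(subjects, `[[`, "", "group"),
                each = parcellation$n_rois),
    roi = rep(seq_len(parcellation$n_rois) - 1L, times = nrow(zmat)),
    roi_name = rep(parcellation$names, times = nrow(zmat)),
    z = as.vector(t(zmat)),
    stringsAsFactors = FALSE
  )
  structure(df, zmat = zmat, reference = reference, channel = channel,
            n_reference = n, class = c("abnormality_table", "data.frame"))
}

#' @export
print.abnormality_table <- function(x, ...) {
  zmat <- attr(x, "zmat")
  cat(sprintf(
    "Abnormality scores (%s reference, channel %s, N = %d): %d subjects x %d ROIs\n",
    attr(x, "reference"), attr(x, "channel"), attr(x, "n_reference"),
    nrow(zmat), ncol(zmat)))
  cat(sprintf("  mean Z = %.3f, per-subject mean Z range [%.2f, %.2f]\n",
              mean(zmat[is.finite(zmat)]),
              min(rowMeans(zmat)), max(rowMeans(zmat))))
  invisible(x)
}

#' Write an abnormality table as tidy CSV
#' @param x An `abnormality_table`.
#' @param path Output CSV path.
#' @export
write_scores_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Cross-validated classification of abnormality-score vectors
#'
#' Stratified k-fold cross-validation of a maximum-margin (SVM) classifier on
#' per-subject score vectors, reporting fold-averaged accuracy, precision and
#' recall. Features containing non-finite values (degenerate ROIs) are dropped
#' with a message. Deterministic given the seed.
#'
#' @param features Subjects x features numeric matrix (e.g. the `zmat`
#'   attribute of [abnormality_scores()]).
#' @param labels Two-class factor or character vector (e.g. "CN"/"AD"); the
#'   second factor level is treated as the positive class.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost SVM cost parameter.
#' @return List with `accuracy`, `precision`, `recall`, and the per-fold
#'   metric matrix `per_fold`.
#' @export
classification_eval <- function(features, labels, folds = 10L, seed = 1L,
                                kernel = "linear", cost = 1) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes are required")
  keep <- apply(is.finite(features), 2, all)
  if (!all(keep)) {
    message(sprintf("dropping %d degenerate feature column(s)", sum(!keep)))
    features <- features[, keep, drop = FALSE]
  }
  n <- nrow(features)
  fold_id <- with_seed_(seed, {
    id <- integer(n)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  pos <- levels(labels)[2]
  per_fold <- t(vapply(seq_len(folds), function(f) {
    test <- fold_id == f
    if (!any(test) || length(unique(labels[!test])) < 2)
      return(c(accuracy = NA, precision = NA, recall = NA))
    m <- e1071::svm(features[!test, , drop = FALSE], labels[!test],
                    kernel = kernel, cost = cost, scale = FALSE)
    pred <- predict(m, features[test, , drop = FALSE])
    truth <- labels[test]
    tp <- sum(pred == pos & truth == pos)
    c(accuracy = mean(pred == truth),
      precision = if (sum(pred == pos) > 0) tp / sum(pred == pos) else NA,
      recall = if (sum(truth == pos) > 0) tp / sum(truth == pos) else NA)
  }, numeric(3)))
  list(accuracy = mean(per_fold[, "accuracy"], na.rm = TRUE),
       precision = mean(per_fold[, "precision"], na.rm = TRUE),
       recall = mean(per_fold[, "recall"], na.rm = TRUE),
       per_fold = per_fold)
}
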