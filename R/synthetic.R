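# Synthetic cortical cohorts on the icosphere: smooth folding fields, a
# gyral/sulcal mask correlated with the features, linear age and sex effects,
# spatially smooth noise, and localized atrophy injected into designated ROIs
# for disease subjects. The generator gives every pipeline stage a
# download-free input whose ground truth is known exactly.

#' Smooth random field on an icosphere
#'
#' Draws i.i.d. standard normal values per vertex, applies `iterations` rounds
#' of 1-ring mean smoothing (7-tap mean over the canonical ring; the 12
#' pentagons weight their center twice through the pad slot), and
#' re-standardizes to mean 0, sd 1.
#'
#' @param ico An `ico_sphere`.
#' @param iterations Number of smoothing rounds (>= 0).
#' @param seed Optional integer for a deterministic field.
#' @return Numeric vector, one value per vertex, mean 0 and sd 1.
#' @export
smooth_field <- function(ico, iterations = 10L, seed = NULL) {
  run <- function() {
    v <- nrow(ico$vertices)
    z <- rnorm(v)
    tab <- ico$neighbor_table
    for (i in seq_len(iterations)) {
      z <- (z + rowSums(matrix(z[tab], v))) / 7
    }
    as.vector(scale(z))
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}

#' Cohort specification for the synthetic generator
#'
#' Defaults define the desk-scale study conditions: a 162-vertex (order-2)
#' sphere, a 34-region parcellation, gyral/sulcal thickness contrast
#' `gamma = 0.5`, age thinning 0.1 standardized units per decade, sex effect
#' 0.1, smooth noise sd 0.3 and atrophy depth `delta = 0.5` in three
#' designated ROIs (MCI subjects receive `delta/2`).
#'
#' @param n_subjects Cohort size.
#' @param order Icosphere order (2 by default; 4 for slower integration work;
#'   6 matches full-resolution cortical maps).
#' @param age_range Uniform age range in years.
#' @param sex_ratio Proportion of male (coded 1) subjects.
#' @param group_probs Named proportions over `c("CN", "MCI", "AD")`.
#' @param smooth_iters Smoothing rounds for the folding and noise fields.
#' @param gamma Gyral/sulcal thickness contrast (standardized units).
#' @param beta_age Thinning per decade of age (standardized units).
#' @param beta_sex Additive sex effect (standardized units).
#' @param sigma Sd of the smooth per-subject noise field.
#' @param n_rois Parcellation size.
#' @param disease_rois Integer ROI ids (0-based) receiving atrophy.
#' @param delta Atrophy depth for AD (MCI gets `delta/2`).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100L, order = 2L,
                        age_range = c(55, 90), sex_ratio = 0.5,
                        group_probs = c(CN = 1),
                        smooth_iters = 10L, gamma = 0.5, beta_age = 0.1,
                        beta_sex = 0.1, sigma = 0.3, n_rois = 34L,
                        disease_rois = 0:2, delta = 0.5, seed = 1L) {
  stopifnot(delta >= 0, sigma > 0, sex_ratio >= 0, sex_ratio <= 1,
            all(group_probs >= 0), n_subjects >= 1)
  structure(list(
    n_subjects = as.integer(n_subjects), order = as.integer(order),
    age_range = age_range, sex_ratio = sex_ratio,
    group_probs = group_probs / sum(group_probs),
    smooth_iters = as.integer(smooth_iters), gamma = gamma,
    beta_age = beta_age, beta_sex = beta_sex, sigma = sigma,
    n_rois = as.integer(n_rois), disease_rois = as.integer(disease_rois),
    delta = delta, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate one synthetic subject
#'
#' A subject-specific folding field `f` defines the gyral/sulcal mask
#' (`f > 0` = gyral); cortical thickness is
#' `gamma * (2*mask - 1) + beta_sex*sex - beta_age*(age - 60)/10 + sigma*noise`
#' with a fresh smooth noise field, and the shape-index analog is `tanh(f)`
#' plus smooth noise. Disease groups have `delta` (AD) or `delta/2` (MCI)
#' subtracted from thickness inside the designated ROIs. Because every random
#' draw is consumed identically for all groups, subjects generated from the
#' same seed but different groups are exact atrophy-shifted twins.
#'
#' @param ico An `ico_sphere` at `spec$order`.
#' @param spec A `cohort_spec`.
#' @param age,sex,group Demographics (`sex` 0/1; `group` "CN"/"MCI"/"AD").
#' @param parcellation A `parcellation` on `ico` (for the disease ROIs).
#' @param subject_id Identifier string.
#' @param seed Optional integer for a deterministic subject.
#' @return Object of class `cortex_subject`: list with `subject_id`,
#'   `features` (V x 2 matrix, columns `ct`, `si`), `mask` (0/1 vector),
#'   `age`, `sex`, `group`.
#' @export
make_subject <- function(ico, spec, age, sex, group = "CN", parcellation,
                         subject_id = "subj", seed = NULL) {
  run <- function() {
    f <- smooth_field(ico, spec$smooth_iters)
    noise_ct <- smooth_field(ico, spec$smooth_iters)
    noise_si <- smooth_field(ico, spec$smooth_iters)
    mask <- as.integer(f > 0)
    ct <- spec$gamma * (2 * mask - 1) + spec$beta_sex * sex -
      spec$beta_age * (age - 60) / 10 + spec$sigma * noise_ct
    si <- tanh(f) + spec$sigma * noise_si
    shift <- switch(group, CN = 0, MCI = spec$delta / 2, AD = spec$delta,
                    stop("unknown group: ", group))
    if (shift > 0) {
      hit <- parcellation$labels %in% spec$disease_rois
      ct[hit] <- ct[hit] - shift
    }
    features <- cbind(ct = ct, si = si)
    structure(list(subject_id = subject_id, features = features,
                   mask = mask, age = age, sex = sex, group = group),
              class = "cortex_subject")
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}

#' Generate a synthetic cohort
#'
#' Ages are uniform on the spec's range, sexes Bernoulli by the sex ratio and
#' groups assigned by the spec's proportions (largest-remainder rounding, so
#' counts match the proportions within rounding). The whole cohort, including
#' its parcellation, is a deterministic function of `spec$seed`.
#'
#' @param spec A `cohort_spec`.
#' @param ico Optional pre-built `ico_sphere` (built from the spec otherwise).
#' @param parcellation Optional pre-built `parcellation` (shared across
#'   cohorts drawn at the same order so train/test subjects agree on ROIs).
#' @param id_prefix Prefix for subject identifiers.
#' @return Object of class `cortex_cohort`: list with `subjects`, `manifest`
#'   (data frame: subject_id, age, sex, group), `ico`, `parcellation`, `spec`.
#' @export
make_cohort <- function(spec, ico = NULL, parcellation = NULL,
                        id_prefix = "S") {
  if (is.null(ico)) ico <- ico_sphere(spec$order)
  if (is.null(parcellation))
    parcellation <- make_parcellation(ico, spec$n_rois, seed = spec$seed)
  n <- spec$n_subjects
  groups <- largest_remainder_groups(spec$group_probs, n)
  subjects <- with_seed_(spec$seed, {
    ages <- runif(n, spec$age_range[1], spec$age_range[2])
    sexes <- as.integer(runif(n) < spec$sex_ratio)
    lapply(seq_len(n), function(i) {
      make_subject(ico, spec, ages[i], sexes[i], groups[i], parcellation,
                   subject_id = sprintf("%s%04d", id_prefix, i))
    })
  })
  manifest <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    age = vapply(subjects, `[[`, 0, "age"),
    sex = vapply(subjects, `[[`, 0L, "sex"),
    group = groups,
    stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, manifest = manifest, ico = ico,
                 parcellation = parcellation, spec = spec),
            class = "cortex_cohort")
}

largest_remainder_groups <- function(probs, n) {
  raw <- probs * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(probs), counts)
}

#' @export
print.cortex_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("Synthetic cortical cohort: %d subjects on an order-%d sphere (%s)\n",
              nrow(x$manifest), x$spec$order,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cortex_cohort <- function(object, ...) {
  m <- object$manifest
  cat(sprintf("Cohort of %d subjects, order %d (%d vertices), %d ROIs\n",
              nrow(m), object$spec$order, nrow(object$ico$vertices),
              object$parcellation$n_rois))
  cat(sprintf("  age: %.1f-%.1f (mean %.1f); %.0f%% male\n",
              min(m$age), max(m$age), mean(m$age), 100 * mean(m$sex)))
  print(table(m$group))
  invisible(object)
}

#' @export
print.cortex_subject <- function(x, ...) {
  cat(sprintf("Subject %s: %s, age %.1f, sex %d, %d vertices\n",
              x$subject_id, x$group, x$age, x$sex, nrow(x$features)))
  invisible(x)
}
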