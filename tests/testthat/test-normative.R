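toy_parc <- function(labels, n_rois = max(labels) + 1L) {
  structure(list(labels = as.integer(labels), n_rois = as.integer(n_rois),
                 names = sprintf("roi_%02d", seq_len(n_rois) - 1L)),
            class = "parcellation")
}

test_that("roi_means averages within regions and flags empty ROIs", {
  p <- toy_parc(c(0, 0, 1))
  expect_equal(unname(roi_means(c(1, 3, 5), p)), c(2, 5))
  # constant map gives the constant everywhere
  p34 <- make_parcellation(get_ico(2), 34, seed = 3)
  expect_equal(unname(roi_means(rep(4.2, 162), p34)), rep(4.2, 34))
  # brute-force loop agreement on a random map
  set.seed(2)
  m <- rnorm(162)
  ref <- vapply(0:33, function(r) mean(m[p34$labels == r]), numeric(1))
  expect_equal(unname(roi_means(m, p34)), ref, tolerance = 1e-12)
  # empty ROI (label 2 never used, n_rois = 3)
  p_empty <- toy_parc(c(0, 0, 1), n_rois = 3)
  expect_true(is.nan(roi_means(c(1, 2, 3), p_empty)[3]))
  expect_error(roi_means(1:5, p), "length")
})

test_that("abnormal score reproduces the hand-worked example with the N-1 denominator", {
  # one ROI whose reference means are {1, 2, 3} and subject mean 4:
  # Z = (4 - 2) / sd({1,2,3}) = 2 / 1 = 2
  p <- toy_parc(c(0, 0))
  subject <- c(4, 4)
  refs <- list(c(1, 1), c(2, 2), c(3, 3))
  z <- abnormal_scores(subject, refs, p)
  expect_equal(unname(z[1]), 2)
  # population (N) denominator is exposed and differs
  z_pop <- abnormal_scores(subject, refs, p, unbiased = FALSE)
  expect_equal(unname(z_pop[1]), 2 / sqrt(2 / 3))
  expect_error(abnormal_scores(subject, refs[1], p), "at least 2")
})

test_that("subject equal to the reference mean scores zero in every ROI", {
  set.seed(4)
  p <- make_parcellation(get_ico(1), 6, seed = 2)
  refs <- lapply(1:8, function(i) rnorm(42))
  subject <- Reduce(`+`, refs) / 8
  z <- abnormal_scores(subject, refs, p)
  expect_lt(max(abs(z)), 1e-10)
})

test_that("scores are location-scale invariant and locally responsive", {
  set.seed(9)
  p <- make_parcellation(get_ico(1), 5, seed = 5)
  refs <- lapply(1:10, function(i) rnorm(42))
  subject <- rnorm(42)
  z <- abnormal_scores(subject, refs, p)
  # same affine map applied to subject and references leaves Z unchanged
  z2 <- abnormal_scores(3 * subject - 1, lapply(refs, function(r) 3 * r - 1), p)
  expect_equal(as.numeric(z), as.numeric(z2), tolerance = 1e-10)
  # shifting the subject within one ROI moves only that ROI's score by d/std
  roi0 <- p$labels == 0
  delta <- 0.8
  shifted <- subject; shifted[roi0] <- shifted[roi0] + delta
  z3 <- abnormal_scores(shifted, refs, p)
  ref_means <- vapply(refs, function(r) mean(r[roi0]), numeric(1))
  expect_equal(unname(z3[1] - z[1]), delta / sd(ref_means), tolerance = 1e-10)
  expect_equal(as.numeric(z3[-1]), as.numeric(z[-1]), tolerance = 1e-12)
})

test_that("degenerate ROIs get infinite sentinels and are flagged", {
  p <- toy_parc(c(0, 1))
  refs <- list(c(1, 5), c(1, 6), c(1, 7))   # ROI 0 has zero spread
  z <- abnormal_scores(c(2, 6), refs, p)
  expect_identical(unname(z[1]), Inf)
  expect_identical(attr(z, "degenerate"), 1L)
  expect_true(is.finite(z[2]))
})

test_that("reference-distribution subjects have near-standard scores on average", {
  set.seed(15)
  p <- make_parcellation(get_ico(1), 6, seed = 8)
  zs <- replicate(300, {
    refs <- lapply(1:10, function(i) rnorm(42))
    as.numeric(abnormal_scores(rnorm(42), refs, p))
  })
  expect_lt(abs(mean(zs)), 0.2)
  expect_gt(var(as.vector(zs)), 0.6)
  expect_lt(var(as.vector(zs)), 1.8)
})

test_that("template reference selects the age-closest subjects deterministically", {
  subjects <- lapply(seq_along(c(60, 61, 70, 80)), function(i)
    structure(list(subject_id = sprintf("S%d", i),
                   age = c(60, 61, 70, 80)[i], sex = 0, group = "CN",
                   features = matrix(0, 2, 1), mask = c(0L, 1L)),
              class = "cortex_subject"))
  sel <- template_reference(subjects, 62, k = 2)
  expect_identical(vapply(sel, `[[`, "", "subject_id"), c("S2", "S1"))
  # exact-age subject is always included
  sel2 <- template_reference(subjects, 70, k = 1)
  expect_identical(sel2[[1]]$subject_id, "S3")
  # k = cohort size returns everyone
  expect_length(template_reference(subjects, 65, k = 4), 4)
  expect_error(template_reference(subjects, 65, k = 5), "cannot supply")
})

test_that("classification separates well-separated scores and is seed-deterministic", {
  set.seed(10)
  n <- 40
  feats <- matrix(rnorm(n * 34), n, 34)
  labs <- rep(c("CN", "AD"), each = n / 2)
  feats[labs == "AD", 1:3] <- feats[labs == "AD", 1:3] - 5   # 5-sd shift
  ce <- classification_eval(feats, labs, folds = 10, seed = 3)
  expect_gte(ce$accuracy, 0.95)
  ce2 <- classification_eval(feats, labs, folds = 10, seed = 3)
  expect_identical(ce, ce2)
  # permuted labels: accuracy within binomial noise of chance
  set.seed(11)
  perm <- sample(labs)
  cep <- classification_eval(feats, perm, folds = 10, seed = 4)
  expect_lt(abs(cep$accuracy - 0.5), 3 * sqrt(0.25 / n) + 0.1)
  expect_error(classification_eval(feats, rep("CN", n)), "two classes")
})

test_that("template-reference scoring recovers planted atrophy without any model", {
  train <- make_cohort(cohort_spec(n_subjects = 100, seed = 301))
  spec_ad <- cohort_spec(n_subjects = 40, seed = 302, group_probs = c(AD = 1))
  test_ad <- make_cohort(spec_ad, ico = train$ico,
                         parcellation = train$parcellation)
  tab <- abnormality_scores(subjects = test_ad,
                            parcellation = train$parcellation,
                            reference = "template", train_cohort = train,
                            n = 10)
  zmat <- attr(tab, "zmat")
  dis <- spec_ad$disease_rois + 1
  mz_dis <- rowMeans(zmat[, dis, drop = FALSE])
  # atrophied ROIs deviate negatively, decisively so across subjects; the
  # template's anatomical mismatch inflates background |Z| everywhere, which
  # is the weakness the generated reference sets exist to remove
  expect_lt(mean(mz_dis), 0)
  expect_lt(t.test(mz_dis, alternative = "less")$p.value, 1e-6)
  mz_other <- rowMeans(zmat[, -dis, drop = FALSE])
  expect_gt(abs(mean(mz_dis)), abs(mean(mz_other)))
})
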