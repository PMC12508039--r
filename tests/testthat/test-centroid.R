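test_that("global centroid is the origin of its own standardized space", {
  set.seed(41)
  sp <- space_from_matrix(matrix(rnorm(30 * 6), 30, 6))
  ctr <- average_person_vector(sp)$global
  expect_lt(max(abs(ctr$std)), 1e-8)
  expect_equal(ctr$raw, sp$mu, tolerance = 1e-10, ignore_attr = TRUE)
  # with the centroid at the origin, distance = L2 norm of the row
  dc <- distance_from_centroid(sp, ctr)
  expect_equal(dc$distance, sqrt(rowSums(sp$X^2)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("two observations: centroid is their equidistant midpoint", {
  sp <- space_from_matrix(rbind(c(0, 0), c(4, 2)))
  ctr <- average_person_vector(sp)$global
  dc <- distance_from_centroid(sp, ctr)
  expect_equal(dc$distance[1], dc$distance[2], tolerance = 1e-12)
})

test_that("stratified centroids partition the cohort and average to global", {
  co <- make_toy_cohort(n_persons = 12L, n_items = 5L, seed = 42L)
  spec <- feature_spec(co)
  sp <- standardize(encode_features(co, spec), spec = spec)
  ctrs <- average_person_vector(sp, cohort = co, stratify_by = "gender")
  expect_length(ctrs, length(unique(co$gender)))
  expect_equal(sum(vapply(ctrs, `[[`, 0L, "n")), nrow(co))
  # observation-count-weighted mean of stratum centroids = global centroid
  w <- vapply(ctrs, `[[`, 0L, "n")
  weighted <- Reduce(`+`, Map(function(ct, wi) ct$std * wi, ctrs, w)) / sum(w)
  expect_lt(max(abs(weighted - average_person_vector(sp)$global$std)), 1e-9)
  # restrict_to_stratum scores only members
  dc <- distance_from_centroid(sp, ctrs[[1L]], restrict_to_stratum = TRUE)
  expect_equal(nrow(dc), ctrs[[1L]]$n)
  expect_error(average_person_vector(sp, cohort = co, stratify_by = "nope"))
})

test_that("centroid distance is monotone in coordinate-wise deviation", {
  set.seed(43)
  sp <- space_from_matrix(matrix(rnorm(20 * 4), 20, 4))
  ctr <- average_person_vector(sp)$global
  x <- sp$X[3, ]
  d0 <- euclidean_distance(x, ctr$std)
  x2 <- x
  x2[2] <- ctr$std[2] + 2 * (x[2] - ctr$std[2])   # double one deviation
  expect_gt(euclidean_distance(x2, ctr$std), d0)
  expect_error(
    distance_from_centroid(
      sp, structure(list(std = 1:3, members = character()),
                    class = "hdss_centroid")),
    "dimension mismatch")
})

test_that("rose data is seeded, sized, and constant for static persons", {
  sim <- generate_cohort(simulation_config(n_persons = 250L, n_items = 20L,
                                           seed = 44L))
  sc <- raw_scale_scores(sim$cohort, sim$scales)
  st <- assign_clinical_status(tscores_from_reference(sc))
  spec <- feature_spec(sim$cohort)
  sp <- standardize(encode_features(sim$cohort, spec), spec = spec)
  dc <- distance_from_centroid(sp, average_person_vector(sp)$global)
  disorder <- names(sim$scales$dsm_proxy)[1L]
  r1 <- rose_data(dc, st, disorder, n_sample = 10L, seed = 99L)
  r2 <- rose_data(dc, st, disorder, n_sample = 10L, seed = 99L)
  expect_identical(r1, r2)
  expect_equal(length(unique(r1$person_id)), 10L)
  expect_equal(nrow(r1), 10L * 4L)
  # fewer eligible than requested: sample all, with a warning
  expect_warning(rall <- rose_data(dc, st, disorder, n_sample = 10000L),
                 "sampling all")
  expect_lt(length(unique(rall$person_id)), 10000L)
})

test_that("severity regression recovers planted linear structure exactly", {
  counts <- rep(0:4, each = 8)
  dist <- 2 + 1.5 * counts
  reg <- suppressWarnings(severity_regression(dist, counts))  # exact fit
  expect_equal(unname(reg$coefficients["n_diagnoses", "Estimate"]), 1.5,
               tolerance = 1e-8)
  expect_equal(reg$r2, 1, tolerance = 1e-12)
  expect_error(severity_regression(dist, rep(1, 40)), "zero variance")
  expect_error(severity_regression(dist[1:5], counts[1:5]), "at least 10")
})

test_that("regression t statistic is central under permuted counts", {
  set.seed(45)
  n <- 150
  counts <- rpois(n, 1.2)
  dist <- 5 + 0.8 * counts + rnorm(n)
  t_obs <- severity_regression(dist, counts)$coefficients["n_diagnoses",
                                                          "t value"]
  t_null <- replicate(999, {
    severity_regression(dist, sample(counts))$coefficients["n_diagnoses",
                                                           "t value"]
  })
  # observed signal is far outside the permutation null; the null itself
  # is central
  expect_gt(t_obs, quantile(t_null, 0.995))
  expect_lt(abs(median(t_null)), 1)
})

test_that("distance-severity correlation behaves at the extremes", {
  x <- seq(1, 40)
  expect_equal(suppressWarnings(distance_severity_correlation(x, x))$r, 1,
               tolerance = 1e-12)
  set.seed(46)
  indep <- distance_severity_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(indep$r), 0.1)
  expect_error(distance_severity_correlation(x, rep(1, 40)), "zero variance")
})
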