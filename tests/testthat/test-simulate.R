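test_that("generation is bitwise deterministic given (config, seed)", {
  cfg <- simulation_config(n_persons = 40L, n_items = 15L, seed = 81L)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(s1$cohort), as.data.frame(s2$cohort))
  expect_identical(s1$truth, s2$truth)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_cohort(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("config validation rejects malformed parameters", {
  expect_error(simulation_config(factor_cor = matrix(c(1, 2, 2, 1), 2, 2),
                                 n_factors = 2L),
               "positive-definite")
  expect_error(simulation_config(cutpoints = c(2, 1)))
  expect_error(simulation_config(race_probs = c(0.5, 0.2),
                                 race_levels = c("A", "B")))
  expect_error(hdss_preset("nope"), "disjoint")
})

test_that("presets encode their scenario definitions", {
  expect_equal(hdss_preset("disjoint")$overlap_share, 0)
  pl <- hdss_preset("paper_like")
  expect_equal(pl$n_timepoints, 4L)
  expect_equal(pl$n_items, 119L)
  expect_equal(pl$n_persons, 1000L)
  expect_equal(pl$overlap_share, 0.3)
  expect_equal(pl$ar1, 0.7)
  expect_true(all(hdss_preset("improving")$drift < 0))
})

test_that("marginal item distribution matches the cutpoint-implied probabilities", {
  # single factor, zero loading: propensity is pure N(0,1), so category
  # probabilities are Phi-differences of the cutpoints
  cfg <- simulation_config(n_persons = 5000L, n_items = 4L, n_timepoints = 1L,
                           n_factors = 1L, factor_cor = matrix(1, 1, 1),
                           loading_dominant = 0, overlap_share = 0,
                           cutpoints = c(0.2, 1.4), seed = 82L)
  sim <- generate_cohort(cfg)
  items <- as.matrix(sim$cohort[item_columns(4L)])
  p_expect <- c(pnorm(0.2), pnorm(1.4) - pnorm(0.2), 1 - pnorm(1.4))
  p_obs <- c(mean(items == 0), mean(items == 1), mean(items == 2))
  # 3 SE binomial tolerance at n = 20000 draws
  tol <- 3 * sqrt(p_expect * (1 - p_expect) / length(items))
  expect_true(all(abs(p_obs - p_expect) < tol))
})

test_that("factor scores carry the configured AR(1) autocorrelation", {
  cfg <- simulation_config(n_persons = 2000L, n_items = 2L, ar1 = 0.7,
                           seed = 83L)
  sim <- generate_cohort(cfg)
  th <- sim$truth$theta
  rho_hat <- sapply(cfg$factor_names, function(f) {
    m <- matrix(th[[f]], nrow = cfg$n_persons)   # persons x timepoints
    mean(sapply(1:3, function(t) cor(m[, t], m[, t + 1])))
  })
  expect_true(all(abs(rho_hat - 0.7) < 0.05))
  # stationarity: marginal variance stays near 1 at every timepoint
  v <- tapply(th$internalizing, th$timepoint, var)
  expect_true(all(abs(v - 1) < 0.15))
})

test_that("orthogonal factors without overlap give weak cross-scale correlations", {
  cfg <- simulation_config(n_persons = 2000L, n_items = 20L,
                           n_timepoints = 1L,
                           factor_cor = diag(5), overlap_share = 0,
                           ar1 = 0, seed = 84L)
  sim <- generate_cohort(cfg)
  sc <- raw_scale_scores(sim$cohort, sim$scales)
  wide <- sapply(names(sim$scales$dsm_proxy), function(s)
    sc$raw_score[sc$scale == s])
  cm <- cor(wide)
  cross <- abs(cm[upper.tri(cm)])
  # same-scale item correlation benchmark: within-scale raw scores are
  # sums of items sharing a factor, so cross-scale r must sit well below
  # the loading-implied within-scale item correlation (~0.5)
  expect_lt(max(cross), 0.15)
})

test_that("degenerate cutpoints behave as limits", {
  cfg <- simulation_config(n_persons = 50L, n_items = 5L, n_timepoints = 1L,
                           cutpoints = c(-30, 1), seed = 85L)
  sim <- generate_cohort(cfg)
  items <- as.matrix(sim$cohort[item_columns(5L)])
  expect_true(all(items >= 1L))                 # tau1 = -Inf limit: no zeros
})

test_that("planted symptom load is recovered by centroid distance at baseline", {
  cfg <- hdss_preset("paper_like", seed = 86L, n_persons = 500L)
  sim <- generate_cohort(cfg)
  spec <- feature_spec(sim$cohort, demographics = "compact")
  sp <- standardize(encode_features(sim$cohort, spec), spec = spec)
  dc <- distance_from_centroid(sp, average_person_vector(sp)$global)
  # baseline-to-baseline pairing: distance at t1 vs rectified norm of theta_1
  th <- sim$truth$theta
  t1 <- th[th$timepoint == 1L, ]
  load1 <- sqrt(rowSums(pmax(as.matrix(t1[cfg$factor_names]), 0)^2))
  base <- dc$timepoint == 1L
  r <- cor(dc$distance[base], load1[match(dc$person_id[base], t1$person_id)])
  expect_gt(r, 0.8)
})

test_that("default scale map groups items by dominant factor with a total scale", {
  cfg <- simulation_config(n_persons = 10L, n_items = 20L, seed = 87L)
  sim <- generate_cohort(cfg)
  sm <- sim$scales
  expect_setequal(sm$hitop$total_problems, 1:20)
  dsm_items <- sort(unlist(sm$dsm_proxy))
  expect_equal(as.integer(dsm_items), 1:20)     # partition of all items
  # dominant loadings agree with group membership
  L <- sim$truth$loadings
  for (nm in names(sm$dsm_proxy)) {
    ids <- sm$dsm_proxy[[nm]]
    doms <- apply(L[ids, , drop = FALSE], 1, which.max)
    expect_length(unique(doms), 1L)
  }
})
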