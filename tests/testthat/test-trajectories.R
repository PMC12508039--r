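tiny_run <- function(n_persons = 40L, seed = 71L, drift = 0) {
  cfg <- simulation_config(n_persons = n_persons, n_items = 12L,
                           drift = drift, seed = seed)
  sim <- generate_cohort(cfg)
  sc <- raw_scale_scores(sim$cohort, sim$scales)
  st <- assign_clinical_status(suppressWarnings(tscores_from_reference(sc)))
  spec <- feature_spec(sim$cohort)
  sp <- standardize(encode_features(sim$cohort, spec), spec = spec)
  dc <- distance_from_centroid(sp, average_person_vector(sp)$global)
  emb <- mds_embed(pairwise_distances(sp), method = "classical", seed = seed)
  skey <- paste(st$summary$person_id, st$summary$timepoint, sep = "@")
  b <- fit_clinical_boundary(
    emb, st$summary$total_clinical[match(rownames(emb$points), skey)])
  list(sim = sim, status = st, space = sp, dc = dc, emb = emb, boundary = b,
       traj = build_trajectories(emb, st, dc))
}

test_that("trajectories cover the embedding exactly, in order", {
  r <- tiny_run()
  tr <- r$traj
  expect_equal(sort(obs_ids(tr)), sort(rownames(r$emb$points)))
  expect_equal(nrow(tr), nrow(r$emb$points))
  # 4 timepoints -> 3 steps per person
  steps <- step_displacements(tr)
  expect_equal(nrow(steps), length(unique(tr$person_id)) * 3L)
  # per-person timepoints strictly increasing
  expect_true(all(tapply(tr$timepoint, tr$person_id,
                         function(t) all(diff(t) > 0))))
  # duplicated observation ids are rejected
  emb_bad <- r$emb
  rownames(emb_bad$points)[2L] <- rownames(emb_bad$points)[1L]
  expect_error(build_trajectories(emb_bad, r$status, r$dc), "duplicate")
})

test_that("static persons have zero displacement; a one-point response change moves 1/sigma", {
  co <- as.data.frame(make_toy_cohort(n_persons = 4L, n_items = 5L,
                                      n_timepoints = 2L, seed = 72L))
  # person p01 static across timepoints; p02 changes item_001 by one point
  items <- item_columns(5L)
  for (p in c("p01", "p02")) {
    co[co$person_id == p & co$timepoint == 2L, items] <-
      co[co$person_id == p & co$timepoint == 1L, items]
  }
  co$age[co$timepoint == 2L] <- co$age[co$timepoint == 1L]   # freeze age
  co$item_001[co$person_id == "p02" & co$timepoint == 1L] <- 0L
  co$item_001[co$person_id == "p02" & co$timepoint == 2L] <- 1L
  cohort <- as_cohort(co, n_items = 5L)
  spec <- feature_spec(cohort, include_demographics = FALSE)
  sp <- standardize(encode_features(cohort, spec), spec = spec)

  tr <- data.frame(person_id = cohort$person_id, timepoint = cohort$timepoint,
                   dim1 = 0, dim2 = 0)
  steps <- step_displacements(tr, metric = "fullspace", space = sp)
  expect_equal(steps$displacement[steps$person_id == "p01"], 0)
  expect_equal(steps$displacement[steps$person_id == "p02"],
               1 / sp$sigma[["item_001"]], tolerance = 1e-10)
})

test_that("transition events equal the label-diff oracle and directions match plants", {
  # planted: boundary is dim1 = 0, clinical on the left (negative side)
  b <- structure(list(intercept = 0, coefficients = c(-4, 0), threshold = 0.5,
                      accuracy = NA, converged = TRUE),
                 class = "hdss_boundary")
  tr <- data.frame(
    person_id = rep(c("a", "b", "c"), each = 3L),
    timepoint = rep(1:3, 3L),
    dim1 = c(-1, -1, 1,        # a: crosses out at step 2 (improves)
             1, -1, 1,         # b: crosses in then out
             1, 2, 3),         # c: never clinical
    dim2 = 0, centroid_distance = 0, clinical = FALSE, n_diagnoses = 0L)
  ev <- detect_transitions(tr, b)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$direction[ev$person_id == "a"], "improved")
  expect_equal(ev$direction[ev$person_id == "b"], c("worsened", "improved"))
  # oracle: count label changes directly
  labs <- classify_region(b, as.matrix(tr[c("dim1", "dim2")]))$clinical
  oracle_count <- sum(tapply(labs, tr$person_id, function(l) sum(diff(l) != 0)))
  expect_equal(nrow(ev), oracle_count)
  # static cohort -> no events
  tr0 <- tr; tr0$dim1 <- 1
  expect_equal(nrow(detect_transitions(tr0, b)), 0L)
})

test_that("event counts match the label-diff oracle on simulated cohorts", {
  r <- tiny_run(seed = 73L)
  ev <- detect_transitions(r$traj, r$boundary)
  tr <- r$traj[order(r$traj$person_id, r$traj$timepoint), ]
  labs <- classify_region(r$boundary, as.matrix(tr[c("dim1", "dim2")]))$clinical
  oracle_count <- sum(tapply(labs, tr$person_id, function(l) sum(diff(l) != 0)))
  expect_equal(nrow(ev), oracle_count)
  # by-tscore mode uses the carried clinical flags instead
  ev_t <- detect_transitions(r$traj, r$boundary, by_tscore = TRUE)
  oracle_t <- sum(tapply(as.logical(tr$clinical), tr$person_id,
                         function(l) sum(diff(l) != 0)))
  expect_equal(nrow(ev_t), oracle_t)
})
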