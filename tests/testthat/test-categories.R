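toy_assignment <- function(membership) {
  structure(list(membership = membership, family = "dsm_proxy"),
            class = "hdss_categories")
}

test_that("within/between cells match the double-loop oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 50
    X <- matrix(rnorm(n * 6), n, 6)
    ids <- paste0("p", seq_len(n), "@1")
    sp <- space_from_matrix(X, ids)
    dd <- pairwise_distances(sp)
    m <- matrix(runif(n * 5) < 0.35, n, 5,
                dimnames = list(ids, paste0("c", 1:5)))
    asg <- toy_assignment(m)
    wb <- suppressWarnings(within_between_matrix(dd, asg))
    oracle <- oracle_within_between(dd$d, m)
    expect_equal(wb$means, oracle, tolerance = 1e-9)
  }
})

test_that("planted tight clusters give within << between", {
  set.seed(62)
  c1 <- matrix(rnorm(20, sd = 0.1), 10, 2)
  c2 <- matrix(rnorm(20, mean = 10, sd = 0.1), 10, 2)
  ids <- paste0("p", 1:20, "@1")
  sp <- space_from_matrix(rbind(c1, c2), ids)
  dd <- pairwise_distances(sp)
  m <- cbind(A = rep(c(TRUE, FALSE), each = 10),
             B = rep(c(FALSE, TRUE), each = 10))
  rownames(m) <- ids
  wb <- within_between_matrix(dd, toy_assignment(m))
  s <- summarize_within_between(wb)
  expect_lt(s$m_within, s$m_between / 5)
})

test_that("comorbid observations contribute to both diagonals and the cross cell", {
  # 3 observations at coordinates 0, 3, 10 on a line; obs 2 is in both
  # categories. Hand-enumerated pairs:
  #  within A {1,2}: d(1,2)=3 ; within B {2,3}: d(2,3)=7
  #  between (A,B): pairs (1,2),(1,3),(2,3) minus self-pair (2,2)
  #               = 3, 10, 7 -> mean 20/3
  d <- as.matrix(dist(matrix(c(0, 3, 10), ncol = 1)))
  ids <- paste0("p", 1:3, "@1")
  dimnames(d) <- list(ids, ids)
  dd <- structure(list(d = d, index = NULL), class = "hdss_dist")
  m <- cbind(A = c(TRUE, TRUE, FALSE), B = c(FALSE, TRUE, TRUE))
  rownames(m) <- ids
  wb <- within_between_matrix(dd, toy_assignment(m))
  expect_equal(wb$means["A", "A"], 3)
  expect_equal(wb$means["B", "B"], 7)
  expect_equal(wb$means["A", "B"], 20 / 3)
  expect_equal(wb$pair_counts["A", "B"], 3)
})

test_that("identical observations give all-zero cells", {
  X <- matrix(1, 6, 3) + 0
  X[, 1] <- c(1, 1, 1, 1, 1, 1)
  ids <- paste0("p", 1:6, "@1")
  d <- matrix(0, 6, 6, dimnames = list(ids, ids))
  dd <- structure(list(d = d, index = NULL), class = "hdss_dist")
  m <- cbind(A = rep(TRUE, 6), B = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  rownames(m) <- ids
  wb <- within_between_matrix(dd, toy_assignment(m))
  expect_true(all(wb$means == 0, na.rm = TRUE))
})

test_that("summaries aggregate cell values, with a pooled alternative", {
  wb <- structure(list(
    means = matrix(c(4, 10, 10, 6), 2, 2,
                   dimnames = list(c("A", "B"), c("A", "B"))),
    sumsq = matrix(c(2 * 16, 5 * 100, 5 * 100, 3 * 36), 2, 2),
    pair_counts = matrix(c(2, 5, 5, 3), 2, 2),
    flagged = c(A = FALSE, B = FALSE), family = "dsm_proxy"),
    class = "hdss_category_distance")
  s <- summarize_within_between(wb)
  expect_equal(s$m_within, 5)           # mean(4, 6)
  expect_equal(s$m_between, 10)
  expect_equal(s$sd_within, sd(c(4, 6)))
  # pooled: weighted by pair counts; here all pairs in a cell equal the
  # cell mean, so pooled SD reflects only the within/between spread
  sp <- summarize_within_between(wb, pooled = TRUE)
  expect_equal(sp$m_within, (4 * 2 + 6 * 3) / 5)
  expect_equal(sp$m_between, 10)
  expect_equal(sp$sd_between, 0)

  wb$flagged <- c(A = TRUE, B = TRUE)
  expect_error(summarize_within_between(wb), "at least 2")
})

test_that("undersized categories are flagged and excluded", {
  set.seed(63)
  ids <- paste0("p", 1:10, "@1")
  sp <- space_from_matrix(matrix(rnorm(20), 10, 2), ids)
  dd <- pairwise_distances(sp)
  m <- cbind(A = c(TRUE, rep(FALSE, 9)),        # 1 member -> flagged
             B = rep(c(TRUE, FALSE), 5),
             C = rep(c(FALSE, TRUE), 5))
  rownames(m) <- ids
  expect_warning(wb <- within_between_matrix(dd, toy_assignment(m)),
                 "flagged: A")
  expect_true(wb$flagged["A"])
  expect_true(is.na(wb$means["A", "A"]))
  s <- summarize_within_between(wb)
  expect_equal(s$n_within_cells, 2L)
})
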