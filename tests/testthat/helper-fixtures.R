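# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, direct formula evaluation) and never call the code paths
# they check.

make_toy_cohort <- function(n_persons = 6L, n_items = 6L, n_timepoints = 2L,
                            seed = 1L) {
  set.seed(seed)
  rows <- expand.grid(timepoint = seq_len(n_timepoints),
                      person_id = sprintf("p%02d", seq_len(n_persons)),
                      stringsAsFactors = FALSE)[, 2:1]
  df <- data.frame(person_id = rows$person_id, timepoint = rows$timepoint,
                   stringsAsFactors = FALSE)
  for (ic in hdss::item_columns(n_items)) {
    df[[ic]] <- sample(0:2, nrow(df), replace = TRUE)
  }
  per_person <- !duplicated(df$person_id)
  df$race <- rep(sample(c("A", "B"), n_persons, replace = TRUE),
                 each = n_timepoints)
  df$gender <- rep(sample(c("f", "m"), n_persons, replace = TRUE),
                   each = n_timepoints)
  df$age <- rep(round(runif(n_persons, 9, 11), 2), each = n_timepoints) +
    (df$timepoint - 1)
  hdss::as_cohort(df, n_items = n_items)
}

# naive per-pair Euclidean distance matrix
oracle_pairwise <- function(X) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
  }
  d
}

# naive within/between cell means over a logical membership matrix
oracle_within_between <- function(D, membership) {
  K <- ncol(membership)
  means <- matrix(NA_real_, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      ia <- which(membership[, a]); ib <- which(membership[, b])
      vals <- c()
      if (a == b) {
        if (length(ia) >= 2) {
          for (i in seq_along(ia)) {
            for (j in seq_along(ia)) {
              if (i < j) vals <- c(vals, D[ia[i], ia[j]])
            }
          }
        }
      } else {
        for (i in ia) for (j in ib) if (i != j) vals <- c(vals, D[i, j])
      }
      if (length(vals) > 0) means[a, b] <- mean(vals)
    }
  }
  dimnames(means) <- list(colnames(membership), colnames(membership))
  means
}

# small standardized space straight from a numeric matrix
space_from_matrix <- function(X, ids = NULL) {
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(X)), "@1")
  rownames(X) <- ids
  hdss::standardize(X)
}
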