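#' Multidimensional scaling embedding of a distance matrix
#'
#' Projects the pairwise distance matrix to a low-dimensional common space.
#' The default is metric MDS by stress majorization (SMACOF): starting from
#' the classical-scaling solution plus seeded random restarts, each Guttman
#' transform step is guaranteed not to increase the raw stress
#' \eqn{\sigma(X) = \sum_{i<j} (d_{ij}(X) - \delta_{ij})^2}, and the best
#' restart by final stress is kept. `method = "classical"` uses
#' Torgerson/Gower classical scaling (eigendecomposition of the
#' double-centered squared distances): deterministic, no restarts, and much
#' faster for large cohorts.
#'
#' Embeddings are centered and defined only up to rotation/reflection;
#' downstream quantities should be rotation-invariant.
#'
#' @param dist An `hdss_dist` or symmetric nonnegative matrix.
#' @param n_components Embedding dimension (default 2).
#' @param method `"smacof"` or `"classical"`.
#' @param seed Integer seed controlling the random restarts.
#' @param max_iter Maximum majorization iterations per restart.
#' @param tol Relative stress-decrease convergence tolerance.
#' @param restarts Number of starts for SMACOF (the first is the
#'   classical-scaling configuration, the rest are random).
#' @return Object of class `hdss_embedding`: `points` (n x k, centered,
#'   observation ids as rownames), `stress` (final raw stress),
#'   `stress_trace` (per-iteration stress of the winning start),
#'   `iterations`, `converged`, `method`, `seed`.
#' @export
mds_embed <- function(dist, n_components = 2L,
                      method = c("smacof", "classical"),
                      seed = 1L, max_iter = 300L, tol = 1e-6, restarts = 4L) {
  method <- match.arg(method)
  d <- check_distance_matrix(dist)
  n <- nrow(d)
  if (n < n_components + 1L) {
    stop(sprintf("need at least %d observations for %d components",
                 n_components + 1L, n_components))
  }
  classical <- classical_config(d, n_components)
  if (method == "classical") {
    emb <- structure(
      list(points = classical, stress = stress_of(classical, d),
           stress_trace = stress_of(classical, d), iterations = 0L,
           converged = TRUE, method = "classical", seed = seed),
      class = "hdss_embedding")
    return(emb)
  }
  starts <- c(list(classical),
              local_seed(seed, lapply(seq_len(max(0L, restarts - 1L)),
                function(i) {
                  x <- matrix(stats::rnorm(n * n_components), n, n_components)
                  scale(x, scale = FALSE) * stats::median(d) / sqrt(n_components)
                })))
  best <- NULL
  for (X0 in starts) {
    run <- smacof_run(d, X0, max_iter = max_iter, tol = tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  best$points <- scale(best$points, scale = FALSE)
  attr(best$points, "scaled:center") <- NULL
  dimnames(best$points) <- list(rownames(d), NULL)
  structure(c(best, list(method = "smacof", seed = seed)),
            class = "hdss_embedding")
}

classical_config <- function(d, k) {
  n <- nrow(d)
  d2 <- d^2
  # double centering: B = -0.5 * J d^2 J
  rm <- rowMeans(d2); gm <- mean(d2)
  B <- -0.5 * (d2 - outer(rm, rm, "+") + gm)
  e <- eigen(B, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(k)], 0)
  X <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  X <- scale(X, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  dimnames(X) <- list(rownames(d), NULL)
  X
}

stress_of <- function(X, d) {
  dx <- as.matrix(stats::dist(X))
  sum((dx[upper.tri(dx)] - d[upper.tri(d)])^2)
}

smacof_run <- function(d, X, max_iter, tol) {
  n <- nrow(d)
  s_prev <- stress_of(X, d)
  trace <- s_prev
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dx <- as.matrix(stats::dist(X))
    ratio <- ifelse(dx > 0, d / dx, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n                     # Guttman transform
    s <- stress_of(X, d)
    trace <- c(trace, s)
    if (s_prev - s < tol * max(s_prev, .Machine$double.eps)) {
      s_prev <- s
      converged <- TRUE
      break
    }
    s_prev <- s
  }
  list(points = X, stress = s_prev, stress_trace = trace,
       iterations = iter, converged = converged)
}

#' @export
print.hdss_embedding <- function(x, ...) {
  cat(sprintf("<hdss_embedding> %d points in %d-D (%s), stress = %.6g\n",
              nrow(x$points), ncol(x$points), x$method, x$stress))
  invisible(x)
}
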