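#' Euclidean distance between two feature vectors
#'
#' The dissimilarity between two observations i and j is the length of the
#' straight line between their vectors,
#' \deqn{d_{ij} = \sqrt{\sum_k (u_k - v_k)^2},}
#' so identical response vectors have distance 0 and larger values indicate
#' a larger difference in responses.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Nonnegative scalar distance.
#' @export
euclidean_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop(sprintf("length mismatch: %d vs %d", length(u), length(v)))
  }
  sqrt(sum((u - v)^2))
}

#' Pairwise distance matrix over a standardized space
#'
#' Computes the full symmetric matrix of Euclidean distances between every
#' pair of observations. Distances are computed in the standardized space by
#' default; `raw = TRUE` computes them on the back-transformed raw values
#' (diagnostic use only).
#'
#' @param space An `hdss_space`.
#' @param raw Use raw-scale coordinates instead of standardized ones.
#' @return An object of class `hdss_dist`: list with `d` (n x n matrix with
#'   observation ids as dimnames) and `index`.
#' @export
pairwise_distances <- function(space, raw = FALSE) {
  stopifnot(inherits(space, "hdss_space"))
  X <- if (raw) unstandardize(space) else space$X
  if (nrow(X) < 1L) stop("empty space")
  d <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(d) <- list(rownames(space$X), rownames(space$X))
  structure(list(d = d, index = space$index), class = "hdss_dist")
}

#' @export
print.hdss_dist <- function(x, ...) {
  cat(sprintf("<hdss_dist> %d x %d Euclidean distance matrix\n",
              nrow(x$d), ncol(x$d)))
  invisible(x)
}

#' Validate distance-matrix structure
#'
#' Checks the metric bookkeeping: square, zero diagonal, symmetric,
#' nonnegative. Used by consumers such as [mds_embed()].
#'
#' @param d Numeric matrix or `hdss_dist`.
#' @param tol Numerical tolerance for symmetry/diagonal checks.
#' @return The plain matrix, invisibly validated.
#' @export
check_distance_matrix <- function(d, tol = 1e-8) {
  if (inherits(d, "hdss_dist")) d <- d$d
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < -tol)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(d))) > tol) stop("distance matrix has nonzero diagonal")
  d
}

#' Build the five-dimensional scale-score space
#'
#' Standardizes the per-observation T-scores of the five broad scales
#' (total problems, internalizing, externalizing, attention, somatic) into
#' a 5-feature space — the HiTOP-style "average vector" space used for the
#' distance-versus-severity comparison.
#'
#' @param tscores An `hdss_tscores` table from [tscores_from_reference()].
#' @param scales Character vector of the five scale names to use.
#' @return An `hdss_space` with exactly `length(scales)` features.
#' @export
build_scale_space <- function(tscores,
                              scales = c("total_problems", "internalizing",
                                         "externalizing", "attention",
                                         "somatic")) {
  stopifnot(is.data.frame(tscores))
  present <- unique(tscores$scale)
  missing <- setdiff(scales, present)
  if (length(missing) > 0L) {
    stop("missing scale column: ", paste(missing, collapse = ", "))
  }
  sub <- tscores[tscores$scale %in% scales, , drop = FALSE]
  ids <- unique(paste(sub$person_id, sub$timepoint, sep = "@"))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(scales),
              dimnames = list(ids, scales))
  m[cbind(match(paste(sub$person_id, sub$timepoint, sep = "@"), ids),
          match(sub$scale, scales))] <- sub$t_score
  if (anyNA(m)) stop("incomplete T-score table: not every observation has all scales")
  standardize(m)
}
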