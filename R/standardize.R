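#' Standardize a raw feature matrix
#'
#' Centers every feature to mean 0 and scales it to standard deviation 1,
#' using the population convention (divide by n). The normalization
#' parameters are stored so that new observations can be projected into the
#' same frozen space and so that the transform is exactly invertible.
#' Constant features cannot be scaled; they are carried as all-zero columns
#' and flagged rather than raising a division-by-zero.
#'
#' Standardization is fitted over all pooled person-timepoint observations,
#' so every timepoint lives in a single comparable space.
#'
#' @param raw Numeric matrix (observations x features) from
#'   [encode_features()], with at least 2 rows. Rownames are kept as the
#'   observation index.
#' @param spec Optional `hdss_features` carried along for provenance.
#' @return An object of class `hdss_space` with elements `X` (standardized
#'   matrix), `mu`, `sigma` (per-feature raw mean / population SD),
#'   `constant` (logical flag per feature), `spec` and `index` (data frame
#'   with `person_id`, `timepoint` parsed from rownames when available).
#' @export
standardize <- function(raw, spec = NULL) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L) {
    stop("standardization requires >= 2 observations (SD undefined for 1 row)")
  }
  if (anyNA(raw)) stop("raw feature matrix contains missing values")
  n <- nrow(raw)
  mu <- colMeans(raw)
  centered <- sweep(raw, 2L, mu)
  sigma <- sqrt(colMeans(centered^2))   # population SD (divide by n)
  constant <- sigma == 0
  scale_by <- ifelse(constant, 1, sigma)
  X <- sweep(centered, 2L, scale_by, "/")
  X[, constant] <- 0
  structure(
    list(X = X, mu = mu, sigma = sigma, constant = constant, spec = spec,
         index = parse_obs_index(rownames(raw))),
    class = "hdss_space"
  )
}

parse_obs_index <- function(ids) {
  if (is.null(ids)) return(NULL)
  at <- regexpr("@[^@]*$", ids)
  data.frame(
    person_id = substr(ids, 1L, at - 1L),
    timepoint = as.integer(substring(ids, at + 1L)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.hdss_space <- function(x, ...) {
  cat(sprintf("<hdss_space> %d observations x %d features (%d constant)\n",
              nrow(x$X), ncol(x$X), sum(x$constant)))
  invisible(x)
}

#' Project new raw observations into a fitted space
#'
#' Applies the frozen normalization parameters `mu`, `sigma` of a fitted
#' `hdss_space` to new raw rows, without refitting.
#'
#' @param object A fitted `hdss_space`.
#' @param newdata Numeric matrix or vector of raw feature values with the
#'   same feature count/order as the fitted space.
#' @param ... Unused.
#' @return Standardized matrix with the same number of rows as `newdata`.
#' @export
predict.hdss_space <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
             else as.matrix(newdata)
  if (ncol(newdata) != length(object$mu)) {
    stop(sprintf("feature count mismatch: space has %d, newdata has %d",
                 length(object$mu), ncol(newdata)))
  }
  scale_by <- ifelse(object$constant, 1, object$sigma)
  out <- sweep(sweep(newdata, 2L, object$mu), 2L, scale_by, "/")
  out[, object$constant] <- 0
  out
}

#' Invert the standardization
#'
#' Recovers raw values from standardized coordinates:
#' `raw = standardized * sigma + mu`. Constant features recover their
#' (constant) raw mean.
#'
#' @param space A fitted `hdss_space`.
#' @param X Standardized matrix; defaults to the space's own matrix.
#' @return Raw-scale matrix.
#' @export
unstandardize <- function(space, X = space$X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  sweep(sweep(X, 2L, space$sigma, "*"), 2L, space$mu, "+")
}
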