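#' Fit the clinical decision boundary in the embedding
#'
#' Trains a logistic regression of clinical status on the first two
#' embedding dimensions. The decision boundary is the straight line where
#' the predicted probability equals the threshold (0.5). A fixed tiny ridge
#' penalty (1e-8) on the slopes keeps the boundary finite when the classes
#' are perfectly separable in the embedding; it is negligible otherwise
#' (the fit matches `glm` on non-separable data).
#'
#' @param embedding An `hdss_embedding` (or an n x 2 coordinate matrix).
#' @param clinical Logical vector of clinical status per embedded point
#'   (conventionally total-problems T >= 65).
#' @param threshold Probability threshold defining the boundary.
#' @param ridge Ridge penalty on the slope coefficients.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `hdss_boundary`: `intercept`, `coefficients`
#'   (length 2), `threshold`, `accuracy` (training accuracy at the
#'   threshold), `converged`.
#' @export
fit_clinical_boundary <- function(embedding, clinical, threshold = 0.5,
                                  ridge = 1e-8, max_iter = 200L, tol = 1e-10) {
  pts <- if (inherits(embedding, "hdss_embedding")) embedding$points
         else as.matrix(embedding)
  stopifnot(ncol(pts) >= 2L, threshold > 0, threshold < 1)
  pts <- pts[, 1:2, drop = FALSE]
  y <- as.numeric(clinical)
  stopifnot(length(y) == nrow(pts), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("both classes must be present")

  X <- cbind(1, pts)
  P <- diag(c(0, ridge, ridge))
  beta <- c(stats::qlogis(mean(y)), 0, 0)
  pen_dev <- function(b) {
    eta <- drop(X %*% b)
    # stable log(1 + exp(eta)) = max(eta, 0) + log1p(exp(-|eta|))
    lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    -2 * sum(y * eta - lse) + drop(t(b) %*% P %*% b)
  }
  dev <- pen_dev(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - p)) - drop(P %*% beta)
    W <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * W, X) + P
    step <- solve(H, grad)
    # step halving on the penalized deviance
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      d_new <- pen_dev(cand)
      if (d_new <= dev + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- cand
    if (abs(dev - d_new) < tol * (abs(dev) + 1) && max(abs(grad)) < 1e-6) {
      converged <- TRUE
      dev <- d_new
      break
    }
    dev <- d_new
  }
  prob <- stats::plogis(drop(X %*% beta))
  acc <- mean((prob >= threshold) == (y == 1))
  structure(list(intercept = beta[1L], coefficients = beta[2:3],
                 threshold = threshold, accuracy = acc,
                 converged = converged),
            class = "hdss_boundary")
}

#' @export
print.hdss_boundary <- function(x, ...) {
  cat(sprintf(
    "<hdss_boundary> logit p = %.4g + %.4g*dim1 + %.4g*dim2 (p = %g line), accuracy %.3f\n",
    x$intercept, x$coefficients[1L], x$coefficients[2L], x$threshold,
    x$accuracy))
  invisible(x)
}

#' Classify points against a fitted boundary
#'
#' Labels 2-D points as clinical when the predicted probability meets the
#' threshold. Points exactly on the boundary line have probability equal to
#' the threshold and take the clinical label (conservative tie rule).
#'
#' @param boundary An `hdss_boundary`.
#' @param points n x 2 matrix (or length-2 vector) of embedding coordinates.
#' @return Data frame with `probability` and logical `clinical`.
#' @export
classify_region <- function(boundary, points) {
  stopifnot(inherits(boundary, "hdss_boundary"))
  pts <- if (is.null(dim(points))) matrix(points, ncol = 2L)
         else as.matrix(points)[, 1:2, drop = FALSE]
  eta <- boundary$intercept + drop(pts %*% boundary$coefficients)
  prob <- stats::plogis(eta)
  data.frame(probability = prob, clinical = prob >= boundary$threshold)
}
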