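#' Average person vector (centroid)
#'
#' Averages the feature vectors of a cohort (or of each demographic stratum)
#' to create a single reference point. Distance from this centroid acts as a
#' dynamically-normed severity index: when the centroid is fitted on the
#' same observations as the space, its standardized form is the zero vector,
#' so an observation's centroid distance equals the L2 norm of its
#' standardized row. Stratified centroids (one per combination of
#' demographic keys) support dynamic norming on identity features.
#'
#' @param space An `hdss_space`.
#' @param cohort Cohort supplying demographic columns; required when
#'   `stratify_by` is used. Rows must align with the space's observations.
#' @param stratify_by Character vector of demographic column names (e.g.
#'   `c("gender", "race")`), or `NULL` for the single global centroid.
#' @return A list of `hdss_centroid` objects (length 1 for the global
#'   case), each with `raw`, `std` (both feature-length vectors), `stratum`
#'   label, `n`, and the member observation ids.
#' @export
average_person_vector <- function(space, cohort = NULL, stratify_by = NULL) {
  stopifnot(inherits(space, "hdss_space"))
  make_centroid <- function(rows, label) {
    if (length(rows) < 2L) {
      stop(sprintf("stratum '%s' has fewer than 2 observations", label))
    }
    std <- colMeans(space$X[rows, , drop = FALSE])
    structure(list(raw = drop(unstandardize(space, std)), std = std,
                   stratum = label, n = length(rows),
                   members = rownames(space$X)[rows]),
              class = "hdss_centroid")
  }
  if (is.null(stratify_by)) {
    return(list(global = make_centroid(seq_len(nrow(space$X)), "global")))
  }
  stopifnot(!is.null(cohort), nrow(cohort) == nrow(space$X),
            all(stratify_by %in% names(cohort)))
  labels <- do.call(paste, c(unname(as.list(cohort[stratify_by])), sep = ":"))
  groups <- split(seq_len(nrow(space$X)), labels)
  out <- lapply(names(groups), function(g) make_centroid(groups[[g]], g))
  names(out) <- names(groups)
  out
}

#' @export
print.hdss_centroid <- function(x, ...) {
  cat(sprintf("<hdss_centroid> stratum '%s', n = %d, %d features\n",
              x$stratum, x$n, length(x$std)))
  invisible(x)
}

#' Distance of each observation from a centroid
#'
#' Euclidean distance in the standardized space between every observation
#' (or only the centroid's stratum members) and the centroid.
#'
#' @param space An `hdss_space`.
#' @param centroid An `hdss_centroid`.
#' @param restrict_to_stratum Score only the centroid's own stratum members
#'   (the dynamic-norming rule for stratified centroids).
#' @return Data frame with `person_id`, `timepoint`, `distance`.
#' @export
distance_from_centroid <- function(space, centroid, restrict_to_stratum = FALSE) {
  stopifnot(inherits(space, "hdss_space"), inherits(centroid, "hdss_centroid"))
  if (length(centroid$std) != ncol(space$X)) {
    stop(sprintf("dimension mismatch: centroid has %d features, space has %d",
                 length(centroid$std), ncol(space$X)))
  }
  rows <- seq_len(nrow(space$X))
  if (restrict_to_stratum) rows <- match(centroid$members, rownames(space$X))
  dev <- sweep(space$X[rows, , drop = FALSE], 2L, centroid$std)
  idx <- parse_obs_index(rownames(space$X)[rows])
  if (is.null(idx)) idx <- data.frame(person_id = as.character(rows),
                                      timepoint = 1L)
  cbind(idx, data.frame(distance = sqrt(rowSums(dev^2))))
}

#' Rose-diagram data for a disorder
#'
#' Samples persons meeting a disorder criterion at baseline (timepoint 1)
#' and returns, for each sampled person, their centroid distance at every
#' timepoint (the segment lengths of one bar of a rose diagram) together
#' with the diagnosis count at that timepoint (the color axis).
#'
#' @param distances Data frame from [distance_from_centroid()] covering all
#'   timepoints.
#' @param status An `hdss_status`.
#' @param disorder Name of the `dsm_proxy` scale defining eligibility.
#' @param n_sample Number of persons to sample (default 30).
#' @param seed Integer seed for the without-replacement sample.
#' @return Data frame with `person_id`, `timepoint`, `segment_length`,
#'   `diagnosis_count`, ordered by person then timepoint.
#' @export
rose_data <- function(distances, status, disorder, n_sample = 30L, seed = 1L) {
  elev <- status$elevations
  eligible <- unique(elev$person_id[
    elev$family == "dsm_proxy" & elev$scale == disorder &
      elev$timepoint == 1L & elev$elevated])
  if (length(eligible) == 0L) stop("no persons meet the criterion for ", disorder)
  eligible <- sort(eligible)
  if (length(eligible) < n_sample) {
    warning(sprintf("only %d eligible persons for %s; sampling all",
                    length(eligible), disorder))
    chosen <- eligible
  } else {
    chosen <- local_seed(seed, sample(eligible, n_sample))
  }
  d <- distances[distances$person_id %in% chosen, , drop = FALSE]
  s <- status$summary
  key <- paste(s$person_id, s$timepoint, sep = "@")
  out <- data.frame(
    person_id = d$person_id, timepoint = d$timepoint,
    segment_length = d$distance,
    diagnosis_count = s$n_diagnoses[match(paste(d$person_id, d$timepoint,
                                                sep = "@"), key)],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$person_id, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' Regression of centroid distance on diagnosis count
#'
#' Ordinary least squares of the per-observation centroid distance on the
#' number of proxy diagnoses (optionally with extra covariates), the
#' severity check that greater distance from the average person goes with
#' more diagnoses. BIC uses the Gaussian-likelihood convention with the
#' variance MLE, counting intercept + slopes + variance as parameters.
#'
#' @param distances Numeric vector of centroid distances.
#' @param diagnosis_counts Integer vector of diagnosis counts, same length.
#' @param covariates Optional data frame of extra regressors.
#' @return Object of class `hdss_regression`: coefficient table (estimate,
#'   t, p), `adj_r2`, `r2`, `bic`, `n`, and the underlying `lm` fit.
#' @export
severity_regression <- function(distances, diagnosis_counts, covariates = NULL) {
  n <- length(distances)
  stopifnot(length(diagnosis_counts) == n)
  if (n < 10L) stop("need at least 10 observations")
  if (stats::var(diagnosis_counts) == 0) stop("zero variance in diagnosis counts")
  df <- data.frame(distance = distances, n_diagnoses = diagnosis_counts)
  form <- distance ~ n_diagnoses
  if (!is.null(covariates)) {
    df <- cbind(df, covariates)
    form <- stats::reformulate(c("n_diagnoses", names(covariates)),
                               response = "distance")
  }
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)
  structure(
    list(coefficients = sm$coefficients, adj_r2 = sm$adj.r.squared,
         r2 = sm$r.squared, bic = stats::BIC(fit), n = n, fit = fit),
    class = "hdss_regression"
  )
}

#' @export
print.hdss_regression <- function(x, ...) {
  cat(sprintf("<hdss_regression> n = %d, adj. R^2 = %.3f, BIC = %.1f\n",
              x$n, x$adj_r2, x$bic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Correlation of centroid distance with total symptom score
#'
#' Pearson correlation (with p-value) between centroid distance and the
#' total symptom score, plus the slope of the simple regression of distance
#' on total score. Distance preserves the pattern of symptoms, not just
#' their sum, so the two track each other strongly but not perfectly.
#'
#' @param distances Numeric vector of centroid distances.
#' @param total_scores Numeric vector of total symptom scores, same length.
#' @return List with `r`, `p_value`, `slope`, `slope_t`, `n`.
#' @export
distance_severity_correlation <- function(distances, total_scores) {
  n <- length(distances)
  stopifnot(length(total_scores) == n)
  if (n < 10L) stop("need at least 10 observations")
  if (stats::var(distances) == 0 || stats::var(total_scores) == 0) {
    stop("zero variance input")
  }
  ct <- stats::cor.test(distances, total_scores, method = "pearson")
  fit <- summary(stats::lm(distances ~ total_scores))
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = fit$coefficients["total_scores", "Estimate"],
       slope_t = fit$coefficients["total_scores", "t value"], n = n)
}
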