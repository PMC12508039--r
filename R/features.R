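#' Define the feature space layout
#'
#' A feature specification fixes the columns of the raw design matrix: the
#' ordinal items in item order, then the demographic features, then age.
#' Two demographic encoding dialects are supported. `"onehot"` expands race
#' and gender into one indicator column per level (statistically cleaner,
#' the default). `"compact"` codes each as a single integer-coded column, so
#' 119 items + race + gender + age gives a 122-column space.
#'
#' @param cohort An `hdss_cohort` used to enumerate the categorical levels,
#'   or `NULL` if `race_levels`/`gender_levels` are given directly.
#' @param demographics Encoding dialect, `"onehot"` or `"compact"`.
#' @param n_items Number of item features; defaults to the cohort's.
#' @param race_levels,gender_levels Explicit level sets (sorted order is
#'   used when taken from the cohort).
#' @param include_demographics If `FALSE`, the space is items only.
#' @return An object of class `hdss_features`: a data frame with columns
#'   `name`, `kind` (item / demographic_dummy / demographic_code / age) and
#'   `source`, plus attributes recording the dialect and level sets.
#' @export
feature_spec <- function(cohort = NULL,
                         demographics = c("onehot", "compact"),
                         n_items = NULL,
                         race_levels = NULL, gender_levels = NULL,
                         include_demographics = TRUE) {
  demographics <- match.arg(demographics)
  if (!is.null(cohort)) {
    if (is.null(n_items)) n_items <- attr(cohort, "n_items")
    if (is.null(race_levels)) race_levels <- sort(unique(cohort$race))
    if (is.null(gender_levels)) gender_levels <- sort(unique(cohort$gender))
  }
  if (is.null(n_items)) n_items <- 119L
  items <- item_columns(n_items)
  spec <- data.frame(name = items, kind = "item", source = items,
                     stringsAsFactors = FALSE)
  if (include_demographics) {
    stopifnot(!is.null(race_levels), !is.null(gender_levels))
    if (demographics == "onehot") {
      dem <- data.frame(
        name = c(paste0("race_", race_levels), paste0("gender_", gender_levels)),
        kind = "demographic_dummy",
        source = c(rep("race", length(race_levels)),
                   rep("gender", length(gender_levels))),
        stringsAsFactors = FALSE
      )
    } else {
      dem <- data.frame(name = c("race", "gender"),
                        kind = "demographic_code",
                        source = c("race", "gender"),
                        stringsAsFactors = FALSE)
    }
    spec <- rbind(spec, dem,
                  data.frame(name = "age", kind = "age", source = "age",
                             stringsAsFactors = FALSE))
  }
  if (anyDuplicated(spec$name)) stop("duplicate feature names in spec")
  structure(spec, dialect = demographics, n_items = n_items,
            race_levels = race_levels, gender_levels = gender_levels,
            class = c("hdss_features", "data.frame"))
}

#' @export
print.hdss_features <- function(x, ...) {
  cat(sprintf("<hdss_features> %d features (%s demographics dialect)\n",
              nrow(x), attr(x, "dialect")))
  invisible(x)
}

#' Encode a cohort into the raw feature matrix
#'
#' Items pass through as raw ordinal values; race/gender are expanded per
#' the feature spec's dialect; age is carried as a real column. Column order matches
#' the feature specification exactly.
#'
#' @param cohort An `hdss_cohort`.
#' @param spec An `hdss_features` from [feature_spec()].
#' @return Numeric matrix (observations x features) with the observation id
#'   `"<person>@<timepoint>"` as rownames and feature names as colnames.
#' @export
encode_features <- function(cohort, spec) {
  stopifnot(inherits(spec, "hdss_features"))
  n <- nrow(cohort)
  check_levels <- function(col, levels) {
    unknown <- setdiff(unique(cohort[[col]]), levels)
    if (length(unknown) > 0L) {
      stop(sprintf("unknown %s level not in feature spec: %s",
                   col, unknown[[1L]]))
    }
  }
  out <- matrix(0, nrow = n, ncol = nrow(spec),
                dimnames = list(obs_ids(cohort), spec$name))
  for (k in seq_len(nrow(spec))) {
    kind <- spec$kind[k]; src <- spec$source[k]; nm <- spec$name[k]
    if (kind %in% c("item", "age")) {
      vals <- cohort[[src]]
      if (anyNA(vals)) {
        i <- which(is.na(vals))[1L]
        stop(sprintf("missing cell for person %s, timepoint %d, column %s",
                     cohort$person_id[i], cohort$timepoint[i], src))
      }
      out[, k] <- as.numeric(vals)
    } else if (kind == "demographic_dummy") {
      lv <- sub(paste0("^", src, "_"), "", nm)
      check_levels(src, attr(spec, paste0(src, "_levels")))
      out[, k] <- as.numeric(cohort[[src]] == lv)
    } else { # demographic_code
      levels <- attr(spec, paste0(src, "_levels"))
      check_levels(src, levels)
      out[, k] <- as.numeric(match(cohort[[src]], levels))
    }
  }
  out
}
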