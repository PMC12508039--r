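#' Construct an item-to-scale map
#'
#' A scale map groups items into named scales under two families: `hitop`
#' (broad dimensions: total problems, internalizing, externalizing,
#' attention, somatic) and `dsm_proxy` (DSM-oriented scales whose T-score
#' elevation defines a proxy diagnosis). Scales may overlap; the two
#' families share no scale names.
#'
#' @param hitop,dsm_proxy Named lists mapping scale name to integer item ids
#'   in `1..n_items`.
#' @param n_items Total number of items (ids are validated against it).
#' @return Object of class `hdss_scales`: list with `hitop`, `dsm_proxy`,
#'   `n_items`.
#' @export
scale_map <- function(hitop = list(), dsm_proxy = list(), n_items = 119L) {
  check_family <- function(fam, label) {
    for (nm in names(fam)) {
      ids <- as.integer(fam[[nm]])
      if (length(ids) == 0L) stop(sprintf("scale %s is empty", nm))
      if (any(ids < 1L | ids > n_items)) {
        stop(sprintf("scale %s (%s) references item ids outside 1..%d",
                     nm, label, n_items))
      }
      fam[[nm]] <- ids
    }
    fam
  }
  hitop <- check_family(hitop, "hitop")
  dsm_proxy <- check_family(dsm_proxy, "dsm_proxy")
  if (length(intersect(names(hitop), names(dsm_proxy))) > 0L) {
    stop("scale families must not share names")
  }
  structure(list(hitop = hitop, dsm_proxy = dsm_proxy, n_items = n_items),
            class = "hdss_scales")
}

#' @export
print.hdss_scales <- function(x, ...) {
  cat(sprintf("<hdss_scales> hitop: %s | dsm_proxy: %s\n",
              paste(names(x$hitop), collapse = ", "),
              paste(names(x$dsm_proxy), collapse = ", ")))
  invisible(x)
}

#' Read / write a scale map as YAML
#'
#' The YAML layout is `families: {hitop: {scale: [ids]}, dsm_proxy: ...}`
#' with an `n_items` entry.
#'
#' @param path YAML file path.
#' @return For the reader, an `hdss_scales`; the writer returns `path`
#'   invisibly.
#' @export
read_scale_map <- function(path) {
  y <- yaml::read_yaml(path)
  scale_map(hitop = y$families$hitop, dsm_proxy = y$families$dsm_proxy,
            n_items = y$n_items)
}

#' @rdname read_scale_map
#' @param scales An `hdss_scales`.
#' @export
write_scale_map <- function(scales, path) {
  yaml::write_yaml(list(n_items = scales$n_items,
                        families = list(hitop = scales$hitop,
                                        dsm_proxy = scales$dsm_proxy)),
                   path)
  invisible(path)
}

#' Raw scale scores
#'
#' The raw score of a scale is the plain sum of its item responses;
#' overlapping scales count shared items independently.
#'
#' @param cohort An `hdss_cohort`.
#' @param scales An `hdss_scales`.
#' @return Data frame (class `hdss_raw_scores`) with columns `person_id`,
#'   `timepoint`, `family`, `scale`, `raw_score`.
#' @export
raw_scale_scores <- function(cohort, scales) {
  stopifnot(inherits(scales, "hdss_scales"))
  n_items <- attr(cohort, "n_items")
  if (scales$n_items > n_items) {
    stop(sprintf("scale map references item ids up to %d but cohort has %d items",
                 scales$n_items, n_items))
  }
  item_mat <- as.matrix(cohort[item_columns(n_items)])
  one_family <- function(fam, label) {
    if (length(fam) == 0L) return(NULL)
    do.call(rbind, lapply(names(fam), function(nm) {
      data.frame(person_id = cohort$person_id, timepoint = cohort$timepoint,
                 family = label, scale = nm,
                 raw_score = as.integer(rowSums(item_mat[, fam[[nm]], drop = FALSE])),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one_family(scales$hitop, "hitop"),
               one_family(scales$dsm_proxy, "dsm_proxy"))
  rownames(out) <- NULL
  class(out) <- c("hdss_raw_scores", "data.frame")
  out
}

#' Norm-referenced T-scores from a reference sample
#'
#' Converts raw scale scores to T-scores against a designated reference
#' sample: `T = 50 + 10 * (raw - mean_ref) / sd_ref`, per scale (and per
#' stratum when `strata` is given, which emulates demographically
#' conditioned norms). With the conventional clinical threshold T >= 65 this
#' selects observations at least 1.5 reference SDs above the reference mean.
#'
#' @param scores An `hdss_raw_scores` table.
#' @param reference Reference rows of the same layout; defaults to `scores`
#'   itself (the whole sample is its own norm).
#' @param strata Optional named character vector (or factor) of stratum
#'   labels per observation id `"<person>@<timepoint>"`, applied to both
#'   subject and reference rows; norms are then computed within stratum.
#' @return Data frame of class `hdss_tscores` with columns `person_id`,
#'   `timepoint`, `family`, `scale`, `raw_score`, `t_score`.
#' @export
tscores_from_reference <- function(scores, reference = scores, strata = NULL) {
  stopifnot(is.data.frame(scores), is.data.frame(reference))
  stratum_of <- function(df) {
    if (is.null(strata)) return(rep("all", nrow(df)))
    as.character(strata[paste(df$person_id, df$timepoint, sep = "@")])
  }
  scores$.stratum <- stratum_of(scores)
  reference$.stratum <- stratum_of(reference)
  key <- function(df) paste(df$scale, df$.stratum, sep = "|")
  ref_split <- split(reference$raw_score, key(reference))
  mu <- vapply(ref_split, mean, 0)
  sd_pop <- vapply(ref_split, function(x) sqrt(mean((x - mean(x))^2)), 0)
  n_ref <- vapply(ref_split, length, 0L)
  if (any(n_ref < 30L)) {
    warning("reference sample has < 30 observations for some scale/stratum")
  }
  zero_sd <- names(sd_pop)[sd_pop == 0]
  if (length(zero_sd) > 0L) {
    stop("zero reference SD for scale: ",
         paste(sub("\\|.*$", "", zero_sd), collapse = ", "))
  }
  k <- key(scores)
  miss <- setdiff(unique(k), names(mu))
  if (length(miss) > 0L) stop("no reference norms for: ", paste(miss, collapse = ", "))
  scores$t_score <- 50 + 10 * (scores$raw_score - mu[k]) / sd_pop[k]
  scores$.stratum <- NULL
  class(scores) <- c("hdss_tscores", "data.frame")
  scores
}

#' Assign clinical status from T-scores
#'
#' A scale is elevated when its T-score meets the threshold (inclusive,
#' default 65, i.e. +1.5 reference SDs). The diagnosis count is the number
#' of elevated `dsm_proxy` scales; `any_clinical` flags observations with at
#' least one proxy diagnosis (the DSM reading) and `total_clinical` flags
#' elevation on the total-problems dimension (the dimensional reading used
#' for the clinical decision boundary).
#'
#' @param tscores An `hdss_tscores` table.
#' @param threshold Elevation threshold on the T-score scale (default 65).
#' @param total_scale Name of the total-problems scale.
#' @return Object of class `hdss_status`: list with `elevations` (long data
#'   frame with `elevated` flags) and `summary` (one row per observation:
#'   `n_diagnoses`, `any_clinical`, `total_clinical`).
#' @export
assign_clinical_status <- function(tscores, threshold = 65,
                                   total_scale = "total_problems") {
  stopifnot(is.finite(threshold))
  elev <- as.data.frame(tscores)
  elev$elevated <- elev$t_score >= threshold
  id <- paste(elev$person_id, elev$timepoint, sep = "@")
  ids <- unique(id)
  dsm <- elev$family == "dsm_proxy"
  n_diag <- integer(length(ids))
  counts <- tapply(elev$elevated[dsm], id[dsm], sum)
  n_diag[match(names(counts), ids)] <- as.integer(counts)
  tot <- elev$scale == total_scale
  total_clin <- logical(length(ids))
  tc <- tapply(elev$elevated[tot], id[tot], any)
  total_clin[match(names(tc), ids)] <- as.logical(tc)
  first <- match(ids, id)
  summary <- data.frame(
    person_id = elev$person_id[first], timepoint = elev$timepoint[first],
    n_diagnoses = n_diag, any_clinical = n_diag > 0L,
    total_clinical = total_clin, stringsAsFactors = FALSE
  )
  summary <- summary[order(summary$person_id, summary$timepoint), ]
  rownames(summary) <- NULL
  structure(list(elevations = elev, summary = summary, threshold = threshold),
            class = "hdss_status")
}

#' @export
print.hdss_status <- function(x, ...) {
  cat(sprintf(
    "<hdss_status> %d observations, threshold T >= %g, %.1f%% any-clinical\n",
    nrow(x$summary), x$threshold, 100 * mean(x$summary$any_clinical)))
  invisible(x)
}
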