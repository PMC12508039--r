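#' Build per-person trajectories through the common space
#'
#' Assembles, for every person, their ordered sequence of positions in the
#' joint 2-D embedding together with their full-space centroid distance,
#' clinical status and diagnosis count at each timepoint. All coordinates
#' must come from one joint embedding so positions are comparable across
#' timepoints.
#'
#' @param embedding An `hdss_embedding` whose rownames are observation ids
#'   `"<person>@<timepoint>"`.
#' @param status An `hdss_status` covering the same observations.
#' @param centroid_distances Data frame from [distance_from_centroid()].
#' @param clinical_field Which status flag to carry as `clinical`
#'   (`"total_clinical"` or `"any_clinical"`).
#' @return Data frame of class `hdss_trajectories`, one row per
#'   person-timepoint with columns `person_id`, `timepoint`, `dim1`,
#'   `dim2`, `centroid_distance`, `clinical`, `n_diagnoses`, ordered by
#'   person then timepoint.
#' @export
build_trajectories <- function(embedding, status, centroid_distances,
                               clinical_field = c("total_clinical",
                                                  "any_clinical")) {
  clinical_field <- match.arg(clinical_field)
  pts <- embedding$points
  ids <- rownames(pts)
  if (is.null(ids)) stop("embedding lacks observation ids")
  if (anyDuplicated(ids)) {
    stop("duplicate (person, timepoint) in embedding: ",
         ids[duplicated(ids)][1L])
  }
  idx <- parse_obs_index(ids)
  s <- status$summary
  skey <- paste(s$person_id, s$timepoint, sep = "@")
  dkey <- paste(centroid_distances$person_id, centroid_distances$timepoint,
                sep = "@")
  out <- data.frame(
    person_id = idx$person_id, timepoint = idx$timepoint,
    dim1 = pts[, 1L], dim2 = pts[, 2L],
    centroid_distance = centroid_distances$distance[match(ids, dkey)],
    clinical = s[[clinical_field]][match(ids, skey)],
    n_diagnoses = s$n_diagnoses[match(ids, skey)],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$person_id, out$timepoint), ]
  rownames(out) <- NULL
  class(out) <- c("hdss_trajectories", "data.frame")
  out
}

#' Per-step displacements along trajectories
#'
#' Euclidean distance between consecutive positions of each person, either
#' in the 2-D embedding or in the full standardized space. Note the
#' embedded displacement is not guaranteed to bound the full-space one in
#' either direction (MDS is not a contraction).
#'
#' @param trajectories An `hdss_trajectories`.
#' @param metric `"embedded"` (uses `dim1`/`dim2`) or `"fullspace"`
#'   (requires `space`).
#' @param space The `hdss_space`, required for `metric = "fullspace"`.
#' @return Data frame with `person_id`, `from_timepoint`, `to_timepoint`,
#'   `displacement`.
#' @export
step_displacements <- function(trajectories,
                               metric = c("embedded", "fullspace"),
                               space = NULL) {
  metric <- match.arg(metric)
  tr <- trajectories[order(trajectories$person_id, trajectories$timepoint), ]
  if (metric == "fullspace") {
    stopifnot(!is.null(space))
    coords <- space$X[match(obs_ids(tr), rownames(space$X)), , drop = FALSE]
  } else {
    coords <- as.matrix(tr[c("dim1", "dim2")])
  }
  same_person <- tr$person_id[-1L] == tr$person_id[-nrow(tr)]
  steps <- which(same_person)
  disp <- sqrt(rowSums((coords[steps + 1L, , drop = FALSE] -
                          coords[steps, , drop = FALSE])^2))
  data.frame(person_id = tr$person_id[steps],
             from_timepoint = tr$timepoint[steps],
             to_timepoint = tr$timepoint[steps + 1L],
             displacement = disp, stringsAsFactors = FALSE)
}

#' Detect clinical boundary crossings
#'
#' Classifies every trajectory position against the fitted boundary and
#' emits one event per consecutive pair of timepoints whose region labels
#' differ: `improved` (clinical region to non-clinical) or `worsened`
#' (non-clinical to clinical). Crossings are attributed to the step, not
#' interpolated within it. `by_tscore = TRUE` uses the carried T-score
#' clinical flag instead of the geometric region label.
#'
#' @param trajectories An `hdss_trajectories`.
#' @param boundary An `hdss_boundary` fitted on the same embedding.
#' @param by_tscore Use the `clinical` column instead of boundary labels.
#' @return Data frame of class `hdss_transitions`: `person_id`,
#'   `from_timepoint`, `to_timepoint`, `direction`.
#' @export
detect_transitions <- function(trajectories, boundary, by_tscore = FALSE) {
  tr <- trajectories[order(trajectories$person_id, trajectories$timepoint), ]
  lab <- if (by_tscore) {
    as.logical(tr$clinical)
  } else {
    classify_region(boundary, as.matrix(tr[c("dim1", "dim2")]))$clinical
  }
  same_person <- tr$person_id[-1L] == tr$person_id[-nrow(tr)]
  steps <- which(same_person & lab[-1L] != lab[-nrow(tr)])
  out <- data.frame(
    person_id = tr$person_id[steps],
    from_timepoint = tr$timepoint[steps],
    to_timepoint = tr$timepoint[steps + 1L],
    direction = ifelse(lab[steps], "improved", "worsened"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("hdss_transitions", "data.frame")
  out
}
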