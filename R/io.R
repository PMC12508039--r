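#' Write / read a distance matrix as CSV
#'
#' The CSV carries the observation ids as both header row and first
#' column. Values are written with 17 significant digits so round-trips
#' are lossless at double precision.
#'
#' @param dist An `hdss_dist` (or plain matrix with dimnames).
#' @param path CSV path.
#' @return The writer returns `path` invisibly; the reader an `hdss_dist`.
#' @export
write_distance_csv <- function(dist, path) {
  d <- if (inherits(dist, "hdss_dist")) dist$d else as.matrix(dist)
  df <- data.frame(obs = rownames(d), stringsAsFactors = FALSE,
                   check.names = FALSE)
  df[colnames(d)] <- as.data.frame(d)
  write_num_csv(df, path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(list(d = m, index = parse_obs_index(rownames(m))),
            class = "hdss_dist")
}

#' Write standardization parameters as a JSON sidecar
#'
#' Records per-feature raw means, population SDs and constant-feature
#' flags of a fitted space so new observations can be projected with the
#' frozen parameters.
#'
#' @param space An `hdss_space`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_space_params <- function(space, path) {
  jsonlite::write_json(
    list(features = names(space$mu), mu = unname(space$mu),
         sigma = unname(space$sigma), constant = unname(space$constant)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an embedding as CSV
#'
#' @param embedding An `hdss_embedding`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(embedding, path) {
  idx <- parse_obs_index(rownames(embedding$points))
  df <- cbind(idx, as.data.frame(embedding$points))
  names(df)[-(1:2)] <- paste0("dim", seq_len(ncol(embedding$points)))
  write_num_csv(df, path)
}

#' Write a fitted boundary as JSON
#'
#' @param boundary An `hdss_boundary`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_boundary_json <- function(boundary, path) {
  jsonlite::write_json(
    list(intercept = boundary$intercept,
         coefficients = unname(boundary$coefficients),
         threshold = boundary$threshold, accuracy = boundary$accuracy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundary_json
#' @export
read_boundary_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = b$intercept, coefficients = b$coefficients,
                 threshold = b$threshold, accuracy = b$accuracy,
                 converged = NA),
            class = "hdss_boundary")
}
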