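#' @keywords internal
"_PACKAGE"

#' Names of the ordinal item columns
#'
#' Item columns follow the fixed naming scheme `item_001 .. item_NNN`.
#'
#' @param n_items Number of items (default 119, the CBCL item count).
#' @return Character vector of column names in item order.
#' @export
item_columns <- function(n_items = 119L) sprintf("item_%03d", seq_len(n_items))

#' Construct and validate a cohort table
#'
#' A cohort table holds one row per (person, timepoint) observation: ordinal
#' item responses scored 0/1/2 plus demographic covariates (`race`, `gender`,
#' `age`). This is the raw input to every downstream stage.
#'
#' @param df A data frame with columns `person_id`, `timepoint`,
#'   `item_001..item_NNN`, `race`, `gender`, `age`.
#' @param n_items Number of item columns expected; `NULL` autodetects from
#'   the `item_` columns present.
#' @param complete_cases If `TRUE`, retain only persons observed at every
#'   timepoint `1..n_timepoints` with no missing cells; the number of persons
#'   dropped is reported and stored in `attr(, "n_dropped")`.
#' @param n_timepoints Number of timepoints required in complete-case mode;
#'   `NULL` uses the maximum observed timepoint.
#' @return The validated data frame with class `hdss_cohort`.
#' @export
as_cohort <- function(df, n_items = NULL, complete_cases = FALSE,
                      n_timepoints = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df)
  if (is.null(n_items)) {
    n_items <- sum(grepl("^item_\\d+$", names(df)))
    if (n_items == 0L) stop("no item_* columns found")
  }
  items <- item_columns(n_items)
  needed <- c("person_id", "timepoint", items, "race", "gender", "age")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$person_id <- as.character(df$person_id)
  df$timepoint <- as.integer(df$timepoint)
  df$age <- as.numeric(df$age)
  for (ic in items) df[[ic]] <- as.integer(df[[ic]])

  key <- paste(df$person_id, df$timepoint, sep = "@")
  if (anyDuplicated(key)) {
    stop("duplicate (person_id, timepoint) pairs: ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = ", "))
  }
  item_mat <- as.matrix(df[items])
  bad <- which(!is.na(item_mat) & !(item_mat %in% c(0L, 1L, 2L)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("item value out of range {0,1,2} at row %d, column %s",
                 bad[1L, 1L], items[bad[1L, 2L]]))
  }

  n_dropped <- 0L
  if (complete_cases) {
    if (is.null(n_timepoints)) n_timepoints <- max(df$timepoint)
    has_na <- rowSums(is.na(df[needed])) > 0L
    ok_rows <- !has_na & df$timepoint %in% seq_len(n_timepoints)
    tp_count <- tapply(df$timepoint[ok_rows], df$person_id[ok_rows],
                       function(t) length(unique(t)))
    keep_persons <- names(tp_count)[tp_count == n_timepoints]
    n_dropped <- length(unique(df$person_id)) - length(keep_persons)
    df <- df[ok_rows & df$person_id %in% keep_persons, , drop = FALSE]
    if (n_dropped > 0L) {
      message(sprintf("complete-case filter dropped %d person(s)", n_dropped))
    }
  } else if (anyNA(df[needed])) {
    nas <- which(is.na(df[needed]), arr.ind = TRUE)
    stop(sprintf(
      "missing cell for person %s, timepoint %d, column %s (use complete_cases = TRUE to filter)",
      df$person_id[nas[1L, 1L]], df$timepoint[nas[1L, 1L]], needed[nas[1L, 2L]]))
  }

  df <- df[order(df$person_id, df$timepoint), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_items = n_items, n_dropped = n_dropped,
            class = c("hdss_cohort", "data.frame"))
}

#' @export
print.hdss_cohort <- function(x, ...) {
  cat(sprintf("<hdss_cohort> %d observations, %d persons, %d items\n",
              nrow(x), length(unique(x$person_id)), attr(x, "n_items")))
  invisible(x)
}

#' Observation identifiers
#'
#' @param x An `hdss_cohort` or any data frame with `person_id` and
#'   `timepoint` columns.
#' @return Character vector `"<person_id>@<timepoint>"`, one per row.
#' @export
obs_ids <- function(x) paste(x$person_id, x$timepoint, sep = "@")

#' Read a cohort table from CSV
#'
#' Wide format has one row per person-timepoint with `item_*` columns; long
#' format has columns `person_id,timepoint,variable,value`. `"auto"` detects
#' the layout from the header.
#'
#' @param path CSV file path.
#' @param format `"auto"`, `"wide"` or `"long"`.
#' @inheritParams as_cohort
#' @return An `hdss_cohort`.
#' @export
read_cohort <- function(path, format = c("auto", "wide", "long"),
                        complete_cases = FALSE, n_timepoints = NULL) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if ("variable" %in% names(df) && "value" %in% names(df))
      "long" else "wide"
  }
  if (format == "long") df <- long_to_wide(df)
  as_cohort(df, complete_cases = complete_cases, n_timepoints = n_timepoints)
}

long_to_wide <- function(df) {
  stopifnot(all(c("person_id", "timepoint", "variable", "value") %in% names(df)))
  key <- paste(df$person_id, df$timepoint, sep = "@")
  obs <- unique(key)
  vars <- unique(df$variable)
  m <- matrix(NA_character_, nrow = length(obs), ncol = length(vars),
              dimnames = list(obs, vars))
  m[cbind(match(key, obs), match(df$variable, vars))] <- as.character(df$value)
  out <- data.frame(
    person_id = df$person_id[match(obs, key)],
    timepoint = df$timepoint[match(obs, key)],
    stringsAsFactors = FALSE
  )
  for (v in vars) {
    col <- m[, v]
    out[[v]] <- if (v %in% c("race", "gender")) col else as.numeric(col)
  }
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort An `hdss_cohort`.
#' @param path Output CSV path.
#' @param format `"wide"` (default) or `"long"`.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- as.data.frame(cohort)
  if (format == "long") {
    vars <- setdiff(names(df), c("person_id", "timepoint"))
    df <- data.frame(
      person_id = rep(df$person_id, times = length(vars)),
      timepoint = rep(df$timepoint, times = length(vars)),
      variable  = rep(vars, each = nrow(df)),
      value     = unlist(lapply(df[vars], as.character), use.names = FALSE),
      stringsAsFactors = FALSE
    )
    df <- df[order(df$person_id, df$timepoint, df$variable), ]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
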