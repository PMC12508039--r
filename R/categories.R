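#' Category membership from clinical status
#'
#' Builds the observation-by-category membership used for within/between
#' distance analysis: an observation belongs to every scale of the chosen
#' family on which it is elevated (comorbid observations carry multiple
#' labels; many carry none).
#'
#' @param status An `hdss_status`.
#' @param family `"dsm_proxy"` or `"hitop"`.
#' @param timepoint Timepoint to restrict to (default 1, baseline);
#'   `NULL` keeps all observations.
#' @return Object of class `hdss_categories`: logical membership matrix
#'   (observation ids x category labels) plus the family tag.
#' @export
category_assignment <- function(status, family = c("dsm_proxy", "hitop"),
                                timepoint = 1L) {
  family <- match.arg(family)
  elev <- status$elevations
  elev <- elev[elev$family == family, , drop = FALSE]
  if (!is.null(timepoint)) {
    elev <- elev[elev$timepoint %in% timepoint, , drop = FALSE]
  }
  if (nrow(elev) == 0L) stop("no observations for family ", family)
  ids <- sort(unique(paste(elev$person_id, elev$timepoint, sep = "@")))
  labels <- sort(unique(elev$scale))
  m <- matrix(FALSE, length(ids), length(labels),
              dimnames = list(ids, labels))
  m[cbind(match(paste(elev$person_id, elev$timepoint, sep = "@"), ids),
          match(elev$scale, labels))] <- elev$elevated
  structure(list(membership = m, family = family), class = "hdss_categories")
}

#' Within- versus between-category mean distances
#'
#' For each pair of categories, averages the Euclidean distance over member
#' pairs: diagonal cells average over unordered pairs of distinct members
#' of one category; off-diagonal cells average over pairs (a in C1, b in
#' C2, a != b). Comorbid observations contribute to every category they
#' hold. Categories with fewer than 2 members are flagged and excluded from
#' the summaries. If categorization carved the space well, diagonal
#' (within) values would sit clearly below the off-diagonal (between) ones;
#' transdiagnostic symptom overlap erodes that gap.
#'
#' @param dist An `hdss_dist` (full-space distances by default; pass a
#'   distance matrix built from embedding coordinates to reproduce the
#'   2-D reading).
#' @param assign An `hdss_categories`.
#' @return Object of class `hdss_category_distance`: `means` (K x K),
#'   `pair_counts` (K x K), `flagged` (logical per category), `family`.
#' @export
within_between_matrix <- function(dist, assign) {
  stopifnot(inherits(assign, "hdss_categories"))
  d <- if (inherits(dist, "hdss_dist")) dist$d else as.matrix(dist)
  m <- assign$membership
  idx <- match(rownames(m), rownames(d))
  if (anyNA(idx)) stop("membership observations missing from distance matrix")
  K <- ncol(m)
  labels <- colnames(m)
  means <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  sumsq <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  counts <- matrix(0, K, K, dimnames = list(labels, labels))
  sizes <- colSums(m)
  flagged <- sizes < 2L
  if (any(flagged)) {
    warning("categories with < 2 members flagged: ",
            paste(labels[flagged], collapse = ", "))
  }
  for (a in seq_len(K)) {
    ia <- idx[m[, a]]
    for (b in a:K) {
      ib <- idx[m[, b]]
      if (a == b) {
        if (length(ia) >= 2L) {
          np <- length(ia) * (length(ia) - 1L) / 2L
          means[a, a] <- sum(d[ia, ia]) / 2 / np
          sumsq[a, a] <- sum(d[ia, ia]^2) / 2
          counts[a, a] <- np
        }
      } else {
        shared <- length(intersect(ia, ib))
        np <- length(ia) * length(ib) - shared  # drop a == b self-pairs
        if (np > 0L && length(ia) > 0L && length(ib) > 0L) {
          means[a, b] <- means[b, a] <- sum(d[ia, ib]) / np
          sumsq[a, b] <- sumsq[b, a] <- sum(d[ia, ib]^2)
          counts[a, b] <- counts[b, a] <- np
        }
      }
    }
  }
  structure(list(means = means, sumsq = sumsq, pair_counts = counts,
                 flagged = flagged, family = assign$family),
            class = "hdss_category_distance")
}

#' @export
print.hdss_category_distance <- function(x, ...) {
  cat(sprintf("<hdss_category_distance> %s, %d categories\n",
              x$family, ncol(x$means)))
  print(round(x$means, 3))
  invisible(x)
}

#' Summarize within- versus between-category distances
#'
#' Mean and SD of the diagonal (within) and upper-triangle off-diagonal
#' (between) cell values, taken over category-level cells by default —
#' matching a matrix-of-means presentation. `pooled = TRUE` instead pools
#' all raw pairs, weighting each cell by its pair count.
#'
#' @param summary An `hdss_category_distance`.
#' @param pooled Pool over raw pairs instead of cell values.
#' @return Named list: `m_within`, `sd_within`, `m_between`, `sd_between`,
#'   `n_within_cells`, `n_between_cells`.
#' @export
summarize_within_between <- function(summary, pooled = FALSE) {
  stopifnot(inherits(summary, "hdss_category_distance"))
  ok <- !summary$flagged
  if (sum(ok) < 2L) stop("need at least 2 non-flagged categories")
  mm <- summary$means[ok, ok, drop = FALSE]
  cc <- summary$pair_counts[ok, ok, drop = FALSE]
  qq <- summary$sumsq[ok, ok, drop = FALSE]
  within <- diag(mm)
  between <- mm[upper.tri(mm)]
  wcount <- diag(cc); wsq <- diag(qq)
  bcount <- cc[upper.tri(cc)]; bsq <- qq[upper.tri(qq)]
  keep_b <- !is.na(between)
  between <- between[keep_b]; bcount <- bcount[keep_b]; bsq <- bsq[keep_b]
  if (pooled) {
    # pair-pooled mean and population SD from per-cell sums of d and d^2
    pool <- function(mn, n, sq) {
      mu <- sum(mn * n) / sum(n)
      list(m = mu, s = sqrt(sum(sq) / sum(n) - mu^2))
    }
    w <- pool(within, wcount, wsq)
    b <- pool(between, bcount, bsq)
    list(m_within = w$m, sd_within = w$s, m_between = b$m, sd_between = b$s,
         n_within_cells = length(within), n_between_cells = length(between))
  } else {
    list(m_within = mean(within), sd_within = stats::sd(within),
         m_between = mean(between), sd_between = stats::sd(between),
         n_within_cells = length(within), n_between_cells = length(between))
  }
}
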