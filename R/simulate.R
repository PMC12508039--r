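#' Configure a synthetic CBCL-like cohort
#'
#' Specifies a longitudinal ordinal-item cohort with known latent
#' structure: person-level factor scores follow a stationary AR(1) across
#' timepoints, items load on a dominant factor (with a share of
#' transdiagnostic items cross-loading on others), and 0/1/2 responses
#' arise from a probit graded-response mechanism with shared cutpoints.
#' Demographics are sampled from an independent mixture.
#'
#' The latent item propensity is `x = lambda' theta + e` with unit-normal
#' noise `e`; the response is 0 below `cutpoints[1]`, 1 between the
#' cutpoints, 2 above `cutpoints[2]`. Factor scores evolve as
#' `theta_t = drift + rho * theta_{t-1} + sqrt(1 - rho^2) * eta_t`, with
#' innovations drawn from the factor correlation matrix, so the stationary
#' marginal distribution is preserved when drift is zero.
#'
#' @param n_persons Number of persons.
#' @param n_items Number of ordinal items (default 119).
#' @param n_timepoints Number of annual timepoints (default 4).
#' @param n_factors Number of latent factors (default 5).
#' @param factor_names Names for the factors; the first five default to
#'   internalizing/externalizing/attention/somatic/thought analogues.
#' @param factor_cor Exchangeable factor correlation (scalar) or a full
#'   symmetric positive-definite correlation matrix.
#' @param loading_dominant Loading of each item on its dominant factor.
#' @param loading_cross Cross-loading of transdiagnostic items on each of
#'   two other factors.
#' @param overlap_share Share of items in `[0, 1]` that are
#'   transdiagnostic (cross-loading).
#' @param cutpoints Two increasing thresholds `(tau1, tau2)` on the
#'   propensity scale.
#' @param ar1 AR(1) coefficient `rho` in `[0, 1)`.
#' @param drift Per-timepoint drift, scalar or per-factor vector (negative
#'   values make the cohort improve over time).
#' @param race_levels,race_probs,gender_levels,gender_probs Demographic
#'   mixture (probabilities must sum to 1).
#' @param age_range Baseline age range in years (uniform); age advances one
#'   year per timepoint.
#' @param confound_age If `TRUE`, baseline age is shifted with the first
#'   factor score to exercise stratified-centroid analyses.
#' @param seed Root seed; all randomness derives from it.
#' @return Object of class `hdss_config` (a validated list).
#' @export
simulation_config <- function(n_persons = 1000L, n_items = 119L,
                              n_timepoints = 4L, n_factors = 5L,
                              factor_names = NULL,
                              factor_cor = 0.4,
                              loading_dominant = 1.0, loading_cross = 0.5,
                              overlap_share = 0.3,
                              cutpoints = c(1.0, 2.2),
                              ar1 = 0.7, drift = 0,
                              race_levels = c("asian", "black", "hispanic",
                                              "other", "white"),
                              race_probs = c(0.06, 0.15, 0.20, 0.07, 0.52),
                              gender_levels = c("female", "male"),
                              gender_probs = c(0.48, 0.52),
                              age_range = c(9, 11),
                              confound_age = FALSE,
                              seed = 1L) {
  if (is.null(factor_names)) {
    base <- c("internalizing", "externalizing", "attention", "somatic",
              "thought")
    factor_names <- if (n_factors <= 5L) base[seq_len(n_factors)]
                    else c(base, paste0("factor_", 6:n_factors))
  }
  if (length(factor_cor) == 1L) {
    R <- matrix(factor_cor, n_factors, n_factors)
    diag(R) <- 1
  } else {
    R <- as.matrix(factor_cor)
  }
  if (!isTRUE(all.equal(R, t(R)))) stop("factor correlation matrix must be symmetric")
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) stop("factor correlation matrix is not positive-definite")
  stopifnot(length(cutpoints) == 2L, cutpoints[1L] < cutpoints[2L],
            ar1 >= 0, ar1 < 1,
            overlap_share >= 0, overlap_share <= 1,
            abs(sum(race_probs) - 1) < 1e-8,
            abs(sum(gender_probs) - 1) < 1e-8,
            length(race_probs) == length(race_levels),
            length(gender_probs) == length(gender_levels))
  drift <- rep_len(drift, n_factors)
  structure(
    list(n_persons = as.integer(n_persons), n_items = as.integer(n_items),
         n_timepoints = as.integer(n_timepoints),
         n_factors = as.integer(n_factors), factor_names = factor_names,
         factor_cor = R, chol_cor = ch,
         loading_dominant = loading_dominant, loading_cross = loading_cross,
         overlap_share = overlap_share, cutpoints = cutpoints, ar1 = ar1,
         drift = drift, race_levels = race_levels, race_probs = race_probs,
         gender_levels = gender_levels, gender_probs = gender_probs,
         age_range = age_range, confound_age = confound_age,
         seed = as.integer(seed)),
    class = "hdss_config"
  )
}

#' @export
print.hdss_config <- function(x, ...) {
  cat(sprintf(
    "<hdss_config> n = %d, %d items x %d timepoints, %d factors, overlap %.2f, rho %.2f, seed %d\n",
    x$n_persons, x$n_items, x$n_timepoints, x$n_factors, x$overlap_share,
    x$ar1, x$seed))
  invisible(x)
}

#' Named simulation presets
#'
#' `paper_like` emulates the study conditions of a large longitudinal
#' CBCL cohort: 1000 persons, 119 items, 4 timepoints, 5 correlated
#' factors, transdiagnostic overlap share 0.3 and AR(1) rho 0.7.
#' `disjoint` removes all cross-loadings (overlap 0), `high_overlap`
#' raises the overlap share to 0.6, and `improving` is a smaller cohort
#' (n = 400) whose factors drift downward (-0.2 per year), so symptoms
#' abate over time.
#'
#' @param name One of `"disjoint"`, `"paper_like"`, `"high_overlap"`,
#'   `"improving"`.
#' @param seed Root seed for the returned config.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return An `hdss_config`.
#' @export
hdss_preset <- function(name, seed = 42L, ...) {
  presets <- list(
    disjoint     = list(overlap_share = 0),
    paper_like   = list(overlap_share = 0.3),
    high_overlap = list(overlap_share = 0.6),
    improving    = list(n_persons = 400L, drift = -0.2)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(presets[[name]], list(seed = seed, ...))
  do.call(simulation_config, args)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a full longitudinal cohort under a [simulation_config()]:
#' baseline factor scores from the correlated multivariate normal, AR(1)
#' evolution across timepoints, probit graded responses, and independent
#' demographics. Also emits the planted truth (factor scores, loading
#' matrix, per-person true severity = L2 norm of the positive part of the
#' mean factor score — the planted symptom load on a floor-bounded
#' checklist — plus the symmetric factor-score norm as `latent_norm`)
#' and a default scale map grouping items by their dominant factor, with a
#' total-problems scale over all items.
#'
#' @param config An `hdss_config`.
#' @return Object of class `hdss_simulation`: list with `cohort`
#'   (`hdss_cohort`), `truth` (list: `theta` long data frame, `loadings`,
#'   `cutpoints`, `severity` data frame), and `scales` (`hdss_scales`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "hdss_config"))
  cf <- config
  local_seed(cf$seed, {
    n <- cf$n_persons; p <- cf$n_items; tt <- cf$n_timepoints
    k <- cf$n_factors
    person_ids <- sprintf("p%05d", seq_len(n))

    # item -> dominant factor, round-robin so groups are near-equal
    dominant <- rep_len(seq_len(k), p)
    Lambda <- matrix(0, p, k,
                     dimnames = list(item_columns(p), cf$factor_names))
    Lambda[cbind(seq_len(p), dominant)] <- cf$loading_dominant
    n_trans <- round(cf$overlap_share * p)
    trans_items <- if (n_trans > 0L) sort(sample.int(p, n_trans)) else integer(0)
    for (it in trans_items) {
      others <- setdiff(seq_len(k), dominant[it])
      cross <- sample(others, min(2L, length(others)))
      Lambda[it, cross] <- cf$loading_cross
    }

    # AR(1) factor scores, stationary marginal N(0, R) when drift = 0
    theta <- array(0, dim = c(n, k, tt))
    theta[, , 1L] <- matrix(stats::rnorm(n * k), n, k) %*% cf$chol_cor
    if (tt > 1L) {
      scale_innov <- sqrt(1 - cf$ar1^2)
      for (t in 2:tt) {
        eta <- matrix(stats::rnorm(n * k), n, k) %*% cf$chol_cor
        theta[, , t] <- matrix(cf$drift, n, k, byrow = TRUE) +
          cf$ar1 * theta[, , t - 1L] + scale_innov * eta
      }
    }

    # demographics (independent of factors unless confounded)
    race <- sample(cf$race_levels, n, replace = TRUE, prob = cf$race_probs)
    gender <- sample(cf$gender_levels, n, replace = TRUE,
                     prob = cf$gender_probs)
    age0 <- stats::runif(n, cf$age_range[1L], cf$age_range[2L])
    if (cf$confound_age) {
      span <- diff(cf$age_range)
      age0 <- pmin(pmax(age0 + span / 4 * theta[, 1L, 1L], cf$age_range[1L]),
                   cf$age_range[2L])
    }

    rows <- vector("list", tt)
    for (t in seq_len(tt)) {
      propensity <- theta[, , t] %*% t(Lambda) +
        matrix(stats::rnorm(n * p), n, p)
      resp <- matrix(0L, n, p)
      resp[propensity >= cf$cutpoints[1L]] <- 1L
      resp[propensity >= cf$cutpoints[2L]] <- 2L
      df <- data.frame(person_id = person_ids, timepoint = t,
                       stringsAsFactors = FALSE)
      df[item_columns(p)] <- as.data.frame(resp)
      df$race <- race; df$gender <- gender; df$age <- age0 + (t - 1)
      rows[[t]] <- df
    }
    cohort <- as_cohort(do.call(rbind, rows), n_items = p)

    theta_long <- do.call(rbind, lapply(seq_len(tt), function(t) {
      out <- data.frame(person_id = person_ids, timepoint = t,
                        stringsAsFactors = FALSE)
      out[cf$factor_names] <- as.data.frame(theta[, , t])
      out
    }))
    # True severity is the planted symptom load: the L2 norm of the
    # positive part of the person's mean factor scores. On a floor-bounded
    # 0/1/2 checklist, factor scores below zero all map to symptom absence,
    # so only the positive side of factor space carries severity; the
    # symmetric norm is kept alongside as a diagnostic.
    mean_theta <- apply(theta, c(1L, 2L), mean)
    severity <- data.frame(person_id = person_ids,
                           true_severity = sqrt(rowSums(pmax(mean_theta, 0)^2)),
                           latent_norm = sqrt(rowSums(mean_theta^2)),
                           stringsAsFactors = FALSE)

    scales <- default_scale_map(dominant, p, cf$factor_names)
    structure(list(cohort = cohort,
                   truth = list(theta = theta_long, loadings = Lambda,
                                cutpoints = cf$cutpoints, severity = severity,
                                transdiagnostic_items = trans_items),
                   scales = scales, config = cf),
              class = "hdss_simulation")
  })
}

# Items grouped by dominant factor. hitop family: the four broad CBCL-style
# dimensions plus total problems over all items; dsm_proxy family: one
# DSM-oriented scale per factor group.
default_scale_map <- function(dominant, n_items, factor_names) {
  groups <- split(seq_len(n_items), factor_names[dominant])
  dsm_names <- c(internalizing = "anxious_depressed",
                 externalizing = "oppositional_defiant",
                 attention = "attention_deficit",
                 somatic = "somatic_problems",
                 thought = "thought_problems")
  hitop <- c(list(total_problems = seq_len(n_items)),
             groups[intersect(c("internalizing", "externalizing",
                                "attention", "somatic"), names(groups))])
  dsm <- groups
  names(dsm) <- ifelse(names(groups) %in% names(dsm_names),
                       dsm_names[names(groups)],
                       paste0(names(groups), "_disorder"))
  scale_map(hitop = hitop, dsm_proxy = dsm, n_items = n_items)
}

#' @export
print.hdss_simulation <- function(x, ...) {
  cat("<hdss_simulation>\n")
  print(x$config)
  print(x$cohort)
  invisible(x)
}
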