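#' Run the full analysis pipeline
#'
#' Executes every stage end to end — simulate (or ingest) -> score ->
#' build space -> distances -> centroid analysis -> embed -> boundary ->
#' category geometry -> trajectories — writing all artifacts plus a JSON
#' manifest (package version, seeds, config, file hashes) to `out`. Given a
#' fixed seed the run is deterministic and reruns produce byte-identical
#' numeric outputs.
#'
#' @param preset Name of a simulation preset (see [hdss_preset()]); ignored
#'   when `config` or `input` is given.
#' @param config An `hdss_config` to simulate from.
#' @param input Path to a cohort CSV to ingest instead of simulating (then
#'   `scales_path` must name a scale-map YAML).
#' @param scales_path Scale-map YAML for ingested cohorts.
#' @param seed Root seed; stage seeds are derived from it.
#' @param out Output directory (created if needed). `NULL` runs in a
#'   temporary directory.
#' @param demographics Feature-encoding dialect, `"onehot"` or `"compact"`.
#' @param threshold Clinical T-score threshold.
#' @param mds_method `"classical"` (default: deterministic and fast at
#'   cohort scale) or `"smacof"`.
#' @param mds_subsample Optional landmark count: fit the embedding stage on
#'   a seeded subsample of observations (approximation for very large
#'   cohorts); `NULL` embeds everything.
#' @param write_distances Also write the full n x n distance matrix CSV
#'   (quadratic in size; off by default).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with every stage result (`simulation`,
#'   `scores`, `tscores`, `status`, `space`, `dist`, `centroid`,
#'   `distances_from_centroid`, `regression`, `correlation`,
#'   `scale_space`, `embedding`, `boundary`, `categories`,
#'   `trajectories`, `transitions`, `summary`, `manifest`).
#' @export
run_pipeline <- function(preset = "paper_like", config = NULL, input = NULL,
                         scales_path = NULL, seed = 42L, out = NULL,
                         demographics = c("onehot", "compact"),
                         threshold = 65, mds_method = c("classical", "smacof"),
                         mds_subsample = NULL, write_distances = FALSE,
                         quiet = FALSE) {
  demographics <- match.arg(demographics)
  mds_method <- match.arg(mds_method)
  if (is.null(out)) out <- tempfile("hdss_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "setup"
  res <- list()
  run_stage <- function(name, code) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    v <- force(code)
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    v
  }
  tryCatch({
    res$simulation <- run_stage("simulate", {
      if (!is.null(input)) {
        cohort <- read_cohort(input, complete_cases = TRUE)
        if (is.null(scales_path)) stop("scales_path required with input")
        list(cohort = cohort, scales = read_scale_map(scales_path),
             truth = NULL, config = NULL)
      } else {
        if (is.null(config)) config <- hdss_preset(preset, seed = seed)
        sim <- generate_cohort(config)
        write_cohort(sim$cohort, file.path(out, "cohort.csv"))
        write_scale_map(sim$scales, file.path(out, "scales.yaml"))
        write_num_csv(sim$truth$severity, file.path(out, "truth_severity.csv"))
        sim
      }
    })
    cohort <- res$simulation$cohort
    scales <- res$simulation$scales

    res$scores <- run_stage("score", {
      sc <- raw_scale_scores(cohort, scales)
      write_num_csv(sc, file.path(out, "raw_scores.csv"))
      sc
    })
    res$tscores <- run_stage("tscore", {
      ts <- tscores_from_reference(res$scores)
      write_num_csv(ts, file.path(out, "tscores.csv"))
      ts
    })
    res$status <- run_stage("status", {
      st <- assign_clinical_status(res$tscores, threshold = threshold)
      write_num_csv(st$summary, file.path(out, "status.csv"))
      st
    })
    res$space <- run_stage("build-space", {
      spec <- feature_spec(cohort, demographics = demographics)
      sp <- standardize(encode_features(cohort, spec), spec = spec)
      write_space_params(sp, file.path(out, "space_params.json"))
      sp
    })
    res$dist <- run_stage("distances", {
      dd <- pairwise_distances(res$space)
      if (write_distances) write_distance_csv(dd, file.path(out, "distances.csv"))
      dd
    })
    res$centroid <- run_stage("centroid", {
      average_person_vector(res$space)$global
    })
    res$distances_from_centroid <- run_stage("centroid-distances", {
      dc <- distance_from_centroid(res$space, res$centroid)
      write_num_csv(dc, file.path(out, "centroid_distances.csv"))
      dc
    })
    res$regression <- run_stage("severity-regression", {
      base <- res$distances_from_centroid$timepoint == 1L
      st <- res$status$summary
      skey <- paste(st$person_id, st$timepoint, sep = "@")
      dkey <- paste(res$distances_from_centroid$person_id,
                    res$distances_from_centroid$timepoint, sep = "@")
      counts <- st$n_diagnoses[match(dkey[base], skey)]
      reg <- severity_regression(res$distances_from_centroid$distance[base],
                                 counts)
      jsonlite::write_json(
        list(slope = unname(reg$coefficients["n_diagnoses", "Estimate"]),
             t = unname(reg$coefficients["n_diagnoses", "t value"]),
             p = unname(reg$coefficients["n_diagnoses", "Pr(>|t|)"]),
             adj_r2 = reg$adj_r2, bic = reg$bic, n = reg$n),
        file.path(out, "severity_regression.json"), auto_unbox = TRUE,
        digits = NA)
      reg
    })
    res$scale_space <- run_stage("scale-space", build_scale_space(res$tscores))
    res$correlation <- run_stage("severity-correlation", {
      # five-dimensional scale space: distance from its centroid vs total
      # problems raw score, at baseline
      ctr5 <- average_person_vector(res$scale_space)$global
      d5 <- distance_from_centroid(res$scale_space, ctr5)
      base <- d5$timepoint == 1L
      sc <- res$scores
      tot <- sc[sc$scale == "total_problems", ]
      key <- paste(tot$person_id, tot$timepoint, sep = "@")
      totals <- tot$raw_score[match(paste(d5$person_id, d5$timepoint,
                                          sep = "@")[base], key)]
      cr <- distance_severity_correlation(d5$distance[base], totals)
      jsonlite::write_json(cr, file.path(out, "severity_correlation.json"),
                           auto_unbox = TRUE, digits = NA)
      cr
    })
    res$embedding <- run_stage("embed", {
      dd <- res$dist
      if (!is.null(mds_subsample) && mds_subsample < nrow(dd$d)) {
        keep <- local_seed(child_seed(seed, 7L),
                           sort(sample.int(nrow(dd$d), mds_subsample)))
        dd <- structure(list(d = dd$d[keep, keep],
                             index = dd$index[keep, , drop = FALSE]),
                        class = "hdss_dist")
      }
      emb <- mds_embed(dd, n_components = 2L, method = mds_method,
                       seed = child_seed(seed, 11L))
      write_embedding_csv(emb, file.path(out, "embedding.csv"))
      emb
    })
    res$boundary <- run_stage("boundary", {
      emb_ids <- rownames(res$embedding$points)
      st <- res$status$summary
      skey <- paste(st$person_id, st$timepoint, sep = "@")
      b <- fit_clinical_boundary(res$embedding,
                                 st$total_clinical[match(emb_ids, skey)])
      write_boundary_json(b, file.path(out, "boundary.json"))
      b
    })
    res$categories <- run_stage("categories", {
      out_fams <- lapply(c(dsm_proxy = "dsm_proxy", hitop = "hitop"),
        function(fam) {
          asg <- category_assignment(res$status, family = fam, timepoint = 1L)
          wb <- within_between_matrix(res$dist, asg)
          mdf <- data.frame(category = rownames(wb$means), wb$means,
                            check.names = FALSE)
          write_num_csv(mdf, file.path(out, paste0("categories_", fam, ".csv")))
          cdf <- data.frame(category = rownames(wb$pair_counts),
                            wb$pair_counts, check.names = FALSE)
          write_num_csv(cdf, file.path(out,
                                       paste0("categories_", fam, "_counts.csv")))
          wb
        })
      summ <- lapply(out_fams, summarize_within_between)
      jsonlite::write_json(summ, file.path(out, "category_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(matrices = out_fams, summary = summ)
    })
    res$trajectories <- run_stage("trajectories", {
      tr <- build_trajectories(res$embedding, res$status,
                               res$distances_from_centroid)
      write_num_csv(tr, file.path(out, "trajectories.csv"))
      tr
    })
    res$transitions <- run_stage("transitions", {
      ev <- detect_transitions(res$trajectories, res$boundary)
      write_num_csv(ev, file.path(out, "transitions.csv"))
      ev
    })
    res$summary <- list(
      n_observations = nrow(cohort),
      n_persons = length(unique(cohort$person_id)),
      within_between = res$categories$summary,
      regression = list(adj_r2 = res$regression$adj_r2,
                        bic = res$regression$bic),
      correlation_r = res$correlation$r,
      boundary_accuracy = res$boundary$accuracy,
      mds_stress = res$embedding$stress,
      n_transitions = table(factor(res$transitions$direction,
                                   levels = c("improved", "worsened")))
    )
    res$manifest <- run_stage("manifest", {
      files <- sort(setdiff(list.files(out), "manifest.json"))
      manifest <- list(
        package = "hdss",
        version = as.character(utils::packageVersion("hdss")),
        seed = seed, preset = if (is.null(config) && is.null(input)) preset
                              else NULL,
        demographics = demographics, threshold = threshold,
        mds_method = mds_method,
        hashes = as.list(tools::md5sum(file.path(out, files)))
      )
      names(manifest$hashes) <- files
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      manifest
    })
    res$out <- out
    invisible(res)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (artifacts preserved in %s)",
                 stage, conditionMessage(e), out), call. = FALSE)
  })
}
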