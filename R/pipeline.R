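#' Pipeline run configuration
#'
#' Fully-defaulted configuration for an end-to-end synthetic audit run:
#' cohort generation, accuracy metrics, volumetry, VAT modelling and the
#' statistical battery.  A serialised copy is written into every output
#' directory so a run can be reproduced from its manifest alone.
#'
#' @param cohort a [cohort_config].
#' @param vat list of VAT settings: `enabled`, `amplitude` (V), `contact`
#'   (0-based active contact), `threshold` (V/mm), `extent_mm`, `spacing`
#'   (mm).
#' @param stats list of statistics settings: `alpha`, `within_threshold_mm`
#'   (the "within target" distance), `shift_family` (Bonferroni family for
#'   the accuracy/shift/pneumocephalus correlations).
#' @param failures list with `registration` and `vat` counts of simulated
#'   pipeline failures.
#' @param seed root seed; overrides the cohort seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       vat = list(), stats = list(), failures = list(),
                       seed = NULL) {
  vat <- modifyList(list(enabled = TRUE, amplitude = 2.5, contact = 0L,
                         threshold = 0.2, extent_mm = 40, spacing = 0.5),
                    vat)
  stats <- modifyList(list(alpha = 0.05, within_threshold_mm = 2,
                           shift_family = 3), stats)
  failures <- modifyList(list(registration = 6L, vat = 2L), failures)
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, vat = vat, stats = stats,
                 failures = failures, seed = cohort$seed),
            class = "run_config")
}

#' Simulate pipeline attrition
#'
#' Marks randomly chosen subjects as excluded at the registration or VAT
#' stage; downstream analyses use only completers.
#'
#' @param cohort result of [generate_cohort()], or a character vector of
#'   subject ids.
#' @param registration_failures,vat_failures counts of excluded subjects
#'   per stage (their sum must not exceed the cohort size).
#' @param seed integer seed for the exclusion draw.
#' @return list with `excluded` (data.frame id, stage), `completers`
#'   (ids), `n_total`, `n_completed` and `pct` (completion percentage,
#'   nearest integer).
#' @export
simulate_failures <- function(cohort, registration_failures = 0L,
                              vat_failures = 0L, seed = 1L) {
  ids <- if (is.character(cohort)) cohort
         else vapply(cohort$subjects, `[[`, character(1), "id")
  n <- length(ids)
  nf <- registration_failures + vat_failures
  if (nf > n)
    stop("failure counts (", nf, ") exceed cohort size (", n, ")")
  set.seed(seed)
  failed <- if (nf > 0) sample(ids, nf) else character(0)
  excluded <- data.frame(
    id = failed,
    stage = rep(c("registration", "vat"),
                c(registration_failures, vat_failures)))
  list(excluded = excluded, completers = setdiff(ids, failed),
       n_total = n, n_completed = n - nf,
       pct = round(100 * (n - nf) / n))
}

write_csv_out <- function(df, dir, name) {
  write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full synthetic audit pipeline
#'
#' Simulate -> accuracy metrics -> volumetry -> VAT -> statistics ->
#' report.  Produces a bundle of tidy CSV tables plus a machine-readable
#' manifest in `out_dir`.  Identical configurations and seeds produce
#' byte-identical CSVs.  Any stage failure aborts with the stage name
#' (and subject id where applicable) and leaves an `INVALID` marker in
#' the output directory.
#'
#' @param config a [run_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory tables (`accuracy`,
#'   `summary`, `target_plots`, `shift`, `correlations`, `outcomes`,
#'   `outcome_tests`, `vat`, `glm`, `completion`) and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  invalid_marker <- file.path(out_dir, "INVALID")
  on_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("run aborted at stage: ", stage), invalid_marker)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (file.exists(invalid_marker)) file.remove(invalid_marker)

  cohort <- on_stage("simulate", generate_cohort(config$cohort))
  completion <- on_stage("simulate", simulate_failures(
    cohort, config$failures$registration, config$failures$vat,
    seed = substream_seed(config$seed, 0L, 9L)))
  completers <- Filter(function(s) s$id %in% completion$completers,
                       cohort$subjects)
  message(sprintf("completion: %d of %d subjects (%d%%)",
                  completion$n_completed, completion$n_total,
                  completion$pct))

  acc <- on_stage("metrics",
                  accuracy_table(completers, cohort$atlas))
  summary_tab <- on_stage("metrics", summarise_accuracy(
    acc[acc$scrf_applied & acc$reference == "main", ],
    c("nucleus", "hemisphere"),
    threshold = config$stats$within_threshold_mm))
  overall_tab <- on_stage("metrics", summarise_accuracy(
    acc[acc$scrf_applied, ], c("reference"),
    threshold = config$stats$within_threshold_mm))
  plots <- on_stage("metrics", target_plot_table(acc))

  pneumo <- on_stage("volumetry", {
    v <- vapply(seq_along(cohort$subjects), function(k) {
      s <- cohort$subjects[[k]]
      if (!s$id %in% completion$completers) return(NA_real_)
      pneumocephalus_volume(cohort$template_brain,
                            subject_brain_mask(cohort, k))
    }, numeric(1))
    setNames(v, vapply(cohort$subjects, `[[`, character(1), "id"))
  })
  shift <- on_stage("volumetry",
                    shift_records(acc, completers, pneumo))
  correlations <- on_stage("volumetry", tryCatch(
    shift_accuracy_correlations(shift, family = config$stats$shift_family),
    error = function(e) {
      if (!grepl("constant", conditionMessage(e))) stop(e)
      # e.g. a perfectly on-target cohort: accuracy has no variance
      message("correlations degenerate: ", conditionMessage(e))
      data.frame(pair = c("accuracy_vs_shift",
                          "accuracy_vs_pneumocephalus",
                          "shift_vs_pneumocephalus"),
                 r = NA_real_, r_squared = NA_real_, df = NA_real_,
                 p = NA_real_, n = nrow(shift), p_corrected = NA_real_,
                 family = config$stats$shift_family)
    }))

  vat_tab <- NULL
  if (isTRUE(config$vat$enabled)) {
    vat_rows <- list()
    for (s in completers) {
      for (hemi in c("left", "right")) {
        res <- on_stage(paste0("vat:", s$id), compute_vat(
          apply_scrf(s$electrodes[[hemi]], s$scrf[[hemi]]),
          contact = config$vat$contact,
          amplitude = config$vat$amplitude, atlas = cohort$atlas,
          overlap_labels = c(target_label(s$target, "main", hemi),
                             target_label(s$target, "motor", hemi)),
          threshold = config$vat$threshold,
          extent_mm = config$vat$extent_mm,
          spacing = config$vat$spacing))
        ov <- res$overlap
        vat_rows[[length(vat_rows) + 1L]] <- data.frame(
          id = s$id, hemisphere = hemi, nucleus = s$target,
          vat_mm3 = res$vat_volume_mm3,
          overlap_main_mm3 = ov$overlap_mm3[1],
          fraction_main = ov$fraction[1],
          overlap_motor_mm3 = ov$overlap_mm3[2],
          fraction_motor = ov$fraction[2])
      }
    }
    vat_tab <- do.call(rbind, vat_rows)
  }

  outcome_rows <- lapply(completers, function(s)
    cbind(data.frame(id = s$id, target = s$target), s$scores))
  outcomes <- do.call(rbind, outcome_rows)
  rownames(outcomes) <- NULL
  outcome_tests <- on_stage("stats", {
    tests <- list()
    for (sc in unique(outcomes$score)) {
      d <- outcomes[outcomes$score == sc, ]
      tests[[paste0("paired_", sc)]] <- paired_t(d$pre, d$post)
    }
    ledd <- outcomes[outcomes$score == "LEDD", ]
    pct <- 100 * (ledd$post - ledd$pre) / ledd$pre
    if (sum(ledd$target == "GPi") >= 2 && sum(ledd$target == "STN") >= 2) {
      tests[["LEDD_pct_GPi_vs_STN"]] <-
        two_sample_t(pct[ledd$target == "GPi"], pct[ledd$target == "STN"])
    } else {
      message("skipping LEDD GPi-vs-STN contrast: a target group has n < 2")
    }
    stat_table(tests)
  })

  glm_tab <- NULL
  stn_completers <- Filter(function(s) s$target == "STN", completers)
  if (!is.null(vat_tab) && length(stn_completers) >= 5) {
    glm_tab <- on_stage("stats", {
      stn <- stn_completers
      per_subj <- lapply(stn, function(s) {
        u <- s$scores[s$scores$score == "UPDRS3", ]
        v <- vat_tab[vat_tab$id == s$id, ]
        a <- acc[acc$id == s$id & acc$reference == "main" &
                   acc$scrf_applied, ]
        data.frame(id = s$id,
                   updrs3_pct = 100 * (u$post - u$pre) / u$pre,
                   accuracy = mean(a$boundary_distance),
                   vat_motor = mean(v$fraction_motor),
                   vat_mm3 = mean(v$vat_mm3))
      })
      gdat <- do.call(rbind, per_subj)
      fit <- glm_fit(gdat$updrs3_pct,
                     gdat[, c("accuracy", "vat_motor")])
      extra <- pearson(gdat$accuracy, gdat$vat_mm3)
      tab <- stat_table(c(fit$results,
                          list(accuracy_vs_vat_volume = extra)))
      tab
    })
  } else if (!is.null(vat_tab)) {
    message("skipping outcome GLM: fewer than 5 STN completers")
  }

  manifest <- list(
    package = "dbsaudit",
    version = as.character(packageVersion("dbsaudit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_subjects = config$cohort$n_subjects,
    completion = completion[c("n_total", "n_completed", "pct")],
    vat_enabled = isTRUE(config$vat$enabled))

  on_stage("report", {
    write_csv_out(acc, out_dir, "accuracy.csv")
    write_csv_out(summary_tab, out_dir, "accuracy_summary.csv")
    write_csv_out(overall_tab, out_dir, "accuracy_overall.csv")
    write_csv_out(plots, out_dir, "target_plots.csv")
    write_csv_out(shift, out_dir, "shift_records.csv")
    write_csv_out(correlations, out_dir, "shift_correlations.csv")
    write_csv_out(outcomes, out_dir, "outcomes.csv")
    write_csv_out(outcome_tests, out_dir, "outcome_tests.csv")
    write_csv_out(completion$excluded, out_dir, "excluded.csv")
    if (!is.null(vat_tab)) write_csv_out(vat_tab, out_dir, "vat_overlap.csv")
    if (!is.null(glm_tab)) write_csv_out(glm_tab, out_dir, "glm_outcomes.csv")
    write_cohort_scores(completers, file.path(out_dir, "scores.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(serialise_config(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(accuracy = acc, summary = summary_tab,
                 overall = overall_tab, target_plots = plots,
                 shift = shift, correlations = correlations,
                 outcomes = outcomes, outcome_tests = outcome_tests,
                 vat = vat_tab, glm = glm_tab, completion = completion,
                 manifest = manifest, out_dir = out_dir))
}

serialise_config <- function(config) {
  rapply(unclass(config), function(x) x, how = "list")
}
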