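# End-to-end cohort report: runs the learning-rate fits, the history kernel
# and every descriptive analysis for a cohort and writes one directory of
# TSV tables keyed to the analysis families, plus a machine-readable run
# log. The whole pipeline is a pure function of the manifest.

#' Build a cohort manifest
#'
#' @param config A [cohort_config()] used to simulate the cohort, or `NULL`
#'   if `sessions` are supplied directly.
#' @param sessions Optional pre-built list of `bandit_session` objects
#'   (e.g. from [read_sessions()]); overrides `config`.
#' @param out_dir Output directory for the report tables.
#' @param params Analysis parameters: `window`, `threshold`, `fit_beta`,
#'   `fallback_alpha`, `fallback_beta` (used when a subject has no
#'   pre-phase sessions to fit), `vcov_type`.
#' @return A list of class `cohort_manifest`.
#' @export
cohort_manifest <- function(config = cohort_config(), sessions = NULL,
                            out_dir = "bandit3arm_report",
                            params = list()) {
  params <- utils::modifyList(list(
    window = 20L, threshold = 0.65, fit_beta = TRUE,
    fallback_alpha = 0.3, fallback_beta = 5, vcov_type = "model"
  ), params)
  if (is.null(sessions) && is.null(config)) {
    stop("either `config` or `sessions` must be given")
  }
  structure(list(config = config, sessions = sessions, out_dir = out_dir,
                 params = params),
            class = "cohort_manifest")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", na = "", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full analysis report for a cohort
#'
#' Executes, per subject and phase: the Rescorla-Wagner learning-rate fit on
#' the subject's pre-phase varying sessions (reused for the post phase; a
#' subject with no pre-phase sessions is flagged and analysed with the
#' manifest's fallback parameters), the history kernel, and all descriptive
#' metrics, and writes the tables to `out_dir`:
#' `fig3_performance.tsv`, `fig3_latency_hist.tsv`, `fig4_switching.tsv`,
#' `fig4_latency.tsv`, `fig5_history_akb.tsv`, `fig5_history_freq.tsv`,
#' `fig6_kernel.tsv`, `fig7_fixed.tsv` (when fixed-schedule sessions are
#' present) and `run_log.json`. A failing stage is recorded in the log and
#' the independent remaining stages still run.
#'
#' @param manifest A [cohort_manifest()].
#' @return Invisibly, a list with `tables` (named file paths), `fits`,
#'   `kernels` and `log`.
#' @export
run_report <- function(manifest) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  p <- manifest$params
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(parameters = p, notices = character(0), errors = character(0),
              package_version = as.character(utils::packageVersion("bandit3arm")))
  note <- function(msg) log$notices <<- c(log$notices, msg)
  fail <- function(stage, e) {
    log$errors <<- c(log$errors, sprintf("%s: %s", stage, conditionMessage(e)))
  }
  sessions <- manifest$sessions
  if (is.null(sessions)) {
    sessions <- simulate_cohort(manifest$config)
    log$seed <- manifest$config$seed
  }
  varying <- filter_sessions(sessions, kind = VARYING_KINDS)
  fixed <- filter_sessions(sessions, kind = FIXED_KINDS)
  subjects <- unique(vapply(sessions, `[[`, character(1), "subject_id"))
  phases <- unique(vapply(sessions, `[[`, character(1), "phase"))
  groups <- unique(vapply(sessions, `[[`, character(1), "group"))
  tables <- list()

  # --- learning-rate fits (pre phase, varying schedules) ---
  fits <- list()
  for (sid in subjects) {
    pre <- filter_sessions(varying, subject_id = sid, phase = "pre")
    fits[[sid]] <- if (length(pre)) {
      tryCatch(fit_learning_rate(pre, fit_beta = p$fit_beta,
                                 beta_fixed = p$fallback_beta),
               error = function(e) { fail(paste0("fit-rl/", sid), e); NULL })
    } else {
      note(sprintf(
        "subject %s has no pre-phase sessions; fit-rl skipped, fallback alpha = %g used",
        sid, p$fallback_alpha))
      NULL
    }
  }
  alpha_of <- function(sid) {
    if (!is.null(fits[[sid]])) fits[[sid]]$alpha_hat else p$fallback_alpha
  }

  # --- fig3: performance and criterion ---
  tryCatch({
    if (length(varying)) {
      perf <- v1_choice_summary(varying, reversal_window = 50L)
      crit_acq <- trials_to_criterion(varying, threshold = p$threshold,
                                      window = p$window,
                                      segment = "acquisition")$per_session
      crit_post <- trials_to_criterion(varying, threshold = p$threshold,
                                       window = p$window,
                                       segment = "post_reversal")$per_session
      perf$criterion_acquisition <- crit_acq$criterion_trial
      perf$criterion_post_reversal <- crit_post$criterion_trial
      perf$p_v1rl <- vapply(varying, function(s) {
        mean(s$trials$choice == v1_rl_labels(s, alpha_of(s$subject_id)))
      }, numeric(1))
      tables$fig3_performance <-
        write_tsv(perf, file.path(manifest$out_dir, "fig3_performance.tsv"))
      lat <- latency_summary(varying)
      tables$fig3_latency_hist <-
        write_tsv(lat$histogram,
                  file.path(manifest$out_dir, "fig3_latency_hist.tsv"))
      tables$fig4_latency <-
        write_tsv(lat$by_subject,
                  file.path(manifest$out_dir, "fig4_latency.tsv"))
    }
  }, error = function(e) fail("fig3_performance", e))

  # --- fig4: switch/stay by group x phase x segment x outcome ---
  tryCatch({
    if (length(varying)) {
      rows <- list()
      for (g in groups) for (ph in phases) {
        sub <- filter_sessions(varying, group = g, phase = ph)
        if (!length(sub)) next
        tab <- switch_stay_table(sub, split_reversal = TRUE)
        tab <- cbind(data.frame(group = g, phase = ph), tab)
        rows[[length(rows) + 1L]] <- tab
      }
      tables$fig4_switching <-
        write_tsv(do.call(rbind, rows),
                  file.path(manifest$out_dir, "fig4_switching.tsv"))
    }
  }, error = function(e) fail("fig4_switching", e))

  # --- fig5: choice-history and choice-frequency tables ---
  tryCatch({
    if (length(varying)) {
      akb <- list(); freq <- list()
      for (g in groups) for (ph in phases) {
        sub <- filter_sessions(varying, group = g, phase = ph)
        if (!length(sub)) next
        akb[[length(akb) + 1L]] <-
          cbind(data.frame(group = g, phase = ph), akb_table(sub))
        freq[[length(freq) + 1L]] <-
          cbind(data.frame(group = g, phase = ph),
                choice_frequency_table(sub))
      }
      tables$fig5_history_akb <-
        write_tsv(do.call(rbind, akb),
                  file.path(manifest$out_dir, "fig5_history_akb.tsv"))
      tables$fig5_history_freq <-
        write_tsv(do.call(rbind, freq),
                  file.path(manifest$out_dir, "fig5_history_freq.tsv"))
    }
  }, error = function(e) fail("fig5_history", e))

  # --- fig6: history kernel per subject x phase ---
  kernels <- list()
  tryCatch({
    if (length(varying)) {
      rows <- list()
      for (sid in subjects) for (ph in phases) {
        sub <- filter_sessions(varying, subject_id = sid, phase = ph)
        if (!length(sub)) next
        kr <- fit_history_kernel(sub, vcov_type = p$vcov_type)
        kernels[[paste(sid, ph, sep = "/")]] <- kr
        cm <- kr$column_map
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = sub[[1]]$group, phase = ph,
          choice_lag = cm$choice_lag, outcome_lag = cm$outcome_lag,
          role = cm$role, beta = as.numeric(kr$beta_combined),
          separation = kr$any_separation)
      }
      tables$fig6_kernel <-
        write_tsv(do.call(rbind, rows),
                  file.path(manifest$out_dir, "fig6_kernel.tsv"))
    }
  }, error = function(e) fail("fig6_kernel", e))

  # --- fig7: fixed schedules ---
  tryCatch({
    if (length(fixed)) {
      fel <- fixed_early_late(fixed, window = p$window)
      out <- fel$per_session
      tables$fig7_fixed <-
        write_tsv(out, file.path(manifest$out_dir, "fig7_fixed.tsv"))
    } else {
      note("no fixed-schedule sessions; fig7 tables skipped")
    }
  }, error = function(e) fail("fig7_fixed", e))

  log$fits <- lapply(fits, function(f) {
    if (is.null(f)) NULL else f[c("alpha_hat", "beta_sm_hat",
                                  "neg_log_likelihood", "converged")]
  })
  jsonlite::write_json(log, file.path(manifest$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tables = tables, fits = fits, kernels = kernels, log = log))
}
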