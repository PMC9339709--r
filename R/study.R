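# End-to-end orchestration: write/read a BIDS-flavored study layout, run the
# offline analysis stages per subject and session, and assemble the crossover
# outcome table and statistics.

#' Analyze one session (pre + post block) of one subject
#'
#' Runs the offline chain: merge + clean, ERP branch (target and standard),
#' TFR branch, and behavioral scoring, returning one row of outcome measures
#' per block.
#'
#' @param pre_rec,post_rec [eeg_recording()]s of the two analyzed blocks.
#' @param behavior_pre,behavior_post behavior tables ([simulate_behavior()]
#'   layout); `NULL` to skip behavioral measures.
#' @param erp_cfg an [offline_config()].
#' @param tfr_cfg a [tfr_config()] (or `NULL` to skip the wavelet branch).
#' @param trial_types ERP conditions to compute (default target + standard).
#' @return data.frame with columns `block`, `measure`, `value`.
#' @export
analyze_session <- function(pre_rec, post_rec, behavior_pre = NULL,
                            behavior_post = NULL,
                            erp_cfg = offline_config(),
                            tfr_cfg = tfr_config(),
                            trial_types = c("target", "standard")) {
  merged <- preprocess_offline(pre_rec, post_rec, erp_cfg)
  erps <- erp_by_condition(merged, erp_cfg, trial_types = trial_types)
  tfrs <- if (!is.null(tfr_cfg)) tfr_by_condition(merged, tfr_cfg, erp_cfg)

  rows <- NULL
  add <- function(block, measure, value) {
    rows <<- rbind(rows, data.frame(block = block, measure = measure,
                                    value = value))
  }
  beh <- list(pre = behavior_pre, post = behavior_post)
  for (bl in c("pre", "post")) {
    tgt <- erps[[bl]][["target"]]
    if (!is.null(tgt)) {
      add(bl, "p300_mean", tgt$p300_mean)
      add(bl, "p300_max", tgt$p300_max)
      add(bl, "late_erp_mean", tgt$late_mean)
    }
    if (!is.null(tfrs[[bl]])) add(bl, "ero_power", tfrs[[bl]]$roi$roi_mean)
    if (!is.null(beh[[bl]])) {
      v <- score_vot(beh[[bl]])
      add(bl, "omission_rate", v$omission_rate)
      add(bl, "commission_rate", v$commission_rate)
      add(bl, "d_prime", v$d_prime)
      add(bl, "rt_mean", v$rt_mean)
      add(bl, "rt_variability", v$rt_variability)
    }
  }
  rows
}

#' Write a simulated crossover study to a BIDS-flavored directory
#'
#' Layout: `sub-XX/ses-{actual,sham}/eeg/sub-XX_ses-YY_block-{pre,post}_eeg.edf`
#' with matching `_events.tsv` (behavioral `response` and `response_time`
#' columns merged in) and a `ground_truth.json` ledger at the root.
#'
#' @param study a [simulate_crossover_study()] result (with recordings).
#' @param dir output directory.
#' @export
write_study_dir <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in study$subjects) {
    for (iv in names(sub$sessions)) {
      eegdir <- file.path(dir, sub$id, paste0("ses-", iv), "eeg")
      dir.create(eegdir, recursive = TRUE, showWarnings = FALSE)
      for (bl in names(sub$sessions[[iv]])) {
        blk <- sub$sessions[[iv]][[bl]]
        stem <- file.path(eegdir, sprintf("%s_ses-%s_block-%s", sub$id, iv, bl))
        ev <- blk$recording$events
        ev$response <- blk$behavior$response
        ev$response_time <- blk$behavior$rt
        write_edf(blk$recording, paste0(stem, "_eeg.edf"))
        write_events_tsv(ev, paste0(stem, "_events.tsv"))
      }
    }
  }
  write_json_report(study$ledger, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

# Collect the four block files of one subject; NULL if any is missing.
.load_subject_session <- function(dir, sub_id, iv, bl) {
  stem <- file.path(dir, sub_id, paste0("ses-", iv), "eeg",
                    sprintf("%s_ses-%s_block-%s", sub_id, iv, bl))
  edf <- paste0(stem, "_eeg.edf")
  tsv <- paste0(stem, "_events.tsv")
  if (!file.exists(edf) || !file.exists(tsv)) return(NULL)
  ev <- read_events_tsv(tsv)
  rec <- read_edf(edf, events = ev)
  behavior <- data.frame(trial = seq_len(nrow(ev)), trial_type = ev$trial_type,
                         tilt = ev$tilt, response = ev$response,
                         rt = ev$response_time, stringsAsFactors = FALSE)
  list(recording = rec, behavior = behavior)
}

#' Run the full offline study analysis over a BIDS-flavored directory
#'
#' Per subject and intervention, loads the pre and post block, runs
#' [analyze_session()], and assembles the long crossover outcome table.
#' Subjects with any missing block file are dropped listwise and listed in
#' the report. The statistics layer then computes the 2x2 repeated-measures
#' ANOVA per measure and the pooled change-score correlation matrix.
#'
#' @param dir study directory (see [write_study_dir()]).
#' @param erp_cfg an [offline_config()].
#' @param tfr_cfg a [tfr_config()] or `NULL` to skip the wavelet branch.
#' @param measures measures to feed into the ANOVA stage (default: all).
#' @return `study_report`: list `outcomes` (long data.frame), `anova` (per
#'   measure), `correlations`, `n_subjects`, `dropped_subjects`,
#'   `provenance`.
#' @export
run_study <- function(dir, erp_cfg = offline_config(), tfr_cfg = tfr_config(),
                      measures = NULL) {
  subs <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  subs <- subs[grepl("^sub-", subs)]
  assert_that(length(subs) > 0, "no sub-* directories under %s", dir)

  outcomes <- NULL
  dropped <- character(0)
  for (sid in subs) {
    blocks <- list()
    complete <- TRUE
    for (iv in c("actual", "sham")) {
      for (bl in c("pre", "post")) {
        blocks[[paste(iv, bl)]] <- .load_subject_session(dir, sid, iv, bl)
        if (is.null(blocks[[paste(iv, bl)]])) complete <- FALSE
      }
    }
    if (!complete) {
      dropped <- c(dropped, sid)
      next
    }
    for (iv in c("actual", "sham")) {
      pre <- blocks[[paste(iv, "pre")]]
      post <- blocks[[paste(iv, "post")]]
      rows <- analyze_session(pre$recording, post$recording,
                              pre$behavior, post$behavior, erp_cfg, tfr_cfg)
      rows$subject <- sid
      rows$intervention <- iv
      outcomes <- rbind(outcomes, rows)
    }
  }
  assert_that(!is.null(outcomes), "no complete subjects found")

  use <- measures %||% unique(outcomes$measure)
  anova <- lapply(stats::setNames(use, use), function(ms) {
    rm_anova_2x2(outcomes[outcomes$measure == ms, ])
  })
  correlations <- if (length(use) >= 2)
    correlate_changes(outcomes[outcomes$measure %in% use, ]) else NULL

  structure(list(outcomes = outcomes, anova = anova,
                 correlations = correlations,
                 n_subjects = length(subs) - length(dropped),
                 dropped_subjects = dropped,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("p300tacs")),
                   dir = normalizePath(dir),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects (%d dropped), %d measures\n",
              x$n_subjects, length(x$dropped_subjects),
              length(unique(x$outcomes$measure))))
  for (ms in names(x$anova)) {
    a <- x$anova[[ms]]
    i <- a[a$effect == "interaction", ]
    cat(sprintf("  %-16s interaction F(1,%d) = %5.2f, p = %.3f, eta_p^2 = %.2f\n",
                ms, i$df2, i$F, i$p, i$eta_p_sq))
  }
  invisible(x)
}
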