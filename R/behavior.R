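# Behavioral scoring: visual oddball task metrics and the d2 paper-pencil
# attention test, plus the 3-SD outlier rule used before the statistics.

#' Score visual oddball behavior
#'
#' Omission errors count target trials without a correct target-key response:
#' wrong-key presses and missing responses both qualify under the protocol's
#' definition ("non-target button responses to target stimuli");
#' `count_no_response` lets the stricter reading (key presses only) be used
#' instead. Commissions are target-key responses to standards. Sensitivity is
#' d' = z(hit rate) - z(false-alarm rate) with extreme rates clipped to
#' `[1/(2N), 1 - 1/(2N)]` so d' stays finite. RT statistics cover correct
#' target responses only; RT variability is their standard deviation.
#'
#' @param behavior data.frame from [simulate_behavior()] (columns
#'   `trial_type`, `tilt`, `response`, `rt`).
#' @param count_no_response include missing responses in the omission rate
#'   (default TRUE).
#' @return list `omission_rate` and `commission_rate` (percent), `d_prime`,
#'   `rt_mean`, `rt_variability` (seconds), `n_targets`, `n_standards`.
#' @export
score_vot <- function(behavior, count_no_response = TRUE) {
  tg <- behavior[behavior$trial_type == "target", , drop = FALSE]
  st <- behavior[behavior$trial_type == "standard", , drop = FALSE]
  assert_that(nrow(tg) > 0, "no target trials: omission rate undefined")

  wrong <- tg$response != tg$tilt
  if (!count_no_response) wrong <- wrong & tg$response != "none"
  omission_rate <- 100 * mean(wrong)
  commission_rate <- if (nrow(st))
    100 * mean(st$response != st$tilt & st$response != "none") else 0

  clip <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  hr <- clip(1 - omission_rate / 100, nrow(tg))
  fa <- clip(commission_rate / 100, max(nrow(st), 1))
  d_prime <- stats::qnorm(hr) - stats::qnorm(fa)

  rts <- tg$rt[tg$response == tg$tilt]
  rts <- rts[!is.na(rts)]
  list(omission_rate = omission_rate, commission_rate = commission_rate,
       d_prime = d_prime,
       rt_mean = if (length(rts)) mean(rts) else NA_real_,
       rt_variability = if (length(rts) > 1) stats::sd(rts) else
         if (length(rts) == 1) 0 else NA_real_,
       n_targets = nrow(tg), n_standards = nrow(st))
}

# ---- d2 attention test ------------------------------------------------------

.d2_symbols <- c("d1", "d2", "d3", "d4", "p1", "p2", "p3", "p4")

#' Generate a d2 test sheet
#'
#' 14 lines of 47 characters; each character is a letter (`d` or `p`) with
#' 1-4 strokes, the target being `d` with exactly two strokes (`"d2"`).
#' Lines alternate 21 and 22 targets placed at random, matching the
#' test's structure; distractors are drawn uniformly from the remaining
#' symbols.
#'
#' @param seed integer seed.
#' @param n_lines,line_length sheet dimensions (test standard: 14 x 47).
#' @return character matrix `n_lines x line_length` of symbols.
#' @export
generate_d2_sheet <- function(seed = 1, n_lines = 14, line_length = 47) {
  with_seed(seed, {
    sheet <- matrix("", n_lines, line_length)
    for (l in seq_len(n_lines)) {
      n_target <- if (l %% 2 == 1) 22L else 21L
      pos <- sample(line_length, n_target)
      row <- sample(setdiff(.d2_symbols, "d2"), line_length, replace = TRUE)
      row[pos] <- "d2"
      sheet[l, ] <- row
    }
    sheet
  })
}

#' Simulate crossing-out marks on a d2 sheet
#'
#' Works through each line left to right for a simulated per-line span
#' (processing speed), crossing targets with probability `p_hit` and
#' distractors with probability `p_false_alarm`.
#'
#' @param sheet a [generate_d2_sheet()] matrix.
#' @param speed mean characters processed per line.
#' @param speed_sd between-line SD of the span.
#' @param p_hit,p_false_alarm per-character probabilities.
#' @param seed integer seed.
#' @return list of integer vectors (marked positions per line).
#' @export
simulate_d2_marks <- function(sheet, speed = 38, speed_sd = 4,
                              p_hit = 0.9, p_false_alarm = 0.02, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(nrow(sheet)), function(l) {
      span <- min(max(round(stats::rnorm(1, speed, speed_sd)), 1), ncol(sheet))
      idx <- seq_len(span)
      is_t <- sheet[l, idx] == "d2"
      p <- ifelse(is_t, p_hit, p_false_alarm)
      idx[stats::runif(span) < p]
    })
  })
}

#' Score a d2 sheet
#'
#' Per line, the processed span runs up to the last marked position (0 for an
#' unmarked line). Metrics follow the test definitions: processing speed =
#' total characters processed; omissions = unmarked targets within the
#' processed span; commissions = marked distractors; concentration
#' performance = correctly marked targets minus commission errors.
#'
#' @param sheet a [generate_d2_sheet()] matrix.
#' @param marks list of marked positions per line.
#' @return list `processing_speed`, `concentration_performance`, `omissions`,
#'   `commissions`, `hits`.
#' @export
score_d2 <- function(sheet, marks) {
  assert_that(length(marks) == nrow(sheet), "one mark vector per line required")
  speed <- 0L; hits <- 0L; commissions <- 0L; omissions <- 0L
  for (l in seq_len(nrow(sheet))) {
    mk <- unique(as.integer(marks[[l]]))
    if (length(mk)) {
      assert_that(all(mk >= 1 & mk <= ncol(sheet)),
                  "mark beyond line length on line %d", l)
    }
    span <- if (length(mk)) max(mk) else 0L
    speed <- speed + span
    if (!span) next
    idx <- seq_len(span)
    is_target <- sheet[l, idx] == "d2"
    marked <- idx %in% mk
    hits <- hits + sum(is_target & marked)
    commissions <- commissions + sum(!is_target & marked)
    omissions <- omissions + sum(is_target & !marked)
  }
  list(processing_speed = speed,
       concentration_performance = hits - commissions,
       omissions = omissions, commissions = commissions, hits = hits)
}

#' 3-SD outlier mask
#'
#' Single-pass rule applied per outcome measure across the analyzed sample:
#' values strictly more than `k` standard deviations from the mean (both
#' computed over all values, outliers included) are excluded; a value exactly
#' at `k` SD is retained.
#'
#' @param values numeric vector (>= 3 values).
#' @param k SD multiplier (default 3).
#' @return logical inclusion mask (TRUE = keep).
#' @export
exclude_outliers <- function(values, k = 3) {
  assert_that(length(values) >= 3, "need at least 3 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= k * s
}
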