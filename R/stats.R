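# Crossover statistics: 2x2 within-subject repeated-measures ANOVA with
# partial eta squared, paired t with Cohen's d, Holm correction, and pooled
# change-score correlations.

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`; in the 2x2 within design every
#' effect has `df1 = 1` and `df2 = n - 1`.
#' @param f F value.
#' @param df1,df2 effect and error degrees of freedom.
#' @export
eta_p_sq <- function(f, df1 = 1, df2) (f * df1) / (f * df1 + df2)

#' Two-way repeated-measures ANOVA (2x2 within design)
#'
#' Within-subject decomposition for the factors Block (pre/post) and
#' Intervention (actual/sham): each effect is tested against its own
#' effect-by-subject interaction (`F = MS_effect / MS_effect_x_subject`).
#' Subjects with incomplete cells are dropped (listwise) with a log message
#' attribute. Sphericity corrections are unnecessary with two-level factors.
#'
#' @param outcomes data.frame with columns `subject`, `intervention`
#'   (`actual`/`sham`), `block` (`pre`/`post`), `value`.
#' @return data.frame, one row per effect (`block`, `intervention`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `eta_p_sq`; attributes `n`
#'   (complete cases) and `dropped` (subjects removed).
#' @export
rm_anova_2x2 <- function(outcomes) {
  need <- c("subject", "intervention", "block", "value")
  assert_that(all(need %in% names(outcomes)), "missing outcome columns")
  # build the four cells explicitly to stay robust to row order
  cell <- function(iv, bl) {
    x <- outcomes[outcomes$intervention == iv & outcomes$block == bl, ]
    stats::setNames(x$value, x$subject)
  }
  subj <- unique(as.character(outcomes$subject))
  m <- cbind(pre_actual = cell("actual", "pre")[subj],
             post_actual = cell("actual", "post")[subj],
             pre_sham = cell("sham", "pre")[subj],
             post_sham = cell("sham", "post")[subj])
  complete <- stats::complete.cases(m)
  dropped <- subj[!complete]
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  assert_that(n >= 2, "need at least 2 complete cases")

  # orthogonal within-subject contrasts; each effect's F equals the squared
  # paired t of its contrast, tested on n - 1 df
  contrast_f <- function(w) {
    d <- as.numeric(m %*% w)
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    tt^2
  }
  eff <- list(
    block = c(-1, 1, -1, 1) / 2,          # post - pre
    intervention = c(1, 1, -1, -1) / 2,   # actual - sham
    interaction = c(-1, 1, 1, -1))        # (postA - preA) - (postS - preS)
  f <- vapply(eff, contrast_f, numeric(1))
  df2 <- n - 1
  res <- data.frame(effect = names(eff), F = as.numeric(f), df1 = 1,
                    df2 = df2,
                    p = stats::pf(f, 1, df2, lower.tail = FALSE),
                    eta_p_sq = eta_p_sq(f, 1, df2),
                    row.names = NULL)
  attr(res, "n") <- n
  attr(res, "dropped") <- dropped
  res
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t; Cohen's d for paired data is the mean difference
#' divided by the SD of the differences. A zero-variance nonzero mean
#' difference is reported as infinite t with p = 0.
#'
#' @param a,b equal-length numeric vectors (n >= 2).
#' @return list `t`, `df`, `p`, `cohen_d`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 2,
              "a and b must have equal length >= 2")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0,
                cohen_d = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                mean_diff = mean(d)))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, cohen_d = mean(d) / sdd, mean_diff = mean(d))
}

#' Holm step-down adjustment
#'
#' Step-down Bonferroni-Holm: sorted p-values are multiplied by
#' `m, m-1, ...`, monotonicity is enforced with a running maximum, and the
#' result is capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @export
holm_adjust <- function(pvalues) {
  assert_that(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m <= 1) return(pvalues)
  ord <- order(pvalues)
  adj <- pmin(cummax((m - seq_len(m) + 1) * pvalues[ord]), 1)
  out <- numeric(m)
  out[ord] <- adj
  out[is.na(pvalues)] <- NA
  out
}

#' Pooled change-score correlations with Holm correction
#'
#' Change scores (post - pre) are stacked across both interventions (two rows
#' per subject) and every pair of measures is correlated (Pearson); raw
#' p-values are Holm-adjusted over all pairs. Pairs involving a constant
#' vector are reported as missing.
#'
#' @param outcomes data.frame `subject`, `intervention`, `block`, `measure`,
#'   `value` (long format over several outcome measures).
#' @param pool if `FALSE`, correlate within each intervention separately.
#' @return list `pairs` (data.frame `measure1`, `measure2`, `r`, `n`, `p`,
#'   `p_holm`) and `r_matrix`.
#' @export
correlate_changes <- function(outcomes, pool = TRUE) {
  need <- c("subject", "intervention", "block", "measure", "value")
  assert_that(all(need %in% names(outcomes)), "missing outcome columns")
  measures <- unique(outcomes$measure)
  chg <- list()
  for (ms in measures) {
    x <- outcomes[outcomes$measure == ms, ]
    pre <- x[x$block == "pre", ]
    post <- x[x$block == "post", ]
    key <- function(d) paste(d$subject, d$intervention, sep = "|")
    idx <- match(key(pre), key(post))
    chg[[ms]] <- stats::setNames(post$value[idx] - pre$value,
                                 key(pre))
  }
  keys <- Reduce(union, lapply(chg, names))
  M <- sapply(chg, function(v) v[keys])
  rownames(M) <- keys

  pairs <- NULL
  k <- length(measures)
  rmat <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(M[, c(i, j)])
      xi <- M[ok, i]; xj <- M[ok, j]
      if (sum(ok) < 3 || stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(xi, xj)
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rmat[i, j] <- rmat[j, i] <- r
      pairs <- rbind(pairs, data.frame(measure1 = measures[i],
                                       measure2 = measures[j],
                                       r = r, n = sum(ok), p = p))
    }
  }
  pairs$p_holm <- holm_adjust(pairs$p)
  list(pairs = pairs, r_matrix = rmat)
}
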