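# Crossover statistics: repeated-measures ANOVA, paired t, Holm correction,
# change-score correlations.

make_outcomes <- function(m) {
  subj <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    data.frame(subject = subj[i],
               intervention = c("actual", "actual", "sham", "sham"),
               block = c("pre", "post", "pre", "post"),
               value = as.numeric(m[i, ]))
  }))
}

test_that("the 2x2 ANOVA matches aov and the paired-t-squared identity", {
  set.seed(12)
  for (r in 1:5) {
    m <- matrix(rnorm(4 * 12), 12, 4)   # pre_a, post_a, pre_s, post_s
    out <- make_outcomes(m)
    res <- rm_anova_2x2(out)

    # algebraic identity: F_interaction = t^2 of the interaction contrast
    d <- (m[, 2] - m[, 1]) - (m[, 4] - m[, 3])
    tt <- mean(d) / (stats::sd(d) / sqrt(nrow(m)))
    expect_equal(res$F[res$effect == "interaction"], tt^2, tolerance = 1e-9)

    # independent oracle: stats::aov with an Error stratum
    out$subject <- factor(out$subject)
    out$block <- factor(out$block); out$intervention <- factor(out$intervention)
    fit <- summary(stats::aov(value ~ block * intervention +
                                Error(subject / (block * intervention)),
                              data = out))
    f_aov <- c(
      block = fit[["Error: subject:block"]][[1]]["block", "F value"],
      intervention = fit[["Error: subject:intervention"]][[1]][
        "intervention", "F value"],
      interaction = fit[["Error: subject:block:intervention"]][[1]][
        "block:intervention", "F value"])
    expect_equal(res$F[match(names(f_aov), res$effect)],
                 unname(f_aov), tolerance = 1e-8)
  }
})

test_that("partial eta squared and degrees of freedom follow the design", {
  set.seed(13)
  m <- matrix(rnorm(4 * 19), 19, 4)
  res <- rm_anova_2x2(make_outcomes(m))
  expect_true(all(res$df1 == 1) && all(res$df2 == 18))
  expect_equal(res$eta_p_sq, res$F / (res$F + 18))

  # zero interaction contrast variance with nonzero mean -> p ~ 0
  m2 <- matrix(rnorm(4 * 10), 10, 4)
  m2[, 2] <- m2[, 1] + 1               # exact +1 under actual only
  m2[, 4] <- m2[, 3]
  res2 <- rm_anova_2x2(make_outcomes(m2))
  expect_lt(res2$p[res2$effect == "interaction"], 1e-12)

  # incomplete subjects are dropped listwise
  out <- make_outcomes(m)
  out <- out[!(out$subject == "s1" & out$block == "post" &
               out$intervention == "sham"), ]
  res3 <- rm_anova_2x2(out)
  expect_equal(attr(res3, "n"), 18)
  expect_equal(attr(res3, "dropped"), "s1")
})

test_that("paired t and Cohen's d follow their closed forms", {
  # differences 1,2,3: t = 2 / (1/sqrt(3)) = 3.464, df = 2
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  res <- paired_t(a, b)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$cohen_d, 2)

  eq <- paired_t(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$cohen_d, 0)

  flip <- paired_t(b, a)
  expect_equal(flip$t, -res$t)
  expect_equal(flip$p, res$p)

  const <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(const$t) && const$t > 0)
  expect_equal(const$p, 0)
})

test_that("Holm adjustment reproduces the hand-computed step-down", {
  expect_equal(holm_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.03, 4)), rep(0.12, 4))
  # monotone, capped, order-preserving; agrees with stats::p.adjust
  set.seed(14)
  for (r in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "holm"))
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("change-score correlations pool interventions and adjust with Holm", {
  set.seed(15)
  n <- 12
  base <- rnorm(n * 2)
  long <- NULL
  add_measure <- function(long, name, change) {
    for (iv in c("actual", "sham")) {
      idx <- if (iv == "actual") 1:n else (n + 1):(2 * n)
      long <- rbind(long,
        data.frame(subject = paste0("s", 1:n), intervention = iv,
                   block = "pre", measure = name, value = 0),
        data.frame(subject = paste0("s", 1:n), intervention = iv,
                   block = "post", measure = name, value = change[idx]))
    }
    long
  }
  long <- add_measure(long, "x", base)
  long <- add_measure(long, "y", 2 * base)            # r = 1 exactly
  long <- add_measure(long, "z", rnorm(2 * n))
  long <- add_measure(long, "const", rep(0, 2 * n))   # undefined r

  res <- correlate_changes(long)
  pr <- res$pairs
  expect_equal(pr$r[pr$measure1 == "x" & pr$measure2 == "y"], 1)
  expect_equal(pr$n[1], 2 * n)                        # pooled: two rows/subject
  expect_true(is.na(pr$r[pr$measure1 == "x" & pr$measure2 == "const"]))
  expect_true(all(pr$p_holm >= pr$p, na.rm = TRUE))
  expect_true(isSymmetric(res$r_matrix))
})

test_that("the interaction test has adequate power at a medium effect size", {
  # subject-level contrast effect d = 0.62 at n = 19, 500 replicate studies
  set.seed(16)
  n <- 19; d_eff <- 0.62; sigma <- 1 / sqrt(2)
  hits <- 0
  for (r in 1:500) {
    b <- rnorm(n)
    m <- cbind(b, b + d_eff + rnorm(n, 0, sigma), b, b + rnorm(n, 0, sigma))
    rownames(m) <- paste0("s", 1:n)
    res <- rm_anova_2x2(make_outcomes(m))
    hits <- hits + (res$p[res$effect == "interaction"] < 0.05)
  }
  expect_gte(hits / 500, 0.6)
})

test_that("pooled change correlations recover a true coupling of 0.7", {
  set.seed(17)
  r_hat <- vapply(1:300, function(r) {
    n <- 40                               # 20 subjects x both interventions
    x <- rnorm(n)
    y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(n)
    stats::cor(x, y)
  }, 0)
  expect_equal(mean(r_hat), 0.7, tolerance = 0.02)
})

test_that("Holm keeps the familywise error of the change matrix at level", {
  set.seed(18)
  n_sub <- 12
  fw <- vapply(1:300, function(r) {
    long <- NULL
    for (ms in paste0("m", 1:8)) {        # 28 independent pairs
      for (iv in c("actual", "sham")) {
        long <- rbind(long,
          data.frame(subject = paste0("s", 1:n_sub), intervention = iv,
                     block = "pre", measure = ms, value = 0),
          data.frame(subject = paste0("s", 1:n_sub), intervention = iv,
                     block = "post", measure = ms, value = rnorm(n_sub)))
      }
    }
    any(correlate_changes(long)$pairs$p_holm < 0.05, na.rm = TRUE)
  }, TRUE)
  # familywise error <= 0.05 within Monte-Carlo error (3 SE)
  expect_lte(mean(fw), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("the printed effect-size identity holds for the Results pairings", {
  printed <- rbind(c(20.13, 0.53), c(17.85, 0.50), c(8.26, 0.31),
                   c(6.56, 0.27), c(4.03, 0.18), c(3.40, 0.16))
  expect_equal(round(eta_p_sq(printed[, 1], 1, 18), 2), printed[, 2])
})
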