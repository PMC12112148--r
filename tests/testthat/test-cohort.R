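make_roster <- function(n_aa = 22, n_au = 8, neg_aa = 4, neg_au = 2) {
  ir <- c(ifelse(seq_len(n_aa) <= neg_aa, -5, 10),
          ifelse(seq_len(n_au) <= neg_au, -2, 12))
  data.frame(subject_id = sprintf("s%02d", seq_len(n_aa + n_au)),
             group = c(rep("AA", n_aa), rep("AU", n_au)),
             sex = "F", smoking = 0, IRmax = ir)
}

test_that("the negative-ischemic-response filter retains the expected counts", {
  ex <- apply_exclusions(make_roster())
  expect_equal(nrow(ex$retained), 24)
  expect_equal(as.integer(ex$counts[c("AA", "AU")]), c(18L, 6L))
  expect_equal(nrow(ex$excluded), 6)
  expect_true(all(grepl("IRmax < 0", ex$excluded$reason)))
})

test_that("exclusions are conservative, ordered and fully logged", {
  roster <- make_roster()
  # no subject flagged: identity with empty log
  clean <- roster; clean$IRmax <- abs(clean$IRmax)
  ex0 <- apply_exclusions(clean)
  expect_equal(ex0$retained, clean)
  expect_equal(nrow(ex0$excluded), 0)

  # all flagged: empty cohort with a warning, 100% logged
  allneg <- roster; allneg$IRmax <- -1
  expect_warning(exa <- apply_exclusions(allneg), "all subjects excluded")
  expect_equal(nrow(exa$retained), 0)
  expect_equal(nrow(exa$excluded), nrow(roster))

  # unmeasurable IRmax is its own reason; flag rules apply in order
  roster$IRmax[7] <- NA
  roster$smoking[c(8, 1)] <- 1     # subject 1 already excluded by IRmax < 0
  ex <- apply_exclusions(roster, sex = "F", exclude_flags = "smoking")
  expect_equal(nrow(ex$retained) + nrow(ex$excluded), nrow(roster))
  expect_equal(ex$excluded$reason[ex$excluded$subject_id == "s07"],
               "unmeasurable ischemic response")
  expect_equal(ex$excluded$reason[ex$excluded$subject_id == "s01"],
               "negative ischemic response (IRmax < 0)")
  expect_equal(ex$excluded$reason[ex$excluded$subject_id == "s08"],
               "comorbidity flag: smoking")
})

test_that("the normality gate selects tests at the expected rates", {
  expect_error(choose_test(c(1, 2), rnorm(10)), "insufficient data")

  # deterministic: same values, same selection
  set.seed(41)
  a <- rnorm(20); b <- rnorm(20)
  expect_identical(choose_test(a, b), choose_test(a, b))

  # two Gaussian samples: t-test selected at about (1 - alpha)^2
  set.seed(42)
  rate_t <- mean(replicate(400, choose_test(rnorm(20), rnorm(20)) == "t_test"))
  expect_equal(rate_t, 0.95^2, tolerance = 0.05)

  # strongly skewed samples: the gate reliably falls back to Mann-Whitney
  set.seed(43)
  rate_mw <- mean(replicate(200,
    choose_test(rexp(20), rexp(20)) == "mann_whitney"))
  expect_gte(rate_mw, 0.9)
})

test_that("two-group comparisons honour their conventions", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.5)
  same_t <- compare_groups(x, x, test = "t_test")
  expect_equal(same_t$statistic, 0)
  expect_equal(same_t$p_value, 1)

  same_mw <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "mann_whitney")
  expect_equal(same_mw$p_value, 1)

  expect_warning(
    degen <- compare_groups(rep(2, 5), rep(2, 5), test = "t_test"),
    "zero variance")
  expect_equal(degen$p_value, 1)

  # swapping groups negates the t statistic and keeps p unchanged
  set.seed(44)
  a <- rnorm(24); b <- rnorm(17, 1)
  ab <- compare_groups(a, b, test = "t_test")
  ba <- compare_groups(b, a, test = "t_test")
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$groups[[1]]$n, 24)

  # pooled-variance flag reproduces the classical two-sample t
  cl <- compare_groups(a, b, test = "t_test", var_equal = TRUE)
  expect_equal(cl$statistic,
               unname(stats::t.test(a, b, var.equal = TRUE)$statistic))
})

test_that("the gated comparison detects a 1.5-SD shift with high power", {
  set.seed(45)
  hits <- replicate(100, {
    a <- rnorm(24); b <- rnorm(17, 1.5)
    compare_groups(a, b)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("gated correlation picks Pearson or Spearman appropriately", {
  set.seed(46)
  x <- rnorm(30)
  lin <- correlate(x, 2 * x + 1)
  expect_equal(lin$method, "pearson")
  expect_equal(lin$estimate, 1.0)

  # monotone nonlinear map: rank correlation is exactly 1
  cub <- correlate(x, x^3)
  if (cub$method == "spearman") expect_equal(cub$estimate, 1.0)
  expect_lt(stats::cor(x, x^3), 1)

  expect_warning(kc <- correlate(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(kc$estimate))
  expect_error(correlate(1:3, 1:3), "at least 4")
})

test_that("group summaries pool patients by n-weighted means exactly", {
  set.seed(47)
  coh <- data.frame(group = rep(c("AA", "AU", "control"), c(18, 6, 17)),
                    FM = rlnorm(41, 3, 0.8), NOI = runif(41, 30, 95))
  s <- summarize_groups(coh, parameters = c("FM", "NOI"))
  pooled <- s[s$group == "AA + AU" & s$parameter == "FM", ]
  aa <- s[s$group == "AA" & s$parameter == "FM", ]
  au <- s[s$group == "AU" & s$parameter == "FM", ]
  expect_equal(pooled$n, 24)
  expect_equal(pooled$mean, (aa$n * aa$mean + au$n * au$mean) / 24)
  expect_equal(pooled$mean, mean(coh$FM[coh$group %in% c("AA", "AU")]))

  # identical values: SD 0; single subject: SD missing; empty group omitted
  coh2 <- data.frame(group = c("AA", "AA", "AU"), FM = c(5, 5, 7))
  s2 <- summarize_groups(coh2, parameters = "FM", pooled = NULL)
  expect_equal(s2$sd[s2$group == "AA"], 0)
  expect_true(is.na(s2$sd[s2$group == "AU"]))
})

test_that("cohort-level comparison wrapper compares pooled patients to controls", {
  set.seed(48)
  coh <- data.frame(group = rep(c("AA", "AU", "control"), c(18, 6, 17)),
                    logFM = c(rnorm(24, 1.55, 0.4), rnorm(17, 2.0, 0.35)))
  cmp <- compare_cohort(coh, parameters = "logFM")
  expect_named(cmp, "logFM")
  expect_s3_class(cmp$logFM, "fmsf_comparison")
  expect_equal(cmp$logFM$groups[["AA + AU"]]$n, 24)
  expect_equal(cmp$logFM$groups[["control"]]$n, 17)
})
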