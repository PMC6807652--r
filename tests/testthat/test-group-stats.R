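make_panel <- function(values, nsub) {
  grid <- expand.grid(session = c("T1000", "T1400", "T1800", "T2200"),
                      condition = c("RW", "SR"),
                      subject = sprintf("S%02d", seq_len(nsub)),
                      stringsAsFactors = FALSE)
  grid$value <- values
  grid
}

test_that("repeated-measures F values match the aov Error-strata oracle", {
  set.seed(42)
  for (rep in 1:12) {
    nsub <- sample(4:8, 1)
    g <- make_panel(rnorm(nsub * 8, sd = 2) +
                      0.8 * (rep(seq_len(nsub), each = 8)), nsub)
    got <- rmAnova(g$value, g$subject, g$condition, g$session)
    df <- data.frame(y = g$value, s = factor(g$subject),
                     a = factor(g$condition), b = factor(g$session))
    fit <- stats::aov(y ~ a * b + Error(s / (a * b)), data = df)
    sm <- summary(fit)
    f_a <- sm[["Error: s:a"]][[1]]["a", "F value"]
    f_b <- sm[["Error: s:b"]][[1]]["b", "F value"]
    f_ab <- sm[["Error: s:a:b"]][[1]]["a:b", "F value"]
    expect_equal(got$F_condition, f_a, tolerance = 1e-10)
    expect_equal(got$F_time, f_b, tolerance = 1e-10)
    expect_equal(got$F_interaction, f_ab, tolerance = 1e-10)
    expect_equal(got$df1_time, 3)
    expect_equal(got$df2_time, 3 * (nsub - 1))
    expect_equal(got$df2_condition, nsub - 1)
  }
})

test_that("F statistics are invariant to constant shifts and time relabelling", {
  set.seed(7)
  g <- make_panel(rnorm(48), 6)
  base <- rmAnova(g$value, g$subject, g$condition, g$session)
  shifted <- rmAnova(g$value + 100, g$subject, g$condition, g$session)
  expect_equal(base$F_condition, shifted$F_condition, tolerance = 1e-9)
  expect_equal(base$F_time, shifted$F_time, tolerance = 1e-9)
  relab <- c(T1000 = "T2200", T1400 = "T1800", T1800 = "T1400",
             T2200 = "T1000")
  perm <- rmAnova(g$value, g$subject, g$condition, relab[g$session])
  expect_equal(base$F_condition, perm$F_condition, tolerance = 1e-9)
})

test_that("degenerate and incomplete designs raise the documented errors", {
  g <- make_panel(rep(0, 24), 3)
  g$value <- 1 * (g$condition == "SR")   # zero within-cell error
  expect_error(rmAnova(g$value, g$subject, g$condition, g$session),
               "zero error variance")
  g2 <- make_panel(rnorm(32), 4)[-5, ]
  expect_error(rmAnova(g2$value, g2$subject, g2$condition, g2$session),
               "missing")
  g3 <- make_panel(rnorm(16), 2)
  expect_error(rmAnova(g3$value, g3$subject, g3$condition, g3$session),
               "3 subjects")
})

test_that("type-I error of the condition test is nominal under the null", {
  set.seed(11)
  p <- replicate(600, {
    g <- make_panel(rnorm(13 * 8), 13)
    rmAnova(g$value, g$subject, g$condition, g$session)$p_condition
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
  # p-values approximately uniform
  expect_lt(abs(mean(p) - 0.5), 0.05)
})

test_that("condition-effect power grows with effect size as the F theory
           predicts", {
  # for a planted shift of delta within-cell SDs the noncentrality is
  # 26 delta^2 at n = 13; power crosses 0.8 between delta = 0.5 (~0.62)
  # and delta = 0.65 (~0.85)
  power_at <- function(delta, reps = 150) {
    mean(replicate(reps, {
      subj <- rnorm(13, sd = 1)
      g <- make_panel(rep(subj, each = 8), 13)
      g$value <- g$value + rnorm(104) + delta * (g$condition == "SR")
      rmAnova(g$value, g$subject, g$condition, g$session)$p_condition
    }) < 0.05)
  }
  set.seed(13)
  p50 <- power_at(0.5)
  p80 <- power_at(0.8)
  expect_gt(p50, 0.45)
  expect_gt(p80, 0.85)
  expect_gt(p80, p50)
  # analytic check of the simulated power at delta = 0.5
  analytic <- stats::pf(stats::qf(0.95, 1, 12), 1, 12,
                        ncp = 26 * 0.25, lower.tail = FALSE)
  expect_lt(abs(p50 - analytic), 0.12)
})

test_that("Greenhouse-Geisser correction shrinks df consistently", {
  set.seed(3)
  g <- make_panel(rnorm(40), 5)
  g$value <- g$value + 1.5 * (g$session == "T2200")   # real time effect
  raw <- rmAnova(g$value, g$subject, g$condition, g$session)
  gg <- rmAnova(g$value, g$subject, g$condition, g$session,
                ggCorrection = TRUE)
  expect_lte(gg$df1_time, raw$df1_time)
  expect_gte(gg$df1_time, 1)            # epsilon floored at 1/(b-1)
  expect_equal(gg$F_time, raw$F_time)   # F itself is untouched
  expect_equal(gg$p_time,
               stats::pf(gg$F_time, gg$df1_time, gg$df2_time,
                         lower.tail = FALSE), tolerance = 1e-12)
  # with F > 1 the corrected p cannot be smaller
  if (raw$F_time > 1) expect_gte(gg$p_time, raw$p_time - 1e-12)
})

test_that("Benjamini-Hochberg step-up matches the hand calculation", {
  res <- fdrBH(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(res$q, rep(0.04, 4))
  expect_equal(res$rejected, 1:4)
  res1 <- fdrBH(rep(1, 5))
  expect_equal(res1$q, rep(1, 5))
  expect_length(res1$rejected, 0)
  expect_equal(fdrBH(0.03)$q, 0.03)
  expect_error(fdrBH(c(0.1, 1.2)), "0, 1")
  # BH never rejects more than the uncorrected test; q monotone in p
  set.seed(5)
  p <- stats::runif(50)^2
  res2 <- fdrBH(p)
  expect_lte(length(res2$rejected), sum(p < 0.05))
  expect_true(all(res2$q >= p - 1e-12))
  ord <- order(p)
  expect_true(all(diff(res2$q[ord]) >= -1e-12))
})

test_that("post hoc paired contrasts match a closed-form paired t", {
  g <- make_panel(0, 2)
  g$value <- c(1, 2, 3, 4, 2, 4, 6, 8,    # S01 RW, SR
               2, 3, 4, 5, 3, 5, 7, 9)    # S02 RW, SR
  ct <- posthocContrasts(g$value, g$subject, g$condition, g$session)
  expect_equal(nrow(ct), 4)
  # at T1000 the paired differences are (1, 1): sd 0 -> handled, but use
  # T1400: diffs (2, 2) -> also sd 0; construct unequal diffs instead
  g$value[16] <- 11   # S02 SR T2200
  ct <- posthocContrasts(g$value, g$subject, g$condition, g$session)
  d <- c(8 - 4, 11 - 5)
  tstat <- mean(d) / (stats::sd(d) / sqrt(2))
  row <- ct[ct$session == "T2200", ]
  expect_equal(row$t, tstat, tolerance = 1e-12)
  expect_equal(row$p, 2 * stats::pt(abs(tstat), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(row$direction, "SR>RW")
})

test_that("identical RW and SR values give t = 0, p = 1 at every time", {
  g <- make_panel(rep(rnorm(4 * 3), 2 * 1), 3)
  # construct: same values in RW and SR per subject/session
  vals <- rnorm(12)
  g$value <- NA
  for (i in seq_len(nrow(g))) {
    key <- paste(g$subject[i], g$session[i])
    g$value[i] <- vals[match(key, unique(paste(g$subject, g$session)))]
  }
  ct <- posthocContrasts(g$value, g$subject, g$condition, g$session)
  expect_equal(ct$t, rep(0, 4))
  expect_equal(ct$p, rep(1, 4))
  ctb <- posthocContrasts(g$value, g$subject, g$condition, g$session,
                          correction = "bonferroni")
  expect_equal(ctb$p, rep(1, 4))
})

test_that("ROI summarisation applies the strict more-than-half rule", {
  fake <- function(nsig, node = "r1") {
    q <- c(rep(0.01, nsig), rep(0.5, 25 - nsig))
    data.frame(node = node, measure = "degree", density = densityGrid(),
               q_condition = 0.5, q_time = q)
  }
  s13 <- summarizeRoi(fake(13))
  expect_true(s13$flagged_time)
  expect_equal(s13$n_significant_time, 13)
  s12 <- summarizeRoi(fake(12))
  expect_false(s12$flagged_time)
  expect_false(s13$flagged_condition)
})

test_that("anovaPanel corrects within the density family and tolerates
           degenerate cells", {
  set.seed(21)
  panel <- do.call(rbind, lapply(c(0.1, 0.2, 0.3), function(d) {
    g <- make_panel(rnorm(40), 5)
    g$density <- d; g$measure <- "path_length"; g$node <- "global"
    g
  }))
  res <- anovaPanel(panel)
  expect_equal(nrow(res), 3)
  expect_true(all(res$q_condition >= res$p_condition - 1e-12))
  # degenerate cell -> NA row with warning, other cells unaffected
  panel2 <- panel
  panel2$value[panel2$density == 0.1] <- 7
  expect_warning(res2 <- anovaPanel(panel2), "zero error variance")
  expect_true(is.na(res2$p_condition[res2$density == 0.1]))
  expect_false(anyNA(res2$p_condition[res2$density != 0.1]))
})
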