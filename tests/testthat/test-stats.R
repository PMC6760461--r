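test_that("partial eta squared follows its closed form", {
  expect_equal(partial_eta_squared(0, 1, 5), 0)
  expect_equal(round(partial_eta_squared(8.392, 1, 5), 3), 0.627)
  expect_equal(partial_eta_squared(4, 2, 10), 8 / 18)
})

test_that("observed power hits its limits", {
  expect_equal(observed_power(0, 1, 5), 0.05, tolerance = 1e-12)
  expect_gt(observed_power(1e5, 1, 5), 0.999999)
  # monotone in F
  f <- c(0, 1, 5, 20)
  expect_true(all(diff(observed_power(f, 1, 5)) > 0))
  # independent numerical-integration oracle for the noncentral tail
  crit <- qf(0.95, 1, 5)
  oracle <- stats::integrate(function(x) df(x, 1, 5, ncp = 8.392),
                             crit, Inf, rel.tol = 1e-10)$value
  expect_equal(observed_power(8.392, 1, 5), oracle, tolerance = 1e-6)
})

test_that("session aggregation matches an independent group-by oracle", {
  set.seed(10)
  tm <- expand.grid(session = c("S1", "S2"), condition = c("SOLO", "PAIRED"),
                    unit = c("J1", "J2"), trial = 1:3,
                    stringsAsFactors = FALSE)
  tm$measure <- "G"
  tm$value <- runif(nrow(tm))
  got <- aggregate_session_means(tm)
  oracle <- stats::aggregate(value ~ session + condition + unit + measure,
                             tm, mean)
  merged <- merge(got, oracle, by = c("session", "condition", "unit",
                                      "measure"))
  expect_equal(merged$value.x, merged$value.y)
  expect_true(all(got$n_trials == 3))
  # single trial: mean equals that trial; two trials 0.4/0.6 -> 0.5
  one <- data.frame(session = "S1", condition = "SOLO", unit = "J1",
                    measure = "G", value = 0.7, trial = 1)
  expect_equal(aggregate_session_means(one)$value, 0.7)
  two <- rbind(one, transform(one, value = 0.5, trial = 2))
  two$value <- c(0.4, 0.6)
  expect_equal(aggregate_session_means(two)$value, 0.5)
})

test_that("split-plot F values match the difference-score oracle", {
  set.seed(33)
  for (rep in 1:5) {
    tbl <- expand.grid(session = sprintf("S%d", 1:4),
                       condition = c("SOLO", "PAIRED"),
                       skill = c("less", "more"))
    tbl$matched <- tbl$session %in% c("S1", "S2")
    tbl$value <- rnorm(nrow(tbl))
    a <- as.data.frame(mixed_anova(tbl))
    cm <- t(sapply(sprintf("S%d", 1:4), function(s) {
      x <- tbl[tbl$session == s, ]
      c(ss = x$value[x$condition == "SOLO" & x$skill == "less"],
        sm = x$value[x$condition == "SOLO" & x$skill == "more"],
        ps = x$value[x$condition == "PAIRED" & x$skill == "less"],
        pm = x$value[x$condition == "PAIRED" & x$skill == "more"])
    }))
    grp <- ifelse(c(TRUE, TRUE, FALSE, FALSE), 1, -1)
    tsq <- function(d) unname(summary(lm(d ~ grp))$coefficients[, 3]^2)
    f_of <- function(eff) a$F[a$effect == eff]
    expect_equal(f_of("matched"),
                 anova(lm(rowMeans(cm) ~ grp))$F[1], tolerance = 1e-10)
    dc <- (cm[, "ps"] + cm[, "pm"] - cm[, "ss"] - cm[, "sm"]) / 2
    expect_equal(c(f_of("condition"), f_of("matched:condition")),
                 tsq(dc), tolerance = 1e-10)
    ds <- (cm[, "sm"] + cm[, "pm"] - cm[, "ss"] - cm[, "ps"]) / 2
    expect_equal(c(f_of("skill"), f_of("matched:skill")),
                 tsq(ds), tolerance = 1e-10)
    dcc <- (cm[, "pm"] - cm[, "ps"] - cm[, "sm"] + cm[, "ss"]) / 2
    expect_equal(c(f_of("condition:skill"),
                   f_of("matched:condition:skill")),
                 tsq(dcc), tolerance = 1e-10)
    expect_true(all(a$df1 == 1) && all(a$df2 == 2))
  }
})

test_that("constant response gives F = 0 everywhere", {
  tbl <- expand.grid(session = sprintf("S%d", 1:5),
                     condition = c("SOLO", "PAIRED"),
                     skill = c("less", "more"))
  tbl$matched <- tbl$session %in% c("S1", "S2")
  tbl$value <- 0.42
  a <- mixed_anova(tbl)
  expect_true(all(a$F == 0))
  expect_true(all(a$p == 1))
  expect_true(all(a$partial_eta_sq == 0))
})

test_that("two-level single-within design reduces to the paired t test", {
  set.seed(44)
  tbl <- expand.grid(session = sprintf("S%d", 1:7),
                     condition = c("SOLO", "PAIRED"))
  tbl$value <- rnorm(14)
  a <- mixed_anova(tbl, within = "condition", between = NULL)
  d <- tbl$value[tbl$condition == "SOLO"] -
    tbl$value[tbl$condition == "PAIRED"]
  expect_equal(a$F[a$effect == "condition"],
               unname(t.test(d)$statistic)^2, tolerance = 1e-10)
})

test_that("group-size preconditions are enforced", {
  tbl <- expand.grid(session = sprintf("S%d", 1:3),
                     condition = c("SOLO", "PAIRED"),
                     skill = c("less", "more"))
  tbl$matched <- tbl$session == "S1"  # one session in a group
  tbl$value <- rnorm(nrow(tbl))
  expect_error(mixed_anova(tbl), "at least two sessions")
  tbl$value <- factor("a")
  expect_error(mixed_anova(transform(tbl, value = "a")), "numeric")
})

test_that("follow-up t tests match closed forms and Bonferroni rules", {
  x <- c(0.1, 0.3, 0.5, 0.4); y <- x
  r <- followup_ttests(list(null = list(x = x, y = y)))
  expect_equal(r$t, 0)
  expect_equal(r$cohen_d, 0)
  expect_equal(r$p_corrected, r$p)  # single contrast: x1

  set.seed(55)
  x <- rnorm(8); y <- x + rnorm(8, mean = 0.5)
  d <- x - y
  r <- followup_ttests(list(a = list(x = x, y = y),
                            b = list(x = y, y = x)))
  tstat <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(r$t[1], tstat, tolerance = 1e-12)
  expect_equal(r$df[1], 7)
  expect_equal(r$cohen_d[1], mean(d) / sd(d), tolerance = 1e-12)
  expect_true(all(r$p_corrected >= r$p))
  expect_true(all(r$p_corrected <= 1))
  expect_equal(r$p_corrected, pmin(2 * r$p, 1))
})

test_that("hyperbrain group tests: cardinality, nulls and degeneracy", {
  set.seed(66)
  tbl <- expand.grid(session = sprintf("S%d", 1:40), measure = c("G", "C",
                                                                 "SWI", "D", "IIR"), stringsAsFactors = FALSE)
  tbl$matched <- rep(c(TRUE, FALSE), each = 20)[match(tbl$session,
                                                      sprintf("S%d", 1:40))]
  tbl$value <- rnorm(nrow(tbl))  # identical distributions
  r <- hyperbrain_group_ttests(tbl)
  expect_equal(nrow(r), 5)
  expect_true(all(r$p > 0.001))  # no systematic rejection under the null
  # degenerate zero-variance groups trip the guard
  tbl0 <- data.frame(session = sprintf("S%d", 1:7), measure = "G",
                     matched = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                                 FALSE),
                     value = c(0, 0, 0, 1, 1, 1, 1))
  r0 <- hyperbrain_group_ttests(tbl0, measures = "G")
  expect_true(r0$zero_variance)
  expect_equal(r0$p, 0)
  expect_error(hyperbrain_group_ttests(
    data.frame(session = "S1", measure = "G", matched = TRUE, value = 1),
    measures = "G"), "two levels")
})
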