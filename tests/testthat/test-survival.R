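test_that("median dichotomization uses the 'ties go Low' convention", {
  expect_identical(as.character(median_dichotomize(c(1, 2, 3, 4))),
                   c("Low", "Low", "High", "High"))
  expect_identical(as.character(median_dichotomize(c(1, 2, 2, 3))),
                   c("Low", "Low", "Low", "High"))
  expect_error(median_dichotomize(c(3, 3, 3)), "identical")
  expect_error(median_dichotomize(2), "at least 2")

  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(2 * sample(3:20, 1) + 1)  # odd length
    grp <- median_dichotomize(x)
    expect_lte(sum(grp == "High"), (length(x) - 1) / 2)
    expect_identical(as.character(grp[which(x == median(x))]), "Low")
  }
})

test_that("Kaplan-Meier estimate matches hand products and survfit", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))

  all_cens <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))

  # times (1, 2 censored, 3): S on [1,3) = 2/3, S after 3 = 0
  km2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival, c(2 / 3, 2 / 3, 0))

  expect_error(km_curve(c(1, -2, 3), c(1, 1, 1)), "positive")

  skip_if_not_installed("survival")
  set.seed(11)
  time <- round(rexp(60), 1) + 0.05
  event <- rbinom(60, 1, 0.7)
  km3 <- km_curve(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km3$survival,
               summary(sf, times = km3$time)$surv, tolerance = 1e-12)
})

test_that("KM invariants: monotone, bounded, ECDF complement when uncensored", {
  set.seed(12)
  for (i in 1:5) {
    n <- sample(10:80, 1)
    time <- rexp(n)
    km <- km_curve(time, rep(1, n))
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= -1e-12 & km$survival <= 1))
    ecdf_at <- vapply(km$time, function(t) mean(time <= t), numeric(1))
    expect_equal(km$survival, 1 - ecdf_at, tolerance = 1e-12)
  }
})

test_that("log-rank matches the hand-computed fixture and edge rules", {
  f <- logrank_fixture
  lr <- logrank_test(f$time, f$event, f$group)
  expect_equal(lr$observed, f$observed)
  expect_equal(lr$expected, f$expected, tolerance = 1e-12)
  expect_equal(lr$statistic, f$statistic, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(f$statistic, 1, lower.tail = FALSE))

  # identical groups (duplicated data) carry no signal
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                      rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)

  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "2 groups")

  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(f$time, f$event) ~ f$group)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-12)
})

test_that("log-rank is invariant under monotone time transformations", {
  set.seed(13)
  time <- rexp(40)
  event <- rbinom(40, 1, 0.8)
  group <- rep(c("a", "b"), 20)
  base <- logrank_test(time, event, group)
  for (f in list(function(t) t^2, function(t) log1p(t) + 1e-9,
                 function(t) 3 * t)) {
    tr <- logrank_test(f(time), event, group)
    expect_equal(tr$statistic, base$statistic, tolerance = 1e-12)
  }
})

test_that("permuted null labels give uniform log-rank p-values", {
  set.seed(14)
  time <- rexp(40)
  event <- rbinom(40, 1, 0.85)
  event[1] <- 1
  labels <- rep(c("a", "b"), each = 20)
  ps <- vapply(1:2000, function(i) {
    logrank_test(time, event, sample(labels))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Newton-Raphson Cox matches the grid-search oracle on fixtures", {
  for (nm in names(cox_fixtures)) {
    f <- cox_fixtures[[nm]]
    fit <- cox_fit(f$time, f$event, cbind(x = f$x))
    beta_grid <- cox_grid_oracle(f$time, f$event, f$x)
    expect_lt(abs(unname(fit$coef) - beta_grid), 1e-3)
    expect_true(fit$converged)
  }
})

test_that("Cox fit agrees with an independent Efron implementation", {
  skip_if_not_installed("survival")
  set.seed(15)
  n <- 120
  df <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
  df$time <- round(rexp(n, exp(0.6 * df$a - 0.5 * df$b)), 1) + 0.05
  df$event <- rbinom(n, 1, 0.8)
  fit <- cox_fit(df$time, df$event, as.matrix(df[, c("a", "b", "c")]))
  ref <- survival::coxph(survival::Surv(time, event) ~ a + b + c,
                         data = df, ties = "efron")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-7)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("Cox partial likelihood is invariant to time rescaling", {
  f <- cox_fixtures$censored
  fit1 <- cox_fit(f$time, f$event, cbind(x = f$x))
  fit2 <- cox_fit(2 * f$time, f$event, cbind(x = f$x))
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-12)
  expect_equal(fit1$hr, fit2$hr, tolerance = 1e-12)
  expect_equal(fit1$wald_p, fit2$wald_p, tolerance = 1e-12)
})

test_that("degenerate Cox designs are caught", {
  f <- cox_fixtures$distinct
  expect_error(cox_fit(f$time, f$event, cbind(f$x, 2 * f$x)), "collinear")
  # perfect separation: the covariate orders survival exactly
  sep <- cox_fit(1:8, rep(1, 8), cbind(x = c(1, 1, 1, 1, 0, 0, 0, 0)))
  expect_false(sep$converged)
  expect_match(sep$diagnostic, "separation|monotone")
  expect_error(cox_fit(1:4, rep(0, 4), cbind(x = rnorm(4))),
               "at least one event")
})

test_that("null-covariate Cox CIs cover 1 at the nominal rate", {
  set.seed(16)
  cover <- vapply(1:200, function(i) {
    n <- 120
    x <- rnorm(n)
    time <- rexp(n)
    event <- rbinom(n, 1, 0.85)
    event[1] <- 1
    fit <- cox_fit(time, event, cbind(x = x))
    fit$ci_lower[1] <= 1 && 1 <= fit$ci_upper[1]
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("dichotomized HR direction matches the KM ordering on fixtures", {
  coh <- small_cohort(seed = 47)
  marker <- coh$truth$marker_value
  uni <- univariate_marker_analysis(coh$clinical$time, coh$clinical$event,
                                    marker)
  km <- uni$km
  last_t <- max(km$time[km$n_event > 0])
  s_at <- function(g) {
    sub <- km[km$group == g & km$time <= last_t, ]
    sub$survival[nrow(sub)]
  }
  if (uni$cox_dichotomized$hr[1] > 1) {
    expect_lte(s_at("High"), s_at("Low"))
  } else {
    expect_gte(s_at("High"), s_at("Low"))
  }
})

test_that("subtype-adjusted analysis mirrors the published table layout", {
  coh <- small_cohort(seed = 48)
  marker <- coh$truth$marker_value
  res <- subtype_adjusted_analysis(coh$clinical$time, coh$clinical$event,
                                   marker, coh$clinical$subtype,
                                   mode = "dichotomized")
  expect_identical(nrow(res$table), 5L)  # marker, overall, three contrasts
  expect_identical(res$table$term[1], "marker High vs. Low")
  expect_identical(res$table$term[2], "Subtype (overall)")
  expect_setequal(res$table$term[3:5],
                  c("Classical vs. Mesenchymal", "Neural vs. Mesenchymal",
                    "Proneural vs. Mesenchymal"))
  expect_true(all(res$table$ci_lower[-2] <= res$table$hr[-2] &
                  res$table$hr[-2] <= res$table$ci_upper[-2]))
  # likelihood-ratio variant of the overall test is available and sane
  lrt <- subtype_adjusted_analysis(coh$clinical$time, coh$clinical$event,
                                   marker, coh$clinical$subtype,
                                   overall_test = "lrt")
  expect_true(lrt$overall_p >= 0 && lrt$overall_p <= 1)
})

test_that("null subtype effects give a calibrated overall test", {
  set.seed(17)
  ps <- vapply(1:150, function(i) {
    n <- 120
    subtype <- sample(c("Classical", "Mesenchymal", "Neural", "Proneural"),
                      n, replace = TRUE)
    marker <- rnorm(n)
    time <- rexp(n)
    event <- rbinom(n, 1, 0.85)
    event[1] <- 1
    subtype_adjusted_analysis(time, event, marker, subtype)$overall_p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("multivariate marker and subtype effects are recovered", {
  # truth: marker HR 1.6; subtype HRs 0.6, 1.1, 0.9 vs the reference
  hrs <- matrix(NA_real_, 60, 2)
  for (i in seq_len(nrow(hrs))) {
    coh <- simulate_survival_cohort(cohort_sim_config(
      n_samples = 600, marker_log_hr = log(1.6),
      subtype_log_hrs = c(Proneural = log(0.6), Neural = log(1.1),
                          Classical = log(0.9), Mesenchymal = 0),
      subtype_proportions = rep(0.25, 4), seed = 6000 + i))
    res <- subtype_adjusted_analysis(coh$clinical$time, coh$clinical$event,
                                     coh$truth$marker_value,
                                     coh$clinical$subtype)
    hrs[i, 1] <- res$table$hr[res$table$term == "marker High vs. Low"]
    hrs[i, 2] <- res$table$hr[res$table$term == "Proneural vs. Mesenchymal"]
  }
  expect_lt(abs(mean(hrs[, 1]) - 1.6) / 1.6, 0.05)
  expect_lt(abs(mean(hrs[, 2]) - 0.6) / 0.6, 0.10)
})

test_that("zero-event subtypes flag their contrasts as unstable", {
  set.seed(18)
  n <- 60
  subtype <- rep(c("Mesenchymal", "Classical", "Neural"), each = 20)
  time <- rexp(n)
  event <- rbinom(n, 1, 0.9)
  event[subtype == "Neural"] <- 0
  event[1] <- 1
  res <- subtype_adjusted_analysis(time, event, rnorm(n), subtype)
  expect_true(res$table$unstable[res$table$term == "Neural vs. Mesenchymal"])
})
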