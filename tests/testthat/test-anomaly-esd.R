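test_that("the ESD critical value reproduces the textbook two-sided value", {
  # classical generalized ESD table value for n = 54, i = 1, alpha = 0.05
  expect_equal(esd_lambda(54, 1, 0.05, "both"), 3.16, tolerance = 0.002)
})

test_that("lambda decreases in k and grows toward its bound as alpha shrinks", {
  lam <- esd_lambda(100, 1:20, 0.01, "upper")
  expect_true(all(diff(lam) < 0))
  # lambda_1 rises monotonically as alpha shrinks, approaching the algebraic
  # ceiling (n - 1) / sqrt(n) from below
  alphas <- 10^-(2:12)
  lam1 <- vapply(alphas, function(a) esd_lambda(100, 1, a, "upper"), numeric(1))
  expect_true(all(diff(lam1) > 0))
  expect_true(all(lam1 < 99 / sqrt(100)))
  expect_gt(lam1[length(lam1)], 6)
  expect_error(esd_lambda(10, 9, 0.05, "both"), "Degenerate")
})

test_that("all-equal residuals yield no outliers with a diagnostic warning", {
  expect_warning(res <- robust_esd(rep(0, 100), alpha = 0.01, k_max = 5),
                 "scale is zero")
  expect_equal(nrow(res), 0)
})

test_that("gross planted values are recovered exactly, matching the brute-force loop", {
  set.seed(13)
  x <- rnorm(100)
  planted <- c(17, 40, 83)
  x[planted] <- 15
  res <- robust_esd(x, alpha = 0.01, k_max = 10, direction = "upper")
  expect_setequal(res$index[res$outlier], planted)
  expect_equal(sort(res$index[res$outlier]),
               robust_esd_oracle(x, 0.01, 10, "upper"))
})

test_that("with mean/sd the procedure reduces to classical generalized ESD", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(15:50, 1)
    x <- rt(n, df = 4)
    if (rep %% 3 == 0) x[sample(n, 2)] <- x[sample(n, 2)] + 8
    k_max <- sample(2:5, 1)
    direction <- sample(c("both", "upper"), 1)
    got <- robust_esd(x, alpha = 0.05, k_max = k_max, direction = direction,
                      center = "mean")
    oracle <- classical_esd_oracle(x, 0.05, k_max, direction)
    expect_equal(sort(got$index[got$outlier]), sort(oracle$indices),
                 info = paste("rep", rep))
    expect_equal(got$stat, oracle$R, tolerance = 1e-12)
    expect_equal(got$lambda, oracle$lambda, tolerance = 1e-12)
  }
})

test_that("a gross outlier does not mask a moderate one under median/MAD", {
  set.seed(41)
  x <- rnorm(200)
  x[50] <- 50   # gross
  x[120] <- 8   # moderate
  robust <- robust_esd(x, alpha = 0.01, k_max = 20, direction = "upper")
  expect_true(all(c(50, 120) %in% robust$index[robust$outlier]))
  # the classical variant's verdict on the moderate one is scale-inflated:
  # its first-step sd includes the gross value, shrinking later statistics
  classical <- robust_esd(x, alpha = 0.01, k_max = 20, direction = "upper",
                          center = "mean")
  expect_gte(sum(robust$outlier), sum(classical$outlier))
})

test_that("ties in the extremum break toward the earliest position", {
  set.seed(3)
  x <- c(rnorm(50, 0, 0.1), 10, rnorm(10, 0, 0.1), 10)
  res <- robust_esd(x, alpha = 0.01, k_max = 3, direction = "upper")
  expect_equal(res$index[1], 51)
  expect_equal(res$index[2], 62)
})

test_that("null noise rarely produces any flag at alpha = 0.01", {
  set.seed(59)
  hits <- vapply(1:200, function(i) {
    res <- robust_esd(rnorm(300), alpha = 0.01, k_max = 30,
                      direction = "upper")
    sum(res$outlier) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("the full detector recovers injected spikes and nothing else", {
  spec <- panel_spec(anomaly_magnitude = 10)
  sim <- gen_pageview_panel(spec, seed = 1)
  fit <- shesd_detect(aggregate_daily_total(sim$panel))
  expect_setequal(as.character(tidy(fit)$date),
                  as.character(sim$truth$anomaly_dates))
  # OutlierResult invariants
  expect_lte(nrow(fit$outliers), floor(0.10 * 1096))
  expect_true(all(fit$outliers$observed > fit$outliers$expected))
  expect_true(all(fit$outliers$stat > fit$outliers$lambda))
  # deterministic under identical params
  fit2 <- shesd_detect(aggregate_daily_total(sim$panel))
  expect_identical(tidy(fit), tidy(fit2))
})

test_that("an exact-model series with zero noise yields zero outliers", {
  spec <- panel_spec(noise = "none", n_anomalies = 0, n_days = 364)
  sim <- gen_pageview_panel(spec, seed = 1)
  fit <- suppressWarnings(shesd_detect(aggregate_daily_total(sim$panel)))
  expect_equal(nrow(fit$outliers), 0)
})

test_that("detection is invariant to shifts and equivariant under positive scaling", {
  spec <- panel_spec(n_days = 400, n_anomalies = 4, anomaly_magnitude = 10)
  sim <- gen_pageview_panel(spec, seed = 5)
  s <- aggregate_daily_total(sim$panel)
  base <- tidy(shesd_detect(s))$date
  shifted <- dplyr::mutate(s, views = .data$views + 5000)
  scaled <- dplyr::mutate(s, views = .data$views * 3.7)
  expect_equal(tidy(shesd_detect(shifted))$date, base)
  expect_equal(tidy(shesd_detect(scaled))$date, base)
})

test_that("Breusch-Pagan matches a hand-computed auxiliary regression", {
  r <- c(1.2, -0.4, 0.3, -2.1, 0.8, 0.2)
  f <- c(10, 12, 11, 15, 9, 13)
  got <- breusch_pagan(r, f)
  # normal-equations oracle for the regression of r^2 on f
  y <- r^2
  X <- cbind(1, f)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(got$statistic, 6 * r2, tolerance = 1e-12)
  expect_equal(got$p_value, pchisq(6 * r2, 1, lower.tail = FALSE))
  # independent implementation cross-check
  skip_if_not_installed("lmtest")
  model <- lm(c(r + f) ~ f)
  ref <- lmtest::bptest(model, varformula = ~ f)
  ours <- breusch_pagan(residuals(model), fitted(model))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
})

test_that("Breusch-Pagan separates homo- from heteroscedastic residuals", {
  set.seed(67)
  n <- 1000
  f <- runif(n, 10, 100)
  expect_gt(breusch_pagan(rnorm(n), f)$p_value, 0.05)
  expect_lt(breusch_pagan(rnorm(n, 0, sqrt(f)), f)$p_value, 0.01)
  expect_error(breusch_pagan(rnorm(10), rep(1, 10)), "constant")
  expect_error(breusch_pagan(rnorm(10), rnorm(9)), "equal length")
})
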