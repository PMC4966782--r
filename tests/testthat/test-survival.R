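# definitional log-rank oracle: observed-minus-expected sums by enumeration
logrank_oracle <- function(times, event, g2) {
  ts <- sort(unique(times[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n2 <- sum(at_risk & g2)
    d <- sum(times == t & event == 1)
    d2 <- sum(times == t & event == 1 & g2)
    O <- O + d2
    E <- E + d * n2 / n
    if (n > 1) V <- V + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# hand-enumerated product-limit estimator
km_oracle <- function(times, event) {
  ts <- sort(unique(times[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(times >= ts[i])
    d <- sum(times == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

test_that("the ESM is the dominant left singular direction", {
  w <- c(3, -1, 2, 0.5)
  w <- w / sqrt(sum(w^2))
  z <- c(1, -2, 0.5, 3, -1, 0.25)
  X <- w %o% z
  rownames(X) <- paste0("g", 1:4)
  esm <- extract_esm(X)
  expect_equal(abs(esm$loadings), abs(w), tolerance = 1e-10)
  expect_equal(sqrt(sum(esm$loadings^2)), 1, tolerance = 1e-10)
  expect_gt(esm$loadings[which.max(abs(esm$loadings))], 0)
  # scores proportional to the right factor
  expect_equal(abs(cor(as.vector(esm$train_scores), z)), 1,
               tolerance = 1e-10)
})

test_that("ESM extraction is permutation-equivariant and matches an oracle", {
  set.seed(3)
  X <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(paste0("g", 1:40), NULL))
  X <- X - rowMeans(X)
  esm <- extract_esm(X)
  perm <- sample.int(40)
  esm_p <- extract_esm(X[perm, ])
  expect_equal(esm_p$train_scores, esm$train_scores, tolerance = 1e-8)
  sv <- svd(X, nu = 1)
  expect_equal(abs(esm$loadings), abs(drop(sv$u)), tolerance = 1e-8)
  expect_error(extract_esm(matrix(0, 3, 5)), "zero")
  expect_error(extract_esm(X[1, , drop = FALSE]), "2 signature variables")
})

test_that("projection matches training scores and is ID-robust", {
  set.seed(5)
  X <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), NULL))
  esm <- extract_esm(X)
  expect_equal(project_scores(esm, X), unname(esm$train_scores),
               tolerance = 1e-12)
  shuf <- sample.int(10)
  expect_equal(project_scores(esm, X[shuf, , drop = FALSE]),
               unname(esm$train_scores), tolerance = 1e-12)
  expect_error(project_scores(esm, X[-1, , drop = FALSE]), "g1")
})

test_that("quartile groups use floor(m/4) and are affine-invariant", {
  set.seed(7)
  for (m in c(291L, 99L)) {
    g <- quartile_groups(rnorm(m))
    expect_equal(sum(g == "top"), m %/% 4L)
    expect_equal(sum(g == "bottom"), m %/% 4L)
  }
  g8 <- quartile_groups(1:8)
  expect_equal(which(g8 == "bottom"), 1:2)
  expect_equal(which(g8 == "top"), 7:8)
  s <- rnorm(40)
  expect_identical(quartile_groups(s), quartile_groups(3 * s + 10))
  expect_error(quartile_groups(1:7), "at least 8")
})

test_that("the log-rank test matches the definitional oracle", {
  # 6-subject hand-worked data set with censoring in both groups
  times <- c(1, 2, 3, 4, 5, 6)
  censored <- c(0, 1, 0, 0, 0, 1)
  groups <- c("a", "a", "a", "b", "b", "b")
  res <- logrank_test(times, censored, groups)
  ora <- logrank_oracle(times, 1 - censored, groups == "b")
  expect_equal(res$statistic, ora, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(ora, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  set.seed(11)
  t2 <- rexp(30) + 0.1
  c2 <- rbinom(30, 1, 0.25)
  g2 <- rep(c("x", "y"), 15)
  res2 <- logrank_test(t2, c2, g2)
  expect_equal(res2$statistic, logrank_oracle(t2, 1 - c2, g2 == "y"),
               tolerance = 1e-8)
})

test_that("identical groups give statistic 0 and one-group input errors", {
  times <- rep(c(1, 2, 3), 2)
  censored <- rep(c(0, 1, 0), 2)
  groups <- rep(c("a", "b"), each = 3)
  res <- logrank_test(times, censored, groups)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "a")), "two")
})

test_that("Cox regression recovers a planted log-hazard ratio", {
  set.seed(13)
  n <- 500
  x <- rnorm(n)
  times <- rexp(n, rate = 0.1 * exp(1 * x))
  censored <- as.numeric(times > quantile(times, 0.9))
  times <- pmin(times, quantile(times, 0.9))
  fit <- cox_ph(times, censored, data.frame(x = x))
  expect_equal(fit["x", "coef"], 1, tolerance = 0.2)
  expect_lt(fit["x", "p_value"], 1e-6)
})

test_that("Cox regression rejects degenerate inputs and null covariates", {
  set.seed(17)
  n <- 120
  times <- rexp(n) + 0.01
  censored <- rbinom(n, 1, 0.2)
  expect_error(cox_ph(times, censored, data.frame(x = rep(2, n))),
               "constant")
  # independent covariate: small coefficient, non-significant typically
  fit <- cox_ph(times, censored, data.frame(x = rnorm(n)))
  expect_lt(abs(fit["x", "coef"]), 0.5)
})

test_that("Kaplan-Meier summaries match the product-limit oracle", {
  km <- km_summary(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  all_c <- km_summary(c(1, 2, 3), c(1, 1, 1))
  expect_true(is.na(all_c$median))
  expect_true(all(all_c$surv == 1))
  # 5-subject mixed-censoring case vs enumeration
  times <- c(2, 3, 3, 5, 8)
  censored <- c(0, 1, 0, 0, 1)
  km5 <- km_summary(times, censored, horizon = 6)
  ora <- km_oracle(times, 1 - censored)
  expect_equal(km5$surv[match(ora$time, km5$time)], ora$surv,
               tolerance = 1e-12)
  # rate at the horizon equals S at the largest event time before it
  expect_equal(km5$rate_at_horizon, ora$surv[ora$time == 5])
})

test_that("the end-to-end prognosis pipeline flags a planted score effect", {
  set.seed(19)
  n <- 200
  w <- c(2, -1, 1.5, 0.5, 1)
  z <- rnorm(n)
  X <- w %o% z + 0.2 * matrix(rnorm(5 * n), 5, n)
  rownames(X) <- paste0("g", 1:5)
  X <- X - rowMeans(X)
  times <- rexp(n, rate = 0.1 * exp(log(2) * z))
  cens <- as.numeric(times > quantile(times, 0.85))
  times <- pmin(times, quantile(times, 0.85))
  prog <- esm_prognosis(X, times, cens)
  expect_lt(prog$logrank$p_value, 0.01)
  expect_lt(prog$cox["score", "p_value"], 0.01)
  expect_true(prog$predictive)
  expect_equal(sum(prog$groups == "top"), n %/% 4)
})
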