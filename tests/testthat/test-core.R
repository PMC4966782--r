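# 500-step power iteration: independent oracle for the leading singular pair
power_iter_rank1 <- function(D, steps = 500L) {
  set.seed(99)
  v <- rnorm(ncol(D))
  for (i in seq_len(steps)) {
    u <- D %*% v
    u <- u / sqrt(sum(u^2))
    v <- crossprod(D, u)
    v <- v / sqrt(sum(v^2))
  }
  sigma <- drop(crossprod(u, D %*% v))
  list(u = drop(u), v = drop(v), sigma = sigma)
}

test_that("svd_rank1 returns the Eckart-Young best rank-1 approximation", {
  r <- svd_rank1(diag(c(3, 1)))
  expect_equal(r$u0, c(1, 0))
  expect_equal(r$v0, c(3, 0))
  expect_equal(r$sigma, 3)
  # exact rank-1 input is reproduced
  a <- c(1, -2, 3)
  b <- c(2, 0.5, -1, 4)
  D <- a %o% b
  r <- svd_rank1(D)
  expect_lt(sqrt(sum((D - r$u0 %o% r$v0)^2)), 1e-10 * sqrt(sum(D^2)))
  expect_error(svd_rank1(matrix(0, 2, 2)), "zero matrix")
})

test_that("svd_rank1 agrees with a power-iteration oracle on random input", {
  set.seed(11)
  D <- matrix(rnorm(50 * 20), 50, 20)
  r <- svd_rank1(D)
  o <- power_iter_rank1(D)
  expect_equal(abs(r$u0), abs(o$u), tolerance = 1e-8)
  expect_equal(r$sigma, o$sigma, tolerance = 1e-8)
  expect_gt(r$u0[which.max(abs(r$u0))], 0)  # sign convention
})

test_that("sparse_u_update solves the penalized row problem in closed form", {
  D <- matrix(c(2, 0, 0, 1), 2, 2)
  v <- c(1, 0)
  expect_equal(sparse_u_update(D, v, 1), c(1.5, 0))
  # lambda = 0 is plain least squares
  set.seed(2)
  D <- matrix(rnorm(12), 4, 3)
  v <- rnorm(3)
  expect_equal(sparse_u_update(D, v, 0), drop(D %*% v) / sum(v^2))
  # full shrinkage at lambda >= 2 max |z|
  z <- drop(D %*% v)
  expect_equal(sparse_u_update(D, v, 2 * max(abs(z))), rep(0, 4))
  expect_error(sparse_u_update(D, c(0, 0, 0), 1), "nonzero")
})

test_that("sparse_u_update matches per-coordinate brute-force minimization", {
  # independent oracle: dense 1-D grid search of
  # f(g) = ||d_i - g v||^2 + lambda |g| per coordinate
  grid_min <- function(d, v, lam) {
    zls <- sum(d * v) / sum(v^2)
    g <- seq(min(0, zls) - 0.1, max(0, zls) + 0.1, by = 1e-4)
    f <- sum(d^2) - 2 * g * sum(d * v) + g^2 * sum(v^2) + lam * abs(g)
    g[which.min(f)]
  }
  set.seed(21)
  for (rep in 1:5) {
    D <- matrix(rnorm(20 * 10), 20, 10)
    v <- rnorm(10)
    for (lam in c(0, 0.3, 1, 3)) {
      u <- sparse_u_update(D, v, lam)
      oracle <- vapply(seq_len(20), function(i) grid_min(D[i, ], v, lam), 0)
      expect_equal(u, oracle, tolerance = 1e-3)
    }
  }
})

test_that("the unpenalized fit reproduces the SVD truncation", {
  set.seed(31)
  D <- matrix(rnorm(80 * 15), 80, 15)
  fit <- jammit(D, 0, scale = FALSE)
  sv <- svd(D)
  err_fit <- sum((D - fitted(fit))^2)
  err_svd <- sum(D^2) - sv$d[1]^2
  expect_equal(err_fit, err_svd, tolerance = 1e-8)
  expect_equal(fit$s, 80L)
})

test_that("the fit honors its return contracts", {
  set.seed(41)
  sm <- stack_mmds(list(rand_dm(60, 12, 41)), scale = TRUE)
  fit <- jammit(sm, 0.05)
  # v = D^T u exactly on return
  expect_equal(fit$v, drop(crossprod(sm$values, fit$u)), tolerance = 1e-8)
  expect_equal(fit$s, sum(fit$u != 0))
  expect_equal(sqrt(sum(fit$u^2)), 1, tolerance = 1e-10)
  # internal objective is non-increasing
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("a small penalty recovers a planted sparse support", {
  for (seed in 1:10) {
    set.seed(seed)
    u_star <- rep(0, 100)
    u_star[sample.int(100, 5)] <- runif(5, 1, 2) * sample(c(-1, 1), 5, TRUE)
    v_star <- rnorm(20)
    D <- u_star %o% v_star + 0.01 * matrix(rnorm(2000), 100, 20)
    sm <- stack_mmds(list(data_matrix(D)), scale = TRUE)
    grid <- lambda_grid(sm, L = 21)
    fit <- jammit(sm, grid$lambdas[8])
    expect_identical(unname(which(fit$u != 0)), which(u_star != 0))
  }
})

test_that("penalties at or above lambda_sup give the empty fit", {
  sm <- stack_mmds(list(rand_dm(40, 10, 51)), scale = TRUE)
  grid <- lambda_grid(sm, L = 5)
  fit <- jammit(sm, grid$lambda_sup * 1.001)
  expect_equal(fit$s, 0L)
  expect_equal(fit$u, setNames(rep(0, 40), sm$variable_ids))
  expect_equal(nrow(fit$signature$entries), 0L)
})

test_that("signature size is non-increasing in lambda and hits p at zero", {
  sm <- stack_mmds(list(rand_dm(50, 10, 61)), scale = TRUE)
  grid <- lambda_grid(sm, L = 15)
  v0 <- svd_rank1(sm$values)$v0
  v0 <- v0 / sqrt(sum(v0^2))
  s <- vapply(grid$lambdas,
              function(l) sum(sparse_u_update(sm$values, v0, l) != 0), 0)
  expect_equal(s[1], 50)
  expect_equal(s[15], 0)
  expect_true(all(diff(s) <= 0))
})

test_that("signatures parse nonzero loadings per block by stacking order", {
  a <- rand_dm(3, 6, 71, "mRNA")
  b <- rand_dm(2, 6, 72, "miRNA")
  sm <- stack_mmds(list(a, b), scale = TRUE)
  fit <- jammit(sm, 0)
  fit$u[] <- 0
  fit$u[c(1, 5)] <- c(0.6, 0.8)
  sig <- jammit_signature(fit, sm)
  expect_equal(unname(sig$per_block_counts), c(1L, 1L))
  expect_equal(sig$entries$dtype_tag, c("mRNA", "miRNA"))
  expect_equal(sig$entries$variable_id, c("v001", "v002"))
  bad <- fit
  bad$u <- bad$u[-1]
  expect_error(jammit_signature(bad, sm), "does not match")
})

test_that("per-block signature counts always sum to s", {
  sm <- stack_mmds(list(rand_dm(30, 8, 81, "a"), rand_dm(20, 8, 82, "b")),
                   scale = TRUE)
  grid <- lambda_grid(sm, L = 12)
  for (l in grid$lambdas) {
    fit <- jammit(sm, l)
    expect_equal(sum(fit$signature$per_block_counts), fit$s)
  }
})

test_that("deflation removes exactly the fitted component", {
  set.seed(91)
  D <- matrix(rnorm(60 * 12), 60, 12)
  fit <- jammit(D, 0, scale = FALSE)
  res <- residualize(D, fit)
  sv <- svd(D)
  expect_equal(sum(res^2), sum(D^2) - sv$d[1]^2, tolerance = 1e-8)
  # a rank-1 matrix deflated by its own unpenalized fit vanishes
  D1 <- c(1, 2, 3) %o% c(4, 5, 6, 7)
  fit1 <- jammit(D1, 0, scale = FALSE)
  expect_lt(sqrt(sum(residualize(D1, fit1)^2)), 1e-10 * sqrt(sum(D1^2)))
  expect_error(residualize(D[1:10, ], fit), "shape mismatch")
})

test_that("deflating a planted signal exposes a second one", {
  set.seed(101)
  n <- 20
  s1 <- make_step_signal(n)
  s2 <- make_random_signal(n)
  s2 <- s2 - mean(s2) - s1 * sum(s1 * s2) / sum(s1^2)
  u1 <- rep(0, 200); u1[1:8] <- 2
  u2 <- rep(0, 200); u2[101:108] <- 1.2
  D <- u1 %o% s1 + u2 %o% s2 + 0.05 * matrix(rnorm(200 * n), 200, n)
  sm <- stack_mmds(list(data_matrix(D)), scale = TRUE)
  g <- lambda_grid(sm, L = 21)
  fit1 <- jammit(sm, g$lambdas[6])
  expect_identical(unname(which(fit1$u != 0)), 1:8)
  res <- residualize(sm, fit1)
  fit2 <- jammit(res, lambda_grid(res, L = 21)$lambdas[6])
  expect_identical(unname(which(fit2$u != 0)), 101:108)
})
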