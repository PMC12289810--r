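test_that("loss terms compute their defining arithmetic", {
  expect_equal(metric_loss(rep(1, 3), rep(1, 3), 1, 1), -2)
  expect_equal(metric_loss(rep(0, 2), rep(1, 2), rep(0, 2), rep(1, 2)), 0)
  expect_equal(metric_loss(c(0.5, -0.5), c(1, 2), numeric(0), numeric(0)), 0.5)

  expect_equal(bound_loss(c(0.3, -0.9), c(1), 2, 1), 0)
  expect_equal(bound_loss(1.5, -2, 1, 1), 0.5^2 + 1^2)
  # TV normalization: proportional duplication leaves the penalty unchanged
  expect_equal(bound_loss(c(1.5, 1.5), c(-2, -2), 2, 2), 1.25)
  # ... and so does merging duplicates into one atom of double weight
  expect_equal(bound_loss(1.5, -2, 2, 2, weights_mu = 2, weights_nu = 2), 1.25)
  expect_error(bound_loss(1, 1, 1, 1, M = 0), "positive")
})

test_that("the adaptive lambda protocol follows its update rules", {
  sch <- adaptive_schedule()   # tol 0.05, up 2, down 0.5, target share 0.1
  losses <- function(lam, Lb = 0.1, Lm = -1) list(metric = Lm, bound = Lb, lambda = lam)
  expect_equal(adapt_lambda(sch, 0.2, losses(10)), 20)           # violation: up
  expect_equal(adapt_lambda(sch, 0.0, losses(10, Lb = 0.0001)), 10) # share low: hold
  expect_equal(adapt_lambda(sch, 0.01, losses(10, Lb = 0.1)), 5)  # share 10x target: down
  expect_equal(adapt_lambda(sch, 0.04, losses(10, Lb = 0.1)), 10) # in the dead band
  expect_equal(adapt_lambda(sch, 0.2, losses(9e5)), 1e6)          # clipped
})

test_that("training a critic on identical measures yields ~0", {
  set.seed(51)
  m <- discrete_measure(matrix(rnorm(40), 20, 2), 1)
  est <- train_flat(m, m, optimizer_config = fast_opt(), seed = 3)
  expect_lt(abs(est$raw), 0.05 * tv_norm(m))
  expect_true(est$lip_certificate)
})

test_that("trained estimates match the LP on Dirac and mixture instances", {
  # two weighted atoms at distance 1 (collapsed 100-sample clouds)
  a <- discrete_measure(matrix(0, 1, 2), 100)
  b <- discrete_measure(matrix(c(1, 0), 1, 2), 100)
  est <- train_flat(a, b, seed = 5)
  truth <- flat_exact(a, b)$value
  expect_lt(abs(est$raw - truth) / truth, 0.15)

  # 1-D two-bump vs central Gaussian mixture, empirical clouds
  set.seed(42)
  xm <- c(rnorm(64, -20, sqrt(0.5)), rnorm(64, 20, sqrt(0.5)))
  xn <- rnorm(128, 0, sqrt(0.5))
  gm <- discrete_measure(matrix(xm, ncol = 1), 1)
  gn <- discrete_measure(matrix(xn, ncol = 1), 1)
  exact <- flat_exact(gm, gn)$value
  est <- train_flat(gm, gn, seed = 7)
  expect_lt(abs(est$raw - exact) / exact, 0.10)
  # the trained critic is bounded by ~1 on the support, with interior
  # slopes well below 1 (the flat-metric optimum is not an isometry)
  expect_lte(est$sup_violation, 0.2)
  grid <- matrix(seq(-25, 25, length.out = 600), ncol = 1)
  fv <- predict(est$net, grid)
  expect_lt(stats::median(abs(diff(fv)) / (50 / 599)), 0.5)
})

test_that("the antagonistic loss trace and one-sided consistency are recorded", {
  set.seed(52)
  mu <- make_dirac(c(0, 0), 8)
  nu <- discrete_measure(sample_sphere(16, 2, 1), 1)
  est <- train_flat(mu, nu, seed = 11)
  tr <- est$loss_trace
  expect_equal(colnames(tr), c("metric_loss", "bound_loss", "lambda"))
  expect_equal(nrow(tr), 1000L)
  expect_true(all(tr[, "bound_loss"] >= 0))
  expect_true(all(tr[, "lambda"] > 0))
  # one-sided consistency: an epsilon-admissible critic cannot exceed the
  # supremum by more than the mass-weighted bound excess
  exact <- dirac_sphere_flat(8, 16, 1)
  slack <- (tv_norm(mu) + tv_norm(nu)) * max(est$sup_violation, 0)
  expect_lte(est$raw, exact + slack + 1e-6)
})

test_that("training is bit-for-bit deterministic given the seed", {
  set.seed(53)
  mu <- discrete_measure(matrix(rnorm(30), 15, 2), 1)
  nu <- discrete_measure(matrix(rnorm(24, 1), 12, 2), 1)
  e1 <- train_flat(mu, nu, optimizer_config = fast_opt(), seed = 99)
  e2 <- train_flat(mu, nu, optimizer_config = fast_opt(), seed = 99)
  expect_identical(e1$raw, e2$raw)
  expect_identical(e1$loss_trace, e2$loss_trace)
  e3 <- train_flat(mu, nu, optimizer_config = fast_opt(), seed = 100)
  expect_false(identical(e1$raw, e3$raw))
})

test_that("estimates scale approximately linearly with joint mass rescaling", {
  set.seed(54)
  mu <- discrete_measure(matrix(rnorm(20), 10, 2), runif(10, 0.5, 2))
  nu <- discrete_measure(matrix(rnorm(16, 2), 8, 2), runif(8, 0.5, 2))
  e1 <- train_flat(mu, nu, optimizer_config = fast_opt(), seed = 7)$raw
  e3 <- train_flat(measure_scale(mu, 3), measure_scale(nu, 3),
                   optimizer_config = fast_opt(), seed = 7)$raw
  expect_lt(abs(e3 - 3 * e1) / (3 * e1), 0.1)
})

test_that("the Wasserstein critic matches transport and ignores mass", {
  a <- discrete_measure(matrix(0, 1, 2), 50)
  b <- discrete_measure(matrix(c(1.5, 0), 1, 2), 50)
  est <- train_wasserstein(a, b, seed = 13)
  expect_lt(abs(est$raw - 1.5) / 1.5, 0.15)

  set.seed(55)
  m <- discrete_measure(matrix(rnorm(30), 15, 2), 1)
  expect_lt(abs(train_wasserstein(m, m, optimizer_config = fast_opt(),
                                  seed = 1)$raw), 0.05)

  # same shape, very different counts: W1 ~ 0 but the flat distance sees the
  # mass difference (both statements checked against the exact solvers)
  set.seed(56)
  big <- discrete_measure(matrix(rnorm(200 * 2), 200, 2), 1)
  small <- discrete_measure(matrix(rnorm(20 * 2), 20, 2), 1)
  w_ex <- wasserstein_exact(big, small, normalize = TRUE)$value
  f_ex <- flat_exact(big, small)$value
  expect_gte(f_ex, 180)                        # >= mass gap of 180
  # normalized W1 sits at the 20-sample sampling-noise floor, orders of
  # magnitude below the flat distance driven by the mass gap
  expect_lt(w_ex, 1)
  expect_lt(w_ex, 0.01 * f_ex)
  w_est <- train_wasserstein(big, small, seed = 21)$raw
  f_est <- train_flat(big, small, seed = 21)$raw
  expect_lt(w_est, 1.2)
  expect_gt(f_est, 0.8 * f_ex)
})
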