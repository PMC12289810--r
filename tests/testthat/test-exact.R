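test_that("flat_exact reproduces the Dirac configurations", {
  expect_equal(flat_exact(make_dirac(0, 1), make_dirac(3, 1))$value, 2)
  expect_equal(flat_exact(make_dirac(0, 1), make_dirac(0.5, 1))$value, 0.5)
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  nu <- discrete_measure(cbind(cos(th), sin(th)), 1)
  expect_equal(flat_exact(make_dirac(c(0, 0), 4), nu)$value, 8)
  mu <- random_measure(5, 2)
  expect_equal(flat_exact(mu, mu)$value, 0)
  expect_equal(flat_exact(make_dirac(c(0, 0), 1), empty_measure(2))$value, 1)
  expect_error(flat_exact(make_dirac(0, 1), make_dirac(c(0, 0), 1)), "mismatch")
})

test_that("flat_exact agrees with an independent simplex LP on random instances", {
  set.seed(41)
  for (i in 1:25) {
    d <- sample(1:3, 1)
    mu <- random_measure(sample(1:4, 1), d)
    nu <- random_measure(sample(1:4, 1), d)
    expect_equal(flat_exact(mu, nu)$value, lp_flat_oracle(mu, nu),
                 tolerance = 1e-9)
  }
})

test_that("recovered test functions are admissible and attain the value", {
  set.seed(42)
  for (i in 1:10) {
    mu <- random_measure(sample(2:6, 1), 2)
    nu <- random_measure(sample(2:6, 1), 2)
    r <- flat_exact(mu, nu)
    f <- r$test_values
    expect_lte(max(abs(f)), 1 + 1e-6)
    D <- pairwise_distances(r$support, r$support)
    expect_lte(max(abs(outer(f, f, `-`)) - D), 1e-6)
    cs <- c(mu$weights, -nu$weights)
    expect_equal(sum(f * cs), r$value, tolerance = 1e-6)
  }
})

test_that("the Dirac sphere closed form matches its examples and the LP", {
  expect_equal(dirac_sphere_flat(1, 1, 0.5), 0.5)
  expect_equal(dirac_sphere_flat(1, 1, 5), 2)
  expect_equal(dirac_sphere_flat(4, 8, 0), 4)
  set.seed(43)
  for (i in 1:50) {
    d <- sample(1:4, 1); k <- sample(1:6, 1)
    m <- runif(1, 0, 4); n <- runif(1, 0, 4); r0 <- runif(1, 0, 4)
    w <- runif(k); w <- w / sum(w) * n      # mass n spread over the sphere
    mu <- make_dirac(rep(0, d), m)
    nu <- discrete_measure(sample_sphere(k, d, r0), w)
    expect_equal(flat_exact(mu, nu)$value, dirac_sphere_flat(m, n, r0),
                 tolerance = 1e-8)
  }
})

test_that("one_point_flat equals the LP and reduces to the sphere form", {
  set.seed(44)
  for (i in 1:20) {
    mu <- random_measure(sample(1:8, 1), 2)
    m <- runif(1, 0, 5); cen <- rnorm(2)
    expect_equal(one_point_flat(mu, cen, m),
                 flat_exact(mu, make_dirac(cen, m))$value, tolerance = 1e-8)
  }
  # all radii equal with unit weights reduces to the sphere closed form
  nu <- discrete_measure(sample_sphere(6, 3, 1.3), 1)
  expect_equal(one_point_flat(nu, rep(0, 3), 4), dirac_sphere_flat(4, 6, 1.3),
               tolerance = 1e-10)
  # m = 0: supremum saturates f at 1 everywhere, value is the total mass
  mu <- random_measure(5, 2)
  expect_equal(one_point_flat(mu, c(0, 0), 0), tv_norm(mu))
})

test_that("wasserstein_exact solves balanced transport and rejects unbalanced", {
  expect_equal(wasserstein_exact(make_dirac(0, 1), make_dirac(5, 1))$value, 5)
  mu <- random_measure(4, 2)
  expect_equal(wasserstein_exact(mu, mu)$value, 0)
  expect_error(wasserstein_exact(make_dirac(0, 2), make_dirac(1, 1)),
               "conservative")
  # normalize flag compares the two shapes at unit mass
  expect_equal(wasserstein_exact(make_dirac(0, 2), make_dirac(1, 1),
                                 normalize = TRUE)$value, 1)
  # primal (min-cost flow) agrees with the independent dual simplex LP
  set.seed(45)
  for (i in 1:8) {
    mu <- random_measure(5, 2)
    nu <- random_measure(5, 2)
    nu <- measure_scale(nu, tv_norm(mu) / tv_norm(nu))
    expect_equal(wasserstein_exact(mu, nu)$value, lp_w1_oracle(mu, nu),
                 tolerance = 1e-8)
  }
})

test_that("tv_distance implements the atomic Jordan decomposition", {
  expect_equal(tv_distance(make_dirac(c(0, 0), 1), make_dirac(c(9, 9), 1)), 2)
  m <- random_measure(4, 2)
  expect_equal(tv_distance(m, m), 0)
  a <- random_measure(3, 2); b <- random_measure(4, 2)
  expect_equal(tv_distance(a, b), tv_norm(a) + tv_norm(b)) # disjoint supports
  shared <- discrete_measure(rbind(c(0, 0), c(1, 0)), c(2, 1))
  shifted <- discrete_measure(rbind(c(0, 0), c(2, 0)), c(0.5, 3))
  expect_equal(tv_distance(shared, shifted), 1.5 + 1 + 3)
})

test_that("the decomposition brute force converges to the flat LP", {
  r <- decomposition_bruteforce(make_dirac(0, 1), make_dirac(1, 1), 20)
  expect_equal(r$value, 1)
  expect_equal(r$transported_mass, 1)
  r <- decomposition_bruteforce(make_dirac(0, 1), make_dirac(3, 1), 20)
  expect_equal(r$value, 2)
  expect_equal(r$transported_mass, 0)
  m <- random_measure(2, 2)
  expect_equal(decomposition_bruteforce(m, m, 8)$value, 0, tolerance = 1e-9)
  set.seed(46)
  mu <- random_measure(2, 2); nu <- random_measure(2, 2)
  exact <- flat_exact(mu, nu)$value
  gaps <- vapply(c(4, 8, 16, 32), function(g) {
    decomposition_bruteforce(mu, nu, g)$value - exact
  }, numeric(1))
  expect_true(all(gaps >= -1e-9))            # discretization can only overshoot
  expect_true(all(diff(gaps) <= 1e-9))       # and shrinks as the grid refines
  expect_lt(gaps[4], 0.1 * max(tv_norm(mu), tv_norm(nu)))
  expect_error(decomposition_bruteforce(random_measure(3, 2),
                                        random_measure(2, 2)), "4 support")
})

test_that("metric axioms, bounds and homogeneity hold on random instances", {
  set.seed(47)
  for (i in 1:10) {
    mu <- random_measure(3, 2); nu <- random_measure(3, 2)
    ka <- random_measure(3, 2)
    fmn <- flat_exact(mu, nu)$value
    expect_equal(fmn, flat_exact(nu, mu)$value, tolerance = 1e-9)
    expect_gte(fmn, 1e-6)                       # distinct random measures
    expect_lte(fmn, flat_exact(mu, ka)$value + flat_exact(ka, nu)$value + 1e-9)
    expect_lte(fmn, tv_distance(mu, nu) + 1e-9)
    expect_lte(fmn, tv_norm(mu) + tv_norm(nu) + 1e-9)
    c0 <- runif(1, 0.2, 3)
    expect_equal(flat_exact(measure_scale(mu, c0), measure_scale(nu, c0))$value,
                 c0 * fmn, tolerance = 1e-8)
    nu_eq <- measure_scale(nu, tv_norm(mu) / tv_norm(nu))
    expect_lte(flat_exact(mu, nu_eq)$value,
               wasserstein_exact(mu, nu_eq)$value + 1e-9)
  }
  expect_equal(flat_exact(random_measure(3, 2), empty_measure(2))$status,
               "optimal")
})
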