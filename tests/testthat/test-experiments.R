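test_that("the cluster simulator respects sizes and is overdispersed", {
  cfg <- cluster_sim_config(cells_per_group = c(300, 30, 150, 150, 150),
                            n_genes = 40)
  groups <- simulate_clusters(cfg, seed = 8)
  expect_length(groups, 5L)
  expect_equal(vapply(groups, tv_norm, numeric(1)), c(300, 30, 150, 150, 150))
  expect_equal(vapply(groups, measure_dim, integer(1)), rep(40L, 5))
  counts <- groups[[1]]$points
  expect_true(all(counts >= 0) && all(counts == round(counts)))

  # Gamma-Poisson: across cells of a group, var > mean for expressed genes
  big <- simulate_clusters(cluster_sim_config(cells_per_group = 2000,
                                              n_genes = 30), seed = 9)[[1]]
  mu_g <- colMeans(big$points)
  var_g <- apply(big$points, 2, stats::var)
  hi <- mu_g > 1
  expect_true(mean(var_g[hi] > mu_g[hi]) > 0.9)

  # dropout thins the matrix
  drp <- simulate_clusters(cluster_sim_config(cells_per_group = 200,
                                              n_genes = 30, dropout_rate = 0.5),
                           seed = 9)[[1]]
  expect_gt(mean(drp$points == 0), mean(big$points == 0))
})

test_that("cluster distance tables expose the mass-vs-shape contrast", {
  cfg <- cluster_sim_config(cells_per_group = c(120, 12, 60), n_genes = 30)
  groups <- simulate_clusters(cfg, seed = 10)
  tab <- cluster_distance_table(groups, reduce_to_dim = 3)
  expect_equal(unname(diag(tab$flat)), rep(0, 3))
  expect_equal(unname(diag(tab$wasserstein)), rep(0, 3))
  expect_equal(tab$flat, t(tab$flat))
  # provable lower bound: rho_F >= |tv(mu) - tv(nu)| via f = +/-1
  sizes <- vapply(groups, tv_norm, numeric(1))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(tab$flat[i, j], abs(sizes[i] - sizes[j]) - 1e-9)
  }
  expect_error(cluster_distance_table(groups, reduce_to_dim = 99), "exceeds")
})

test_that("the shipped domain scenario separates flat from Wasserstein matching", {
  dm <- domain_match(seed = 1)
  expect_equal(unname(dm$flat_assignment[c("X", "Y", "Z")]), c("A", "B", "C"))
  expect_equal(unname(dm$wasserstein_assignment[c("X", "Y")]), c("A", "B"))
  expect_equal(unname(dm$wasserstein_assignment["Z"]), "B") # the mass-blind mismatch
  expect_equal(tv_norm(dm$measures$Z), 2.25, tolerance = 1e-9)
  expect_equal(tv_norm(dm$measures$C), 3, tolerance = 1e-9)
})

test_that("targets identical to sources match identically with ~0 distance", {
  blob <- function(mean, sd, mass) list(mean = mean, sd = sd, mass = mass)
  sc <- domain_scenario(
    classes = list(A = list(blob(c(0, 0), 0.4, 1)),
                   B = list(blob(c(5, 0), 0.4, 2)),
                   X = list(blob(c(0, 0), 0.4, 1)),
                   Y = list(blob(c(5, 0), 0.4, 2))),
    sources = c("A", "B"), targets = c("X", "Y"))
  dm <- domain_match(sc, seed = 2)
  expect_equal(unname(dm$flat_assignment), c("A", "B"))
  expect_lt(dm$flat_table["X", "A"], 0.25 * dm$flat_table["X", "B"])

  # scaling every mass by c scales flat distances ~linearly, same assignment
  sc3 <- sc
  sc3$classes <- lapply(sc3$classes, function(cl) {
    lapply(cl, function(b) { b$mass <- 3 * b$mass; b })
  })
  dm3 <- domain_match(sc3, seed = 2)
  expect_equal(unname(dm3$flat_assignment), c("A", "B"))
  expect_equal(dm3$flat_table["X", "B"], 3 * dm$flat_table["X", "B"],
               tolerance = 0.1)
})

test_that("benchmark image generators honor their binning contracts", {
  for (cl in c("shapes", "cauchy", "random_field")) {
    grids <- generate_benchmark_images(cl, resolution = 32, count = 3, seed = 5)
    for (g in grids) {
      expect_true(all(g == round(g)))
      expect_true(all(g >= 0 & g <= 255))
      expect_equal(dim(g), c(32L, 32L))
    }
    if (cl == "shapes") {
      expect_true(all(unlist(grids) %in% c(0L, 255L)))
    }
    again <- generate_benchmark_images(cl, resolution = 32, count = 3, seed = 5)
    expect_identical(grids, again)
  }
})

test_that("image-vs-pixel ground truths are exact and residuals attributable", {
  grids <- generate_benchmark_images("cauchy", resolution = 8, count = 2, seed = 6)
  # closed form equals the full LP on images
  for (g in grids) {
    mu <- image_to_measure(g)
    m <- 100
    expect_equal(one_point_flat(mu, c(0.5, 0.5), m),
                 flat_exact(mu, make_dirac(c(0.5, 0.5), m))$value,
                 tolerance = 1e-6)
  }
  res <- image_pixel_residuals(grids, pixel_mass = 64, seed = 6,
                               optimizer_config = fast_opt())
  expect_equal(nrow(res), 2L)
  expect_true(all(res$residual >= 0))
  expect_true(all(res$true_value > 0))
  expect_warning(
    image_pixel_residuals(list(matrix(0L, 4, 4)), pixel_mass = 1,
                          optimizer_config = fast_opt(epochs = 50)),
    "all-zero")
})
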