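#' Configuration for the Gamma-Poisson cluster simulator
#'
#' Desk-scale emulation of Splatter-style single-cell RNA count simulation:
#' gene base means are Gamma distributed, groups shift a random subset of
#' genes multiplicatively (differential expression), cells carry log-normal
#' library-size factors, counts are Gamma-Poisson (negative binomial) with a
#' common dispersion, and dropout zeroes entries at a fixed rate.
#'
#' @param cells_per_group integer vector; one group per entry.
#' @param n_genes number of genes (ambient dimension before reduction).
#' @param gene_mean_shape,gene_mean_scale Gamma parameters of gene means.
#' @param de_prob probability a gene is differentially expressed in a group.
#' @param de_facloc,de_facscale log-normal parameters of DE factors.
#' @param lib_sdlog sdlog of the cell library-size factors.
#' @param dispersion Gamma-Poisson overdispersion (variance = m + disp m^2).
#' @param dropout_rate probability an entry is zeroed.
#' @return A `cluster_sim_config` list.
#' @export
cluster_sim_config <- function(cells_per_group = c(300, 30, 150, 150, 150),
                               n_genes = 200,
                               gene_mean_shape = 0.6, gene_mean_scale = 3.3,
                               de_prob = 0.1, de_facloc = 0.1, de_facscale = 0.4,
                               lib_sdlog = 0.2, dispersion = 0.2,
                               dropout_rate = 0) {
  stopifnot(all(cells_per_group >= 1), n_genes >= 1,
            dropout_rate >= 0, dropout_rate < 1, dispersion >= 0)
  structure(list(cells_per_group = as.integer(cells_per_group),
                 n_genes = as.integer(n_genes),
                 gene_mean_shape = gene_mean_shape,
                 gene_mean_scale = gene_mean_scale,
                 de_prob = de_prob, de_facloc = de_facloc,
                 de_facscale = de_facscale, lib_sdlog = lib_sdlog,
                 dispersion = dispersion, dropout_rate = dropout_rate),
            class = "cluster_sim_config")
}

#' Simulate Gamma-Poisson count clusters
#'
#' @param config a [cluster_sim_config()].
#' @param seed integer seed.
#' @return List of `discrete_measure` objects (one per group, unit-weight
#'   cells as atoms in gene space), labelled `Group1`, `Group2`, ...
#' @export
simulate_clusters <- function(config = cluster_sim_config(), seed = 1) {
  with_seed(substream_seed(seed, "clusters"), {
    ng <- config$n_genes
    base <- stats::rgamma(ng, shape = config$gene_mean_shape,
                          scale = config$gene_mean_scale)
    lapply(seq_along(config$cells_per_group), function(g) {
      nc <- config$cells_per_group[g]
      de <- stats::runif(ng) < config$de_prob
      fac <- rep(1, ng)
      fac[de] <- exp(stats::rnorm(sum(de), config$de_facloc, config$de_facscale) *
                       sample(c(-1, 1), sum(de), replace = TRUE))
      mean_g <- base * fac
      sf <- stats::rlnorm(nc, 0, config$lib_sdlog)
      lam <- outer(sf, mean_g)                      # cells x genes
      if (config$dispersion > 0) {
        shape <- 1 / config$dispersion
        lam[] <- stats::rgamma(length(lam), shape = shape, scale = lam / shape)
      }
      counts <- matrix(stats::rpois(length(lam), lam), nrow = nc)
      if (config$dropout_rate > 0) {
        counts[stats::runif(length(counts)) < config$dropout_rate] <- 0L
      }
      discrete_measure(counts, 1, label = paste0("Group", g))
    })
  })
}

#' Pairwise flat / Wasserstein distance table between clusters
#'
#' Pools the cells, applies log1p and PCA (plumbing, not part of the distance
#' method), projects every group to the leading principal directions, and
#' computes all pairwise flat distances plus Wasserstein distances of the
#' separately normalized groups. `method = "exact"` uses the LP/flow solvers
#' (deterministic); `method = "neural"` uses the trained critic.
#'
#' @param measures list of `discrete_measure` objects (counts in gene space).
#' @param reduce_to_dim number of principal directions to keep.
#' @param seed seed for the neural path.
#' @param method `"exact"` or `"neural"`.
#' @param calibration optional `calibration_model` for the neural flat path.
#' @param net_config,optimizer_config neural training configuration.
#' @return List with matrices `flat` and `wasserstein` (labelled by group),
#'   and `reduced` (the projected measures).
#' @export
cluster_distance_table <- function(measures, reduce_to_dim = 5, seed = 1,
                                   method = c("exact", "neural"),
                                   calibration = NULL,
                                   net_config = flatmetric::net_config(),
                                   optimizer_config = flatmetric::optimizer_config()) {
  method <- match.arg(method)
  if (length(measures) < 2L) stop("need at least two groups")
  if (reduce_to_dim > measure_dim(measures[[1]])) {
    stop("reduce_to_dim exceeds the number of genes")
  }
  pooled <- log1p(do.call(rbind, lapply(measures, `[[`, "points")))
  pca <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  proj <- pooled %*% pca$rotation[, seq_len(reduce_to_dim), drop = FALSE]
  sizes <- vapply(measures, n_atoms, integer(1))
  idx <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  reduced <- lapply(seq_along(measures), function(g) {
    discrete_measure(proj[idx[[g]], , drop = FALSE], measures[[g]]$weights,
                     label = measures[[g]]$label)
  })
  k <- length(reduced)
  labs <- vapply(reduced, function(m) m$label %||% "", character(1))
  flat <- wass <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (method == "exact") {
        fv <- flat_exact(reduced[[i]], reduced[[j]])$value
        wv <- wasserstein_exact(reduced[[i]], reduced[[j]], normalize = TRUE)$value
      } else {
        sd_ij <- substream_seed(seed, sprintf("pair/%d/%d", i, j))
        ef <- train_flat(reduced[[i]], reduced[[j]], net_config,
                         optimizer_config = optimizer_config,
                         seed = sd_ij, calibration = calibration)
        fv <- if (!is.null(ef$corrected)) ef$corrected else ef$raw
        wv <- train_wasserstein(reduced[[i]], reduced[[j]], net_config,
                                optimizer_config, seed = sd_ij)$raw
      }
      flat[i, j] <- flat[j, i] <- fv
      wass[i, j] <- wass[j, i] <- wv
    }
  }
  list(flat = flat, wasserstein = wass, reduced = reduced)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unbalanced domain-matching scenario
#'
#' A scenario holds labelled source and target classes, each a mixture of
#' isotropic Gaussian blobs with a mass. The shipped default realizes the
#' qualitative geometry in which mass awareness changes the matching: targets
#' X, Y, Z originate from sources A, B, C with masses
#' m(A) = m(B) = 1, m(C) = 3, m(X) = 0.75, m(Y) = 0.85, m(Z) = 2.25; C is
#' bimodal with a far secondary lobe, and the heavy target Z sits on C's main
#' lobe while a lighter source B is nearby. Under the flat metric Z matches C
#' (the mass difference to B is penalized), while normalized Wasserstein
#' matches Z to B.
#'
#' @param classes named list; each element is a list of blobs, each blob a
#'   list with `mean` (length-2), `sd` (scalar), `mass`.
#' @param sources,targets character vectors naming the two sides.
#' @return A `domain_scenario` object.
#' @export
domain_scenario <- function(classes, sources, targets) {
  stopifnot(all(c(sources, targets) %in% names(classes)))
  structure(list(classes = classes, sources = sources, targets = targets),
            class = "domain_scenario")
}

#' @rdname domain_scenario
#' @export
default_domain_scenario <- function() {
  blob <- function(mean, sd, mass) list(mean = mean, sd = sd, mass = mass)
  domain_scenario(
    classes = list(
      A = list(blob(c(0, 0), 0.5, 1)),
      B = list(blob(c(11.5, 0), 0.5, 1)),
      C = list(blob(c(14, 0), 0.6, 2.25), blob(c(14, 12), 0.6, 0.75)),
      X = list(blob(c(0.3, 0.2), 0.55, 0.75)),
      Y = list(blob(c(11.75, -0.15), 0.5, 0.85)),
      Z = list(blob(c(14.3, 0.2), 0.6, 2.25))),
    sources = c("A", "B", "C"),
    targets = c("X", "Y", "Z"))
}

sample_scenario_class <- function(blobs, samples_per_unit_mass, label) {
  pts <- NULL; w <- NULL
  for (bl in blobs) {
    if (bl$mass <= 0) stop("zero-mass component in scenario")
    cnt <- max(1L, round(bl$mass * samples_per_unit_mass))
    pts <- rbind(pts, matrix(stats::rnorm(2 * cnt, sd = bl$sd), cnt, 2,
                             byrow = FALSE) +
                   matrix(bl$mean, cnt, 2, byrow = TRUE))
    w <- c(w, rep(bl$mass / cnt, cnt))
  }
  discrete_measure(pts, w, label = label)
}

#' Match target classes to source classes under flat and Wasserstein metrics
#'
#' Samples every class (point count proportional to mass, weights scaled so
#' the total mass is exact), computes the full target-by-source distance
#' tables under the flat metric and under separately normalized Wasserstein,
#' and assigns each target to its least-distance source per metric.
#'
#' @param scenario a [domain_scenario()].
#' @param samples_per_unit_mass sampling density.
#' @param seed integer seed.
#' @param method `"exact"` (LP/flow solvers) or `"neural"`.
#' @param calibration,net_config,optimizer_config neural-path configuration.
#' @return List with `flat_table`, `wasserstein_table` (targets x sources),
#'   `flat_assignment`, `wasserstein_assignment` (named character vectors),
#'   and the sampled `measures`.
#' @export
domain_match <- function(scenario = default_domain_scenario(),
                         samples_per_unit_mass = 80, seed = 1,
                         method = c("exact", "neural"),
                         calibration = NULL,
                         net_config = flatmetric::net_config(),
                         optimizer_config = flatmetric::optimizer_config()) {
  method <- match.arg(method)
  measures <- with_seed(substream_seed(seed, "domain"), {
    lapply(names(scenario$classes), function(nm) {
      sample_scenario_class(scenario$classes[[nm]], samples_per_unit_mass, nm)
    })
  })
  names(measures) <- names(scenario$classes)
  ft <- wt <- matrix(0, length(scenario$targets), length(scenario$sources),
                     dimnames = list(scenario$targets, scenario$sources))
  for (tg in scenario$targets) {
    for (sc in scenario$sources) {
      if (method == "exact") {
        ft[tg, sc] <- flat_exact(measures[[tg]], measures[[sc]])$value
        wt[tg, sc] <- wasserstein_exact(measures[[tg]], measures[[sc]],
                                        normalize = TRUE)$value
      } else {
        sd_p <- substream_seed(seed, paste0("pair/", tg, "/", sc))
        ef <- train_flat(measures[[tg]], measures[[sc]], net_config,
                         optimizer_config = optimizer_config, seed = sd_p,
                         calibration = calibration)
        ft[tg, sc] <- if (!is.null(ef$corrected)) ef$corrected else ef$raw
        wt[tg, sc] <- train_wasserstein(measures[[tg]], measures[[sc]],
                                        net_config, optimizer_config,
                                        seed = sd_p)$raw
      }
    }
  }
  pick <- function(tab) {
    stats::setNames(colnames(tab)[apply(tab, 1L, which.min)], rownames(tab))
  }
  list(flat_table = ft, wasserstein_table = wt,
       flat_assignment = pick(ft), wasserstein_assignment = pick(wt),
       measures = measures)
}

#' Generate benchmark image classes
#'
#' Procedural grayscale test images in three classes of increasing
#' diffuseness: filled geometric shapes (binary 0/255), bivariate Cauchy
#' densities with random center and elliptical scale, and Gaussian random
#' fields (squared-exponential covariance, random length scale). Intensities
#' are binned to integers in 0..255.
#'
#' @param class one of `"shapes"`, `"cauchy"`, `"random_field"`.
#' @param resolution image side length (32 or 64 typical).
#' @param count number of images.
#' @param seed integer seed.
#' @return List of `count` integer intensity matrices.
#' @export
generate_benchmark_images <- function(class = c("shapes", "cauchy", "random_field"),
                                      resolution = 32, count = 10, seed = 1) {
  class <- match.arg(class)
  n <- resolution
  ax <- (seq_len(n) - 0.5) / n
  with_seed(substream_seed(seed, paste0("images/", class)), {
    lapply(seq_len(count), function(i) {
      if (class == "shapes") {
        cx <- stats::runif(1, 0.3, 0.7); cy <- stats::runif(1, 0.3, 0.7)
        a <- stats::runif(1, 0.08, 0.3); b <- stats::runif(1, 0.08, 0.3)
        th <- stats::runif(1, 0, pi)
        X <- outer(rep(1, n), ax) - cx; Y <- outer(ax, rep(1, n)) - cy
        U <- cos(th) * X + sin(th) * Y; V <- -sin(th) * X + cos(th) * Y
        g <- ifelse((U / a)^2 + (V / b)^2 <= 1, 255, 0)
      } else if (class == "cauchy") {
        cx <- stats::runif(1, 0.2, 0.8); cy <- stats::runif(1, 0.2, 0.8)
        s1 <- stats::runif(1, 0.05, 0.25); s2 <- stats::runif(1, 0.05, 0.25)
        th <- stats::runif(1, 0, pi)
        X <- outer(rep(1, n), ax) - cx; Y <- outer(ax, rep(1, n)) - cy
        U <- (cos(th) * X + sin(th) * Y) / s1
        V <- (-sin(th) * X + cos(th) * Y) / s2
        dens <- (1 + U^2 + V^2)^(-1.5)
        g <- round(dens / max(dens) * 255)
      } else {
        ell <- stats::runif(1, 0.1, 0.3)
        K <- exp(-outer(ax, ax, `-`)^2 / (2 * ell^2)) + diag(1e-8, n)
        L <- chol(K)
        Z <- matrix(stats::rnorm(n * n), n, n)
        fld <- t(L) %*% Z %*% L
        g <- round((fld - min(fld)) / (max(fld) - min(fld)) * 255)
      }
      storage.mode(g) <- "integer"
      g
    })
  })
}

#' Image-versus-pixel flat-distance residual benchmark
#'
#' For each image, the flat distance between the image as a measure on the
#' unit square and a single Dirac "pixel" is computed twice: exactly via the
#' closed form [one_point_flat()] (the ground truth) and with the neural
#' critic (optionally bias-corrected). The per-image residual
#' \eqn{|\rho_F - \tilde\rho| / \rho_F} is attributable entirely to the
#' estimator.
#'
#' @param grids list of intensity matrices.
#' @param pixel_location coordinate of the Dirac in the unit square.
#' @param pixel_mass Dirac mass; a single value recycled, or `NULL` to draw
#'   one integer mass in 1..255 per image.
#' @param model optional `calibration_model`.
#' @param seed integer seed.
#' @param net_config,optimizer_config neural training configuration.
#' @return Data frame with per-image `true_value`, `estimate`, `corrected`,
#'   `residual`. All-zero images are skipped with a warning.
#' @export
image_pixel_residuals <- function(grids, pixel_location = c(0.5, 0.5),
                                  pixel_mass = NULL, model = NULL, seed = 1,
                                  net_config = flatmetric::net_config(),
                                  optimizer_config = flatmetric::optimizer_config()) {
  masses <- if (is.null(pixel_mass)) {
    with_seed(substream_seed(seed, "pixmass"),
              sample(1:255, length(grids), replace = TRUE))
  } else rep(pixel_mass, length.out = length(grids))
  if (any(masses <= 0)) stop("pixel_mass must be positive")
  rows <- lapply(seq_along(grids), function(i) {
    mu <- image_to_measure(grids[[i]])
    if (n_atoms(mu) == 0L) {
      warning(sprintf("image %d is all-zero; skipped", i))
      return(NULL)
    }
    m <- masses[i]
    truth <- one_point_flat(mu, pixel_location, m)
    nu <- make_dirac(pixel_location, m)
    est <- train_flat(mu, nu, net_config, optimizer_config = optimizer_config,
                      seed = substream_seed(seed, paste0("img", i)))$raw
    tvs <- sort(c(tv_norm(mu), m))
    corr <- if (is.null(model)) est else
      apply_correction(est, tvs[2] / tvs[1], 2, model)
    data.frame(image = i, pixel_mass = m, true_value = truth,
               estimate = est, corrected = corr,
               residual = abs(truth - corr) / truth)
  })
  do.call(rbind, rows)
}
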