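test_that("prior sampling: degenerate covariance, determinism, consistency", {
  tiny <- gaussian_prior(rep(1e-12, 3))
  s <- sample_prior(tiny, 50, rng_seed = 1)
  expect_lt(max(abs(s)), 1e-5)

  spec <- point_cloud_prior(rbind(c(2, 0, 0), c(-2, 0, 0)))
  a <- sample_prior(spec, 20, rng_seed = 7)
  b <- sample_prior(spec, 20, rng_seed = 7)
  expect_identical(a, b)
})

test_that("one-mean point cloud sampling concentrates on the mean", {
  mu <- c(1.5, -2, 0.5)
  spec <- point_cloud_prior(matrix(mu, 1), c(1, 1, 1))
  s <- sample_prior(spec, 1e4, rng_seed = 42)
  expect_lt(max(abs(colMeans(s) - mu)), 0.05)
})

test_that("Gaussian prior force is -Sigma^{-1} r", {
  expect_equal(unname(gaussian_prior_force(matrix(c(1, 2, 3), 1), c(1, 1, 1))),
               matrix(c(-1, -2, -3), 1))
  expect_equal(unname(gaussian_prior_force(matrix(c(1, 1.4, 2.6), 1),
                                           c(1, 1.4, 2.6))),
               matrix(c(-1, -1, -1), 1))
  expect_identical(unname(gaussian_prior_force(matrix(0, 1, 3))),
                   matrix(0, 1, 3))
})

test_that("point-cloud prior force: reduction, symmetry, weight normalisation", {
  mu <- c(0.4, -1, 2)
  one <- point_cloud_prior(matrix(mu, 1), c(1, 1.4, 2.6))
  x <- matrix(c(1, 1, 1), 1)
  expect_equal(point_cloud_prior_force(x, one),
               gaussian_prior_force(x - rep(mu, each = 1), c(1, 1.4, 2.6)),
               tolerance = 1e-12)

  sym <- point_cloud_prior(rbind(c(3, 0, 0), c(-3, 0, 0)), c(1, 1, 1))
  f0 <- point_cloud_prior_force(matrix(0, 1, 3), sym)
  expect_lt(max(abs(f0)), 1e-12)
})

test_that("exact-responsibility force is the analytic mixture gradient", {
  set.seed(31)
  spec <- point_cloud_prior(matrix(rnorm(9, sd = 2), 3, 3), c(1, 1.4, 0.5))
  neg_log_f <- function(x) {
    d <- sweep(spec$means, 2, x)
    -log(sum(exp(-0.5 * rowSums(sweep(d^2, 2, spec$covariance, `/`)))))
  }
  for (probe in 1:4) {
    x <- rnorm(3, sd = 1.5)
    f <- point_cloud_prior_force(matrix(x, 1), spec, weights = "exact")
    h <- 1e-6
    fd <- vapply(1:3, function(a) {
      xp <- x; xp[a] <- xp[a] + h
      xm <- x; xm[a] <- xm[a] - h
      -(neg_log_f(xp) - neg_log_f(xm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(f - fd)), 1e-6)
  }
})

test_that("circle point cloud geometry", {
  spec <- circle_point_cloud(4, 100)
  chord <- sqrt(sum((spec$means[1, ] - spec$means[2, ])^2))
  expect_equal(chord, 2 * 4 * sin(pi / 100), tolerance = 1e-12)
  expect_identical(max(abs(spec$means[, 3])), 0)
  expect_lt(max(abs(colMeans(spec$means))), 1e-10)
  expect_equal(spec$covariance, c(1, 1, 0.5))
  expect_error(circle_point_cloud(-1), "radius")
})

test_that("schedules reproduce their closed forms", {
  s <- force_schedule()
  expect_equal(s$k_sim(10), 1)
  expect_equal(s$k_sim(0), 120)
  expect_equal(s$sigma(10), 1)
  expect_equal(s$sigma(0), 120^(-0.5))
  expect_equal(s$k_prior(0), 0)
  expect_equal(s$k_prior(1), tanh(20))
  expect_error(s$k_sim(11), "outside")
  grid <- time_grid(s, 40)              # descending t, as the sampler sees it
  expect_true(all(diff(s$sigma(grid)) < 0))
  expect_true(all(diff(s$k_sim(grid)) > 0))
})

test_that("time grid is linear then geometric and strictly decreasing", {
  s <- force_schedule()
  g <- time_grid(s, 2)
  expect_length(g, 3)
  expect_true(all(diff(g) < 0))

  g <- time_grid(s, 50)
  expect_length(g, 51)
  n_lin <- 25
  lin_diffs <- diff(g[1:(n_lin + 1)])
  expect_lt(max(abs(lin_diffs - lin_diffs[1])), 1e-10)
  geo <- g[(n_lin + 1):51]
  ratios <- geo[-1] / geo[-length(geo)]
  expect_lt(max(abs(ratios - ratios[1])), 1e-10)
  expect_equal(g[1], s$t_max)
  expect_equal(g[51], s$t_min)
})

test_that("combined force honours the frozen mask and 1/n prior scaling", {
  p <- default_params
  ref <- small_refset()
  s <- force_schedule()
  prior <- gaussian_prior(c(1, 1, 1))

  # far-separated atoms at t_max: force is parallel to -r per atom
  far <- atomic_config(c("C", "C"), rbind(c(20, 0, 0), c(-20, 0, 0)))
  f <- combined_force(far, ref, prior, s, s$t_max, p)
  dir <- f$force / sqrt(rowSums(f$force^2))
  expect_lt(max(abs(dir - rbind(c(-1, 0, 0), c(1, 0, 0)))), 1e-6)

  frozen <- atomic_config(c("C", "C", "O"),
                          rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0)),
                          frozen = TRUE)
  ff <- combined_force(frozen, ref, prior, s, 5, p)
  expect_identical(max(abs(ff$force)), 0)

  # doubling n halves the prior contribution per atom
  one <- atomic_config("C", matrix(c(0, 3, 0), 1, 3))
  two <- atomic_config(c("C", "C"), rbind(c(0, 3, 0), c(40, 3, 0)))
  f1 <- combined_force(one, ref, prior, s, s$t_max, p,
                       repulsion_strength = 0)
  f2 <- combined_force(two, ref, prior, s, s$t_max, p,
                       repulsion_strength = 0)
  expect_equal(f2$force_prior[1, ], f1$force_prior[1, ] / 2, tolerance = 1e-12)
})

test_that("prior forces vanish at their density modes", {
  expect_identical(max(abs(gaussian_prior_force(matrix(0, 1, 3)))), 0)
  line <- point_cloud_prior(cbind(-2:2, 0, 0), c(1, 1, 1))
  at_centre <- point_cloud_prior_force(matrix(0, 1, 3), line, weights = "exact")
  expect_lt(max(abs(at_centre)), 1e-12)  # symmetric mode of the line cloud
})

test_that("priors load from YAML configs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("type: circle", "radius: 6", "n_points: 50"), path)
  spec <- prior_from_config(path)
  expect_s3_class(spec, "point_cloud_prior")
  expect_identical(nrow(spec$means), 50L)
  writeLines(c("type: gaussian"), path)
  expect_equal(prior_from_config(path)$covariance, c(1.0, 1.4, 2.6))
})
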