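test_that("guided score: identity at zero gain, pure similarity at zero base", {
  p <- default_params
  ref <- small_refset()
  cfg <- random_cluster(3, seed = 21)
  zero_model <- function(config, t) matrix(0, 3, 3)
  noisy_model <- function(config, t) config$positions * 0.3

  g0 <- guided_score(noisy_model, cfg, 1, ref,
                     guidance_config(k_gui = 0), sigma = 0.3, params = p)
  expect_equal(g0, noisy_model(cfg, 1))

  g1 <- guided_score(zero_model, cfg, 1, ref,
                     guidance_config(k_gui = 2.5), sigma = 0.3, params = p)
  expect_equal(g1, 2.5 * similarity_force(cfg, ref, 0.3, p)$force,
               tolerance = 1e-12)

  bad <- function(config, t) matrix(NaN, 3, 3)
  expect_error(guided_score(bad, cfg, 1, ref, guidance_config(), 0.3, p),
               "non-finite")
})

test_that("guidance on frozen atoms is zeroed", {
  p <- default_params
  ref <- small_refset()
  cfg <- atomic_config(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
                       frozen = c(TRUE, FALSE))
  zero_model <- function(config, t) matrix(0, 2, 3)
  g <- guided_score(zero_model, cfg, 1, ref, guidance_config(k_gui = 1),
                    sigma = 0.3, params = p)
  expect_identical(unname(g[1, ]), c(0, 0, 0))
})

test_that("toy mixture score: closed form, symmetry point, finite differences", {
  mu <- matrix(c(1, -1, 2), 1)
  model <- toy_gaussian_mixture_score(mu, sigma_t = 0.7)
  cfg <- atomic_config("C", matrix(c(0.2, 0.4, 1.1), 1, 3))
  s <- model(cfg, 1)
  expect_equal(unname(s[1, ]), (c(1, -1, 2) - c(0.2, 0.4, 1.1)) / 0.7^2)

  pair <- rbind(c(2, 0, 0), c(-2, 0, 0))
  model2 <- toy_gaussian_mixture_score(pair, sigma_t = 1)
  mid <- atomic_config("C", matrix(0, 1, 3))
  expect_lt(max(abs(model2(mid, 1))), 1e-12)

  # finite-difference check of grad log density
  log_dens <- function(x, st) {
    log(sum(exp(-rowSums(sweep(pair, 2, x)^2) / (2 * st^2))))
  }
  x <- c(0.7, -0.3, 0.4)
  s <- model2(atomic_config("C", matrix(x, 1, 3)), 1)
  h <- 1e-6
  fd <- vapply(1:3, function(a) {
    xp <- x; xp[a] <- xp[a] + h
    xm <- x; xm[a] <- xm[a] - h
    (log_dens(xp, 1) - log_dens(xm, 1)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(s[1, ] - fd)), 1e-6)
})

test_that("importance resampling: size, reproducibility, limits, uniformity", {
  batch <- as.list(1:6)
  en <- c(1, 2, 3, 4, 5, 6)
  set.seed(3); a <- importance_resample(batch, en, 1)
  set.seed(3); b <- importance_resample(batch, en, 1)
  expect_identical(a, b)
  expect_length(a, 6)

  cold <- importance_resample(batch, en, 1e-9)
  expect_true(all(unlist(cold) == 1))

  expect_identical(importance_resample(list("x"), 5, 1), list("x"))

  # equal energies: marginal inclusion uniform across slots
  set.seed(17)
  counts <- integer(6)
  for (i in 1:4000) {
    out <- unlist(importance_resample(batch, rep(2, 6), 1))
    counts <- counts + tabulate(out, 6)
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
  expect_error(importance_resample(batch, rep(Inf, 6), 1), "non-finite")
})

test_that("similarity guidance steers a toy score model towards the fragment", {
  # paired comparison: Langevin-style dynamics under a broad analytic
  # Gaussian score, with and without inverse-energy similarity guidance
  # towards a two-environment fragment; guided runs must end at lower E_inv
  p <- default_params
  refmol <- build_fixture("methanol", with_hydrogens = FALSE)
  ref <- build_reference_set(list(m = refmol), p)
  base_score <- toy_gaussian_mixture_score(matrix(0, 1, 3), sigma_t = 1.5)
  run <- function(seed, k_gui) {
    set.seed(seed)
    cfg <- atomic_config(c("C", "O"), matrix(rnorm(6, sd = 2), 2, 3))
    g <- guidance_config(energy = "inverse", k_gui = k_gui)
    for (k in 1:40) {
      s <- guided_score(base_score, cfg, 1, ref, g, sigma = 0.25, params = p)
      step <- 0.08 * s
      len <- sqrt(rowSums(step^2))
      over <- len > 0.2
      step[over, ] <- step[over, , drop = FALSE] * 0.2 / len[over]
      cfg <- atomic_config(cfg$elements,
                           cfg$positions + step + matrix(rnorm(6, sd = 0.04), 2, 3))
    }
    inverse_similarity_energy(compute_descriptors(cfg, p), ref, 0.25)
  }
  diffs <- vapply(1:20, function(s) run(s, 0.5) - run(s, 0), numeric(1))
  wins <- sum(diffs < 0)
  expect_lt(binom.test(wins, 20, alternative = "greater")$p.value, 0.05)
})

test_that("inverse energy spreads atoms over references where standard collapses", {
  # two reference environments (methanol heavy: a C and an O end);
  # three atoms guided by each energy in a plain gradient descent
  p <- default_params
  refmol <- build_fixture("methanol", with_hydrogens = FALSE)
  ref <- build_reference_set(list(m = refmol), p)
  start <- atomic_config(c("C", "O", "O"),
                         rbind(c(0, 0, 0), c(2.2, 0.4, 0), c(-2.2, 0.4, 0)),
                         frozen = c(TRUE, FALSE, FALSE))
  descend <- function(energy) {
    cfg <- start
    for (i in 1:60) {
      f <- if (energy == "inverse") {
        inverse_similarity_force(cfg, ref, 0.25, p)$force
      } else {
        similarity_force(cfg, ref, 0.25, p)$force
      }
      f[cfg$frozen, ] <- 0
      step <- 0.05 * f
      len <- sqrt(rowSums(step^2))
      over <- len > 0.2
      step[over, ] <- step[over, , drop = FALSE] * 0.2 / len[over]
      cfg <- atomic_config(cfg$elements, cfg$positions + step, cfg$frozen)
    }
    cfg
  }
  std <- descend("standard")
  inv <- descend("inverse")
  e_inv_std <- inverse_similarity_energy(compute_descriptors(std, p), ref, 0.25)
  e_inv_inv <- inverse_similarity_energy(compute_descriptors(inv, p), ref, 0.25)
  expect_lt(e_inv_inv, e_inv_std)
})
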