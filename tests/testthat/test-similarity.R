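test_that("RBF kernel closed forms", {
  chi <- c(1, 0, 0)
  expect_equal(rbf_kernel(chi, chi, 0.3), 1)
  other <- chi + c(0.3 * sqrt(2), 0, 0)   # distance sigma * sqrt(2)
  expect_equal(rbf_kernel(chi, other, 0.3), exp(-1))
  expect_lt(abs(rbf_kernel(c(1, 0), c(0, 1), 1e9) - 1), 1e-12)
  expect_error(rbf_kernel(c(1, 0), c(1, 0, 0), 0.3), "mismatch")
  expect_error(rbf_kernel(chi, chi, 0), "sigma")
})

test_that("local similarity energy: matches, multiplicity and wide kernels", {
  chi <- c(0.6, 0.8)
  expect_equal(local_similarity_energy(chi, matrix(chi, 1), 0.2), 0)
  m5 <- matrix(rep(chi, each = 5), 5)
  expect_equal(local_similarity_energy(chi, m5, 0.2), -log(5))
  refs <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  expect_equal(local_similarity_energy(chi, refs, 1e9), -log(3),
               tolerance = 1e-10)
  expect_error(local_similarity_energy(chi, matrix(numeric(0), 0, 2), 0.2),
               "empty")
})

test_that("log-sum-exp evaluation survives huge descriptor distances", {
  chi <- c(1, rep(0, 4))
  far <- matrix(rep(c(0, 1e3, 0, 0, 0), 2), 2, byrow = TRUE)
  e <- local_similarity_energy(chi, far, 1)
  expect_true(is.finite(e))
  expect_gt(e, 1e5)
})

test_that("total similarity energy is additive over distant subsystems", {
  p <- default_params
  ref <- small_refset()
  a <- build_fixture("ethanol", FALSE)
  b <- build_fixture("acetone", FALSE)
  b_far <- atomic_config(b$elements, b$positions + 30)
  ea <- similarity_energy(compute_descriptors(a, p), ref, 0.3)
  eb <- similarity_energy(compute_descriptors(b_far, p), ref, 0.3)
  eab <- similarity_energy(compute_descriptors(combine_configs(a, b_far), p),
                           ref, 0.3)
  expect_equal(eab, ea + eb, tolerance = 1e-9)
  # one-atom system reduces to the local energy
  one <- atomic_config("C", matrix(0, 1, 3))
  d1 <- compute_descriptors(one, p)
  expect_equal(similarity_energy(d1, ref, 0.3),
               local_similarity_energy(d1[1, ], ref, 0.3))
})

test_that("similarity force matches finite differences of the energy", {
  p <- default_params
  ref <- small_refset()
  cfg <- random_cluster(4, seed = 7)
  for (sigma in c(0.5, 0.15)) {
    sf <- similarity_force(cfg, ref, sigma, p)
    fd <- fd_gradient(cfg, function(c_) {
      similarity_energy(compute_descriptors(c_, p), ref, sigma)
    })
    expect_lt(max(abs(-fd - sf$force)), 1e-5)
    expect_equal(unclass(sf$force_tilde), unclass(sf$force) * sigma^2)
  }
})

test_that("softmax weights normalise and collapse as sigma shrinks", {
  p <- default_params
  ref <- small_refset()
  cfg <- random_cluster(3, seed = 5)
  w <- similarity_force(cfg, ref, 0.4, p)$weights
  expect_equal(unname(rowSums(w)), rep(1, 3), tolerance = 1e-12)
  # as sigma -> 0 the weight mass collapses onto the nearest reference
  # environment(s); identical fixture environments (benzene's six carbons)
  # tie exactly, so compare against the tied-nearest set
  sf_tiny <- similarity_force(cfg, ref, 1e-3, p)
  d2 <- molforge:::cross_dist2(unclass(sf_tiny$desc), ref$desc)
  for (i in 1:3) {
    nearest <- d2[i, ] <= min(d2[i, ]) + 1e-9
    expect_gt(sum(sf_tiny$weights[i, nearest]), 1 - 1e-9)
  }
})

test_that("inverse-sum energy: matches, symmetry with one atom, errors", {
  p <- default_params
  one <- compute_descriptors(atomic_config("C", matrix(0, 1, 3)), p)
  ref1 <- matrix(one[1, ], 1)
  expect_equal(inverse_similarity_energy(one, ref1, 0.2), 0)
  expect_equal(inverse_similarity_energy(one, ref1, 0.2),
               similarity_energy(one, ref1, 0.2))
  # a configuration containing each reference exactly once: energy -> 0
  eth <- build_fixture("ethanol", FALSE)
  d <- compute_descriptors(eth, p)
  expect_lt(abs(inverse_similarity_energy(d, d, 1e-4)), 1e-6)
  expect_error(inverse_similarity_energy(matrix(numeric(0), 0, ncol(d)),
                                         d, 0.2), "empty configuration")
})

test_that("inverse-sum gradient matches finite differences", {
  p <- default_params
  ref <- small_refset()
  cfg <- random_cluster(4, seed = 19)
  ivf <- inverse_similarity_force(cfg, ref, 0.3, p)
  fd <- fd_gradient(cfg, function(c_) {
    inverse_similarity_energy(compute_descriptors(c_, p), ref, 0.3)
  })
  expect_lt(max(abs(-fd - ivf$force)), 1e-5)
})

test_that("repulsion closed forms, momentum conservation and FD", {
  two <- function(r) atomic_config(c("C", "O"), rbind(c(0, 0, 0), c(r, 0, 0)))
  expect_equal(repulsive_energy_force(two(1.3), 4)$energy, exp(-4 * 1.3))
  expect_lt(repulsive_energy_force(two(50), 4)$energy, 1e-80)
  expect_equal(repulsive_energy_force(two(0), 4)$energy, 1)
  expect_equal(repulsive_energy_force(two(1.0), 4, strength = 7)$energy,
               7 * exp(-4))

  cfg <- random_cluster(6, seed = 3)
  rf <- repulsive_energy_force(cfg, 4)
  expect_lt(max(abs(colSums(rf$force))), 1e-10)
  fd <- fd_gradient(cfg, function(c_) repulsive_energy_force(c_, 4)$energy)
  expect_lt(max(abs(-fd - rf$force)), 1e-6)
})

test_that("energies are translation invariant, forces rotation equivariant", {
  p <- default_params
  ref <- small_refset()
  cfg <- random_cluster(5, seed = 23)
  sf <- similarity_force(cfg, ref, 0.25, p)
  shifted <- atomic_config(cfg$elements, cfg$positions + 4.2)
  sfs <- similarity_force(shifted, ref, 0.25, p)
  expect_equal(sfs$energy, sf$energy, tolerance = 1e-10)
  expect_lt(max(abs(sfs$force - sf$force)), 1e-8)
  set.seed(8)
  R <- random_rotation()
  rot <- atomic_config(cfg$elements, cfg$positions %*% t(R))
  sfr <- similarity_force(rot, ref, 0.25, p)
  expect_lt(max(abs(sfr$force - sf$force %*% t(R))), 1e-8)
})

test_that("a probe descending onto its matching site has non-increasing energy", {
  # probe O approaching the hydroxyl position of ethanol from 0.3 A out
  p <- default_params
  ref <- small_refset()
  eth <- build_fixture("ethanol", FALSE)
  base <- subset_config(eth, 1:2)
  target <- eth$positions[3, ]
  dir <- (target - eth$positions[2, ])
  dir <- dir / sqrt(sum(dir^2))
  offs <- seq(0.3, 0, length.out = 16)
  en <- vapply(offs, function(o) {
    probe <- atomic_config("O", matrix(target + o * dir, 1, 3))
    similarity_energy(compute_descriptors(combine_configs(base, probe), p),
                      ref, 0.12)
  }, numeric(1))
  expect_true(all(diff(en) <= 1e-9))
})

test_that("reference banks carry their parameter fingerprint", {
  p <- default_params
  ref <- small_refset(p)
  other <- descriptor_params(n_radial = 4)
  cfg <- build_fixture("ethanol", FALSE)
  expect_error(similarity_force(cfg, ref, 0.3, other), "different descriptor")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_set(ref, path)
  back <- read_reference_set(path)
  expect_equal(back$desc, ref$desc, tolerance = 1e-12)
  expect_identical(back$hash, ref$hash)
})
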