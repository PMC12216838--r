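test_that("sampler step: null force field leaves positions unchanged", {
  p <- default_params
  s <- force_schedule(c_prior = 0)
  # atoms farther apart than r_cut: similarity gradient is exactly zero
  cfg <- atomic_config(c("C", "C"), rbind(c(0, 0, 0), c(12, 0, 0)))
  ref <- small_refset()
  ctl <- sampler_config(noise_floor = 0, noise_scale = 0,
                        repulsion_strength = 0)
  out <- sampler_step(cfg, ref, gaussian_prior(), s, 10, 9.6, ctl, p)
  expect_identical(out$positions, cfg$positions)
})

test_that("sampler step: frozen atoms are bit-identical", {
  p <- default_params
  s <- force_schedule()
  cfg <- atomic_config(c("C", "C", "O"),
                       rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 1, 0)),
                       frozen = c(TRUE, FALSE, TRUE))
  set.seed(4)
  out <- sampler_step(cfg, small_refset(), gaussian_prior(), s, 5, 4.6,
                      sampler_config(), p)
  expect_identical(out$positions[c(1, 3), ], cfg$positions[c(1, 3), ])
  expect_false(identical(out$positions[2, ], cfg$positions[2, ]))
})

test_that("pure prior dynamics contract the norm monotonically", {
  p <- default_params
  s <- force_schedule(c_prior = 1)
  cfg <- atomic_config("C", matrix(c(3, -2, 1), 1, 3))
  ref <- small_refset()   # single isolated atom: zero similarity gradient
  ctl <- sampler_config(noise_floor = 0, noise_scale = 0,
                        repulsion_strength = 0)
  g <- time_grid(s, 20)
  norms <- sqrt(sum(cfg$positions^2))
  for (k in 1:20) {
    cfg <- sampler_step(cfg, ref, gaussian_prior(c(1, 1, 1)), s,
                        g[k], g[k + 1], ctl, p)
    norms <- c(norms, sqrt(sum(cfg$positions^2)))
  }
  expect_true(all(diff(norms) < 0))
})

test_that("swarm mutation: counts, elitism, frozen atoms, mutation targeting", {
  p <- default_params
  ref <- small_refset()
  s <- force_schedule()
  cfg <- random_cluster(7, seed = 2)
  sw <- swarm_config()
  set.seed(1)
  particles <- mutate_swarm(cfg, ref, sw, 5, s, p)
  expect_length(particles, 10)
  expect_identical(particles[[1]]$elements, cfg$elements)
  n_changed <- vapply(particles[-1], function(pt) {
    sum(pt$elements != cfg$elements)
  }, numeric(1))
  expect_true(all(n_changed <= ceiling(0.2 * 7)))  # = 2 sites drawn
  expect_true(any(n_changed > 0))

  frz <- atomic_config(cfg$elements, cfg$positions,
                       frozen = c(TRUE, TRUE, rep(FALSE, 5)))
  set.seed(2)
  for (round in 1:100) {
    parts <- mutate_swarm(frz, ref, sw, runif(1, 0.1, 9), s, p)
    for (pt in parts) {
      expect_identical(pt$elements[1:2], cfg$elements[1:2])
    }
  }
})

test_that("particle selection: limits and uniformity at beta = 0", {
  parts <- as.list(letters[1:4])
  en <- c(3, 1, 2, 5)
  set.seed(9)
  picks <- replicate(200, select_particle(parts, en, 1e9))
  expect_true(all(picks == "b"))

  picks <- replicate(4000, select_particle(parts, en, 0))
  tab <- table(factor(picks, levels = letters[1:4]))
  expect_gt(chisq.test(tab)$p.value, 0.01)

  expect_identical(select_particle(parts[1], en[1], 2), "a")
  expect_error(select_particle(parts, c(1, 2, Inf, 3), 1), "non-finite")
})

test_that("generation is deterministic under a fixed seed", {
  p <- default_params
  ref <- small_refset()
  a <- generate(n_atoms = 5, refset = ref, seed = 12, params = p,
                sampler = sampler_config(n_steps = 10))
  b <- generate(n_atoms = 5, refset = ref, seed = 12, params = p,
                sampler = sampler_config(n_steps = 10))
  expect_identical(a$config$positions, b$config$positions)
  expect_identical(a$config$elements, b$config$elements)
  expect_identical(a$energies, b$energies)
})

test_that("degenerate one-atom generation returns a finite structure", {
  p <- default_params
  iso <- build_reference_set(list(c1 = atomic_config("C", matrix(0, 1, 3))), p)
  res <- generate(n_atoms = 1, refset = iso, seed = 3, params = p,
                  swarm = swarm_config(elements = "C"),
                  sampler = sampler_config(n_steps = 10))
  expect_identical(res$config$elements, "C")
  expect_true(all(is.finite(res$config$positions)))
})

test_that("frozen scaffolds never move during generation", {
  p <- default_params
  ref <- small_refset()
  scaffold <- build_fixture("benzene", with_hydrogens = FALSE)
  scaffold$frozen[] <- TRUE
  free <- atomic_config(c("C", "C"), matrix(0, 2, 3))
  start <- combine_configs(scaffold, free)
  res <- generate(config = start, refset = ref, seed = 5, params = p,
                  sampler = sampler_config(n_steps = 16))
  expect_identical(res$config$positions[1:6, ], scaffold$positions)
  expect_identical(res$config$elements[1:6], scaffold$elements)
})

test_that("trajectories are recorded at every retained knot", {
  p <- default_params
  ref <- small_refset()
  res <- generate(n_atoms = 4, refset = ref, seed = 2, params = p,
                  sampler = sampler_config(n_steps = 8), swarm = NULL,
                  trajectory = TRUE)
  expect_length(res$trajectory, 9)
  expect_false(any(vapply(res$trajectory, is.null, logical(1))))
  expect_length(res$energies, 9)
})

test_that("generated structures keep atoms apart", {
  p <- default_params
  ref <- default_reference_set(p)
  for (sd_ in c(2, 6)) {
    res <- generate(n_atoms = 8, refset = ref, seed = sd_, params = p)
    expect_gt(min(pair_distances(res$config)), 0.8)
  }
})
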