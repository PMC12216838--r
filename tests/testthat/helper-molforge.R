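# shared test helpers: small seeded clusters, finite differences, rotations

default_params <- descriptor_params()

random_cluster <- function(n, seed, elements = c("C", "N", "O"), sd = 1.1) {
  set.seed(seed)
  atomic_config(sample(elements, n, replace = TRUE),
                matrix(rnorm(3 * n, sd = sd), n, 3))
}

# central finite difference of a scalar function of a configuration's
# positions; returns the n x 3 gradient
fd_gradient <- function(config, fun, h = 1e-5) {
  n <- length(config$elements)
  g <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    for (a in 1:3) {
      pp <- config$positions; pp[k, a] <- pp[k, a] + h
      pm <- config$positions; pm[k, a] <- pm[k, a] - h
      g[k, a] <- (fun(atomic_config(config$elements, pp, config$frozen)) -
                  fun(atomic_config(config$elements, pm, config$frozen))) / (2 * h)
    }
  }
  g
}

random_rotation <- function() {
  # QR-based uniform random rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

pair_distances <- function(config) {
  d <- as.matrix(stats::dist(config$positions))
  diag(d) <- Inf
  d
}

small_refset <- function(params = default_params) {
  build_reference_set(c("ethanol", "acetone", "benzene"), params)
}
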