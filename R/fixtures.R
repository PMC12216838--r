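# Deterministic idealized small-molecule geometries used as reference
# structures and test fixtures. Built from standard bond lengths
# (C-C 1.54, C=C/aromatic 1.39, C-O 1.43, C=O 1.22, C-H 1.09, O-H 0.96,
# all in Angstrom) and ideal angles (109.47 / 120 degrees); furan uses its
# literature planar ring coordinates because a regular pentagon misrepresents
# its alternating bond orders. No randomness anywhere.

DEG <- pi / 180
TET <- 109.4712206 * DEG  # tetrahedral angle

unit3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
rotz <- function(v, ang) {
  c(cos(ang) * v[1] - sin(ang) * v[2], sin(ang) * v[1] + cos(ang) * v[2], v[3])
}

tetra_dirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

# three H directions completing an sp3 centre with one existing bond along u
sp3_dirs_1 <- function(u) {
  e <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  p1 <- unit3(e - sum(e * u) * u)
  p2 <- cross3(u, p1)
  t(vapply(c(0, 120, 240) * DEG, function(az) {
    cos(TET) * u + sin(TET) * (cos(az) * p1 + sin(az) * p2)
  }, numeric(3)))
}

# two H directions completing an sp3 centre with bonds along u1, u2
sp3_dirs_2 <- function(u1, u2) {
  b <- unit3(-(u1 + u2))
  a <- unit3(cross3(u1, u2))
  phi <- TET / 2
  rbind(unit3(cos(phi) * b + sin(phi) * a),
        unit3(cos(phi) * b - sin(phi) * a))
}

ring_coords <- function(n, bond) {
  radius <- bond / (2 * sin(pi / n))
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(radius * cos(th), radius * sin(th), 0)
}

# append radial H (length 1.09) to ring atoms that carry one
ring_with_h <- function(elements, pos, h_on) {
  centroid <- colMeans(pos)
  hpos <- t(apply(pos[h_on, , drop = FALSE], 1, function(p) {
    p + 1.09 * unit3(p - centroid)
  }))
  list(elements = c(elements, rep("H", sum(h_on))), pos = rbind(pos, hpos))
}

methyl_h <- function(c_pos, toward) {
  u <- unit3(toward - c_pos)
  dirs <- sp3_dirs_1(u)
  sweep(1.09 * dirs, 2, c_pos, `+`)
}

hydroxyl_h <- function(o_pos, c_pos, away_from) {
  u <- unit3(c_pos - o_pos)
  cand <- rbind(o_pos + 0.96 * rotz(u, TET), o_pos + 0.96 * rotz(u, -TET))
  d <- apply(cand, 1, function(p) sum((p - away_from)^2))
  cand[which.max(d), ]
}

fixture_builders <- list(
  methane = function() {
    pos <- rbind(c(0, 0, 0), 1.09 * tetra_dirs())
    list(elements = c("C", rep("H", 4)), pos = pos, heavy = 1L)
  },
  ethanol = function() {
    cb <- c(0, 0, 0)
    ca <- c(1.54, 0, 0)
    o <- ca + 1.43 * c(cos(pi - TET), sin(pi - TET), 0)
    h_b <- methyl_h(cb, ca)
    h_a <- sweep(1.09 * sp3_dirs_2(unit3(cb - ca), unit3(o - ca)), 2, ca, `+`)
    h_o <- hydroxyl_h(o, ca, cb)
    list(elements = c("C", "C", "O", rep("H", 6)),
         pos = rbind(cb, ca, o, h_b, h_a, h_o), heavy = 1:3)
  },
  methanol = function() {
    cpos <- c(0, 0, 0); o <- c(1.43, 0, 0)
    h_c <- methyl_h(cpos, o)
    h_o <- hydroxyl_h(o, cpos, c(-3, 0, 0))
    list(elements = c("C", "O", rep("H", 4)), pos = rbind(cpos, o, h_c, h_o),
         heavy = 1:2)
  },
  propane = function() {
    c0 <- c(0, 0, 0); c1 <- c(1.54, 0, 0)
    c2 <- c1 + 1.54 * c(cos(pi - TET), sin(pi - TET), 0)
    h0 <- methyl_h(c0, c1)
    h1 <- sweep(1.09 * sp3_dirs_2(unit3(c0 - c1), unit3(c2 - c1)), 2, c1, `+`)
    h2 <- methyl_h(c2, c1)
    list(elements = c(rep("C", 3), rep("H", 8)),
         pos = rbind(c0, c1, c2, h0, h1, h2), heavy = 1:3)
  },
  isobutane = function() {
    dirs <- tetra_dirs()
    centre <- c(0, 0, 0)
    cs <- 1.54 * dirs[1:3, ]
    hc <- 1.09 * dirs[4, ]
    hm <- do.call(rbind, lapply(1:3, function(k) methyl_h(cs[k, ], centre)))
    list(elements = c(rep("C", 4), rep("H", 10)),
         pos = rbind(centre, cs, hc, hm), heavy = 1:4)
  },
  dimethyl_ether = function() {
    o <- c(0, 0, 0)
    half <- TET / 2
    c1 <- 1.43 * c(cos(half), sin(half), 0)
    c2 <- 1.43 * c(cos(half), -sin(half), 0)
    list(elements = c("O", "C", "C", rep("H", 6)),
         pos = rbind(o, c1, c2, methyl_h(c1, o), methyl_h(c2, o)), heavy = 1:3)
  },
  benzene = function() {
    pos <- ring_coords(6, 1.39)
    full <- ring_with_h(rep("C", 6), pos, rep(TRUE, 6))
    list(elements = full$elements, pos = full$pos, heavy = 1:6)
  },
  pyridine = function() {
    pos <- ring_coords(6, 1.39)
    full <- ring_with_h(c("N", rep("C", 5)), pos, c(FALSE, rep(TRUE, 5)))
    list(elements = full$elements, pos = full$pos, heavy = 1:6)
  },
  furan = function() {
    pos <- rbind(c(0, 1.1637, 0), c(1.0945, 0.3478, 0), c(0.7130, -0.9542, 0),
                 c(-0.7130, -0.9542, 0), c(-1.0945, 0.3478, 0))
    full <- ring_with_h(c("O", rep("C", 4)), pos, c(FALSE, rep(TRUE, 4)))
    list(elements = full$elements, pos = full$pos, heavy = 1:5)
  },
  acetone = function() {
    c1 <- c(0, 0, 0); o <- c(0, 1.22, 0)
    c2 <- 1.54 * c(sin(120 * DEG), cos(120 * DEG), 0)
    c3 <- 1.54 * c(-sin(120 * DEG), cos(120 * DEG), 0)
    list(elements = c("C", "O", "C", "C", rep("H", 6)),
         pos = rbind(c1, o, c2, c3, methyl_h(c2, c1), methyl_h(c3, c1)),
         heavy = 1:4)
  },
  acetic_acid = function() {
    c1 <- c(0, 0, 0); o1 <- c(0, 1.22, 0)
    o2 <- 1.43 * c(sin(120 * DEG), cos(120 * DEG), 0)
    c2 <- 1.54 * c(-sin(120 * DEG), cos(120 * DEG), 0)
    h_o <- hydroxyl_h(o2, c1, o1)
    list(elements = c("C", "O", "O", "C", rep("H", 4)),
         pos = rbind(c1, o1, o2, c2, methyl_h(c2, c1), h_o), heavy = 1:4)
  },
  formic_acid = function() {
    c1 <- c(0, 0, 0); o1 <- c(0, 1.22, 0)
    o2 <- 1.43 * c(sin(120 * DEG), cos(120 * DEG), 0)
    h_c <- 1.09 * c(-sin(120 * DEG), cos(120 * DEG), 0)
    h_o <- hydroxyl_h(o2, c1, o1)
    list(elements = c("C", "O", "O", rep("H", 2)),
         pos = rbind(c1, o1, o2, h_c, h_o), heavy = 1:3)
  },
  acetaldehyde = function() {
    c1 <- c(0, 0, 0); o <- c(0, 1.22, 0)        # carbonyl C and O
    c2 <- 1.54 * c(sin(120 * DEG), cos(120 * DEG), 0)
    h1 <- 1.09 * c(-sin(120 * DEG), cos(120 * DEG), 0)
    list(elements = c("C", "O", "C", rep("H", 4)),
         pos = rbind(c1, o, c2, h1, methyl_h(c2, c1)), heavy = 1:3)
  },
  methylamine = function() {
    cpos <- c(0, 0, 0); npos <- c(1.47, 0, 0)
    h_c <- methyl_h(cpos, npos)
    h_n <- sweep(1.01 * sp3_dirs_1(unit3(cpos - npos))[1:2, ], 2, npos, `+`)
    list(elements = c("C", "N", rep("H", 5)), pos = rbind(cpos, npos, h_c, h_n),
         heavy = 1:2)
  },
  formaldehyde = function() {
    c1 <- c(0, 0, 0); o <- c(0, 1.22, 0)
    h <- rbind(1.09 * c(sin(120 * DEG), cos(120 * DEG), 0),
               1.09 * c(-sin(120 * DEG), cos(120 * DEG), 0))
    list(elements = c("C", "O", "H", "H"), pos = rbind(c1, o, h), heavy = 1:2)
  }
)

#' Names of the built-in fixture molecules
#'
#' @return Character vector of molecule names accepted by [build_fixture()].
#' @export
fixture_names <- function() names(fixture_builders)

#' Build an idealized fixture molecule
#'
#' Deterministic geometries from standard bond lengths and ideal angles;
#' heavy-atom skeletons of all fixtures lie in the xy-plane except the
#' branched alkanes. These molecules stand in for a reference set drawn from
#' real data: a handful of small C/N/O molecules covering sp3 and sp2 carbon
#' and single- and double-bonded oxygen and nitrogen environments.
#'
#' @param name one of [fixture_names()].
#' @param with_hydrogens keep hydrogens (`TRUE`, default) or return the
#'   heavy-atom skeleton only.
#' @return An [atomic_config()] with an all-`FALSE` frozen mask.
#' @examples
#' build_fixture("ethanol", with_hydrogens = FALSE)
#' @export
build_fixture <- function(name, with_hydrogens = TRUE) {
  if (!name %in% names(fixture_builders)) {
    stop("unknown fixture '", name, "'; see fixture_names()", call. = FALSE)
  }
  raw <- fixture_builders[[name]]()
  rownames(raw$pos) <- NULL
  config <- atomic_config(raw$elements, raw$pos)
  if (!with_hydrogens) config <- subset_config(config, raw$heavy)
  config
}
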