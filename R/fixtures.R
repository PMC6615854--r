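# Seeded generators of labeled synthetic networks and toy reaction systems.
# Fixtures emulate the geometric/connectivity structure of the terminal
# morphologies (bundles, asters, intermediates, sarcomere-like bands, and the
# two catastrophe classes) so that every classification stage is testable
# without running the simulator. They make no attempt at mechanical or
# chemical realism.

# evenly spread unit directions (Fibonacci sphere), deterministic
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

rot_matrix_small <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

straight_filament <- function(from, dir, length_nm, plus_end = "last",
                              seg_nm = 108) {
  dir <- dir / sqrt(sum(dir^2))
  nseg <- max(2L, ceiling(length_nm / seg_nm))
  s <- seq(0, length_nm, length.out = nseg + 1)
  beads <- cbind(from[1] + s * dir[1], from[2] + s * dir[2], from[3] + s * dir[3])
  filament(beads, plus_end = plus_end)
}

apply_noise <- function(fils, noise) {
  if (noise <= 0) return(fils)
  lapply(fils, function(f) {
    ctr <- colMeans(f$beads)
    R <- rot_matrix_small(rnorm(3, sd = noise / 500))
    b <- t(R %*% t(f$beads - matrix(ctr, nrow(f$beads), 3, byrow = TRUE))) +
      matrix(ctr, nrow(f$beads), 3, byrow = TRUE)
    b <- b + matrix(rnorm(length(b), sd = noise), nrow(b), 3)
    f$beads <- b
    f
  })
}

alpha_element <- function(f1, c1, fr1, f2, c2, fr2) {
  data.frame(species = "alpha", fil1 = f1, cyl1 = c1, frac1 = fr1,
             fil2 = f2, cyl2 = c2, frac2 = fr2, n_heads = NA_real_,
             rest_length = 35, k = 8)
}

motor_element <- function(f1, c1, fr1, f2, c2, fr2, n_heads = 16) {
  data.frame(species = "motor", fil1 = f1, cyl1 = c1, frac1 = fr1,
             fil2 = f2, cyl2 = c2, frac2 = fr2, n_heads = n_heads,
             rest_length = 200, k = 2.5)
}

# crosslink lattice neighbors of parallel filaments at a few axial positions
crosslink_parallel <- function(fils, lat, max_lat = 45, fracs = c(0.25, 0.5, 0.75)) {
  n <- length(fils)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((lat[i, 1:2] - lat[j, 1:2])^2))
      if (d > max_lat) next
      ncyl <- min(nrow(fils[[i]]$beads), nrow(fils[[j]]$beads)) - 1
      for (fr in fracs) {
        cyl <- max(1L, min(ncyl, as.integer(ceiling(fr * ncyl))))
        rows[[length(rows) + 1]] <- alpha_element(i, cyl, 0.5, j, cyl, 0.5)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_bound()
}

#' Generate a labeled synthetic network fixture
#'
#' Seeded generator of point/segment geometries with bound-species
#' annotations, one per morphology class:
#' \describe{
#'   \item{bundle}{parallel unipolar filaments on the 35 nm hexagonal lattice,
#'     crosslinked between neighbors (ground truth BL; nematic S = 1 at zero
#'     noise).}
#'   \item{aster}{filaments radiating from a center with plus ends inward
#'     (ground truth AL; positive polarity-sorting score by construction).}
#'   \item{intermediate}{half bundle, half radial (ground truth ABI).}
#'   \item{sarcomere}{apolar bundle with minifilaments confined to two axial
#'     bands at minus-end overlaps and crosslinkers elsewhere (ground truth
#'     BL with sarcomeric banding).}
#'   \item{fragmented}{two spatially disjoint crosslinked sub-bundles (ground
#'     truth Type A catastrophe).}
#'   \item{sparse}{a widely spaced network whose linker graph is a partial
#'     chain: the largest component still holds ~70\% of filaments but the
#'     mean linker degree is below the Type B threshold (ground truth Type B
#'     catastrophe).}
#' }
#'
#' Noise adds isotropic Gaussian bead jitter plus a small random rigid
#' rotation per filament.
#'
#' @param class fixture class (see above)
#' @param n_filaments number of filaments
#' @param filament_length nm
#' @param noise jitter scale, nm (>= 0)
#' @param seed RNG seed (fixture generation is deterministic per seed)
#' @return list with \code{net} (an [network_state()]), \code{label} (ground
#'   truth: BL, AL, ABI, catastrophe_A or catastrophe_B) and \code{class}
#' @export
make_fixture <- function(class = c("bundle", "aster", "intermediate",
                                   "sarcomere", "fragmented", "sparse"),
                         n_filaments = 20, filament_length = 1000,
                         noise = 10, seed = 1) {
  class <- match.arg(class)
  if (noise < 0) stop("noise must be >= 0")
  if (n_filaments < 4) stop("infeasible spec: need >= 4 filaments")
  set.seed(seed)
  L <- filament_length
  n <- n_filaments

  if (class == "bundle" || class == "sarcomere") {
    lat <- hex_lattice(n, 35)
    apolar <- class == "sarcomere"
    fils <- vector("list", n)
    for (i in seq_len(n)) {
      plus <- if (apolar && i %% 2 == 0) "first" else "last"
      fils[[i]] <- straight_filament(c(-L / 2, lat[i, "y"], lat[i, "z"]),
                                     c(1, 0, 0), L, plus_end = plus)
    }
    bound <- crosslink_parallel(fils, lat[, c("y", "z")])
    label <- "BL"
    if (apolar) {
      # minifilaments confined to two bands at ~1/4 and ~3/4 of the axis
      ncyl <- nrow(fils[[1]]$beads) - 1
      bands <- unique(pmax(1L, pmin(ncyl, c(ceiling(0.25 * ncyl),
                                            ceiling(0.75 * ncyl)))))
      rows <- list()
      for (i in seq_len(n - 1)) {
        d <- sqrt(sum((lat[i, 1:2] - lat[i + 1, 1:2])^2))
        if (d > 45) next
        for (b in bands)
          rows[[length(rows) + 1]] <- motor_element(i, b, 0.5, i + 1, b, 0.5)
      }
      if (length(rows)) bound <- rbind(bound, do.call(rbind, rows))
    }
  } else if (class == "aster") {
    r0 <- 80
    dirs <- fib_sphere(n)
    fils <- lapply(seq_len(n), function(i) {
      straight_filament(r0 * dirs[i, ], dirs[i, ], L, plus_end = "first")
    })
    # ring of crosslinks near the core
    rows <- lapply(seq_len(n), function(i) {
      j <- if (i < n) i + 1L else 1L
      alpha_element(i, 1, 0.1, j, 1, 0.1)
    })
    bound <- do.call(rbind, rows)
    label <- "AL"
  } else if (class == "intermediate") {
    nb <- floor(n / 2)
    lat <- hex_lattice(nb, 35)
    fils_b <- lapply(seq_len(nb), function(i) {
      straight_filament(c(-L / 2, lat[i, "y"], lat[i, "z"]), c(1, 0, 0), L)
    })
    dirs <- fib_sphere(n - nb)
    fils_a <- lapply(seq_len(n - nb), function(i) {
      straight_filament(80 * dirs[i, ], dirs[i, ], L, plus_end = "first")
    })
    fils <- c(fils_b, fils_a)
    bound <- crosslink_parallel(fils_b, lat[, c("y", "z")])
    rows <- lapply(seq_len(n - nb - 1), function(i) {
      alpha_element(nb + i, 1, 0.1, nb + i + 1, 1, 0.1)
    })
    bound <- rbind(bound, do.call(rbind, rows),
                   alpha_element(1, 1, 0.5, nb + 1, 1, 0.5))
    label <- "ABI"
  } else if (class == "fragmented") {
    half <- floor(n / 2)
    lat1 <- hex_lattice(half, 35)
    lat2 <- hex_lattice(n - half, 35)
    gap <- 4 * L
    f1 <- lapply(seq_len(half), function(i) {
      straight_filament(c(-L / 2, lat1[i, "y"], lat1[i, "z"]), c(1, 0, 0), L)
    })
    f2 <- lapply(seq_len(n - half), function(i) {
      straight_filament(c(gap, lat2[i, "y"] + gap, lat2[i, "z"]), c(1, 0, 0), L)
    })
    fils <- c(f1, f2)
    b1 <- crosslink_parallel(f1, lat1[, c("y", "z")])
    b2 <- crosslink_parallel(f2, lat2[, c("y", "z")])
    b2$fil1 <- b2$fil1 + half
    b2$fil2 <- b2$fil2 + half
    bound <- rbind(b1, b2)
    label <- "catastrophe_A"
  } else { # sparse
    lat <- hex_lattice(n, 150) # widely spaced: few binding opportunities
    fils <- lapply(seq_len(n), function(i) {
      straight_filament(c(-L / 2, lat[i, "y"], lat[i, "z"]), c(1, 0, 0), L)
    })
    m <- ceiling(0.7 * n) # chain spanning 70% of filaments, rest isolated
    rows <- lapply(seq_len(m - 1), function(i) {
      alpha_element(i, 1, 0.5, i + 1, 1, 0.5)
    })
    bound <- do.call(rbind, rows)
    label <- "catastrophe_B"
  }

  fils <- apply_noise(fils, noise)
  net <- network_state(fils, bound = bound, validate = FALSE)
  validate_network(net)
  list(net = net, label = label, class = class)
}

#' Toy constant-propensity reaction system
#'
#' A closed system of channels with fixed rates: the analytic firing fraction
#' of channel i is \code{rates[i] / sum(rates)} and waiting times are
#' exponential with mean \code{1 / sum(rates)}. Used as the oracle fixture for
#' the next-reaction engine.
#'
#' @param rates positive channel rates (s^-1)
#' @return list with \code{rates}, \code{probs}, \code{mean_wait} and
#'   \code{system()} (a fresh [nrm_system()] factory)
#' @export
make_toy_reaction_system <- function(rates) {
  if (any(rates <= 0)) stop("rates must be > 0")
  list(rates = rates, probs = rates / sum(rates), mean_wait = 1 / sum(rates),
       system = function() nrm_system(rates))
}
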