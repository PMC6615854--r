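#' Stretching energy of a filament
#'
#' Harmonic stretching of each cylinder about its equilibrium length,
#' \code{sum (k/2) (l - l0_eq)^2}, where \code{l0_eq = monomers * 2.7} nm so a
#' partially filled end cylinder has a proportionally shorter rest length.
#'
#' @param fil an [filament()] object
#' @param params [mechanical_params()]
#' @return energy in pN nm (non-negative)
#' @export
stretching_energy <- function(fil, params = mechanical_params()) {
  stopifnot(inherits(fil, "abm_filament"))
  seg <- fil$beads[-1, , drop = FALSE] - fil$beads[-nrow(fil$beads), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  if (any(len <= 1e-9)) stop("degenerate cylinder (zero length)")
  sum(0.5 * params$k_stretch_filament * (len - fil$monomers * MONOMER_NM)^2)
}

#' Bending energy of a filament
#'
#' Discrete worm-like-chain bending: \code{sum k_bend (1 - cos theta)} over
#' interior hinges, with \code{theta} the angle between consecutive cylinder
#' tangents and \code{k_bend = lp * kBT / l0} by default.
#'
#' @inheritParams stretching_energy
#' @return energy in pN nm
#' @export
bending_energy <- function(fil, params = mechanical_params()) {
  stopifnot(inherits(fil, "abm_filament"))
  b <- fil$beads
  if (nrow(b) < 3) return(0)
  seg <- b[-1, , drop = FALSE] - b[-nrow(b), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  if (any(len <= 1e-9)) stop("zero-length tangent")
  n <- nrow(seg)
  ct <- rowSums(seg[-n, , drop = FALSE] * seg[-1, , drop = FALSE]) /
    (len[-n] * len[-1])
  ct <- pmin(1, pmax(-1, ct))
  sum(params$k_bend * (1 - ct))
}

#' Excluded-volume energy between two cylinders
#'
#' Double line integral of the repulsive kernel \code{k_vol / r^4} over the two
#' segments, evaluated by Gauss-Legendre quadrature. Finite for
#' non-intersecting segments and monotone non-increasing in separation; for
#' (nearly) intersecting segments the kernel is clamped below 1 nm, yielding a
#' large finite capped energy.
#'
#' @param cyl_a,cyl_b 2 x 3 matrices of segment endpoints (nm)
#' @param params [mechanical_params()]
#' @param n_quad quadrature nodes per segment (default from \code{params})
#' @return energy in pN nm
#' @export
excluded_volume_energy <- function(cyl_a, cyl_b, params = mechanical_params(),
                                   n_quad = max(8, params$n_quad)) {
  cyl_a <- as.matrix(cyl_a); cyl_b <- as.matrix(cyl_b)
  stopifnot(dim(cyl_a) == c(2, 3), dim(cyl_b) == c(2, 3))
  evol_pair_cpp(cyl_a[1, ], cyl_a[2, ], cyl_b[1, ], cyl_b[2, ],
                params$k_vol, as.integer(n_quad))
}

#' Spring energy and tension of a bound crosslinker or minifilament
#'
#' Resolves the two attachment points of a bound element, returning the
#' harmonic spring energy \code{(k/2)(d - L0)^2} and the signed tension
#' \code{k (d - L0)} (positive when stretched).
#'
#' @param element one row of a network's \code{bound} table (data frame or list)
#' @param net an [network_state()] object
#' @return list with \code{energy} (pN nm), \code{tension} (pN) and
#'   \code{distance} (nm)
#' @export
linker_energy <- function(element, net) {
  el <- as.list(element)
  nf <- length(net$filaments)
  for (side in 1:2) {
    fi <- el[[paste0("fil", side)]]
    if (is.na(fi) || fi < 1 || fi > nf) stop("dangling attachment")
    if (el[[paste0("cyl", side)]] > nrow(net$filaments[[fi]]$beads) - 1)
      stop("dangling attachment")
  }
  p1 <- attachment_point(net, el$fil1, el$cyl1, el$frac1)
  p2 <- attachment_point(net, el$fil2, el$cyl2, el$frac2)
  d <- sqrt(sum((p1 - p2)^2))
  list(energy = 0.5 * el$k * (d - el$rest_length)^2,
       tension = el$k * (d - el$rest_length),
       distance = d)
}

#' Total mechanical energy of a network
#'
#' @param net an [network_state()] object
#' @param params [mechanical_params()]
#' @param with_walls include the boundary-wall penalty
#' @return named list: \code{total}, \code{stretch}, \code{bend}, \code{evol},
#'   \code{spring}, \code{wall}, and \code{clamped} (TRUE if the
#'   excluded-volume cap engaged)
#' @export
network_energy <- function(net, params = mechanical_params(), with_walls = TRUE) {
  fl <- net_flat(net, params)
  net_energy_cpp(fl$beads, fl$fil_first0, fl$fil_nbeads, fl$l0,
                 params$k_stretch_filament, params$k_bend, params$k_vol,
                 fl$springs, as.numeric(net$box),
                 if (with_walls) params$k_wall else 0,
                 params$evol_cutoff, as.integer(params$n_quad))
}

#' Forces on every bead
#'
#' @inheritParams network_energy
#' @return an n x 3 matrix of forces (pN), \code{-dE/dx}
#' @export
network_forces <- function(net, params = mechanical_params(), with_walls = TRUE) {
  fl <- net_flat(net, params)
  -net_grad_cpp(fl$beads, fl$fil_first0, fl$fil_nbeads, fl$l0,
                params$k_stretch_filament, params$k_bend, params$k_vol,
                fl$springs, as.numeric(net$box),
                if (with_walls) params$k_wall else 0,
                params$evol_cutoff, as.integer(params$n_quad))
}

#' Mechanically equilibrate a network
#'
#' Polak-Ribiere conjugate gradient with restarts and a backtracking line
#' search, run until the largest per-bead force component falls below
#' \code{force_tolerance}. Energy never increases across accepted iterations;
#' topology and bead count are unchanged. Non-convergence is flagged on the
#' result (attribute \code{minimization}), never silent.
#'
#' @inheritParams network_energy
#' @param force_tolerance stopping threshold on max |force component|, pN
#' @param max_iter iteration cap
#' @param with_walls include the boundary wall
#' @return the relaxed \code{abm_network}, with attribute \code{minimization}
#'   holding \code{converged}, \code{iterations}, \code{max_force} and
#'   \code{energy}
#' @export
minimize_network <- function(net, params = mechanical_params(),
                             force_tolerance = 1, max_iter = 5000,
                             with_walls = TRUE) {
  fl <- net_flat(net, params)
  res <- minimize_cpp(fl$beads, fl$fil_first0, fl$fil_nbeads, fl$l0,
                      params$k_stretch_filament, params$k_bend, params$k_vol,
                      fl$springs, as.numeric(net$box),
                      if (with_walls) params$k_wall else 0,
                      params$evol_cutoff, as.integer(params$n_quad),
                      force_tolerance, as.integer(max_iter))
  out <- net_unflat(net, res$beads)
  attr(out, "minimization") <- list(converged = res$converged,
                                    iterations = res$iterations,
                                    max_force = res$max_force,
                                    energy = res$energy)
  if (!res$converged)
    warning(sprintf(
      "minimization did not converge: max force %.3g pN after %d iterations",
      res$max_force, res$iterations))
  out
}

# numerical gradient of the total network energy (finite-difference oracle
# helper, exported for tests and diagnostics)
#' @rdname network_forces
#' @param h central-difference step, nm
#' @export
network_forces_fd <- function(net, params = mechanical_params(),
                              with_walls = TRUE, h = 1e-4) {
  fl <- net_flat(net, params)
  beads <- fl$beads
  e_of <- function(b) {
    net_energy_cpp(b, fl$fil_first0, fl$fil_nbeads, fl$l0,
                   params$k_stretch_filament, params$k_bend, params$k_vol,
                   fl$springs, as.numeric(net$box),
                   if (with_walls) params$k_wall else 0,
                   params$evol_cutoff, as.integer(params$n_quad))$total
  }
  g <- matrix(0, nrow(beads), 3)
  for (i in seq_len(nrow(beads))) {
    for (d in 1:3) {
      bp <- beads; bp[i, d] <- bp[i, d] + h
      bm <- beads; bm[i, d] <- bm[i, d] - h
      g[i, d] <- (e_of(bp) - e_of(bm)) / (2 * h)
    }
  }
  -g
}
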