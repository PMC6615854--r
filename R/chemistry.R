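#' Next-reaction-method event system
#'
#' A set of reaction channels evolved by the next reaction method: every
#' channel keeps a tentative absolute firing time; each step fires the channel
#' with the minimal tentative time, and propensity updates reuse the remaining
#' exponential waiting time (Gibson-Bruck scaling), which makes the trajectory
#' statistically equivalent to the direct stochastic simulation algorithm.
#'
#' Randomness is drawn from R's global RNG stream, so a trajectory is fully
#' reproducible from \code{set.seed()}.
#'
#' @param propensities non-negative numeric vector of initial propensities
#' @param t0 start time (s)
#' @return an environment of class \code{abm_nrm}
#' @export
nrm_system <- function(propensities, t0 = 0) {
  a <- as.numeric(propensities)
  if (any(a < 0)) stop("propensities must be >= 0")
  sys <- new.env(parent = emptyenv())
  sys$a <- a
  sys$t <- t0
  sys$tt <- ifelse(a > 0, t0 + rexp(length(a)) / a, Inf)
  class(sys) <- "abm_nrm"
  sys
}

#' @rdname nrm_system
#' @param sys an \code{abm_nrm} system
#' @return \code{next_reaction_step()}: a list with \code{channel} (index of
#'   the fired channel or NA), \code{time} (absolute firing time), \code{wait}
#'   (waiting time since the previous event) and \code{stalled} (TRUE when all
#'   propensities are zero; the clock does not advance)
#' @export
next_reaction_step <- function(sys) {
  stopifnot(inherits(sys, "abm_nrm"))
  i <- which.min(sys$tt)
  if (length(i) == 0 || !is.finite(sys$tt[i]))
    return(list(channel = NA_integer_, time = sys$t, wait = NA_real_,
                stalled = TRUE))
  tnew <- sys$tt[i]
  wait <- tnew - sys$t
  sys$t <- tnew
  # fired channel draws a fresh exponential
  sys$tt[i] <- if (sys$a[i] > 0) tnew + rexp(1) / sys$a[i] else Inf
  list(channel = i, time = tnew, wait = wait, stalled = FALSE)
}

#' @rdname nrm_system
#' @param i channel index
#' @param a_new new propensity
#' @export
nrm_set_propensity <- function(sys, i, a_new) {
  stopifnot(inherits(sys, "abm_nrm"))
  a_old <- sys$a[i]
  if (a_new < 0) stop("propensity must be >= 0")
  if (a_new == 0) {
    sys$tt[i] <- Inf
  } else if (a_old > 0 && is.finite(sys$tt[i])) {
    sys$tt[i] <- sys$t + (a_old / a_new) * (sys$tt[i] - sys$t)
  } else {
    sys$tt[i] <- sys$t + rexp(1) / a_new
  }
  sys$a[i] <- a_new
  invisible(sys)
}

#' Brownian-ratchet polymerization rate
#'
#' A filament tip growing against an obstacle polymerizes at the reduced rate
#' \code{base_rate * exp(-F * delta / kBT)}, with \code{delta} the monomer step
#' (2.7 nm).
#'
#' @param base_rate unloaded polymerization propensity (s^-1)
#' @param force compressive load on the tip, pN (must be >= 0)
#' @param params [chemistry_params()] (uses \code{delta_ratchet})
#' @param kBT thermal energy, pN nm
#' @return the reduced rate (s^-1)
#' @export
ratcheted_polymerization_rate <- function(base_rate, force,
                                          params = chemistry_params(),
                                          kBT = 4.1) {
  if (any(force < 0)) stop("ratchet load force must be >= 0")
  base_rate * exp(-force * params$delta_ratchet / kBT)
}

#' Slip-bond unbinding rate (alpha-actinin)
#'
#' Crosslinker unbinding accelerates exponentially under extension:
#' \code{base_rate * exp(max(F, 0) * x_slip / kBT)}. Compression (negative
#' tension) leaves the base rate unchanged.
#'
#' @param base_rate unloaded off-rate (s^-1)
#' @param tension signed spring tension, pN (positive = stretched)
#' @param params [chemistry_params()] (uses \code{x_slip})
#' @param kBT thermal energy, pN nm
#' @return the modified off-rate (s^-1), monotone non-decreasing in tension
#' @export
slip_unbinding_rate <- function(base_rate, tension,
                                params = chemistry_params(), kBT = 4.1) {
  base_rate * exp(pmax(tension, 0) * params$x_slip / kBT)
}

#' Catch-bond ensemble unbinding rate (myosin minifilament)
#'
#' The minifilament detaches when all heads of the engaged ensemble release.
#' Following the parallel cluster picture, the bound-head number performs a
#' birth-death walk: a free head attaches at \code{k_a} (set by the duty
#' ratio), a bound head detaches at \code{base_rate * exp(-F / (n_b * f_catch))}
#' with the load shared equally over the \code{n_b} bound heads (catch bond:
#' detachment slows under load). The effective ensemble off-rate is the inverse
#' mean first-passage time to zero bound heads, computed from the closed-form
#' birth-death recursion; it decreases monotonically with tension.
#'
#' @param base_rate unloaded per-head detachment rate (s^-1)
#' @param tension load on the minifilament, pN (negative values treated as 0)
#' @param n_heads heads per engaged ensemble side
#' @param params [chemistry_params()] (uses \code{f_catch}, \code{duty_ratio})
#' @param n0 initial bound-head count (default \code{max(1, round(duty * n_heads))})
#' @return effective ensemble off-rate (s^-1)
#' @export
catch_unbinding_rate <- function(base_rate, tension, n_heads,
                                 params = chemistry_params(), n0 = NULL) {
  stopifnot(n_heads >= 1)
  if (base_rate <= 0) return(0)
  f <- max(tension, 0)
  duty <- params$duty_ratio
  ka <- base_rate * duty / (1 - duty)
  if (is.null(n0)) n0 <- max(1L, round(duty * n_heads))
  n0 <- min(n0, n_heads)
  # h_k = expected time from k bound heads to k-1; h_k = (1 + lambda_k h_{k+1})/mu_k
  mu <- vapply(seq_len(n_heads), function(n) {
    n * base_rate * exp(-f / (n * params$f_catch))
  }, numeric(1))
  lambda <- ka * (n_heads - seq_len(n_heads))
  h <- numeric(n_heads)
  h[n_heads] <- 1 / mu[n_heads]
  if (n_heads > 1) {
    for (k in (n_heads - 1):1) h[k] <- (1 + lambda[k] * h[k + 1]) / mu[k]
  }
  1 / sum(h[seq_len(n0)])
}

#' Linear force-velocity relation for minifilament walking
#'
#' @param stall_free_velocity unloaded walking speed v0, nm/s
#' @param tension opposing load, pN
#' @param stall_force stall force, pN (> 0)
#' @return walking velocity \code{v0 * max(0, 1 - F / F_stall)}, nm/s
#' @export
motor_walk_velocity <- function(stall_free_velocity, tension, stall_force) {
  stopifnot(stall_force > 0)
  stall_free_velocity * pmax(0, 1 - tension / stall_force)
}

#' Enumerate binding-compatible site pairs
#'
#' All unordered pairs of binding sites on distinct filaments whose separation
#' falls in the species' binding band (30-40 nm for alpha-actinin, 175-225 nm
#' for minifilaments). Sites are the quarter, mid and three-quarter points of
#' every cylinder. Used both as the binding propensity input and as the
#' available-site diagnostic.
#'
#' @param net an [network_state()] object
#' @param species \code{"alpha"} or \code{"motor"}
#' @param params [chemistry_params()] (binding bands)
#' @param exclude_occupied drop sites already carrying a bound element of the
#'   same species
#' @return data frame with columns \code{fil1, cyl1, frac1, fil2, cyl2, frac2,
#'   dist}
#' @export
eligible_binding_pairs <- function(net, species = c("alpha", "motor"),
                                   params = chemistry_params(),
                                   exclude_occupied = TRUE) {
  species <- match.arg(species)
  band <- if (species == "alpha") params$linker_band else params$motor_band
  sites <- binding_sites(net)
  if (exclude_occupied && nrow(net$bound)) {
    occ <- net$bound[net$bound$species == species, , drop = FALSE]
    if (nrow(occ)) {
      key <- function(fil, cyl, frac) paste(fil, cyl, round(frac * 100))
      occupied <- c(key(occ$fil1, occ$cyl1, occ$frac1),
                    key(occ$fil2, occ$cyl2, occ$frac2))
      keep <- !(key(sites[, "fil"], sites[, "cyl"], sites[, "frac"]) %in% occupied)
      sites <- sites[keep, , drop = FALSE]
    }
  }
  if (nrow(sites) < 2) {
    return(data.frame(fil1 = integer(0), cyl1 = integer(0), frac1 = numeric(0),
                      fil2 = integer(0), cyl2 = integer(0), frac2 = numeric(0),
                      dist = numeric(0)))
  }
  idx <- eligible_pairs_cpp(sites[, 1:3, drop = FALSE],
                            as.integer(sites[, "fil"]), band[1], band[2])
  i <- idx[, 1]; j <- idx[, 2]
  d <- sqrt(rowSums((sites[i, 1:3, drop = FALSE] -
                       sites[j, 1:3, drop = FALSE])^2))
  data.frame(fil1 = as.integer(sites[i, "fil"]),
             cyl1 = as.integer(sites[i, "cyl"]), frac1 = sites[i, "frac"],
             fil2 = as.integer(sites[j, "fil"]),
             cyl2 = as.integer(sites[j, "cyl"]), frac2 = sites[j, "frac"],
             dist = d)
}
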