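#' Simulation configuration
#'
#' Collects everything needed to run one trajectory: bundle geometry and
#' polarity, concentrations (total actin in uM; alpha-actinin and myosin-head
#' mole ratios relative to actin), the treadmilling factor chi, durations, the
#' RNG seed, and the mechanical/chemical parameter blocks.
#'
#' The reference system is a 2 um bundle of 30 filaments on a 35 nm hexagonal
#' lattice in a 4 x 1.5 x 1.5 um box at 5 uM total actin. Non-treadmilling
#' bundles set \code{treadmilling = FALSE}, which zeroes all four end rates
#' (chi = 0 semantics).
#'
#' @param polarity \code{"unipolar"} or \code{"apolar"}
#' @param n_filaments number of filaments (default 30)
#' @param bundle_length initial filament length, nm
#' @param lattice_spacing hexagonal lattice constant, nm
#' @param box length-3 box extents, nm
#' @param actin_uM total actin concentration, uM
#' @param alpha_ratio alpha-actinin : actin mole ratio (alpha:A)
#' @param motor_ratio myosin head : actin mole ratio (M:A)
#' @param chi treadmilling factor (ignored when \code{treadmilling = FALSE})
#' @param treadmilling logical; FALSE freezes all end kinetics
#' @param duration trajectory length, s
#' @param snapshot_interval s between stored snapshots
#' @param dt_chem chemistry span between mechanical equilibrations, s
#' @param seed integer RNG seed
#' @param flexible_volume expand/contract the box X-extent with the bundle
#' @param margin flexible-volume margin, nm
#' @param force_tolerance CG stopping force, pN
#' @param mech [mechanical_params()]
#' @param chem [chemistry_params()]
#' @return an object of class \code{abm_config}
#' @export
simulation_config <- function(polarity = c("unipolar", "apolar"),
                              n_filaments = 30,
                              bundle_length = 2000,
                              lattice_spacing = 35,
                              box = c(4000, 1500, 1500),
                              actin_uM = 5,
                              alpha_ratio = 0.1,
                              motor_ratio = 0.0225,
                              chi = 1,
                              treadmilling = TRUE,
                              duration = 2000,
                              snapshot_interval = 10,
                              dt_chem = 0.05,
                              seed = 1,
                              flexible_volume = TRUE,
                              margin = 500,
                              force_tolerance = 1,
                              mech = mechanical_params(),
                              chem = chemistry_params()) {
  polarity <- match.arg(polarity)
  if (alpha_ratio <= 0 || motor_ratio <= 0) stop("mole ratios must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (treadmilling && chi <= 0) stop("chi must be > 0 when treadmilling")
  cfg <- structure(list(polarity = polarity, n_filaments = n_filaments,
                        bundle_length = bundle_length,
                        lattice_spacing = lattice_spacing, box = box,
                        actin_uM = actin_uM, alpha_ratio = alpha_ratio,
                        motor_ratio = motor_ratio, chi = chi,
                        treadmilling = treadmilling, duration = duration,
                        snapshot_interval = snapshot_interval,
                        dt_chem = dt_chem, seed = as.integer(seed),
                        flexible_volume = flexible_volume, margin = margin,
                        force_tolerance = force_tolerance,
                        mech = mech, chem = chem),
                   class = "abm_config")
  cfg
}

# copies of a species at concentration c_uM in a box of given nm^3 volume
uM_to_copies <- function(c_uM, volume_nm3) c_uM * 6.02214076e-7 * volume_nm3

copies_to_uM <- function(n, volume_nm3) n / (6.02214076e-7 * volume_nm3)

# hexagonal lattice positions (YZ plane) closest to the origin, spacing a.
# Deterministic fill order: concentric by distance, then by angle.
hex_lattice <- function(n, a) {
  m <- ceiling(sqrt(n)) + 3
  ij <- expand.grid(i = -m:m, j = -m:m)
  y <- a * (ij$i + ij$j / 2)
  z <- a * ij$j * sqrt(3) / 2
  d <- sqrt(y^2 + z^2)
  ord <- order(round(d, 6), round(atan2(z, y), 6))
  sel <- ord[seq_len(n)]
  cbind(y = y[sel], z = z[sel], col = ij$i[sel])
}

#' Build the initial bundle
#'
#' Places \code{n_filaments} straight filaments of length \code{bundle_length}
#' along the box X-axis, with cross-section positions on a hexagonal lattice
#' of the configured spacing, centered in the YZ plane. Unipolar bundles point
#' every plus end toward +X; apolar bundles alternate orientation by lattice
#' column, with a deterministic fix-up so the two orientation counts differ by
#' at most one.
#'
#' @param config a [simulation_config()]
#' @return an [network_state()] with free-species totals derived from the mole
#'   ratios and box volume
#' @export
build_initial_bundle <- function(config) {
  stopifnot(inherits(config, "abm_config"))
  a <- config$lattice_spacing
  lat <- hex_lattice(config$n_filaments, a)
  if (max(abs(lat[, "y"])) > config$box[2] / 2 - a ||
      max(abs(lat[, "z"])) > config$box[3] / 2 - a)
    stop("n_filaments exceeds lattice capacity for the box cross-section")
  box <- c(0, config$box[1], 0, config$box[2], 0, config$box[3])
  yc <- config$box[2] / 2
  zc <- config$box[3] / 2
  xc <- config$box[1] / 2
  L <- config$bundle_length

  total_mono <- max(2L, round(L / MONOMER_NM))
  ncyl <- ceiling(total_mono / 40)
  mono <- rep(40L, ncyl)
  rem <- total_mono - 40L * (ncyl - 1L)
  mono[ncyl] <- as.integer(rem)

  # orientation: +1 plus end toward +X, -1 toward -X
  orient <- rep(1L, config$n_filaments)
  if (config$polarity == "apolar") {
    orient <- ifelse(lat[, "col"] %% 2 == 0, 1L, -1L)
    target <- c(ceiling(config$n_filaments / 2), floor(config$n_filaments / 2))
    excess <- sum(orient == 1L) - target[1]
    if (excess > 0) {
      flip <- rev(which(orient == 1L))[seq_len(excess)]
      orient[flip] <- -1L
    } else if (excess < 0) {
      flip <- rev(which(orient == -1L))[seq_len(-excess)]
      orient[flip] <- 1L
    }
  }

  fils <- vector("list", config$n_filaments)
  for (i in seq_len(config$n_filaments)) {
    # the partial cylinder belongs at the plus end
    m <- if (orient[i] == 1L) mono else rev(mono)
    xs <- cumsum(c(0, m * MONOMER_NM))
    xs <- xs - mean(range(xs)) + xc
    beads <- cbind(xs, yc + lat[i, "y"], zc + lat[i, "z"])
    fils[[i]] <- filament(beads, monomers = m,
                          plus_end = if (orient[i] == 1L) "last" else "first")
  }

  vol <- prod(config$box)
  total_actin <- uM_to_copies(config$actin_uM, vol)
  in_filaments <- sum(vapply(fils, function(f) sum(f$monomers), integer(1)))
  free_g <- max(0, round(total_actin - in_filaments))
  n_alpha <- round(config$alpha_ratio * total_actin)
  heads_per_mf <- 2 * config$chem$n_heads
  n_motor <- round(config$motor_ratio * total_actin / heads_per_mf)
  network_state(fils, bound = NULL, box = box,
                free = c(gactin = free_g, alpha = n_alpha, motor = n_motor))
}

# ---- voxelized species field ------------------------------------------------

#' Voxelized field of freely diffusing species
#'
#' Tiles the box into near-cubic voxels (target edge \code{voxel_nm}, the
#' Kuramoto-length scale) and spreads each species total uniformly over them.
#'
#' @param box length-6 extents, nm
#' @param voxel_nm target voxel edge, nm
#' @param totals named counts \code{c(gactin=, alpha=, motor=)}
#' @return an object of class \code{abm_field}
#' @export
species_field <- function(box, voxel_nm = 500,
                          totals = c(gactin = 0, alpha = 0, motor = 0)) {
  ext <- c(box[2] - box[1], box[4] - box[3], box[6] - box[5])
  dims <- pmax(1L, as.integer(round(ext / voxel_nm)))
  edge <- ext / dims
  nv <- prod(dims)
  counts <- lapply(totals, function(n) {
    base <- rep(floor(n / nv), nv)
    extra <- n - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
    array(base, dim = dims)
  })
  structure(list(dims = dims, edge = edge, origin = box[c(1, 3, 5)],
                 counts = counts),
            class = "abm_field")
}

field_total <- function(field, species) sum(field$counts[[species]])

# voxel index (length-3) containing a point; clamped to grid
voxel_of <- function(field, p) {
  i <- floor((p - field$origin) / field$edge) + 1
  pmin(pmax(i, 1), field$dims)
}

# local concentration (uM) of a species in the voxel containing p
local_uM <- function(field, species, p) {
  v <- voxel_of(field, p)
  n <- field$counts[[species]][v[1], v[2], v[3]]
  copies_to_uM(n, prod(field$edge))
}

# re-tile the field onto a new box, conserving totals: each voxel's content is
# mapped to the new voxel containing its center (clamped)
retile_field <- function(field, box, voxel_nm) {
  totals <- vapply(names(field$counts), function(s) field_total(field, s),
                   numeric(1))
  new <- species_field(box, voxel_nm, setNames(rep(0, length(totals)),
                                               names(totals)))
  idx <- which(array(TRUE, dim = field$dims), arr.ind = TRUE)
  centers <- t(t((idx - 0.5) * rep(field$edge, each = nrow(idx))) +
                 field$origin)
  for (s in names(field$counts)) {
    cnt <- field$counts[[s]][idx]
    keep <- cnt > 0
    if (!any(keep)) next
    for (r in which(keep)) {
      v <- voxel_of(new, centers[r, ])
      new$counts[[s]][v[1], v[2], v[3]] <- new$counts[[s]][v[1], v[2], v[3]] + cnt[r]
    }
  }
  new
}

# ---- flexible volume --------------------------------------------------------

#' Flexible-volume update
#'
#' Sets the box X-extent to the filament X-span plus a margin on both sides;
#' Y and Z are unchanged. The voxel grid is re-tiled and free diffusing copies
#' are reassigned by voxel-center containment, conserving every total exactly.
#'
#' @param state a list with \code{net} (an \code{abm_network}) and optionally
#'   \code{field} (an \code{abm_field}); a bare \code{abm_network} is also
#'   accepted
#' @param margin nm added on both X sides
#' @param voxel_nm voxel edge used when re-tiling
#' @return the state (or network) with the new box
#' @export
update_flexible_volume <- function(state, margin = 500, voxel_nm = 500) {
  bare <- inherits(state, "abm_network")
  net <- if (bare) state else state$net
  allx <- unlist(lapply(net$filaments, function(f) f$beads[, 1]))
  if (!length(allx)) stop("empty network")
  newbox <- net$box
  newbox[1] <- min(allx) - margin
  newbox[2] <- max(allx) + margin
  net$box <- newbox
  if (bare) return(net)
  state$net <- net
  if (!is.null(state$field)) state$field <- retile_field(state$field, newbox, voxel_nm)
  state
}

# ---- steady-state detection -------------------------------------------------

#' Detect the steady-state onset of an observable series
#'
#' Slides a window of length \code{window} (seconds) over the series and finds
#' the earliest time from which every subsequent window mean stays within
#' \code{rel_tol} (relative) of the final-window mean. To rule out trivially
#' "flat" trailing windows of a still-drifting series, the onset must leave at
#' least two full windows of steady data; otherwise the series is reported as
#' not reached.
#'
#' @param series numeric observable values, or a data frame with columns
#'   \code{time} and \code{value}
#' @param time sample times (s); default index times
#' @param window window length, s (default 100)
#' @param rel_tol relative tolerance (default 0.05)
#' @return an object of class \code{abm_steady}: list with \code{observable},
#'   \code{onset} (s, or NA), \code{reached}, \code{time}, \code{value}
#' @export
detect_steady_state <- function(series, time = NULL, window = 100,
                                rel_tol = 0.05) {
  if (is.data.frame(series)) {
    time <- series$time
    series <- series$value
  }
  n <- length(series)
  if (is.null(time)) time <- seq_len(n) - 1
  dt <- stats::median(diff(time))
  w <- max(2L, as.integer(round(window / dt)))
  if (n < 2 * w) stop("series too short: need at least two windows")
  nw <- n - w + 1
  cs <- cumsum(c(0, series))
  wm <- (cs[(w + 1):(n + 1)] - cs[1:nw]) / w # window means, by start index
  mf <- wm[nw]
  scale <- max(abs(mf), max(abs(series)) * 1e-8, .Machine$double.eps)
  ok <- abs(wm - mf) <= rel_tol * scale
  # earliest start index from which all subsequent windows are ok
  all_ok_from <- rev(cumprod(rev(ok))) > 0
  onset_idx <- if (any(all_ok_from)) which(all_ok_from)[1] else NA_integer_
  reached <- !is.na(onset_idx) && onset_idx <= n - 2 * w + 1
  structure(list(observable = attr(series, "observable") %||% "value",
                 onset = if (reached) time[onset_idx] else NA_real_,
                 reached = reached, time = time, value = as.numeric(series),
                 window = window, rel_tol = rel_tol),
            class = "abm_steady")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.abm_steady <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("steady state reached at t = %.1f s (window %.0f s, tol %.0f%%)\n",
                x$onset, x$window, 100 * x$rel_tol))
  } else {
    cat("steady state not reached\n")
  }
  invisible(x)
}

# ---- observables ------------------------------------------------------------

#' Radius of gyration of a network
#'
#' Root-mean-square distance of all beads from their centroid, nm.
#' @param net an \code{abm_network}
#' @export
radius_of_gyration <- function(net) {
  b <- do.call(rbind, lapply(net$filaments, `[[`, "beads"))
  ctr <- colMeans(b)
  sqrt(mean(rowSums((b - matrix(ctr, nrow(b), 3, byrow = TRUE))^2)))
}

mean_filament_length <- function(net) {
  mean(vapply(net$filaments, function(f) sum(f$monomers) * MONOMER_NM,
              numeric(1)))
}
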