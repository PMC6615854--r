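#' @useDynLib actobundle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp runif rnorm sd prcomp setNames
#' @importFrom utils head tail modifyList write.table read.table
NULL

# monomer contribution to filament length: one actin monomer extends the
# two-start helix by ~2.7 nm
MONOMER_NM <- 2.7

#' Mechanical parameters of the bundle force field
#'
#' Collects the stiffnesses and geometric constants of the mechanical model:
#' filaments are chains of cylinders joined at hinges with harmonic stretching
#' and worm-like-chain bending, cylinder pairs repel through a \code{1/r^4}
#' excluded-volume kernel integrated over both segments, and bound
#' crosslinkers/motors act as harmonic springs between attachment points.
#'
#' The default bending constant is derived from the actin persistence length
#' via \code{k_bend = lp * kBT / l0_cylinder}; with \code{lp} = 17000 nm,
#' \code{kBT} = 4.1 pN nm and \code{l0_cylinder} = 108 nm this gives
#' ~645 pN nm.
#'
#' @param l0_cylinder equilibrium cylinder length, nm (full 40-monomer cylinder)
#' @param lp_actin actin persistence length, nm
#' @param k_stretch_filament cylinder stretching stiffness, pN/nm
#' @param k_bend hinge bending modulus, pN nm; default derived from \code{lp_actin}
#' @param k_vol excluded-volume strength, pN nm^3 (kernel \code{k_vol/r^4}
#'   integrated over both segment arc lengths)
#' @param k_stretch_linker,k_stretch_motor spring stiffness of alpha-actinin and
#'   of a myosin minifilament, pN/nm
#' @param rest_length_linker,rest_length_motor spring rest lengths, nm
#' @param kBT thermal energy, pN nm
#' @param k_wall harmonic boundary-wall stiffness, pN/nm
#' @param evol_cutoff midpoint cutoff beyond which excluded volume is skipped,
#'   nm (the 1/r^4 kernel contributes < 0.1 pN nm per pair beyond it)
#' @param n_quad Gauss-Legendre nodes per segment for the excluded-volume
#'   integral in network-level force evaluations (the pairwise
#'   \code{excluded_volume_energy()} uses at least 8)
#' @return an object of class \code{abm_mech_params}
#' @export
mechanical_params <- function(l0_cylinder = 108,
                              lp_actin = 17000,
                              k_stretch_filament = 100,
                              k_bend = NULL,
                              k_vol = 1e4,
                              k_stretch_linker = 8,
                              k_stretch_motor = 2.5,
                              rest_length_linker = 35,
                              rest_length_motor = 200,
                              kBT = 4.1,
                              k_wall = 50,
                              evol_cutoff = 150,
                              n_quad = 4) {
  if (is.null(k_bend)) k_bend <- lp_actin * kBT / l0_cylinder
  p <- list(l0_cylinder = l0_cylinder, lp_actin = lp_actin,
            k_stretch_filament = k_stretch_filament, k_bend = k_bend,
            k_vol = k_vol, k_stretch_linker = k_stretch_linker,
            k_stretch_motor = k_stretch_motor,
            rest_length_linker = rest_length_linker,
            rest_length_motor = rest_length_motor, kBT = kBT,
            k_wall = k_wall, evol_cutoff = evol_cutoff, n_quad = n_quad)
  stiff <- c(p$k_stretch_filament, p$k_bend, p$k_stretch_linker,
             p$k_stretch_motor, p$kBT)
  if (any(stiff <= 0)) stop("all stiffnesses and kBT must be > 0")
  if (p$l0_cylinder >= p$lp_actin)
    stop("cylinder length must be far below the persistence length")
  structure(p, class = "abm_mech_params")
}

#' Chemical rate parameters
#'
#' Rate constants for the reaction-diffusion half of the model. End kinetics
#' default to the in-vitro actin constants (plus end 11.6 uM^-1 s^-1 on /
#' 1.4 s^-1 off; minus end 1.3 uM^-1 s^-1 on / 0.8 s^-1 off); the treadmilling
#' factor \code{chi} multiplies all four. Binding bands are 30-40 nm for
#' alpha-actinin and 175-225 nm for minifilaments.
#'
#' @param k_on_plus,k_off_plus plus (barbed) end rates, uM^-1 s^-1 and s^-1
#' @param k_on_minus,k_off_minus minus (pointed) end rates
#' @param chi treadmilling factor multiplying all four end rates (> 0); see
#'   [apply_treadmilling_factor()]
#' @param diffusion diffusion coefficient of free species, nm^2/s
#' @param voxel_nm voxel edge length, nm (Kuramoto-length scale)
#' @param spatial_diffusion if TRUE, free species hop between voxels as
#'   explicit first-order events; if FALSE (the desk-scale default) the box is
#'   a single well-mixed voxel, the fast-diffusion limit of the same model
#' @param k_on_linker,k_off_linker alpha-actinin pairwise binding (uM^-1 s^-1)
#'   and unbinding (s^-1) rates
#' @param k_on_motor,k_off_motor minifilament binding/unbinding rates
#' @param linker_band,motor_band binding distance bands, nm
#' @param x_slip slip-bond characteristic length of alpha-actinin, nm
#' @param f_catch catch-bond characteristic force per myosin head, pN
#' @param n_heads number of heads per minifilament side (parallel cluster size)
#' @param duty_ratio unloaded fraction of time a head spends bound
#' @param v_motor unloaded minifilament walking speed, nm/s
#' @param f_stall minifilament stall force, pN
#' @param step_nm walking step, nm (one monomer)
#' @param delta_ratchet Brownian-ratchet step length, nm
#' @return an object of class \code{abm_chem_params}
#' @export
chemistry_params <- function(k_on_plus = 11.6, k_off_plus = 1.4,
                             k_on_minus = 1.3, k_off_minus = 0.8,
                             chi = 1,
                             diffusion = 1e6,
                             voxel_nm = 500,
                             spatial_diffusion = FALSE,
                             k_on_linker = 0.7, k_off_linker = 0.3,
                             k_on_motor = 0.2, k_off_motor = 1.7,
                             linker_band = c(30, 40),
                             motor_band = c(175, 225),
                             x_slip = 0.24,
                             f_catch = 12.6,
                             n_heads = 16,
                             duty_ratio = 0.1,
                             v_motor = 200,
                             f_stall = 100,
                             step_nm = MONOMER_NM,
                             delta_ratchet = MONOMER_NM) {
  p <- list(k_on_plus = k_on_plus, k_off_plus = k_off_plus,
            k_on_minus = k_on_minus, k_off_minus = k_off_minus, chi = chi,
            diffusion = diffusion, voxel_nm = voxel_nm,
            spatial_diffusion = spatial_diffusion,
            k_on_linker = k_on_linker, k_off_linker = k_off_linker,
            k_on_motor = k_on_motor, k_off_motor = k_off_motor,
            linker_band = linker_band, motor_band = motor_band,
            x_slip = x_slip, f_catch = f_catch, n_heads = n_heads,
            duty_ratio = duty_ratio, v_motor = v_motor, f_stall = f_stall,
            step_nm = step_nm, delta_ratchet = delta_ratchet)
  rates <- c(k_on_plus, k_off_plus, k_on_minus, k_off_minus, diffusion,
             k_on_linker, k_off_linker, k_on_motor, k_off_motor)
  if (any(rates < 0)) stop("all rate constants must be >= 0")
  if (chi <= 0) stop("treadmilling factor chi must be > 0 (use non-treadmilling mode for chi = 0 semantics)")
  if (length(linker_band) != 2 || diff(linker_band) <= 0)
    stop("linker_band must be an increasing length-2 range")
  if (length(motor_band) != 2 || diff(motor_band) <= 0)
    stop("motor_band must be an increasing length-2 range")
  structure(p, class = "abm_chem_params")
}

#' Scale treadmilling kinetics by a common factor
#'
#' Multiplies the four filament-end rate constants (plus/minus end
#' polymerization and depolymerization) by the factor \code{chi}, leaving every
#' other parameter untouched. \code{chi = 1} is the in-vitro treadmilling rate.
#'
#' @param params an \code{abm_chem_params} object
#' @param chi positive scale factor
#' @return the rescaled parameter object (with \code{chi} recorded)
#' @export
apply_treadmilling_factor <- function(params, chi) {
  stopifnot(inherits(params, "abm_chem_params"))
  if (!is.numeric(chi) || length(chi) != 1 || chi <= 0)
    stop("chi must be a single positive number")
  params$k_on_plus <- params$k_on_plus * chi
  params$k_off_plus <- params$k_off_plus * chi
  params$k_on_minus <- params$k_on_minus * chi
  params$k_off_minus <- params$k_off_minus * chi
  params$chi <- params$chi * chi
  params
}

#' @export
print.abm_mech_params <- function(x, ...) {
  cat("Mechanical parameters (nm, pN, pN nm):\n")
  cat(sprintf("  cylinder l0 %.0f, lp %.0f, k_bend %.1f, k_stretch %.1f\n",
              x$l0_cylinder, x$lp_actin, x$k_bend, x$k_stretch_filament))
  cat(sprintf("  linker k %.1f (rest %.0f), motor k %.1f (rest %.0f), k_vol %.3g\n",
              x$k_stretch_linker, x$rest_length_linker, x$k_stretch_motor,
              x$rest_length_motor, x$k_vol))
  invisible(x)
}

#' @export
print.abm_chem_params <- function(x, ...) {
  cat("Chemistry parameters:\n")
  cat(sprintf("  plus end %.2f uM-1 s-1 on / %.2f s-1 off; minus end %.2f / %.2f (chi %.2f)\n",
              x$k_on_plus, x$k_off_plus, x$k_on_minus, x$k_off_minus, x$chi))
  cat(sprintf("  linker on %.2f / off %.2f; motor on %.2f / off %.2f; v0 %.0f nm/s\n",
              x$k_on_linker, x$k_off_linker, x$k_on_motor, x$k_off_motor,
              x$v_motor))
  invisible(x)
}
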