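test_that("next-reaction engine reproduces exponential waiting statistics", {
  set.seed(101)
  sys <- nrm_system(2) # single channel, k = 2 /s
  waits <- vapply(seq_len(1e5), function(i) next_reaction_step(sys)$wait,
                  numeric(1))
  expect_lt(abs(mean(waits) - 0.5) / 0.5, 0.02)

  set.seed(102)
  sys2 <- nrm_system(c(1, 3))
  fired <- vapply(seq_len(1e5), function(i) next_reaction_step(sys2)$channel,
                  integer(1))
  expect_lt(abs(mean(fired == 2) - 0.75), 0.01)

  sys0 <- nrm_system(c(0, 0))
  ev <- next_reaction_step(sys0)
  expect_true(ev$stalled)
  expect_identical(sys0$t, 0) # no time advance
})

test_that("next-reaction trajectories match a direct-SSA reference (chi-square)", {
  rates <- c(1, 2, 3)
  n_ev <- 1e4
  set.seed(7)
  sys <- nrm_system(rates)
  nrm_counts <- tabulate(vapply(seq_len(n_ev), function(i) {
    next_reaction_step(sys)$channel
  }, integer(1)), nbins = 3)
  ssa_counts <- ssa_direct_counts(rates, n_ev, seed = 8)
  # two-sample homogeneity test between the engines
  p_two <- stats::chisq.test(rbind(nrm_counts, ssa_counts))$p.value
  expect_gt(p_two, 0.01)
  # and each against the analytic law
  p_an <- stats::chisq.test(nrm_counts, p = rates / sum(rates))$p.value
  expect_gt(p_an, 0.01)
})

test_that("propensity rescaling keeps the engine unbiased", {
  # halve the rate of channel 1 midstream; long-run frequencies follow the
  # updated propensities
  set.seed(11)
  sys <- nrm_system(c(2, 1))
  for (i in 1:100) next_reaction_step(sys)
  nrm_set_propensity(sys, 1, 0.5)
  fired <- vapply(seq_len(4e4), function(i) next_reaction_step(sys)$channel,
                  integer(1))
  expect_lt(abs(mean(fired == 1) - 1 / 3), 0.02)
})

test_that("Brownian-ratchet polymerization rate", {
  p <- chemistry_params()
  expect_equal(ratcheted_polymerization_rate(10, 0, p), 10)
  # F chosen so F * delta / kBT = 1
  f1 <- 4.1 / p$delta_ratchet
  expect_equal(ratcheted_polymerization_rate(10, f1, p), 10 * exp(-1),
               tolerance = 1e-12)
  expect_equal(round(ratcheted_polymerization_rate(10, f1, p), 3), 3.679)
  ff <- seq(0, 20, by = 0.5)
  expect_true(all(diff(ratcheted_polymerization_rate(10, ff, p)) < 0))
  expect_error(ratcheted_polymerization_rate(10, -1, p), "force")
})

test_that("slip-bond unbinding rate", {
  p <- chemistry_params()
  expect_equal(slip_unbinding_rate(0.3, 0, p), 0.3)
  f2 <- 2 * 4.1 / p$x_slip # F x_c / kBT = 2
  expect_equal(slip_unbinding_rate(0.3, f2, p), 0.3 * exp(2), tolerance = 1e-12)
  expect_equal(round(slip_unbinding_rate(0.3, f2, p), 3), 2.217)
  expect_equal(slip_unbinding_rate(0.3, -5, p), 0.3) # compression rectified
  ff <- seq(0, 30, by = 1)
  expect_true(all(diff(slip_unbinding_rate(0.3, ff, p)) >= 0))
})

test_that("catch-bond ensemble rate: catch property and head-level MC oracle", {
  p <- chemistry_params()
  r0 <- catch_unbinding_rate(p$k_off_motor, 0, p$n_heads, p)
  expect_gt(r0, 0)
  expect_lt(catch_unbinding_rate(p$k_off_motor, 0.5 * p$f_catch, p$n_heads, p), r0)
  ff <- seq(0, 5 * p$f_catch, length.out = 20)
  rr <- vapply(ff, catch_unbinding_rate, numeric(1),
               base_rate = p$k_off_motor, n_heads = p$n_heads, params = p)
  expect_true(all(diff(rr) < 0))

  # closed-form MFPT vs brute-force Monte-Carlo of the same head chain
  ka <- p$k_off_motor * p$duty_ratio / (1 - p$duty_ratio)
  n0 <- max(1L, round(p$duty_ratio * p$n_heads))
  for (f in c(0, p$f_catch)) {
    mc <- catch_mc_rate(p$k_off_motor, f, p$n_heads, ka, p$f_catch, n0,
                        n_rep = 4000, seed = 21)
    cf <- catch_unbinding_rate(p$k_off_motor, f, p$n_heads, p)
    expect_lt(abs(cf - mc) / cf, 0.1)
  }
})

test_that("motor force-velocity relation", {
  expect_equal(motor_walk_velocity(200, 0, 100), 200)
  expect_equal(motor_walk_velocity(200, 100, 100), 0)
  expect_equal(motor_walk_velocity(200, 50, 100), 100)
  expect_equal(motor_walk_velocity(200, 150, 100), 0) # clamped past stall
})

test_that("eligible binding pairs respect the species bands", {
  p <- chemistry_params()
  mk <- function(gap) {
    f1 <- filament(cbind(c(0, 108, 216, 324), 0, 0))
    f2 <- filament(cbind(c(0, 108, 216, 324), gap, 0))
    network_state(list(f1, f2), box = c(-500, 900, -500, gap + 500, -500, 500))
  }
  pr35 <- eligible_binding_pairs(mk(35), "alpha", p)
  expect_gt(nrow(pr35), 0)
  expect_true(all(pr35$dist >= 30 & pr35$dist <= 40))
  # brute-force O(n^2) scan over all site pairs
  sites <- actobundle:::binding_sites(mk(35))
  d <- as.matrix(dist(sites[, 1:3]))
  same <- outer(sites[, "fil"], sites[, "fil"], "==")
  n_brute <- sum(d >= 30 & d <= 40 & !same & upper.tri(d))
  expect_equal(nrow(pr35), n_brute)

  expect_equal(nrow(eligible_binding_pairs(mk(50), "alpha", p)), 0)
  net200 <- mk(200)
  expect_gt(nrow(eligible_binding_pairs(net200, "motor", p)), 0)
  expect_equal(nrow(eligible_binding_pairs(net200, "alpha", p)), 0)

  # occupied sites are excluded
  occ <- mk(35)
  occ$bound <- rbind(occ$bound,
                     data.frame(species = "alpha", fil1 = 1L, cyl1 = 1L,
                                frac1 = 0.5, fil2 = 2L, cyl2 = 1L, frac2 = 0.5,
                                n_heads = NA_real_, rest_length = 35, k = 8))
  expect_lt(nrow(eligible_binding_pairs(occ, "alpha", p)), n_brute)
})

test_that("treadmilling factor rescales exactly the four end rates", {
  p <- chemistry_params()
  expect_equal(apply_treadmilling_factor(p, 1), p)
  p10 <- apply_treadmilling_factor(p, 10)
  expect_equal(p10$k_on_plus, 10 * p$k_on_plus)
  expect_equal(p10$k_off_plus, 10 * p$k_off_plus)
  expect_equal(p10$k_on_minus, 10 * p$k_on_minus)
  expect_equal(p10$k_off_minus, 10 * p$k_off_minus)
  expect_equal(p10$k_on_linker, p$k_on_linker) # nothing else changes
  expect_equal(p10$v_motor, p$v_motor)
  expect_error(apply_treadmilling_factor(p, 0), "positive")
  expect_error(apply_treadmilling_factor(p, -2), "positive")
})

test_that("treadmilling flux scales about linearly with chi on one filament", {
  # single short filament in a large G-actin bath; the mean elongation over a
  # fixed time should scale ~linearly with chi
  elong <- function(chi, seed) {
    # box long enough that tips never feel the wall, and a G-actin bath deep
    # enough that depletion stays ~1%
    cfg <- simulation_config(n_filaments = 4, bundle_length = 300,
                             lattice_spacing = 300, box = c(12000, 1500, 1500),
                             actin_uM = 20, alpha_ratio = 1e-6,
                             motor_ratio = 1e-6, chi = chi, treadmilling = TRUE,
                             duration = 2, dt_chem = 0.25,
                             snapshot_interval = 2, seed = seed,
                             flexible_volume = FALSE)
    tr <- evolve_bundle(cfg)
    last <- tr$snapshots[[length(tr$snapshots)]]$net
    mean(vapply(last$filaments, function(f) sum(f$monomers), numeric(1))) -
      300 / 2.7
  }
  chis <- c(0.5, 1, 2)
  means <- vapply(chis, function(ch) {
    mean(vapply(1:4, function(s) elong(ch, 100 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # linearity: growth per unit chi roughly constant (within 35% at this n)
  slopes <- means / chis
  expect_lt(max(slopes) / min(slopes), 1.35)
})

test_that("diffusion hops relax an initial point distribution toward uniform", {
  chem <- chemistry_params(spatial_diffusion = TRUE, diffusion = 1e6,
                           voxel_nm = 500, k_on_linker = 0, k_on_motor = 0,
                           k_on_plus = 0, k_off_plus = 0, k_on_minus = 0,
                           k_off_minus = 0)
  cfg <- simulation_config(duration = 1, dt_chem = 0.5, seed = 9,
                           treadmilling = FALSE, chem = chem)
  f <- filament(cbind(c(900, 1100), 750, 750))
  net <- network_state(list(f), box = c(0, 2000, 0, 1500, 0, 1500),
                       free = c(gactin = 0, alpha = 0, motor = 0))
  field <- species_field(net$box, 500, c(gactin = 400, alpha = 0, motor = 0))
  # pile everything into one corner voxel
  field$counts$gactin[] <- 0
  field$counts$gactin[1, 1, 1] <- 400
  st <- new.env(parent = emptyenv())
  st$net <- net
  st$field <- field
  st$next_id <- 1L
  st$tension <- setNames(numeric(0), character(0))
  st$events <- c(poly = 0, depoly = 0, bind = 0, unbind = 0, walk = 0,
                 hop = 0, null = 0)
  set.seed(9)
  v0 <- stats::var(as.numeric(st$field$counts$gactin))
  for (i in 1:6)
    actobundle:::advance_chemistry_span(st, 0.5, (i - 1) * 0.5, chem,
                                        cfg$mech, cfg)
  v1 <- stats::var(as.numeric(st$field$counts$gactin))
  expect_equal(sum(st$field$counts$gactin), 400) # copies conserved
  expect_lt(v1, v0 / 10)
  expect_gt(st$events["hop"], 0)
})
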