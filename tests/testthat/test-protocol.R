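test_that("initial bundle geometry: polarity, lattice spacing, capacity", {
  cfg_u <- simulation_config(polarity = "unipolar", n_filaments = 30,
                             treadmilling = FALSE)
  net_u <- build_initial_bundle(cfg_u)
  e <- actobundle:::network_ends(net_u)
  expect_equal(sum(sign(e$plus[, 1] - e$minus[, 1])), 30)

  cfg_a <- simulation_config(polarity = "apolar", n_filaments = 30,
                             treadmilling = FALSE)
  net_a <- build_initial_bundle(cfg_a)
  e <- actobundle:::network_ends(net_a)
  expect_equal(sum(sign(e$plus[, 1] - e$minus[, 1])), 0)

  # odd filament count: orientation counts differ by at most one
  cfg_odd <- simulation_config(polarity = "apolar", n_filaments = 15,
                               treadmilling = FALSE)
  e <- actobundle:::network_ends(build_initial_bundle(cfg_odd))
  expect_lte(abs(sum(sign(e$plus[, 1] - e$minus[, 1]))), 1)

  # minimum pairwise cross-section distance is the lattice spacing exactly
  yz <- t(vapply(net_u$filaments, function(f) f$beads[1, 2:3], numeric(2)))
  d <- as.matrix(dist(yz))
  diag(d) <- Inf
  expect_equal(min(d), 35)

  # filament length and monomer bookkeeping
  lens <- vapply(net_u$filaments, function(f) sum(f$monomers) * 2.7, numeric(1))
  expect_equal(unique(round(lens)), 2001) # 741 monomers x 2.7 nm ~ 2 um
  expect_error(build_initial_bundle(
    simulation_config(n_filaments = 30, box = c(4000, 150, 150),
                      treadmilling = FALSE)), "capacity")
})

test_that("flexible volume: extent rule, idempotence, conservation", {
  f <- filament(cbind(c(500, 1500, 2500), 750, 750)) # X-span 2000
  net <- network_state(list(f), box = c(0, 3000, 0, 1500, 0, 1500),
                       free = c(gactin = 777, alpha = 55, motor = 5))
  out <- update_flexible_volume(net, margin = 500)
  expect_equal(out$box[2] - out$box[1], 3000)

  field <- species_field(net$box, 500, net$free)
  st <- list(net = net, field = field)
  st2 <- update_flexible_volume(st, margin = 500, voxel_nm = 500)
  for (sp in c("gactin", "alpha", "motor"))
    expect_equal(sum(st2$field$counts[[sp]]), sum(field$counts[[sp]]))

  # expand then contract back restores the original extent
  st3 <- st2
  st3$net$filaments[[1]]$beads[3, 1] <- 3500
  st3 <- update_flexible_volume(st3, margin = 500, voxel_nm = 500)
  expect_equal(st3$net$box[2], 4000)
  st3$net$filaments[[1]]$beads[3, 1] <- 2500
  st4 <- update_flexible_volume(st3, margin = 500, voxel_nm = 500)
  expect_equal(st4$net$box[2] - st4$net$box[1], 3000)
  expect_equal(sum(st4$field$counts$gactin), 777)
})

test_that("steady-state detection: constant, ramp, noisy changepoint", {
  tt <- seq(0, 1000, by = 10)
  expect_error(detect_steady_state(rep(1, 5), window = 100), "too short")

  const <- detect_steady_state(rep(3.3, length(tt)), time = tt, window = 100)
  expect_true(const$reached)
  expect_equal(const$onset, 0)

  ramp <- detect_steady_state(seq_along(tt) * 5, time = tt, window = 100)
  expect_false(ramp$reached)

  # plateau after transient: onset within one window of the changepoint
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    cp <- 300
    y <- ifelse(tt < cp, 100 + (tt - cp)^2 / 100, 100) + rnorm(length(tt), sd = 1)
    det <- detect_steady_state(y, time = tt, window = 100, rel_tol = 0.05)
    det$reached && abs(det$onset - cp) <= 100
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null dynamics leave the geometry at its minimum", {
  chem <- chemistry_params(k_on_linker = 0, k_on_motor = 0)
  cfg <- simulation_config(n_filaments = 4, bundle_length = 500,
                           lattice_spacing = 300, box = c(2000, 1500, 1500),
                           duration = 1, dt_chem = 0.25, snapshot_interval = 1,
                           seed = 2, treadmilling = FALSE, chem = chem,
                           flexible_volume = FALSE)
  tr <- evolve_bundle(cfg)
  expect_equal(sum(tr$events[c("poly", "depoly", "bind", "unbind", "walk")]), 0)
  b0 <- tr$snapshots[[1]]$net$filaments
  b1 <- tr$snapshots[[length(tr$snapshots)]]$net$filaments
  for (i in seq_along(b0))
    expect_lt(max(abs(b0[[i]]$beads - b1[[i]]$beads)), 1)
})

test_that("conservation holds at every snapshot and trajectories are reproducible", {
  cfg <- simulation_config(polarity = "apolar", n_filaments = 6,
                           bundle_length = 500, box = c(2500, 800, 800),
                           duration = 3, dt_chem = 0.1, chi = 2,
                           motor_ratio = 0.09, alpha_ratio = 0.1,
                           actin_uM = 8, snapshot_interval = 1, seed = 31,
                           treadmilling = TRUE)
  tr <- evolve_bundle(cfg)
  totals <- lapply(tr$snapshots, function(s) conservation_totals(s$net))
  for (tot in totals[-1]) expect_identical(tot, totals[[1]])
  expect_gt(sum(tr$events[c("poly", "depoly", "bind", "walk")]), 0)

  tr2 <- evolve_bundle(cfg)
  expect_identical(tr$snapshots[[length(tr$snapshots)]]$net$filaments,
                   tr2$snapshots[[length(tr2$snapshots)]]$net$filaments)
  expect_identical(tr$events, tr2$events)
})

test_that("reduced smoke grid completes and yields classifiable archives", {
  dir <- file.path(tempdir(), "smoke_grid")
  on.exit(unlink(dir, recursive = TRUE))
  spec <- list(alpha_ratios = 0.1, motor_ratios = c(0.0225, 0.675),
               replicates = 2, base_seed = 5,
               config = list(n_filaments = 6, bundle_length = 500,
                             box = c(2000, 800, 800), duration = 2,
                             dt_chem = 0.1, snapshot_interval = 1,
                             polarity = "apolar"))
  manifest <- run_condition_grid(spec, dir)
  expect_equal(nrow(manifest), 4)
  expect_true(all(manifest$status == "ok"))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))

  files <- file.path(dir, manifest$file)
  nets <- lapply(files, function(f) {
    recs <- read_trajectory(f)
    expect_false(is.unsorted(vapply(recs, `[[`, numeric(1), "time")))
    recs[[length(recs)]]$net
  })
  res <- classify_networks(nets)
  expect_equal(nrow(res), 4)
  expect_true(all(res$label %in% c("BL", "AL", "ABI", "catastrophe_A",
                                   "catastrophe_B")))
})

test_that("apolar two-filament system polarity-sorts under one motor", {
  fA <- filament(cbind(seq(0, 999, length.out = 11), 0, 0), plus_end = "last")
  fB <- filament(cbind(seq(0, 999, length.out = 11), 200, 0), plus_end = "first")
  bd <- data.frame(species = "motor", fil1 = 1L, cyl1 = 5L, frac1 = 0.5,
                   fil2 = 2L, cyl2 = 6L, frac2 = 0.5, n_heads = 16,
                   rest_length = 200, k = 2.5)
  net <- network_state(list(fA, fB), bound = bd,
                       box = c(-2000, 3000, -500, 700, -500, 500),
                       free = c(gactin = 0, alpha = 0, motor = 0))
  chem <- chemistry_params(k_off_motor = 0, k_on_motor = 0, k_on_linker = 0)
  cfg <- simulation_config(duration = 8, dt_chem = 0.1, seed = 5,
                           treadmilling = FALSE, snapshot_interval = 1,
                           chem = chem, flexible_volume = FALSE)
  tr <- evolve_bundle(cfg, initial_state = net)
  sep <- vapply(tr$snapshots, function(s) {
    e <- actobundle:::network_ends(s$net)
    abs(e$plus[1, 1] - e$plus[2, 1])
  }, numeric(1))
  expect_true(all(diff(sep) <= 1e-9)) # plus ends approach monotonically
  expect_lt(sep[length(sep)], 999)    # plus-end segments end up overlapping
})
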