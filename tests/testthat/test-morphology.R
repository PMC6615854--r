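make_parallel_pair <- function(gap = 35, L = 999) {
  f1 <- filament(cbind(seq(0, L, length.out = 11), 0, 0))
  f2 <- filament(cbind(seq(0, L, length.out = 11), gap, 0))
  network_state(list(f1, f2), box = c(-500, L + 500, -500, gap + 500, -500, 500))
}

test_that("end-distance distributions: hand geometry and brute-force scan", {
  net <- make_parallel_pair(gap = 35, L = 999)
  ed <- end_distance_distributions(net, breaks = seq(0, 2000, 50))
  bin_of <- function(x) findInterval(x, seq(0, 2000, 50))
  expect_equal(ed$pp[bin_of(35)], 1)
  expect_equal(ed$mm[bin_of(35)], 1)
  expect_equal(ed$pm[bin_of(sqrt(35^2 + 999^2))], 1)
  expect_equal(sum(ed$pp), 1)

  # all ends coincident: mass in the zero-distance bin
  f1 <- filament(rbind(c(0, 0, 0), c(500, 0, 0), c(0.01, 0.01, 0)))
  f2 <- filament(rbind(c(0, 0.02, 0), c(500, 5, 0), c(0.02, 0, 0)))
  net0 <- network_state(list(f1, f2), box = c(-100, 600, -100, 100, -100, 100))
  ed0 <- end_distance_distributions(net0, breaks = seq(0, 1000, 50))
  expect_equal(ed0$pp[1], 1)
  expect_equal(ed0$pm[1], 1)

  # brute-force all-pairs oracle on a random 10-filament snapshot
  fx <- make_fixture("intermediate", n_filaments = 10, noise = 30, seed = 77)
  breaks <- seq(0, 4000, 50)
  ed10 <- end_distance_distributions(fx$net, breaks = breaks)
  ends <- actobundle:::network_ends(fx$net)
  pp <- mm <- pm <- numeric(0)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      pp <- c(pp, sqrt(sum((ends$plus[i, ] - ends$plus[j, ])^2)))
      mm <- c(mm, sqrt(sum((ends$minus[i, ] - ends$minus[j, ])^2)))
      pm <- c(pm, sqrt(sum((ends$plus[i, ] - ends$minus[j, ])^2)),
              sqrt(sum((ends$plus[j, ] - ends$minus[i, ])^2)))
    }
  }
  hcount <- function(x) graphics::hist(pmin(x, 3999.99), breaks = breaks,
                                       plot = FALSE)$counts
  expect_equal(ed10$pp * length(pp), hcount(pp))
  expect_equal(ed10$mm * length(mm), hcount(mm))
  expect_equal(ed10$pm * length(pm), hcount(pm))

  # single filament: flagged empty
  ed1 <- end_distance_distributions(
    network_state(list(f1), box = c(-100, 600, -100, 100, -100, 100)))
  expect_true(ed1$empty)
})

test_that("Jensen-Shannon divergence: worked value, bounds, properties", {
  expect_equal(jensen_shannon_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0, 1)), 1)
  expect_equal(jensen_shannon_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.0488,
               tolerance = 5e-4)
  expect_error(jensen_shannon_divergence(c(1, 0), c(0.2, 0.3, 0.5)),
               "mismatched")

  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    P <- stats::runif(n)
    P <- P / sum(P)
    Q <- stats::runif(n)
    Q <- Q / sum(Q)
    d_pq <- jensen_shannon_divergence(P, Q)
    expect_equal(d_pq, jensen_shannon_divergence(Q, P)) # symmetry
    expect_gte(d_pq, 0)
    expect_lte(d_pq, 1)
    expect_equal(jensen_shannon_divergence(P, P), 0) # identity
  }
})

test_that("dissimilarity matrix: arithmetic oracle, symmetry, exclusions", {
  net_a <- make_parallel_pair(35)
  net_b <- make_parallel_pair(300)
  breaks <- seq(0, 2000, 50)
  da <- end_distance_distributions(net_a, breaks, condition = "a")
  db <- end_distance_distributions(net_b, breaks, condition = "b")
  D <- build_dissimilarity_matrix(list(da, db))
  hand <- mean(c(jensen_shannon_divergence(da$pp, db$pp),
                 jensen_shannon_divergence(da$mm, db$mm),
                 jensen_shannon_divergence(da$pm, db$pm)))
  expect_equal(D["a", "b"], hand)
  expect_equal(D["a", "a"], 0)
  expect_equal(D, t(D))

  # identical conditions give a zero entry
  D2 <- build_dissimilarity_matrix(list(da, da))
  expect_equal(max(D2), 0)

  # empty condition excluded with a message
  single <- end_distance_distributions(
    network_state(list(filament(cbind(c(0, 500), 0, 0))),
                  box = c(-100, 600, -100, 100, -100, 100)),
    breaks, condition = "empty")
  expect_message(D3 <- build_dissimilarity_matrix(list(da, db, single)),
                 "excluded")
  expect_equal(dim(D3), c(2, 2))
})

test_that("complete linkage: hand example, monotonicity, naive oracle, hclust", {
  D <- matrix(c(0, 1, 4, 1, 0, 3, 4, 3, 0), 3, 3)
  tree <- complete_linkage(D)
  expect_equal(tree$height, c(1, 4))
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))

  # duplicate leaves merge first at height zero
  D0 <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 0), 3, 3)
  expect_equal(complete_linkage(D0)$height[1], 0)

  set.seed(99)
  for (i in 1:10) {
    M <- matrix(stats::runif(64), 8, 8)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    tr <- complete_linkage(M)
    expect_true(all(diff(tr$height) >= -1e-12)) # monotone merges
    expect_equal(tr$height, naive_complete_heights(M), tolerance = 1e-12)
    hc <- stats::hclust(stats::as.dist(M), method = "complete")
    expect_equal(tr$height, hc$height, tolerance = 1e-12)
  }
})

test_that("cut_and_label recovers constructed classes and ignores input order", {
  nets <- c(lapply(1:5, function(s) make_fixture("bundle", seed = s)$net),
            lapply(1:5, function(s) make_fixture("aster", seed = s)$net),
            lapply(1:5, function(s) make_fixture("intermediate", seed = s)$net))
  truth <- rep(c("BL", "AL", "ABI"), each = 5)
  res <- classify_networks(nets)
  expect_equal(res$label, truth)

  perm <- c(3, 11, 7, 1, 15, 9, 2, 13, 5, 10, 4, 14, 8, 6, 12)
  res_p <- classify_networks(nets[perm])
  expect_equal(res_p$label, truth[perm])

  # all-identical conditions: every leaf ends up with the same label
  same <- lapply(rep(4, 5), function(s) make_fixture("bundle", seed = s)$net)
  res_same <- classify_networks(same)
  expect_equal(unique(res_same$label), "BL")
})

test_that("morphology features: closed-form cases and frame invariance", {
  # all cylinders parallel
  par_net <- make_parallel_pair(100)
  expect_equal(morphology_features(par_net)$S, 1, tolerance = 1e-12)

  # two perpendicular equal-length cylinders: S = 0.25 by Q-tensor eigenvalue
  f1 <- filament(rbind(c(0, 0, 0), c(100, 0, 0)))
  f2 <- filament(rbind(c(0, 30, 0), c(0, 30, 100)))
  perp <- network_state(list(f1, f2), box = c(-200, 200, -200, 230, -200, 200))
  expect_equal(morphology_features(perp)$S, 0.25, tolerance = 1e-12)

  # two beads a distance d apart: Rg = d / 2
  net2 <- network_state(list(filament(rbind(c(0, 0, 0), c(80, 0, 0)))),
                        box = c(-100, 200, -100, 100, -100, 100))
  expect_equal(morphology_features(net2)$Rg, 40)

  fx <- make_fixture("intermediate", n_filaments = 12, noise = 20, seed = 55)
  a <- morphology_features(fx$net)
  b <- morphology_features(rigid_transform(fx$net))
  for (fld in c("S", "Rg", "asphericity", "polarity_sorting"))
    expect_lt(abs(a[[fld]] - b[[fld]]) / max(abs(a[[fld]]), 1e-12), 1e-9)
})

test_that("catastrophe detection follows the component/degree rule", {
  frag <- make_fixture("fragmented", n_filaments = 30, seed = 2)
  expect_equal(detect_catastrophe(frag$net), "catastrophe_A")

  # connected 30-filament chain with 29 edges: mean degree 1.93 -> none
  fils <- lapply(1:30, function(i) {
    filament(cbind(c(0, 500), (i - 1) * 38, 0))
  })
  bd <- do.call(rbind, lapply(1:29, function(i) {
    data.frame(species = "alpha", fil1 = i, cyl1 = 1L, frac1 = 0.5,
               fil2 = i + 1L, cyl2 = 1L, frac2 = 0.5, n_heads = NA_real_,
               rest_length = 35, k = 8)
  }))
  chain <- network_state(fils, bound = bd,
                         box = c(-500, 1000, -500, 1500, -500, 500))
  expect_equal(morphology_features(chain)$mean_degree, 29 * 2 / 30)
  expect_true(is.na(detect_catastrophe(chain)))

  bundle <- make_fixture("bundle", n_filaments = 20, seed = 3)
  expect_true(is.na(detect_catastrophe(bundle$net)))

  sparse <- make_fixture("sparse", n_filaments = 20, seed = 4)
  expect_equal(detect_catastrophe(sparse$net), "catastrophe_B")
})

test_that("axial species distribution: normalization, banding, uniformity", {
  sarc <- make_fixture("sarcomere", n_filaments = 12, noise = 5, seed = 6)
  h <- axial_species_distribution(sarc$net, "motor", nbins = 20)
  expect_equal(sum(h), 1)
  # motors were placed in two bands at ~25% and ~75% of the axis; allow one
  # bin of leakage on each side
  band_bins <- sort(unique(c(5, 6, 15, 16, 4, 7, 14, 17)))
  expect_gte(sum(h[band_bins]), 0.9)

  # uniform fixture: many motors spread evenly along the axis
  f1 <- filament(cbind(seq(0, 999, length.out = 11), 0, 0))
  f2 <- filament(cbind(seq(0, 999, length.out = 11), 200, 0))
  set.seed(8)
  n_el <- 1000
  cyls <- sample.int(10, n_el, replace = TRUE)
  bd <- data.frame(species = "motor", fil1 = 1L, cyl1 = cyls,
                   frac1 = stats::runif(n_el), fil2 = 2L, cyl2 = cyls,
                   frac2 = stats::runif(n_el), n_heads = 16,
                   rest_length = 200, k = 2.5)
  unet <- network_state(list(f1, f2), bound = bd,
                        box = c(-500, 1500, -500, 700, -500, 500))
  hu <- axial_species_distribution(unet, "motor", nbins = 10)
  expect_true(all(hu <= 3 * 0.1))

  # absent species: flagged empty
  he <- axial_species_distribution(unet, "alpha", nbins = 10)
  expect_true(attr(he, "empty"))
})

test_that("available crosslink sites track the binding band geometry", {
  counts <- vapply(c(35, 45, 60), function(gap) {
    available_crosslink_sites(make_parallel_pair(gap))
  }, numeric(1))
  expect_gt(counts[1], 0)
  expect_true(all(diff(counts) <= 0)) # non-increasing as spacing widens
  expect_equal(available_crosslink_sites(make_parallel_pair(150)), 0)

  # equals a brute-force scan on the ideal bundle
  net <- make_parallel_pair(35)
  sites <- actobundle:::binding_sites(net)
  d <- as.matrix(dist(sites[, 1:3]))
  same <- outer(sites[, "fil"], sites[, "fil"], "==")
  expect_equal(available_crosslink_sites(net),
               sum(d >= 30 & d <= 40 & !same & upper.tri(d)))
})
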