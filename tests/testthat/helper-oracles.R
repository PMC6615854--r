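# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route than the package (brute force, enumeration,
# direct simulation), so agreement is evidence rather than tautology.

# random gently-bent filament for gradient checks
random_filament <- function(n_beads = 5, seed = 1, bend = 0.2) {
  set.seed(seed)
  u <- c(1, 0, 0)
  beads <- matrix(0, n_beads, 3)
  for (i in 2:n_beads) {
    u <- u + rnorm(3, sd = bend)
    u <- u / sqrt(sum(u^2))
    beads[i, ] <- beads[i - 1, ] + u * runif(1, 80, 120)
  }
  filament(beads)
}

# direct SSA (Gillespie first-reaction equivalent): sample event types from
# constant propensities
ssa_direct_counts <- function(rates, n_events, seed) {
  set.seed(seed)
  probs <- rates / sum(rates)
  tabulate(sample.int(length(rates), n_events, replace = TRUE, prob = probs),
           nbins = length(rates))
}

# brute-force double Riemann sum of the 1/r^4 segment-segment integral
evol_riemann <- function(a1, a2, b1, b2, kvol, n = 100) {
  s <- (seq_len(n) - 0.5) / n
  La <- sqrt(sum((a2 - a1)^2))
  Lb <- sqrt(sum((b2 - b1)^2))
  acc <- 0
  for (i in seq_len(n)) {
    p <- a1 + s[i] * (a2 - a1)
    q <- outer(s, b2 - b1) + matrix(b1, n, 3, byrow = TRUE)
    d2 <- rowSums((q - matrix(p, n, 3, byrow = TRUE))^2)
    acc <- acc + sum(1 / (d2 * d2))
  }
  kvol * La * Lb * acc / (n * n)
}

# naive complete-linkage agglomeration: cluster distances recomputed from the
# original matrix at every merge (no Lance-Williams update)
naive_complete_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-15) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Monte-Carlo mean-first-passage rate of the parallel-cluster head chain:
# attach ka per free head, detach kd * exp(-F/(n*Fc)) per bound head,
# absorbed at zero bound heads
catch_mc_rate <- function(kd, F, N, ka, Fc, n0, n_rep = 2000, seed = 1) {
  set.seed(seed)
  times <- vapply(seq_len(n_rep), function(r) {
    n <- n0
    t <- 0
    while (n > 0) {
      mu <- n * kd * exp(-F / (n * Fc))
      lam <- ka * (N - n)
      t <- t + rexp(1, mu + lam)
      n <- n + if (runif(1) < lam / (mu + lam)) 1L else -1L
    }
    t
  }, numeric(1))
  1 / mean(times)
}

# minimum distance between two 3D segments (for the crossing test)
seg_seg_dist <- function(p1, p2, q1, q2) {
  u <- p2 - p1
  v <- q2 - q1
  w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  den <- a * cc - b * b
  s <- if (den > 1e-12) (b * e - cc * d) / den else 0
  s <- min(1, max(0, s))
  t <- if (cc > 1e-12) (b * s + e) / cc else 0
  t <- min(1, max(0, t))
  s <- if (a > 1e-12) (b * t - d) / a else 0
  s <- min(1, max(0, s))
  sqrt(sum((p1 + s * u - (q1 + t * v))^2))
}

min_network_separation <- function(net) {
  segs <- list()
  for (fi in seq_along(net$filaments)) {
    b <- net$filaments[[fi]]$beads
    for (c in seq_len(nrow(b) - 1))
      segs[[length(segs) + 1]] <- list(fil = fi, p = b[c, ], q = b[c + 1, ])
  }
  best <- Inf
  for (i in seq_along(segs)) {
    for (j in seq_along(segs)) {
      if (j <= i) next
      if (segs[[i]]$fil == segs[[j]]$fil) next
      best <- min(best, seg_seg_dist(segs[[i]]$p, segs[[i]]$q,
                                     segs[[j]]$p, segs[[j]]$q))
    }
  }
  best
}

# rigid rotation + translation of a whole network
rigid_transform <- function(net, angles = c(0.3, -0.5, 0.8),
                            shift = c(100, -50, 30)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  net$filaments <- lapply(net$filaments, function(f) {
    f$beads <- t(R %*% t(f$beads)) + matrix(shift, nrow(f$beads), 3, byrow = TRUE)
    f
  })
  allb <- do.call(rbind, lapply(net$filaments, `[[`, "beads"))
  net$box <- as.numeric(rbind(apply(allb, 2, min) - 500,
                              apply(allb, 2, max) + 500))
  net
}

# tiny two-filament network bound by one alpha-actinin, for spring tests
two_filament_net <- function(gap = 50, k_linker = 8, rest = 35) {
  f1 <- filament(cbind(c(0, 108, 216), 0, 0))
  f2 <- filament(cbind(c(0, 108, 216), gap, 0))
  bd <- data.frame(species = "alpha", fil1 = 1L, cyl1 = 1L, frac1 = 0.5,
                   fil2 = 2L, cyl2 = 1L, frac2 = 0.5, n_heads = NA_real_,
                   rest_length = rest, k = k_linker)
  network_state(list(f1, f2), bound = bd,
                box = c(-500, 700, -500, 600, -500, 500))
}
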