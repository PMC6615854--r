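# Trajectory propagation: alternating next-reaction-method chemistry spans and
# conjugate-gradient mechanical equilibration, with mechanosensitive rate
# updates in between. All randomness flows through R's global RNG, so a
# trajectory is bit-reproducible from (config, seed).

nrm_add_channel <- function(sys, a) {
  sys$a <- c(sys$a, a)
  sys$tt <- c(sys$tt, if (a > 0) sys$t + rexp(1) / a else Inf)
  length(sys$a)
}

# effective chemistry parameters: chi applied, or all end rates zeroed in
# non-treadmilling mode
effective_chem <- function(cfg) {
  ch <- cfg$chem
  if (cfg$treadmilling) {
    ch <- apply_treadmilling_factor(ch, cfg$chi)
  } else {
    ch$k_on_plus <- ch$k_off_plus <- ch$k_on_minus <- ch$k_off_minus <- 0
    ch$chi <- 0
  }
  ch
}

# plus/minus end cylinder index and outward unit tangent
end_info <- function(fil, which) {
  n <- nrow(fil$beads)
  at_last <- (fil$plus_end == "last") == (which == "plus")
  if (at_last) {
    u <- fil$beads[n, ] - fil$beads[n - 1, ]
    list(cyl = n - 1L, bead = n, u = u / sqrt(sum(u^2)), at_last = TRUE)
  } else {
    u <- fil$beads[1, ] - fil$beads[2, ]
    list(cyl = 1L, bead = 1L, u = u / sqrt(sum(u^2)), at_last = FALSE)
  }
}

# wall penetration force magnitude on a bead (pN)
wall_force_on <- function(p, box, k_wall) {
  pen <- pmax(0, box[c(1, 3, 5)] - p) + pmax(0, p - box[c(2, 4, 6)])
  k_wall * sqrt(sum(pen^2))
}

site_key <- function(fil, cyl, frac) paste(fil, cyl, round(frac * 100))

#' Conservation totals of a simulation state
#'
#' @param net an \code{abm_network}
#' @param field an \code{abm_field} (or NULL to use \code{net$free})
#' @return named totals: actin (free G + polymerized monomers), alpha-actinin
#'   (free + bound), minifilaments (free + bound)
#' @export
conservation_totals <- function(net, field = NULL) {
  freeg <- if (is.null(field)) net$free[["gactin"]] else field_total(field, "gactin")
  freea <- if (is.null(field)) net$free[["alpha"]] else field_total(field, "alpha")
  freem <- if (is.null(field)) net$free[["motor"]] else field_total(field, "motor")
  mono <- sum(vapply(net$filaments, function(f) sum(f$monomers), integer(1)))
  c(actin = freeg + mono,
    alpha = freea + sum(net$bound$species == "alpha"),
    motor = freem + sum(net$bound$species == "motor"))
}

# tension of every bound element (named by element id), vectorized
element_tensions <- function(net) {
  bd <- net$bound
  if (!nrow(bd)) return(setNames(numeric(0), character(0)))
  nb <- vapply(net$filaments, function(f) nrow(f$beads), integer(1))
  off <- cumsum(c(0L, nb[-length(nb)]))
  beads <- do.call(rbind, lapply(net$filaments, `[[`, "beads"))
  i1 <- off[bd$fil1] + bd$cyl1
  i2 <- off[bd$fil2] + bd$cyl2
  p1 <- beads[i1, , drop = FALSE] * (1 - bd$frac1) +
    beads[i1 + 1, , drop = FALSE] * bd$frac1
  p2 <- beads[i2, , drop = FALSE] * (1 - bd$frac2) +
    beads[i2 + 1, , drop = FALSE] * bd$frac2
  d <- sqrt(rowSums((p1 - p2)^2))
  setNames(bd$k * (d - bd$rest_length), as.character(bd$id))
}

#' Evolve a bundle trajectory
#'
#' Runs the mechanochemical propagation loop: advance chemistry by
#' \code{dt_chem} seconds of next-reaction events, re-equilibrate mechanics by
#' conjugate gradient, update mechanosensitive rates (slip/catch unbinding,
#' walking loads, Brownian-ratchet polymerization against the boundary), apply
#' the flexible-volume update, and record snapshots at the configured
#' interval.
#'
#' @param config a [simulation_config()]
#' @param initial_state optional [network_state()] to evolve instead of the
#'   configured initial bundle (free-species totals are taken from its
#'   \code{free} field); used for bespoke microscale systems such as the
#'   two-filament sliding assay
#' @param progress print progress every this many seconds of simulated time
#'   (NULL for silent)
#' @return an object of class \code{abm_trajectory}: list with \code{config},
#'   \code{snapshots} (each holding \code{time}, \code{net}, \code{free}),
#'   \code{events} (event-type counts) and \code{flags} (convergence warnings)
#' @export
evolve_bundle <- function(config, initial_state = NULL, progress = NULL) {
  stopifnot(inherits(config, "abm_config"))
  set.seed(config$seed)
  chem <- effective_chem(config)
  mech <- config$mech

  net <- if (is.null(initial_state)) build_initial_bundle(config) else initial_state
  field <- species_field(net$box,
                         if (chem$spatial_diffusion) chem$voxel_nm else Inf,
                         net$free)
  net$bound$id <- if (nrow(net$bound)) seq_len(nrow(net$bound)) else integer(0)
  st <- new.env(parent = emptyenv())
  st$net <- net
  st$field <- field
  st$next_id <- nrow(net$bound) + 1L
  st$tension <- setNames(numeric(0), character(0))
  st$events <- c(poly = 0, depoly = 0, bind = 0, unbind = 0, walk = 0,
                 hop = 0, null = 0)
  st$flags <- character(0)

  # initial equilibration
  st$net <- minimize_network(st$net, mech,
                             force_tolerance = config$force_tolerance,
                             max_iter = 5000)
  st$tension <- element_tensions(st$net)

  snapshots <- list()
  take_snapshot <- function(t) {
    free <- vapply(c("gactin", "alpha", "motor"),
                   function(s) field_total(st$field, s), numeric(1))
    names(free) <- c("gactin", "alpha", "motor")
    net <- st$net
    net$free <- free
    snapshots[[length(snapshots) + 1]] <<- list(time = t, net = net)
  }
  take_snapshot(0)

  t <- 0
  next_snap <- config$snapshot_interval
  while (t < config$duration - 1e-9) {
    span <- min(config$dt_chem, config$duration - t)
    advance_chemistry_span(st, span, t, chem, mech, config)
    t <- t + span
    res <- minimize_network(st$net, mech,
                            force_tolerance = config$force_tolerance,
                            max_iter = 3000)
    diag <- attr(res, "minimization")
    if (!diag$converged)
      st$flags <- c(st$flags, sprintf("t=%.2f: max force %.3g", t, diag$max_force))
    st$net <- res
    if (config$flexible_volume) {
      tmp <- update_flexible_volume(list(net = st$net, field = st$field),
                                    margin = config$margin,
                                    voxel_nm = if (chem$spatial_diffusion)
                                      chem$voxel_nm else Inf)
      st$net <- tmp$net
      st$field <- tmp$field
    }
    st$tension <- element_tensions(st$net)
    if (t + 1e-9 >= next_snap) {
      take_snapshot(t)
      next_snap <- next_snap + config$snapshot_interval
    }
    if (!is.null(progress) && abs(t %% progress) < config$dt_chem / 2)
      message(sprintf("t = %.1f s, %d bound, Rg %.0f nm", t,
                      nrow(st$net$bound), radius_of_gyration(st$net)))
  }

  structure(list(config = config, seed = config$seed, snapshots = snapshots,
                 events = st$events, flags = st$flags),
            class = "abm_trajectory")
}

# advance one chemistry span of length dt starting at absolute time t0;
# mutates st (net, field, tension bookkeeping, event counts)
advance_chemistry_span <- function(st, dt, t0, chem, mech, cfg) {
  net <- st$net
  nf <- length(net$filaments)
  meta <- list()
  prop <- numeric(0)
  add <- function(m, a) {
    meta[[length(meta) + 1]] <<- m
    prop[length(prop) + 1] <<- a
  }

  # --- end kinetics ---
  min_mono <- 20L
  tip_voxel <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    f <- net$filaments[[i]]
    pe <- end_info(f, "plus")
    me <- end_info(f, "minus")
    tip_voxel[i, ] <- voxel_of(st$field, f$beads[pe$bead, ])
    fw <- wall_force_on(f$beads[pe$bead, ], net$box, mech$k_wall)
    ratchet <- exp(-fw * chem$delta_ratchet / mech$kBT)
    if (chem$k_on_plus > 0)
      add(list(kind = "poly", fil = i, end = "plus"),
          chem$k_on_plus * local_uM(st$field, "gactin", f$beads[pe$bead, ]) * ratchet)
    if (chem$k_on_minus > 0)
      add(list(kind = "poly", fil = i, end = "minus"),
          chem$k_on_minus * local_uM(st$field, "gactin", f$beads[me$bead, ]))
    total <- sum(f$monomers)
    if (chem$k_off_plus > 0)
      add(list(kind = "depoly", fil = i, end = "plus"),
          if (total > min_mono) chem$k_off_plus else 0)
    if (chem$k_off_minus > 0)
      add(list(kind = "depoly", fil = i, end = "minus"),
          if (total > min_mono) chem$k_off_minus else 0)
  }

  # --- unbinding; walking is aggregated per span (see below) ---
  # Within a span all tensions are frozen, and walking perturbs no other
  # propensity, so the Poisson number of steps an attachment takes over its
  # alive interval is drawn in one shot instead of as individual events.
  bd <- net$bound
  walk_rate <- setNames(numeric(0), character(0))
  alive_from <- setNames(numeric(0), character(0))
  for (r in seq_len(nrow(bd))) {
    id <- bd$id[r]
    tens <- st$tension[[as.character(id)]] %||% 0
    if (bd$species[r] == "alpha") {
      add(list(kind = "unbind", id = id),
          slip_unbinding_rate(chem$k_off_linker, tens, chem, mech$kBT))
    } else {
      add(list(kind = "unbind", id = id),
          catch_unbinding_rate(chem$k_off_motor, tens, chem$n_heads, chem))
      walk_rate[as.character(id)] <- motor_walk_velocity(chem$v_motor, max(tens, 0),
                                                         chem$f_stall) / chem$step_nm
      alive_from[as.character(id)] <- t0
    }
  }

  apply_pending_walk <- function(id, t_until) {
    key <- as.character(id)
    rate <- walk_rate[key]
    if (is.na(rate) || rate <= 0) return(invisible())
    dt_alive <- t_until - alive_from[key]
    if (dt_alive <= 0) return(invisible())
    row <- match(id, net$bound$id)
    if (is.na(row)) return(invisible())
    for (side in 1:2) {
      nsteps <- stats::rpois(1, rate * dt_alive)
      if (nsteps > 0) {
        net <<- walk_attachment(net, row, side, nsteps, chem$step_nm)
        st$events["walk"] <- st$events["walk"] + attr(net, "steps_applied")
      }
    }
    alive_from[key] <<- t_until
  }

  # --- binding aggregates ---
  vol <- prod(c(net$box[2] - net$box[1], net$box[4] - net$box[3],
                net$box[6] - net$box[5]))
  pairs <- list()
  occ <- if (nrow(bd)) {
    c(site_key(bd$fil1, bd$cyl1, bd$frac1), site_key(bd$fil2, bd$cyl2, bd$frac2))
  } else character(0)
  bind_channel <- c(alpha = NA_integer_, motor = NA_integer_)
  for (sp in c("alpha", "motor")) {
    kon <- if (sp == "alpha") chem$k_on_linker else chem$k_on_motor
    if (kon <= 0) next
    pr <- eligible_binding_pairs(net, sp, chem, exclude_occupied = FALSE)
    if (nrow(pr)) {
      pr$key1 <- site_key(pr$fil1, pr$cyl1, pr$frac1)
      pr$key2 <- site_key(pr$fil2, pr$cyl2, pr$frac2)
      pr$alive <- !(pr$key1 %in% occ | pr$key2 %in% occ)
    }
    pairs[[sp]] <- pr
    conc <- copies_to_uM(field_total(st$field, sp), vol)
    n_alive <- if (nrow(pr)) sum(pr$alive) else 0
    add(list(kind = "bind", species = sp), kon * conc * n_alive)
    bind_channel[sp] <- length(prop)
  }

  # --- diffusion hops (aggregated per voxel x species) ---
  dims <- st$field$dims
  if (chem$diffusion > 0 && prod(dims) > 1) {
    krate <- chem$diffusion / st$field$edge^2
    vox_idx <- which(array(TRUE, dim = dims), arr.ind = TRUE)
    hop_channel <- list()
    for (sp in c("gactin", "alpha", "motor")) {
      cnt <- st$field$counts[[sp]]
      ch <- integer(prod(dims))
      for (v in seq_len(nrow(vox_idx))) {
        ndir <- sum((vox_idx[v, ] > 1) + (vox_idx[v, ] < dims))
        if (ndir == 0) next
        iv <- vox_idx[v, ]
        rate_out <- cnt[iv[1], iv[2], iv[3]] *
          sum(krate * ((iv > 1) + (iv < dims)))
        add(list(kind = "hop", species = sp, vox = iv), rate_out)
        ch[v] <- length(prop)
      }
      hop_channel[[sp]] <- ch
    }
  } else {
    hop_channel <- NULL
    vox_idx <- NULL
  }

  sys <- nrm_system(prop, t0 = t0)
  tend <- t0 + dt
  id_row <- function(id) match(id, net$bound$id)

  hop_rate_of <- function(sp, iv) {
    krate <- chem$diffusion / st$field$edge^2
    st$field$counts[[sp]][iv[1], iv[2], iv[3]] *
      sum(krate * ((iv > 1) + (iv < dims)))
  }
  vox_lin <- function(iv) (iv[3] - 1) * dims[1] * dims[2] + (iv[2] - 1) * dims[1] + iv[1]
  update_hop <- function(sp, iv) {
    if (is.null(hop_channel)) return(invisible())
    chn <- hop_channel[[sp]][vox_lin(iv)]
    if (!is.na(chn) && chn > 0) nrm_set_propensity(sys, chn, hop_rate_of(sp, iv))
  }
  update_bind <- function(sp) {
    chn <- bind_channel[sp]
    if (is.na(chn)) return(invisible())
    kon <- if (sp == "alpha") chem$k_on_linker else chem$k_on_motor
    conc <- copies_to_uM(field_total(st$field, sp), vol)
    pr <- pairs[[sp]]
    n_alive <- if (!is.null(pr) && nrow(pr)) sum(pr$alive) else 0
    nrm_set_propensity(sys, chn, kon * conc * n_alive)
  }
  update_poly <- function(fi) {
    # refresh this filament's end-kinetics propensities after a local change
    for (k in seq_along(meta)) {
      m <- meta[[k]]
      if (is.null(m$fil) || m$fil != fi) next
      f <- net$filaments[[fi]]
      total <- sum(f$monomers)
      if (m$kind == "poly") {
        e <- end_info(f, m$end)
        base <- if (m$end == "plus") chem$k_on_plus else chem$k_on_minus
        ratchet <- if (m$end == "plus")
          exp(-wall_force_on(f$beads[e$bead, ], net$box, mech$k_wall) *
                chem$delta_ratchet / mech$kBT) else 1
        nrm_set_propensity(sys, k, base *
                             local_uM(st$field, "gactin", f$beads[e$bead, ]) * ratchet)
      } else if (m$kind == "depoly") {
        base <- if (m$end == "plus") chem$k_off_plus else chem$k_off_minus
        nrm_set_propensity(sys, k, if (total > min_mono) base else 0)
      }
    }
  }

  release_element <- function(row) {
    # return the species to the field at the element midpoint
    el <- net$bound[row, ]
    p <- (attachment_point(net, el$fil1, el$cyl1, el$frac1) +
            attachment_point(net, el$fil2, el$cyl2, el$frac2)) / 2
    iv <- voxel_of(st$field, p)
    sp <- if (el$species == "alpha") "alpha" else "motor"
    st$field$counts[[sp]][iv[1], iv[2], iv[3]] <-
      st$field$counts[[sp]][iv[1], iv[2], iv[3]] + 1
    freed <- c(site_key(el$fil1, el$cyl1, el$frac1),
               site_key(el$fil2, el$cyl2, el$frac2))
    occ <<- setdiff(occ, freed)
    pr <- pairs[[sp]]
    if (!is.null(pr) && nrow(pr)) {
      hit <- pr$key1 %in% freed | pr$key2 %in% freed
      if (any(hit)) {
        revive <- hit & !(pr$key1 %in% occ | pr$key2 %in% occ)
        pairs[[sp]]$alive[revive] <<- TRUE
      }
    }
    net$bound <<- net$bound[-row, , drop = FALSE]
    update_hop(sp, iv)
    update_bind(sp)
  }

  # renumber cylinder references on filament fi by delta (bead removed/added
  # at the chain start)
  shift_cyls <- function(fi, delta) {
    b <- net$bound
    if (!nrow(b)) return(invisible())
    for (side in 1:2) {
      selcol <- b[[paste0("fil", side)]] == fi
      if (any(selcol))
        net$bound[[paste0("cyl", side)]][selcol] <<-
          b[[paste0("cyl", side)]][selcol] + delta
    }
  }

  # drop bound elements attached to cylinder ci of filament fi
  drop_on_cylinder <- function(fi, ci) {
    repeat {
      b <- net$bound
      hit <- which((b$fil1 == fi & b$cyl1 == ci) | (b$fil2 == fi & b$cyl2 == ci))
      if (!length(hit)) break
      id <- b$id[hit[1]]
      for (k in seq_along(meta)) {
        m <- meta[[k]]
        if (!is.null(m$id) && m$id == id) nrm_set_propensity(sys, k, 0)
      }
      release_element(hit[1])
      st$events["unbind"] <- st$events["unbind"] + 1
    }
  }

  repeat {
    i <- which.min(sys$tt)
    if (!length(i) || !is.finite(sys$tt[i]) || sys$tt[i] > tend) break
    ev <- next_reaction_step(sys)
    m <- meta[[ev$channel]]
    kind <- m$kind

    if (kind == "poly" || kind == "depoly") {
      fi <- m$fil
      f <- net$filaments[[fi]]
      e <- end_info(f, m$end)
      if (kind == "poly") {
        iv <- voxel_of(st$field, f$beads[e$bead, ])
        if (st$field$counts$gactin[iv[1], iv[2], iv[3]] < 1) {
          st$events["null"] <- st$events["null"] + 1
          next
        }
        st$field$counts$gactin[iv[1], iv[2], iv[3]] <-
          st$field$counts$gactin[iv[1], iv[2], iv[3]] - 1
        if (f$monomers[e$cyl] < 40L) {
          f$monomers[e$cyl] <- f$monomers[e$cyl] + 1L
          f$beads[e$bead, ] <- f$beads[e$bead, ] + MONOMER_NM * e$u
          net$filaments[[fi]] <- f
        } else if (e$at_last) {
          f$beads <- rbind(f$beads, f$beads[e$bead, ] + MONOMER_NM * e$u)
          f$monomers <- c(f$monomers, 1L)
          net$filaments[[fi]] <- f
        } else {
          f$beads <- rbind(f$beads[1, ] + MONOMER_NM * e$u, f$beads)
          f$monomers <- c(1L, f$monomers)
          net$filaments[[fi]] <- f
          shift_cyls(fi, 1L)
        }
        st$events["poly"] <- st$events["poly"] + 1
        update_hop("gactin", iv)
      } else {
        if (sum(f$monomers) <= min_mono) {
          st$events["null"] <- st$events["null"] + 1
          next
        }
        iv <- voxel_of(st$field, f$beads[e$bead, ])
        if (f$monomers[e$cyl] > 1L) {
          f$monomers[e$cyl] <- f$monomers[e$cyl] - 1L
          f$beads[e$bead, ] <- f$beads[e$bead, ] - MONOMER_NM * e$u
          net$filaments[[fi]] <- f
        } else if (e$at_last) {
          drop_on_cylinder(fi, e$cyl)
          f <- net$filaments[[fi]]
          f$beads <- f$beads[-nrow(f$beads), , drop = FALSE]
          f$monomers <- f$monomers[-length(f$monomers)]
          net$filaments[[fi]] <- f
        } else {
          drop_on_cylinder(fi, 1L)
          f <- net$filaments[[fi]]
          f$beads <- f$beads[-1, , drop = FALSE]
          f$monomers <- f$monomers[-1]
          net$filaments[[fi]] <- f
          shift_cyls(fi, -1L)
        }
        st$field$counts$gactin[iv[1], iv[2], iv[3]] <-
          st$field$counts$gactin[iv[1], iv[2], iv[3]] + 1
        st$events["depoly"] <- st$events["depoly"] + 1
        update_hop("gactin", iv)
      }
      update_poly(fi)

    } else if (kind == "unbind") {
      row <- id_row(m$id)
      if (is.na(row)) {
        st$events["null"] <- st$events["null"] + 1
        next
      }
      apply_pending_walk(m$id, ev$time)
      for (k in seq_along(meta)) {
        mm <- meta[[k]]
        if (!is.null(mm$id) && mm$id == m$id) nrm_set_propensity(sys, k, 0)
      }
      release_element(match(m$id, net$bound$id))
      st$events["unbind"] <- st$events["unbind"] + 1

    } else if (kind == "bind") {
      sp <- m$species
      pr <- pairs[[sp]]
      alive <- which(pr$alive)
      if (!length(alive) || field_total(st$field, sp) < 1) {
        st$events["null"] <- st$events["null"] + 1
        update_bind(sp)
        next
      }
      pick <- alive[sample.int(length(alive), 1)]
      row <- pr[pick, ]
      mid <- (attachment_point(net, row$fil1, row$cyl1, row$frac1) +
                attachment_point(net, row$fil2, row$cyl2, row$frac2)) / 2
      iv <- voxel_of(st$field, mid)
      if (st$field$counts[[sp]][iv[1], iv[2], iv[3]] < 1) {
        nz <- which(st$field$counts[[sp]] > 0, arr.ind = TRUE)
        iv <- nz[1, ]
      }
      st$field$counts[[sp]][iv[1], iv[2], iv[3]] <-
        st$field$counts[[sp]][iv[1], iv[2], iv[3]] - 1
      id <- st$next_id
      st$next_id <- st$next_id + 1L
      new <- data.frame(species = sp, fil1 = row$fil1, cyl1 = row$cyl1,
                        frac1 = row$frac1, fil2 = row$fil2, cyl2 = row$cyl2,
                        frac2 = row$frac2,
                        n_heads = if (sp == "motor") chem$n_heads else NA_real_,
                        rest_length = if (sp == "alpha") mech$rest_length_linker
                        else mech$rest_length_motor,
                        k = if (sp == "alpha") mech$k_stretch_linker
                        else mech$k_stretch_motor,
                        id = id)
      net$bound <- rbind(net$bound, new)
      occ <- c(occ, row$key1, row$key2)
      dead <- pr$key1 %in% c(row$key1, row$key2) |
        pr$key2 %in% c(row$key1, row$key2)
      pairs[[sp]]$alive[dead] <- FALSE
      # freshly created element: tension from current geometry
      tens <- linker_energy(net$bound[nrow(net$bound), ], net)$tension
      st$tension[as.character(id)] <- tens
      if (sp == "alpha") {
        k <- nrm_add_channel(sys, slip_unbinding_rate(chem$k_off_linker, tens,
                                                      chem, mech$kBT))
        meta[[k]] <- list(kind = "unbind", id = id)
      } else {
        k <- nrm_add_channel(sys, catch_unbinding_rate(chem$k_off_motor, tens,
                                                       chem$n_heads, chem))
        meta[[k]] <- list(kind = "unbind", id = id)
        walk_rate[as.character(id)] <- motor_walk_velocity(chem$v_motor, max(tens, 0),
                                                           chem$f_stall) / chem$step_nm
        alive_from[as.character(id)] <- ev$time
      }
      st$events["bind"] <- st$events["bind"] + 1
      update_hop(sp, iv)
      update_bind(sp)

    } else if (kind == "hop") {
      sp <- m$species
      iv <- m$vox
      if (st$field$counts[[sp]][iv[1], iv[2], iv[3]] < 1) {
        st$events["null"] <- st$events["null"] + 1
        update_hop(sp, iv)
        next
      }
      krate <- chem$diffusion / st$field$edge^2
      wdir <- c(krate * (iv > 1), krate * (iv < dims)) # -x,-y,-z,+x,+y,+z
      d <- sample.int(6, 1, prob = wdir)
      jv <- iv
      ax <- ((d - 1) %% 3) + 1
      jv[ax] <- jv[ax] + if (d <= 3) -1L else 1L
      st$field$counts[[sp]][iv[1], iv[2], iv[3]] <-
        st$field$counts[[sp]][iv[1], iv[2], iv[3]] - 1
      st$field$counts[[sp]][jv[1], jv[2], jv[3]] <-
        st$field$counts[[sp]][jv[1], jv[2], jv[3]] + 1
      st$events["hop"] <- st$events["hop"] + 1
      update_hop(sp, iv)
      update_hop(sp, jv)
      if (sp == "gactin") {
        # local G-actin moved: refresh end kinetics of filaments whose tip
        # sits in either voxel
        for (fi in seq_len(nf)) {
          if (all(tip_voxel[fi, ] == iv) || all(tip_voxel[fi, ] == jv))
            update_poly(fi)
        }
      } else {
        update_bind(if (sp == "alpha") "alpha" else "motor")
      }
    }
  }

  # flush pending walks for attachments still bound at span end
  for (key in names(walk_rate)) apply_pending_walk(as.integer(key), tend)

  st$net <- net
  invisible(st)
}

# advance one attachment of bound-element row `row` by nsteps walking steps
# toward its filament's plus end, crossing cylinder boundaries and stopping at
# the tip; attribute `steps_applied` records the realized step count
walk_attachment <- function(net, row, side, nsteps, step_nm) {
  fi <- net$bound[[paste0("fil", side)]][row]
  ci <- net$bound[[paste0("cyl", side)]][row]
  fr <- net$bound[[paste0("frac", side)]][row]
  f <- net$filaments[[fi]]
  toward_last <- f$plus_end == "last"
  ncyl <- nrow(f$beads) - 1
  applied <- 0L
  for (s in seq_len(nsteps)) {
    cl <- sqrt(sum((f$beads[ci + 1, ] - f$beads[ci, ])^2))
    dfr <- step_nm / cl
    fr2 <- fr + if (toward_last) dfr else -dfr
    if (fr2 > 1) {
      if (ci < ncyl) {
        ci <- ci + 1L
        fr2 <- fr2 - 1
      } else break # a full step would overrun the plus tip: stall
    } else if (fr2 < 0) {
      if (ci > 1) {
        ci <- ci - 1L
        fr2 <- fr2 + 1
      } else break
    }
    fr <- fr2
    applied <- applied + 1L
  }
  net$bound[[paste0("cyl", side)]][row] <- ci
  net$bound[[paste0("frac", side)]][row] <- fr
  attr(net, "steps_applied") <- applied
  net
}

#' Extract an observable time series from a trajectory
#'
#' @param traj an \code{abm_trajectory}
#' @param observable \code{"radius_of_gyration"} or
#'   \code{"mean_filament_length"}
#' @return data frame with \code{time} and \code{value}
#' @export
trajectory_series <- function(traj,
                              observable = c("radius_of_gyration",
                                             "mean_filament_length")) {
  observable <- match.arg(observable)
  fn <- switch(observable, radius_of_gyration = radius_of_gyration,
               mean_filament_length = mean_filament_length)
  data.frame(time = vapply(traj$snapshots, `[[`, numeric(1), "time"),
             value = vapply(traj$snapshots, function(s) fn(s$net), numeric(1)))
}

#' @export
print.abm_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d snapshots over %.0f s (%s, %d filaments, seed %d)\n",
              length(x$snapshots), x$config$duration, x$config$polarity,
              x$config$n_filaments, x$seed))
  cat("  events:", paste(names(x$events), x$events, sep = "=", collapse = " "), "\n")
  if (length(x$flags)) cat(sprintf("  %d convergence flags\n", length(x$flags)))
  invisible(x)
}

#' Run a grid of conditions
#'
#' Runs one trajectory per (alpha:A, M:A[, chi], replicate) combination,
#' writing each to a snapshot archive file under \code{out_dir} and returning
#' a manifest. Failures in individual conditions are recorded and the grid
#' continues. The paper-scale grids are 42 mole-ratio pairs x 8 replicates
#' (non-treadmilling) and 84 triads x 7 replicates (treadmilling); a reduced
#' smoke grid is a config choice away.
#'
#' @param grid_spec list with \code{alpha_ratios}, \code{motor_ratios},
#'   optional \code{chis} (NULL for non-treadmilling), \code{replicates},
#'   \code{base_seed} and \code{config} (named overrides passed to
#'   [simulation_config()])
#' @param out_dir archive directory (created)
#' @return manifest data frame (also written as \code{manifest.tsv}) with one
#'   row per (condition, replicate): ratios, chi, seed, file, status
#' @export
run_condition_grid <- function(grid_spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chis <- grid_spec$chis %||% NA_real_
  grid <- expand.grid(alpha = grid_spec$alpha_ratios,
                      motor = grid_spec$motor_ratios,
                      chi = chis,
                      rep = seq_len(grid_spec$replicates %||% 1))
  base_seed <- grid_spec$base_seed %||% 1L
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    seed <- (base_seed + 7919L * (g - 1L)) %% .Machine$integer.max
    over <- grid_spec$config %||% list()
    over$alpha_ratio <- grid$alpha[g]
    over$motor_ratio <- grid$motor[g]
    over$seed <- seed
    if (!is.na(grid$chi[g])) {
      over$chi <- grid$chi[g]
      over$treadmilling <- TRUE
    } else {
      over$treadmilling <- FALSE
    }
    cfg <- do.call(simulation_config, over)
    fname <- sprintf("traj_a%s_m%s_chi%s_r%d.snap",
                     format(grid$alpha[g]), format(grid$motor[g]),
                     ifelse(is.na(grid$chi[g]), "NT", format(grid$chi[g])),
                     grid$rep[g])
    path <- file.path(out_dir, fname)
    status <- tryCatch({
      traj <- evolve_bundle(cfg)
      write_trajectory(traj, path)
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    rows[[g]] <- data.frame(alpha_ratio = grid$alpha[g],
                            motor_ratio = grid$motor[g],
                            chi = grid$chi[g], replicate = grid$rep[g],
                            seed = seed, file = fname, status = status)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
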