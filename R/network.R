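#' Construct a filament
#'
#' A filament is an ordered chain of 3D beads (hinges) whose consecutive pairs
#' form cylinders. Each cylinder carries the number of actin monomers it
#' contains; its equilibrium length is \code{monomers * 2.7} nm so that
#' polymerization changes the rest length smoothly. One chain terminus is the
#' fast-growing plus (barbed) end.
#'
#' @param beads numeric matrix (n x 3) of bead coordinates in nm, n >= 2
#' @param monomers integer vector of per-cylinder monomer counts (length n-1);
#'   default fills each cylinder from its current length
#' @param plus_end \code{"last"} or \code{"first"}: which terminus is the plus end
#' @return an object of class \code{abm_filament}
#' @export
filament <- function(beads, monomers = NULL, plus_end = "last") {
  beads <- as.matrix(beads)
  if (ncol(beads) != 3 || nrow(beads) < 2)
    stop("beads must be an n x 3 matrix with n >= 2")
  seg <- beads[-1, , drop = FALSE] - beads[-nrow(beads), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  if (any(len <= 0)) stop("degenerate cylinder (zero length)")
  if (is.null(monomers)) monomers <- pmax(1L, as.integer(round(len / MONOMER_NM)))
  if (length(monomers) != nrow(beads) - 1)
    stop("monomers must have one entry per cylinder")
  if (any(monomers < 1)) stop("each cylinder must hold at least one monomer")
  plus_end <- match.arg(plus_end, c("last", "first"))
  structure(list(beads = beads, monomers = as.integer(monomers),
                 plus_end = plus_end),
            class = "abm_filament")
}

#' @rdname filament
#' @param x an \code{abm_filament}
#' @param which \code{"plus"} or \code{"minus"}
#' @return \code{filament_end()}: the 3D coordinate of the requested terminus
#' @export
filament_end <- function(x, which = c("plus", "minus")) {
  which <- match.arg(which)
  last <- (x$plus_end == "last") == (which == "plus")
  if (last) x$beads[nrow(x$beads), ] else x$beads[1, ]
}

#' Assemble a network mechanical state
#'
#' Bundles filaments, bound crosslinkers/motors and the axis-aligned reaction
#' box into one state object. Bound elements reference filaments and cylinders
#' by index with a fractional position along the cylinder.
#'
#' @param filaments list of [filament()] objects
#' @param bound data frame of bound elements with columns \code{species}
#'   ("alpha" or "motor"), \code{fil1}, \code{cyl1}, \code{frac1}, \code{fil2},
#'   \code{cyl2}, \code{frac2}, \code{n_heads} (NA for alpha-actinin),
#'   \code{rest_length}, \code{k}; \code{NULL} for none
#' @param box numeric length-6 extents \code{c(xmin, xmax, ymin, ymax, zmin, zmax)} in nm
#' @param free named numeric totals of freely diffusing species
#'   (\code{gactin}, \code{alpha}, \code{motor})
#' @param validate check invariants (beads inside box, resolvable attachments)
#' @return an object of class \code{abm_network}
#' @export
network_state <- function(filaments, bound = NULL, box = NULL,
                          free = c(gactin = 0, alpha = 0, motor = 0),
                          validate = TRUE) {
  stopifnot(is.list(filaments), length(filaments) >= 1)
  if (is.null(bound)) bound <- empty_bound()
  if (is.null(box)) {
    all_b <- do.call(rbind, lapply(filaments, `[[`, "beads"))
    pad <- 500
    box <- as.numeric(rbind(apply(all_b, 2, min) - pad, apply(all_b, 2, max) + pad))
  }
  net <- structure(list(filaments = filaments, bound = bound, box = box,
                        free = free),
                   class = "abm_network")
  if (validate) validate_network(net)
  net
}

empty_bound <- function() {
  data.frame(species = character(0), fil1 = integer(0), cyl1 = integer(0),
             frac1 = numeric(0), fil2 = integer(0), cyl2 = integer(0),
             frac2 = numeric(0), n_heads = numeric(0),
             rest_length = numeric(0), k = numeric(0))
}

#' @rdname network_state
#' @param net an \code{abm_network}
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "abm_network"))
  box <- net$box
  for (f in net$filaments) {
    b <- f$beads
    if (any(b[, 1] < box[1] - 1e-6 | b[, 1] > box[2] + 1e-6 |
            b[, 2] < box[3] - 1e-6 | b[, 2] > box[4] + 1e-6 |
            b[, 3] < box[5] - 1e-6 | b[, 3] > box[6] + 1e-6))
      stop("bead outside box")
  }
  bd <- net$bound
  if (nrow(bd)) {
    nf <- length(net$filaments)
    for (r in seq_len(nrow(bd))) {
      for (side in 1:2) {
        fi <- bd[[paste0("fil", side)]][r]
        ci <- bd[[paste0("cyl", side)]][r]
        fr <- bd[[paste0("frac", side)]][r]
        if (fi < 1 || fi > nf) stop("dangling attachment: bad filament id")
        ncyl <- nrow(net$filaments[[fi]]$beads) - 1
        if (ci < 1 || ci > ncyl) stop("dangling attachment: bad cylinder id")
        if (fr < 0 || fr > 1) stop("fractional position outside [0, 1]")
      }
      if (bd$fil1[r] == bd$fil2[r])
        stop("bound element must connect two distinct filaments")
    }
  }
  invisible(net)
}

# Flatten a network into the arrays the C++ kernels consume.
net_flat <- function(net, params) {
  nb <- vapply(net$filaments, function(f) nrow(f$beads), integer(1))
  fil_first0 <- cumsum(c(0L, nb[-length(nb)]))
  beads <- do.call(rbind, lapply(net$filaments, `[[`, "beads"))
  l0 <- unlist(lapply(net$filaments, function(f) f$monomers * MONOMER_NM),
               use.names = FALSE)
  bd <- net$bound
  if (nrow(bd)) {
    b0a <- fil_first0[bd$fil1] + bd$cyl1 - 1L
    b0b <- fil_first0[bd$fil2] + bd$cyl2 - 1L
    springs <- cbind(b0a, b0a + 1L, bd$frac1, b0b, b0b + 1L, bd$frac2,
                     bd$k, bd$rest_length)
  } else {
    springs <- matrix(0, 0, 8)
  }
  list(beads = beads, fil_first0 = as.integer(fil_first0),
       fil_nbeads = as.integer(nb), l0 = as.numeric(l0),
       springs = unname(as.matrix(springs)))
}

# Rebuild filament bead matrices from a flat bead matrix.
net_unflat <- function(net, beads) {
  nb <- vapply(net$filaments, function(f) nrow(f$beads), integer(1))
  off <- cumsum(c(0L, nb[-length(nb)]))
  for (i in seq_along(net$filaments)) {
    net$filaments[[i]]$beads <-
      beads[(off[i] + 1):(off[i] + nb[i]), , drop = FALSE]
  }
  net
}

# 3D coordinate of a (filament, cylinder, fraction) attachment
attachment_point <- function(net, fil, cyl, frac) {
  b <- net$filaments[[fil]]$beads
  b[cyl, ] * (1 - frac) + b[cyl + 1, ] * frac
}

#' @export
print.abm_network <- function(x, ...) {
  nb <- sum(vapply(x$filaments, function(f) nrow(f$beads), integer(1)))
  cat(sprintf("Actin network: %d filaments (%d beads), %d bound elements\n",
              length(x$filaments), nb, nrow(x$bound)))
  cat(sprintf("  box [%.0f, %.0f] x [%.0f, %.0f] x [%.0f, %.0f] nm\n",
              x$box[1], x$box[2], x$box[3], x$box[4], x$box[5], x$box[6]))
  cat(sprintf("  free species: G-actin %g, alpha-actinin %g, minifilament %g\n",
              x$free[["gactin"]], x$free[["alpha"]], x$free[["motor"]]))
  invisible(x)
}

# end coordinates of every filament: list(plus = matrix, minus = matrix)
network_ends <- function(net) {
  plus <- t(vapply(net$filaments, filament_end, numeric(3), which = "plus"))
  minus <- t(vapply(net$filaments, filament_end, numeric(3), which = "minus"))
  list(plus = plus, minus = minus)
}

# candidate binding sites: quarter, mid and three-quarter point of every
# cylinder; returns coordinates, filament id, cylinder id and fraction
binding_sites <- function(net, fractions = c(0.25, 0.5, 0.75)) {
  out <- vector("list", length(net$filaments))
  for (fi in seq_along(net$filaments)) {
    b <- net$filaments[[fi]]$beads
    ncyl <- nrow(b) - 1
    p0 <- b[seq_len(ncyl), , drop = FALSE]
    p1 <- b[seq_len(ncyl) + 1, , drop = FALSE]
    per <- lapply(fractions, function(fr) {
      cbind(p0 * (1 - fr) + p1 * fr, fi, seq_len(ncyl), fr)
    })
    out[[fi]] <- do.call(rbind, per)
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("x", "y", "z", "fil", "cyl", "frac")
  m
}
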