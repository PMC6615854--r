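# Morphology classification: end-distance distributions, Jensen-Shannon
# dissimilarity, complete-linkage clustering into bundle-like / aster-like /
# intermediate states, catastrophe detection and order parameters.

#' Filament end-distance distributions
#'
#' Pools, over one or more snapshots, the Euclidean distances between filament
#' ends across distinct filaments: plus-plus (Dis++), minus-minus (Dis--) and
#' plus-minus (Dis+-, both ordered cross-polarity pairs of each unordered
#' filament pair). The three histograms share bin edges and are normalized to
#' sum to one.
#'
#' @param snapshots a single \code{abm_network}, or a list of networks /
#'   snapshot records (anything with \code{$net})
#' @param breaks bin edges in nm (default 50 nm bins over [0, box diagonal]);
#'   distances beyond the last edge are clamped into the last bin
#' @param condition id string recorded on the result
#' @return an object of class \code{abm_enddist}: list of three normalized
#'   histograms (\code{pp}, \code{mm}, \code{pm}), \code{breaks},
#'   \code{condition}, \code{n_snapshots} and an \code{empty} flag
#' @export
end_distance_distributions <- function(snapshots, breaks = NULL,
                                       condition = "") {
  nets <- as_network_list(snapshots)
  if (is.null(breaks)) {
    box <- nets[[1]]$box
    diag <- sqrt(sum((box[c(2, 4, 6)] - box[c(1, 3, 5)])^2))
    breaks <- seq(0, ceiling(diag / 50) * 50, by = 50)
  }
  pp <- mm <- pm <- numeric(0)
  for (net in nets) {
    e <- network_ends(net)
    n <- nrow(e$plus)
    if (n < 2) next
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pp <- c(pp, sqrt(rowSums((e$plus[ut[, 1], , drop = FALSE] -
                                e$plus[ut[, 2], , drop = FALSE])^2)))
    mm <- c(mm, sqrt(rowSums((e$minus[ut[, 1], , drop = FALSE] -
                                e$minus[ut[, 2], , drop = FALSE])^2)))
    od <- rbind(ut, ut[, 2:1, drop = FALSE]) # both ordered pairs, once each
    pm <- c(pm, sqrt(rowSums((e$plus[od[, 1], , drop = FALSE] -
                                e$minus[od[, 2], , drop = FALSE])^2)))
  }
  hist1 <- function(x) {
    if (!length(x)) return(rep(NA_real_, length(breaks) - 1))
    x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)] - 1e-9)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
    h / sum(h)
  }
  out <- structure(list(pp = hist1(pp), mm = hist1(mm), pm = hist1(pm),
                        breaks = breaks, condition = condition,
                        n_snapshots = length(nets),
                        empty = !length(pp)),
                   class = "abm_enddist")
  out
}

as_network_list <- function(snapshots) {
  if (inherits(snapshots, "abm_network")) return(list(snapshots))
  lapply(snapshots, function(s) {
    if (inherits(s, "abm_network")) s
    else if (!is.null(s$net)) s$net
    else stop("cannot interpret snapshot entry as a network")
  })
}

#' Jensen-Shannon divergence (base 2)
#'
#' Mean of the two Kullback-Leibler divergences to the midpoint mixture, in
#' bits (range [0, 1]); \code{0 log 0 = 0}. Symmetric, zero iff P = Q, one for
#' disjoint supports.
#'
#' @param P,Q equal-length normalized histograms
#' @return JSD in bits
#' @export
jensen_shannon_divergence <- function(P, Q) {
  if (length(P) != length(Q)) stop("mismatched bins: P and Q differ in length")
  if (anyNA(P) || anyNA(Q)) stop("empty (NA) histogram")
  sp <- sum(P); sq <- sum(Q)
  if (sp <= 0 || sq <= 0) stop("histogram sums to zero")
  P <- P / sp; Q <- Q / sq
  M <- (P + Q) / 2
  kl <- function(A) {
    nz <- A > 0
    sum(A[nz] * log2(A[nz] / M[nz]))
  }
  (kl(P) + kl(Q)) / 2
}

#' Condition dissimilarity matrix
#'
#' Entry (i, j) is the unweighted mean of the three Jensen-Shannon divergences
#' between the conditions' Dis++, Dis-- and Dis+- histograms (shared bins).
#' Conditions with an empty distribution are excluded with a message.
#'
#' @param dists list of [end_distance_distributions()] results
#' @return symmetric matrix with zero diagonal, dimnames = condition ids,
#'   class \code{abm_dissim}
#' @export
build_dissimilarity_matrix <- function(dists) {
  ok <- !vapply(dists, `[[`, logical(1), "empty")
  if (any(!ok))
    message(sum(!ok), " condition(s) excluded: empty end-distance distribution")
  dists <- dists[ok]
  n <- length(dists)
  if (n < 2) stop("need at least two non-empty conditions")
  ids <- vapply(seq_len(n), function(i) {
    id <- dists[[i]]$condition
    if (nzchar(id)) id else as.character(i)
  }, character(1))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!isTRUE(all.equal(dists[[i]]$breaks, dists[[j]]$breaks)))
        stop("conditions use different bin edges")
      v <- mean(c(jensen_shannon_divergence(dists[[i]]$pp, dists[[j]]$pp),
                  jensen_shannon_divergence(dists[[i]]$mm, dists[[j]]$mm),
                  jensen_shannon_divergence(dists[[i]]$pm, dists[[j]]$pm)))
      D[i, j] <- D[j, i] <- v
    }
  }
  class(D) <- c("abm_dissim", class(D))
  D
}

#' Complete-linkage agglomerative clustering
#'
#' Merges the closest pair of clusters under the maximum-linkage rule until
#' one cluster remains; merge heights are monotone non-decreasing. Ties are
#' broken deterministically by the lowest pair of cluster indices. The result
#' is \code{hclust}-compatible (works with [stats::cutree()] and
#' [ape::as.phylo()]).
#'
#' @param D symmetric dissimilarity matrix (zero diagonal)
#' @return an object of class \code{c("abm_tree", "hclust")}
#' @export
complete_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least two leaves")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12, check.attributes = FALSE)))
    stop("dissimilarity matrix must be symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters keyed by hclust convention: -i singleton, +k merge k
  key <- -seq_len(n)
  active <- rep(TRUE, n)
  work <- D
  diag(work) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(seq_len(n)) # leaf sets per active slot
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    hmin <- min(sub)
    cand <- which(sub == hmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    a <- idx[cand[1, 1]]
    b <- idx[cand[1, 2]]
    pair <- sort(c(key[a], key[b]))
    merge[step, ] <- pair
    height[step] <- hmin
    # complete linkage update into slot a
    for (o in idx) {
      if (o == a || o == b) next
      work[a, o] <- work[o, a] <- max(work[a, o], work[b, o])
    }
    members[[a]] <- c(members[[a]], members[[b]])
    key[a] <- step
    active[b] <- FALSE
  }
  order_leaves <- tree_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order_leaves,
                 labels = labels, method = "complete",
                 call = match.call(), dist.method = "jsd"),
            class = c("abm_tree", "hclust"))
}

tree_leaf_order <- function(merge) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' Export a cluster tree as Newick
#'
#' @param tree an \code{abm_tree}
#' @param path output file
#' @return the path, invisibly
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Morphology order parameters of a network
#'
#' Computes, from one snapshot: the nematic order parameter S (largest
#' eigenvalue of the length-weighted cylinder orientation Q-tensor
#' \code{3/2 <uu> - 1/2 I}); the radius of gyration over all beads; the
#' asphericity of the gyration tensor (0 for a sphere, 1 for a rod),
#' normalized by its trace; the polarity-sorting score (mean minus-end
#' centroid distance minus mean plus-end centroid distance, over Rg; positive
#' when plus ends are central, as in an aster); crosslink connectivity
#' (largest-component fraction and mean linker degree 2E/N); and a radial
#' bead-density profile about the centroid.
#'
#' @param net an \code{abm_network}
#' @param radial_bins number of radial profile bins
#' @return an object of class \code{abm_features} (a named list)
#' @export
morphology_features <- function(net, radial_bins = 20) {
  beads <- do.call(rbind, lapply(net$filaments, `[[`, "beads"))
  ctr <- colMeans(beads)
  cen <- beads - matrix(ctr, nrow(beads), 3, byrow = TRUE)

  # nematic order: length-weighted Q-tensor over cylinders
  Q <- matrix(0, 3, 3)
  wtot <- 0
  for (f in net$filaments) {
    seg <- f$beads[-1, , drop = FALSE] - f$beads[-nrow(f$beads), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    u <- seg / len
    for (s in seq_len(nrow(u))) {
      Q <- Q + len[s] * (1.5 * tcrossprod(u[s, ]) - 0.5 * diag(3))
      wtot <- wtot + len[s]
    }
  }
  S <- max(eigen(Q / wtot, symmetric = TRUE)$values)

  rg2 <- mean(rowSums(cen^2))
  gyr <- crossprod(cen) / nrow(cen)
  lam <- sort(eigen(gyr, symmetric = TRUE)$values, decreasing = TRUE)
  asph <- (lam[1] - 0.5 * (lam[2] + lam[3])) / sum(lam)

  e <- network_ends(net)
  dplus <- sqrt(rowSums((e$plus - matrix(ctr, nrow(e$plus), 3, byrow = TRUE))^2))
  dminus <- sqrt(rowSums((e$minus - matrix(ctr, nrow(e$minus), 3, byrow = TRUE))^2))
  rg <- sqrt(rg2)
  sorting <- if (rg > 0) (mean(dminus) - mean(dplus)) / rg else 0

  nf <- length(net$filaments)
  bd <- net$bound
  if (nrow(bd)) {
    g <- igraph::graph_from_edgelist(cbind(bd$fil1, bd$fil2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nf - igraph::vcount(g)))
    comp <- igraph::components(g)
    largest <- max(comp$csize) / nf
    mean_degree <- 2 * nrow(bd) / nf
  } else {
    largest <- 1 / nf
    mean_degree <- 0
  }

  r <- sqrt(rowSums(cen^2))
  rb <- seq(0, max(r) + 1e-9, length.out = radial_bins + 1)
  radial <- graphics::hist(r, breaks = rb, plot = FALSE)$counts / length(r)

  structure(list(S = S, Rg = rg, asphericity = asph,
                 polarity_sorting = sorting,
                 largest_component = largest, mean_degree = mean_degree,
                 radial_profile = radial, radial_breaks = rb),
            class = "abm_features")
}

#' @export
print.abm_features <- function(x, ...) {
  cat(sprintf("S = %.3f, Rg = %.0f nm, asphericity = %.3f, sorting = %.3f\n",
              x$S, x$Rg, x$asphericity, x$polarity_sorting))
  cat(sprintf("largest component %.2f, mean linker degree %.2f\n",
              x$largest_component, x$mean_degree))
  invisible(x)
}

#' Catastrophe detection
#'
#' Builds the filament connectivity graph (one edge per bound crosslinker or
#' minifilament) and labels the network a Type A catastrophe if the largest
#' connected component holds fewer than \code{f_A} of the filaments
#' (fragmented), else a Type B catastrophe if the mean linker degree
#' \code{2E/N} falls below \code{d_B} (connected but poorly crosslinked), else
#' no catastrophe.
#'
#' @param net an \code{abm_network}
#' @param f_A largest-component fraction threshold (default 0.6)
#' @param d_B mean-degree threshold (default 1.5)
#' @return \code{"catastrophe_A"}, \code{"catastrophe_B"} or \code{NA}
#' @export
detect_catastrophe <- function(net, f_A = 0.6, d_B = 1.5) {
  ft <- morphology_features(net, radial_bins = 2)
  if (ft$largest_component < f_A) return("catastrophe_A")
  if (ft$mean_degree < d_B) return("catastrophe_B")
  NA_character_
}

#' Cut a cluster tree into labeled morphology classes
#'
#' Cuts the tree into \code{k} clusters (falling back to \code{k - 1} with a
#' warning if a requested cluster would be degenerate) and assigns semantic
#' labels from each cluster medoid's order parameters: bundle-like (BL) for
#' high nematic order (S >= 0.6); aster-like (AL) for positive polarity
#' sorting (> 0.2) with a near-spherical shape (asphericity < 0.1);
#' aster-bundle intermediate (ABI) otherwise.
#'
#' @param tree an [complete_linkage()] result
#' @param features data frame of per-condition features (rows in tree leaf
#'   label order) with columns \code{S}, \code{asphericity},
#'   \code{polarity_sorting}
#' @param D the dissimilarity matrix used to build the tree (for medoids);
#'   NULL picks the feature-space centroid-nearest condition instead
#' @param k number of clusters (default 3)
#' @return character vector of labels, named by condition id, with attribute
#'   \code{clusters} (the cut assignments)
#' @export
cut_and_label <- function(tree, features, D = NULL, k = 3) {
  n <- length(tree$labels)
  k <- min(k, n)
  cl <- stats::cutree(tree, k = k)
  if (length(unique(cl)) < k) {
    warning("degenerate cut; falling back to k = ", k - 1)
    k <- k - 1
    cl <- stats::cutree(tree, k = k)
  }
  labs <- character(n)
  for (c_id in sort(unique(cl))) {
    members <- which(cl == c_id)
    med <- if (!is.null(D) && length(members) > 1) {
      sub <- as.matrix(D)[members, members, drop = FALSE]
      members[which.min(rowSums(sub))]
    } else members[1]
    f <- features[med, ]
    lab <- if (f$S >= 0.6) "BL"
    else if (f$polarity_sorting > 0.2 && f$asphericity < 0.1) "AL"
    else "ABI"
    labs[members] <- lab
  }
  names(labs) <- tree$labels
  attr(labs, "clusters") <- cl
  labs
}

#' Axial distribution of a bound species
#'
#' Projects the midpoints of bound elements of one species onto the network's
#' first principal axis and histograms them (normalized to one). This is the
#' diagnostic that reveals sarcomere-like banding of minifilaments near
#' minus-end overlaps.
#'
#' @param net an \code{abm_network}
#' @param species \code{"motor"} or \code{"alpha"}
#' @param nbins number of bins along the axis
#' @return normalized histogram with attributes \code{breaks} (axial
#'   coordinates, nm) and \code{empty}
#' @export
axial_species_distribution <- function(net, species = c("motor", "alpha"),
                                       nbins = 20) {
  species <- match.arg(species)
  bd <- net$bound[net$bound$species == species, , drop = FALSE]
  beads <- do.call(rbind, lapply(net$filaments, `[[`, "beads"))
  axis1 <- stats::prcomp(beads, center = TRUE)$rotation[, 1]
  ctr <- colMeans(beads)
  if (!nrow(bd)) {
    out <- rep(NA_real_, nbins)
    attr(out, "empty") <- TRUE
    return(out)
  }
  proj <- vapply(seq_len(nrow(bd)), function(r) {
    mid <- (attachment_point(net, bd$fil1[r], bd$cyl1[r], bd$frac1[r]) +
              attachment_point(net, bd$fil2[r], bd$cyl2[r], bd$frac2[r])) / 2
    sum((mid - ctr) * axis1)
  }, numeric(1))
  span <- range(vapply(seq_len(nrow(beads)), function(i)
    sum((beads[i, ] - ctr) * axis1), numeric(1)))
  breaks <- seq(span[1] - 1e-9, span[2] + 1e-9, length.out = nbins + 1)
  proj <- pmin(pmax(proj, breaks[1]), breaks[nbins + 1])
  h <- graphics::hist(proj, breaks = breaks, plot = FALSE)$counts
  out <- h / sum(h)
  attr(out, "breaks") <- breaks
  attr(out, "empty") <- FALSE
  out
}

#' Count available crosslinker binding-site pairs
#'
#' Number of unbound site pairs within the alpha-actinin 30-40 nm band
#' (delegates to [eligible_binding_pairs()]); tracking this over time shows
#' how myosin-driven widening of inter-filament distances depletes the
#' network of crosslinker binding sites.
#'
#' @param net an \code{abm_network}
#' @param params [chemistry_params()]
#' @return integer count
#' @export
available_crosslink_sites <- function(net, params = chemistry_params()) {
  nrow(eligible_binding_pairs(net, "alpha", params, exclude_occupied = TRUE))
}

#' End-to-end morphology labeling of a set of networks
#'
#' The full classification pipeline applied to independent networks (each
#' treated as one condition): catastrophe detection first (catastrophe labels
#' preempt the morphology classes), then end-distance distributions on shared
#' bins, the Jensen-Shannon dissimilarity matrix, complete-linkage clustering
#' cut into three clusters, and medoid-feature labeling into BL / AL / ABI.
#'
#' @param nets list of \code{abm_network} objects (or snapshot records)
#' @param f_A,d_B catastrophe thresholds, see [detect_catastrophe()]
#' @param breaks shared histogram bin edges (default: 50 nm bins to the
#'   largest box diagonal)
#' @return data frame with columns \code{id}, \code{label}, \code{S},
#'   \code{Rg}, \code{asphericity}, \code{polarity_sorting},
#'   \code{largest_component}, \code{mean_degree}
#' @export
classify_networks <- function(nets, f_A = 0.6, d_B = 1.5, breaks = NULL) {
  nets <- as_network_list(nets)
  n <- length(nets)
  feats <- lapply(nets, morphology_features)
  cat_lab <- vapply(nets, detect_catastrophe, character(1), f_A = f_A, d_B = d_B)
  labels <- cat_lab
  rest <- which(is.na(cat_lab))
  if (length(rest) >= 3) {
    if (is.null(breaks)) {
      diag <- max(vapply(nets[rest], function(net) {
        sqrt(sum((net$box[c(2, 4, 6)] - net$box[c(1, 3, 5)])^2))
      }, numeric(1)))
      breaks <- seq(0, ceiling(diag / 50) * 50, by = 50)
    }
    dists <- lapply(rest, function(i) {
      end_distance_distributions(nets[[i]], breaks = breaks,
                                 condition = as.character(i))
    })
    D <- build_dissimilarity_matrix(dists)
    tree <- complete_linkage(D)
    fsub <- do.call(rbind, lapply(feats[rest], function(f) {
      data.frame(S = f$S, asphericity = f$asphericity,
                 polarity_sorting = f$polarity_sorting)
    }))
    labels[rest] <- cut_and_label(tree, fsub, D = D, k = 3)
  } else if (length(rest)) {
    labels[rest] <- vapply(rest, function(i) {
      f <- feats[[i]]
      if (f$S >= 0.6) "BL"
      else if (f$polarity_sorting > 0.2 && f$asphericity < 0.1) "AL"
      else "ABI"
    }, character(1))
  }
  data.frame(id = seq_len(n), label = labels,
             S = vapply(feats, `[[`, numeric(1), "S"),
             Rg = vapply(feats, `[[`, numeric(1), "Rg"),
             asphericity = vapply(feats, `[[`, numeric(1), "asphericity"),
             polarity_sorting = vapply(feats, `[[`, numeric(1), "polarity_sorting"),
             largest_component = vapply(feats, `[[`, numeric(1), "largest_component"),
             mean_degree = vapply(feats, `[[`, numeric(1), "mean_degree"))
}
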