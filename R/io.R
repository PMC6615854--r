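# Plain-text snapshot/trajectory serialization and configuration I/O.
#
# There is no established trajectory standard for cytoskeletal bead-spring
# networks, so a versioned, human-diffable block format is used; a strict
# round-trip test guards it. Unknown future header fields are preserved
# opaquely.

SNAP_FORMAT_VERSION <- 1L

# FNV-1a 32-bit hash of a string (no digest package in the frozen stack).
# All arithmetic is kept inside the exactly-representable double range by
# splitting words into 16-bit halves (R's bitwXor only takes 32-bit signed
# integers, and 32x24-bit products overflow 2^53).
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    lo <- bitwXor(h %% 65536, b %% 65536)
    # (hi*2^16 + lo) * p mod 2^32, in pieces
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash a configuration
#'
#' Stable 32-bit FNV-1a hash of the canonical JSON serialization of a config;
#' embedded in every output artifact so results are reproducible from their
#' headers.
#' @param config an \code{abm_config} (or any list)
#' @return 8-character hex string
#' @export
config_hash <- function(config) {
  fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         force = TRUE))
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write and read network snapshots
#'
#' Serializes a network state (plus metadata) as a versioned plain-text block
#' format: a header (format version, time, seed, config hash), one block per
#' filament (plus-end flag, per-bead coordinates, per-cylinder monomer
#' counts), a bound-element table, box extents and free-species totals.
#' \code{read_snapshot()} reproduces all fields bit-exactly and rejects
#' malformed input with a diagnostic naming the offending block.
#'
#' @param net an [network_state()] object
#' @param path file path
#' @param time snapshot time, s
#' @param seed RNG seed to record
#' @param confighash config hash to record (see [config_hash()])
#' @param extra named character vector of extra header fields
#' @param append append to an existing archive file
#' @return \code{write_snapshot()}: the path, invisibly
#' @export
write_snapshot <- function(net, path, time = 0, seed = NA_integer_,
                           confighash = "", extra = NULL, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("#SNAPSHOT v", SNAP_FORMAT_VERSION)
  wl("time ", fmt_num(time))
  wl("seed ", ifelse(is.na(seed), "NA", as.integer(seed)))
  wl("confighash ", confighash)
  if (!is.null(extra)) for (nm in names(extra)) wl(nm, " ", extra[[nm]])
  wl("box ", paste(fmt_num(net$box), collapse = " "))
  wl("free ", paste(names(net$free), fmt_num(net$free), collapse = " "))
  wl("nfilaments ", length(net$filaments))
  for (i in seq_along(net$filaments)) {
    f <- net$filaments[[i]]
    wl("filament ", i, " nbeads ", nrow(f$beads), " plus_end ", f$plus_end)
    for (b in seq_len(nrow(f$beads)))
      wl("  bead ", paste(fmt_num(f$beads[b, ]), collapse = " "))
    wl("  monomers ", paste(f$monomers, collapse = " "))
  }
  bd <- net$bound
  wl("nbound ", nrow(bd))
  for (r in seq_len(nrow(bd))) {
    wl("  bound ", bd$species[r], " ",
       paste(bd$fil1[r], bd$cyl1[r], fmt_num(bd$frac1[r]),
             bd$fil2[r], bd$cyl2[r], fmt_num(bd$frac2[r]),
             ifelse(is.na(bd$n_heads[r]), "NA", bd$n_heads[r]),
             fmt_num(bd$rest_length[r]), fmt_num(bd$k[r])))
  }
  wl("#END")
  invisible(path)
}

parse_snapshot_block <- function(lines, start) {
  i <- start
  need <- function(cond, what) {
    if (is.na(cond) || !cond)
      stop(sprintf("snapshot parse error at line %d: %s", i, what))
  }
  getline <- function(i) {
    if (i > length(lines))
      stop(sprintf("snapshot parse error at line %d: truncated file", i))
    strsplit(trimws(lines[i]), "\\s+")[[1]]
  }
  need(grepl("^#SNAPSHOT v", lines[i]), "missing #SNAPSHOT header")
  ver <- as.integer(sub("^#SNAPSHOT v", "", lines[i]))
  if (ver != SNAP_FORMAT_VERSION)
    stop(sprintf("snapshot format version %d, this reader supports %d",
                 ver, SNAP_FORMAT_VERSION))
  i <- i + 1
  hdr <- list()
  extra <- character(0)
  repeat {
    need(i <= length(lines), "truncated header")
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] == "nfilaments") break
    key <- tok[1]
    if (key %in% c("time", "seed", "confighash", "box", "free")) {
      hdr[[key]] <- tok[-1]
    } else {
      extra[key] <- paste(tok[-1], collapse = " ")
    }
    i <- i + 1
  }
  nfil <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]][2])
  i <- i + 1
  fils <- vector("list", nfil)
  for (fidx in seq_len(nfil)) {
    need(i <= length(lines) && grepl("^filament ", trimws(lines[i])),
         sprintf("expected filament block %d", fidx))
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nb <- as.integer(tok[4])
    plus_end <- tok[6]
    i <- i + 1
    beads <- matrix(0, nb, 3)
    for (b in seq_len(nb)) {
      tok <- getline(i)
      need(tok[1] == "bead", sprintf("expected bead line in filament %d", fidx))
      beads[b, ] <- as.numeric(tok[2:4])
      i <- i + 1
    }
    tok <- getline(i)
    need(tok[1] == "monomers", sprintf("expected monomers line in filament %d", fidx))
    mono <- as.integer(tok[-1])
    i <- i + 1
    fils[[fidx]] <- filament(beads, monomers = mono, plus_end = plus_end)
  }
  tok <- getline(i)
  need(tok[1] == "nbound", "expected nbound line")
  nbd <- as.integer(tok[2])
  i <- i + 1
  bd <- empty_bound()
  if (nbd > 0) {
    rows <- vector("list", nbd)
    for (r in seq_len(nbd)) {
      tok <- getline(i)
      need(tok[1] == "bound", sprintf("expected bound element %d", r))
      rows[[r]] <- data.frame(
        species = tok[2], fil1 = as.integer(tok[3]), cyl1 = as.integer(tok[4]),
        frac1 = as.numeric(tok[5]), fil2 = as.integer(tok[6]),
        cyl2 = as.integer(tok[7]), frac2 = as.numeric(tok[8]),
        n_heads = suppressWarnings(as.numeric(tok[9])),
        rest_length = as.numeric(tok[10]), k = as.numeric(tok[11]))
      i <- i + 1
    }
    bd <- do.call(rbind, rows)
  }
  need(i <= length(lines) && trimws(lines[i]) == "#END", "missing #END marker")
  free_tok <- hdr$free
  free <- setNames(as.numeric(free_tok[seq(2, length(free_tok), 2)]),
                   free_tok[seq(1, length(free_tok), 2)])
  net <- network_state(fils, bound = bd, box = as.numeric(hdr$box),
                       free = free, validate = FALSE)
  list(net = net, time = as.numeric(hdr$time),
       seed = suppressWarnings(as.integer(hdr$seed)),
       confighash = if (length(hdr$confighash)) hdr$confighash else "",
       extra = extra, next_line = i + 1)
}

#' @rdname write_snapshot
#' @return \code{read_snapshot()}: a list with \code{net}, \code{time},
#'   \code{seed}, \code{confighash} and \code{extra} (opaque unknown header
#'   fields)
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  rec <- parse_snapshot_block(lines, 1)
  rec$next_line <- NULL
  rec
}

#' Write and read a whole trajectory archive
#'
#' Concatenated snapshot blocks in time order, one file per trajectory.
#' @param traj an \code{abm_trajectory}
#' @param path archive path
#' @export
write_trajectory <- function(traj, path) {
  ch <- config_hash(traj$config)
  first <- TRUE
  for (s in traj$snapshots) {
    write_snapshot(s$net, path, time = s$time, seed = traj$seed,
                   confighash = ch, append = !first)
    first <- FALSE
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @return \code{read_trajectory()}: list of snapshot records in time order
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1
      next
    }
    rec <- parse_snapshot_block(lines, i)
    i <- rec$next_line
    rec$next_line <- NULL
    out[[length(out) + 1]] <- rec
  }
  times <- vapply(out, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("archive snapshots out of time order")
  out
}

#' Load a simulation configuration from JSON
#'
#' Reads the documented key-value schema, validates every field against the
#' model invariants (positive mole ratios, chi > 0 unless non-treadmilling,
#' feasible geometry), applies defaults for absent keys, and reports all
#' violations at once. Nested \code{mech} and \code{chem} blocks override
#' [mechanical_params()] / [chemistry_params()] defaults.
#'
#' @param path JSON file
#' @return an \code{abm_config}
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c(names(formals(simulation_config)), "comment")
  errs <- character(0)
  bad <- setdiff(names(raw), known)
  if (length(bad)) errs <- c(errs, paste("unknown key(s):", paste(bad, collapse = ", ")))
  num_pos <- c("n_filaments", "bundle_length", "lattice_spacing", "actin_uM",
               "alpha_ratio", "motor_ratio", "duration", "snapshot_interval",
               "dt_chem")
  for (k in intersect(num_pos, names(raw))) {
    if (!is.numeric(raw[[k]]) || any(raw[[k]] <= 0))
      errs <- c(errs, sprintf("%s must be numeric > 0", k))
  }
  if (!is.null(raw$polarity) && !raw$polarity %in% c("unipolar", "apolar"))
    errs <- c(errs, "polarity must be 'unipolar' or 'apolar'")
  tread <- raw$treadmilling %||% TRUE
  if (!is.null(raw$chi)) {
    if (raw$chi < 0) errs <- c(errs, "chi must be >= 0")
    if (raw$chi == 0 && tread)
      errs <- c(errs, "chi = 0 requires treadmilling = false (non-treadmilling flag)")
  }
  if (length(errs))
    stop(paste0("invalid configuration (", path, "):\n  ",
                paste(errs, collapse = "\n  ")))
  raw$comment <- NULL
  if (!is.null(raw$mech)) raw$mech <- do.call(mechanical_params, as.list(raw$mech))
  if (!is.null(raw$chem)) raw$chem <- do.call(chemistry_params, as.list(raw$chem))
  if (!is.null(raw$chi) && raw$chi == 0) raw$chi <- 1 # rates zeroed by the flag
  do.call(simulation_config, raw)
}

#' Expand the mole-ratio grids of a study configuration
#'
#' Convenience for grid configs: returns the condition table for vectors of
#' mole ratios (and optionally chi values), e.g. the 7 x 6 = 42 mole-ratio
#' grid of the reference non-treadmilling study.
#' @param alpha_ratios,motor_ratios,chis condition vectors (chis NULL for
#'   non-treadmilling)
#' @return data frame of conditions
#' @export
condition_grid <- function(alpha_ratios, motor_ratios, chis = NULL) {
  if (is.null(chis)) {
    expand.grid(alpha_ratio = alpha_ratios, motor_ratio = motor_ratios)
  } else {
    expand.grid(alpha_ratio = alpha_ratios, motor_ratio = motor_ratios,
                chi = chis)
  }
}
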