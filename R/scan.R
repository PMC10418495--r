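#' Default critical-energy grid
#'
#' 0.250e-22 to 0.600e-22 N m in steps of 0.050e-22: from the energy where
#' every occupancy is positive up to the energy where every occupancy
#' vanishes for the modelled gene.
#'
#' @return Strictly increasing numeric vector of 8 energies (N m).
#' @export
default_energy_grid <- function() {
  seq(250, 600, by = 50) * 1e-25
}

#' Format an energy as its grid label
#'
#' Energies are carried in file outputs as exact decimal strings on the
#' conventional 1e-22 N m scale (e.g. \code{"0.250"}) to avoid float-keyed
#' joins.
#'
#' @param energy Energy in N m.
#' @return Character label.
#' @export
energy_label <- function(energy) {
  sprintf("%.3f", energy / 1e-22)
}

validate_grid <- function(grid) {
  stopifnot(is.numeric(grid), length(grid) >= 1L, all(grid > 0))
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("energy grid must be strictly increasing")
  grid
}

run_one <- function(duplex, base_mech, forcing, integ, energy, position, kD,
                    mode, delta_gates_both) {
  iso <- if (position == 0L) isotope_spec() else isotope_spec(position, kD)
  mech <- build_pair_mechanics(duplex, base_mech, iso = iso, Ecr = energy)
  traj <- simulate(mech, forcing, integ, mode = mode,
                   delta_gates_both = delta_gates_both, record_mask = FALSE)
  occupancy_probability(traj)
}

profile_rows <- function(energy, position, p) {
  data.frame(energy = energy_label(energy), group = names(p),
             position = position, P = unname(p), stringsAsFactors = FALSE)
}

#' All-protium baseline occupancy profile
#'
#' One deterministic simulation per grid energy with no substitution;
#' returns the occupancy probability P0 of every size group.
#'
#' @param duplex A \code{\link{gene_duplex}}.
#' @param base_mech A \code{\link{base_mechanics}}.
#' @param forcing,integ Forcing and integration specifications.
#' @param grid Critical-energy grid (N m); each value is applied uniformly
#'   as the critical energy of both pair kinds for that run.
#' @param mode,delta_gates_both Passed to \code{\link{simulate}}.
#' @return Data frame (\code{energy}, \code{group}, \code{position} = 0,
#'   \code{P}).
#' @export
baseline_profile <- function(duplex, base_mech = default_base_mechanics(),
                             forcing = forcing_spec(), integ = integration_spec(),
                             grid = default_energy_grid(),
                             mode = "conservative", delta_gates_both = NULL) {
  grid <- validate_grid(grid)
  out <- lapply(grid, function(e)
    profile_rows(e, 0L, run_one(duplex, base_mech, forcing, integ, e, 0L, 1,
                                mode, delta_gates_both)))
  structure(do.call(rbind, out), class = c("bubble_profile", "data.frame"),
            n = duplex$n)
}

#' Per-position single-substitution scan
#'
#' For every grid energy and every position i, runs one simulation with a
#' single deuterium substitution at i (bond constant and critical energy of
#' that pair scaled by \code{kD}) and records the occupancy probability of
#' every size group, alongside the all-protium baseline (position 0). The
#' scan is deterministic and embarrassingly parallel over (energy,
#' position); rows are emitted in (energy, position) order regardless of
#' execution order.
#'
#' @inheritParams baseline_profile
#' @param kD Deuterium-to-protium bond strength ratio (default 1.05).
#' @param positions Positions to scan; default all of \code{1..n}.
#' @param checkpoint Optional TSV path: each completed (energy, position)
#'   appends its rows, and an interrupted scan restarted with the same path
#'   resumes where it stopped.
#' @return A \code{bubble_profile} data frame (\code{energy}, \code{group},
#'   \code{position} with 0 = baseline, \code{P}).
#' @export
scan_positions <- function(duplex, base_mech = default_base_mechanics(),
                           forcing = forcing_spec(), integ = integration_spec(),
                           grid = default_energy_grid(), kD = 1.05,
                           positions = seq_len(duplex$n), checkpoint = NULL,
                           mode = "conservative", delta_gates_both = NULL) {
  grid <- validate_grid(grid)
  stopifnot(kD > 0, all(positions >= 1L), all(positions <= duplex$n))
  jobs <- expand.grid(position = c(0L, as.integer(positions)), energy = grid,
                      KEEP.OUT.ATTRS = FALSE)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- tryCatch(
      suppressWarnings(utils::read.delim(checkpoint, colClasses = c(
        energy = "character", group = "character", position = "integer",
        P = "numeric"))),
      error = function(e) stop(sprintf("corrupt checkpoint file: %s", checkpoint)))
    if (!identical(names(done), c("energy", "group", "position", "P")))
      stop(sprintf("corrupt checkpoint file: %s", checkpoint))
  }
  rows <- vector("list", nrow(jobs))
  for (j in seq_len(nrow(jobs))) {
    e <- jobs$energy[j]; pos <- jobs$position[j]
    key <- !is.null(done) & NROW(done) > 0
    if (key) {
      hit <- done[done$energy == energy_label(e) & done$position == pos, , drop = FALSE]
      if (nrow(hit) == length(bubble_size_groups()$group)) {
        rows[[j]] <- hit
        next
      }
    }
    p <- run_one(duplex, base_mech, forcing, integ, e, pos, kD, mode, delta_gates_both)
    rows[[j]] <- profile_rows(e, pos, p)
    if (!is.null(checkpoint)) {
      utils::write.table(rows[[j]], checkpoint, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = !file.exists(checkpoint),
                         append = file.exists(checkpoint))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$energy, energy_label(grid)), out$position,
                   match(out$group, bubble_size_groups()$group)), ]
  rownames(out) <- NULL
  structure(out, class = c("bubble_profile", "data.frame"), n = duplex$n)
}

#' Extremes of the substitution profile
#'
#' The highest and lowest per-position occupancy probability for one
#' (energy, group) cell, with tie-preserving argument sets.
#'
#' @param profile A \code{bubble_profile}.
#' @param energy Energy (N m) or its grid label (e.g. \code{"0.250"}).
#' @param group Size-group code.
#' @return List with \code{Pimax}, \code{Pimin}, \code{argmax},
#'   \code{argmin} (integer position sets), and \code{P0} (baseline, if the
#'   profile carries position-0 rows, else \code{NA}).
#' @export
profile_extrema <- function(profile, energy, group) {
  lab <- if (is.numeric(energy)) energy_label(energy) else energy
  sub <- profile[profile$energy == lab & profile$group == group, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("profile has no rows for energy %s, group %s", lab, group))
  pos <- sub[sub$position > 0L, , drop = FALSE]
  if (nrow(pos) == 0L)
    stop(sprintf("profile has no substitution rows for energy %s, group %s", lab, group))
  p0 <- sub$P[sub$position == 0L]
  list(
    Pimax = max(pos$P),
    Pimin = min(pos$P),
    argmax = sort(pos$position[pos$P == max(pos$P)]),
    argmin = sort(pos$position[pos$P == min(pos$P)]),
    P0 = if (length(p0)) p0[1L] else NA_real_
  )
}
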