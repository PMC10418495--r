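#' "Maximum" range of the extremum classifier
#'
#' Selects the substitution positions whose occupancy probability Pi sits in
#' the top band near Pimax. The band is the tighter of two cuts: the default
#' cut \code{Pimax - (Pimax - Pimin)/10} is used when it still clears the
#' midpoint \code{P0 + (Pimax - P0)/2}; otherwise the band widens to
#' \code{Pimax - (Pimax - P0)/4}. Either way the range only exists when
#' \code{Pimax > P0 >= Pimin >= 0}; ties at the threshold are included
#' (non-strict inequality).
#'
#' @param Pi Numeric vector of per-position probabilities (one energy, one
#'   size group).
#' @param P0 Baseline (all-protium) probability.
#' @param Pimax,Pimin Extremes of \code{Pi}; computed if omitted.
#' @return List: \code{members} (integer positions), \code{threshold}
#'   (\code{NA} when the range is empty by condition), \code{branch}
#'   (\code{"tenth"}, \code{"quarter"} or \code{"none"}), \code{nmax}.
#' @export
bj_max_range <- function(Pi, P0, Pimax = max(Pi), Pimin = min(Pi)) {
  stopifnot(is.numeric(Pi), length(Pi) >= 1L, is.numeric(P0))
  if (!(Pimax > P0 && P0 >= Pimin && Pimin >= 0)) {
    return(list(members = integer(0), threshold = NA_real_, branch = "none",
                nmax = 0L))
  }
  thr10 <- Pimax - (Pimax - Pimin) / 10
  if (thr10 >= P0 + (Pimax - P0) / 2) {
    thr <- thr10; branch <- "tenth"
  } else {
    thr <- Pimax - (Pimax - P0) / 4; branch <- "quarter"
  }
  members <- which(Pi >= thr)
  list(members = members, threshold = thr, branch = branch,
       nmax = length(members))
}

#' "Minimum" range of the extremum classifier
#'
#' Mirror image of \code{\link{bj_max_range}} around Pimin, with one extra
#' rule for the degenerate floor: when \code{Pimin = 0} the members are the
#' closed-state positions (Pi = 0) and the reported count is corrected
#' downward to \code{nCS * (1 - (nCS/ng)^2)} (differentiated counting: when
#' every position is closed the range carries no information and the
#' effective count vanishes). The alternative reading
#' \code{nCS * (1 - nCS/ng)^2} of that correction is available via
#' \code{correction}.
#'
#' @inheritParams bj_max_range
#' @param ng Total pair count of the whole gene (defaults to
#'   \code{length(Pi)}, i.e. Pi spans the gene).
#' @param correction Closed-state correction variant:
#'   \code{"one_minus_ratio_sq"} (default) computes
#'   \code{nCS*(1 - (nCS/ng)^2)}; \code{"one_minus_ratio_all_sq"} computes
#'   \code{nCS*(1 - nCS/ng)^2}.
#' @return List: \code{members}, \code{threshold}, \code{branch}
#'   (\code{"tenth"}, \code{"quarter"}, \code{"closed"} or \code{"none"}),
#'   \code{nmin} (raw member count), \code{effective_nmin} (real number;
#'   equals \code{nmin} outside the closed branch), \code{closed}
#'   (positions with Pi = 0), \code{all_closed}.
#' @export
bj_min_range <- function(Pi, P0, Pimax = max(Pi), Pimin = min(Pi),
                         ng = length(Pi),
                         correction = c("one_minus_ratio_sq", "one_minus_ratio_all_sq")) {
  stopifnot(is.numeric(Pi), length(Pi) >= 1L, is.numeric(P0), ng >= length(Pi))
  correction <- match.arg(correction)
  closed <- which(Pi == 0)
  all_closed <- length(closed) == length(Pi)
  if (Pimin > 0 && Pimax != Pimin) {
    thr10 <- Pimin + (Pimax - Pimin) / 10
    if (thr10 <= P0 - (P0 - Pimin) / 2) {
      thr <- thr10; branch <- "tenth"
    } else {
      thr <- Pimin + (P0 - Pimin) / 4; branch <- "quarter"
    }
    members <- which(Pi <= thr)
    return(list(members = members, threshold = thr, branch = branch,
                nmin = length(members), effective_nmin = length(members),
                closed = closed, all_closed = all_closed))
  }
  if (Pimin == 0) {
    ncs <- length(closed)
    ratio <- ncs / ng
    eff <- if (correction == "one_minus_ratio_sq") ncs * (1 - ratio^2)
           else ncs * (1 - ratio)^2
    return(list(members = closed, threshold = 0, branch = "closed",
                nmin = ncs, effective_nmin = eff, closed = closed,
                all_closed = all_closed))
  }
  # Pimax == Pimin > 0: flat positive profile, no minimum range
  list(members = integer(0), threshold = NA_real_, branch = "none",
       nmin = 0L, effective_nmin = 0, closed = closed, all_closed = all_closed)
}

#' Closed-state census per region
#'
#' Counts, per region, the substitution positions whose occupancy
#' probability equals 0 for the given (energy, group) cell, and flags the
#' all-closed case (the "-" rows of the summary tables).
#'
#' @param profile A \code{bubble_profile}.
#' @param energy Energy (N m) or grid label.
#' @param group Size-group code.
#' @param partition A \code{\link{region_partition}}.
#' @return List: \code{per_region} (named integer vector), \code{total},
#'   \code{all_closed}.
#' @export
closed_state_census <- function(profile, energy, group, partition) {
  lab <- if (is.numeric(energy)) energy_label(energy) else energy
  sub <- profile[profile$energy == lab & profile$group == group &
                   profile$position > 0L, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("profile has no rows for energy %s, group %s", lab, group))
  sub <- sub[order(sub$position), ]
  n <- nrow(sub)
  if (partition$end[nrow(partition)] != n)
    stop("partition does not cover the scanned positions")
  reg <- factor(character(n), levels = partition$name)
  for (r in seq_len(nrow(partition)))
    reg[partition$start[r]:partition$end[r]] <- partition$name[r]
  closed <- sub$P == 0
  per_region <- vapply(split(closed, reg), function(x) as.integer(sum(x)), integer(1L))
  list(per_region = per_region, total = sum(closed), all_closed = all(closed))
}

#' Classify every (energy, group) cell of a scan profile
#'
#' Applies \code{\link{bj_max_range}} and \code{\link{bj_min_range}} to
#' every energy and size group of a substitution-scan profile.
#'
#' @param profile A \code{bubble_profile} containing baseline (position 0)
#'   and substitution rows.
#' @param correction Passed to \code{\link{bj_min_range}}.
#' @return Object of class \code{bj_result}: a list with one record per
#'   (energy, group) holding the extrema, both ranges, and the closed set.
#' @export
bj_classify <- function(profile, correction = "one_minus_ratio_sq") {
  energies <- unique(profile$energy)
  groups <- bubble_size_groups()$group
  records <- list()
  for (e in energies) {
    for (g in groups) {
      sub <- profile[profile$energy == e & profile$group == g, , drop = FALSE]
      if (nrow(sub) == 0L) next
      pos <- sub[sub$position > 0L, , drop = FALSE]
      pos <- pos[order(pos$position), ]
      p0 <- sub$P[sub$position == 0L]
      if (length(p0) != 1L)
        stop(sprintf("profile is missing the baseline row for energy %s, group %s", e, g))
      Pi <- pos$P
      mx <- bj_max_range(Pi, p0)
      mn <- bj_min_range(Pi, p0, correction = correction)
      records[[paste(e, g, sep = "|")]] <- list(
        energy = e, group = g, P0 = p0,
        Pimax = max(Pi), Pimin = min(Pi),
        positions = pos$position,
        max = mx, min = mn
      )
    }
  }
  structure(list(records = records, energies = energies,
                 n = max(profile$position)),
            class = "bj_result")
}

#' Tabulate range membership per region
#'
#' Converts a classification into the long cell table behind the summary
#' tables: one row per (range, energy, region, group) with the member count
#' and the A-T member count. All-closed cells (every position has Pi = 0)
#' get \code{all_closed = TRUE} and NA counts, mirroring the "-" convention.
#' The closed-state corrected minimum count is reported in a separate
#' per-gene column (\code{effective_nmin}), never mixed into the raw cells.
#'
#' @param result A \code{bj_result}.
#' @param duplex The scanned \code{\link{gene_duplex}}.
#' @param partition A \code{\link{region_partition}}.
#' @return List with \code{cells} (data frame: \code{table} in
#'   \code{"Maximum"}/\code{"Minimum"}, \code{energy}, \code{region},
#'   \code{group}, \code{n}, \code{at}, \code{all_closed}) and
#'   \code{effective} (data frame per energy x group: raw \code{nmin},
#'   \code{effective_nmin}).
#' @export
summarize_ranges <- function(result, duplex, partition) {
  stopifnot(inherits(result, "bj_result"), inherits(duplex, "gene_duplex"))
  reg <- partition_regions(duplex, partition)
  at <- is_at_pair(duplex)
  cells <- list()
  eff <- list()
  for (rec in result$records) {
    all_closed <- length(rec$min$closed) == length(rec$positions)
    for (side in c("Maximum", "Minimum")) {
      members <- if (side == "Maximum") rec$max$members else rec$min$members
      members <- rec$positions[members]
      for (r in partition$name) {
        inreg <- members[reg[members] == r]
        cells[[length(cells) + 1L]] <- data.frame(
          table = side, energy = rec$energy, region = r, group = rec$group,
          n = if (all_closed) NA_integer_ else length(inreg),
          at = if (all_closed) NA_integer_ else sum(at[inreg]),
          all_closed = all_closed, stringsAsFactors = FALSE)
      }
    }
    eff[[length(eff) + 1L]] <- data.frame(
      energy = rec$energy, group = rec$group, nmin = rec$min$nmin,
      effective_nmin = rec$min$effective_nmin,
      min_branch = rec$min$branch, stringsAsFactors = FALSE)
  }
  list(cells = do.call(rbind, cells), effective = do.call(rbind, eff))
}

#' Aggregate range cells into an A-T percentage
#'
#' Sums member counts and A-T counts over any selection of regions, groups
#' and energies of a cell table (either from \code{\link{summarize_ranges}}
#' or a packaged printed table) and reports the A-T percentage, rounded
#' half-away-from-zero to one decimal as in the summary tables. All-closed
#' cells contribute nothing.
#'
#' @param cells Cell data frame with columns \code{energy}, \code{region},
#'   \code{group}, \code{n}, \code{at} (and optionally \code{all_closed}).
#' @param regions,groups,energies Optional filters (character vectors).
#' @return List: \code{n}, \code{at}, \code{at_pct} (rounded to one
#'   decimal), \code{at_pct_raw}.
#' @export
aggregate_range_cells <- function(cells, regions = NULL, groups = NULL,
                                  energies = NULL) {
  sel <- cells
  if (!is.null(regions)) sel <- sel[sel$region %in% regions, , drop = FALSE]
  if (!is.null(groups)) sel <- sel[sel$group %in% groups, , drop = FALSE]
  if (!is.null(energies)) sel <- sel[sel$energy %in% energies, , drop = FALSE]
  sel <- sel[!is.na(sel$n), , drop = FALSE]
  n <- sum(sel$n); at <- sum(sel$at)
  pct <- if (n > 0) 100 * at / n else NA_real_
  list(n = n, at = at, at_pct = round_half_up(pct, 1L), at_pct_raw = pct)
}
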