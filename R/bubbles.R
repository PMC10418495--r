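#' Bubble size groups
#'
#' The size classification used throughout: an open state (OS) is a single
#' broken pair; bubbles are maximal runs of 2 or more broken pairs, split
#' into small (2-4 bp), metastable (5-10 bp), large (11-30 bp), and very
#' large (31+ bp) groups. The ranges are disjoint, ordered, and jointly
#' cover every possible run length.
#'
#' @return Data frame with columns \code{group} (\code{OS}, \code{g1} ..
#'   \code{g4}), \code{min}, \code{max} (inclusive; \code{Inf} for g4), and
#'   \code{label}.
#' @export
bubble_size_groups <- function() {
  data.frame(
    group = c("OS", "g1", "g2", "g3", "g4"),
    min = c(1, 2, 5, 11, 31),
    max = c(1, 4, 10, 30, Inf),
    label = c("open state (1 bp)", "small (2-4 bp)", "metastable (5-10 bp)",
              "large (11-30 bp)", "very large (31+ bp)"),
    stringsAsFactors = FALSE
  )
}

#' Decompose a broken-bond mask into maximal runs
#'
#' @param mask Logical (or 0/1) vector; \code{TRUE} = broken.
#' @return Data frame with one row per maximal run: \code{start} (1-based)
#'   and \code{length}. Runs touching the sequence ends are ordinary runs
#'   (linear topology, no wrap-around).
#' @examples
#' decompose_runs(c(0, 1, 1, 1, 0, 1, 0, 0, 0, 0))
#' @export
decompose_runs <- function(mask) {
  mask <- as.logical(mask)
  stopifnot(!anyNA(mask))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  keep <- r$values
  data.frame(start = (ends - r$lengths + 1L)[keep], length = r$lengths[keep])
}

#' Occupancy fraction of each size group at one instant
#'
#' The fraction q of all base pairs that sit in broken runs whose length
#' falls in the group's range: q = (sum of lengths of qualifying runs) / n.
#'
#' @param mask Logical vector of length n; \code{TRUE} = broken.
#' @param group Optional group code (\code{"OS"}, \code{"g1"} ..
#'   \code{"g4"}); default returns all five as a named vector.
#' @return Numeric in [0, 1] (or a named length-5 vector).
#' @export
occupancy_fraction <- function(mask, group = NULL) {
  mask <- as.logical(mask)
  n <- length(mask)
  runs <- decompose_runs(mask)
  groups <- bubble_size_groups()
  q <- vapply(seq_len(nrow(groups)), function(g) {
    sel <- runs$length >= groups$min[g] & runs$length <= groups$max[g]
    sum(runs$length[sel]) / n
  }, numeric(1L))
  names(q) <- groups$group
  if (is.null(group)) return(q)
  if (!group %in% groups$group) stop(sprintf("unknown size group '%s'", group))
  q[[group]]
}

#' Bubble-occupancy probability over a trajectory
#'
#' The arithmetic mean over the recorded sample points of the per-instant
#' occupancy fractions: P = (sum_j q_j) / m. Samples start at t = tau; the
#' initial state is not included.
#'
#' @param traj A \code{bond_trajectory} (from \code{\link{simulate}},
#'   \code{\link{threshold_trajectory}} or
#'   \code{\link{generate_mask_series}}).
#' @param group Optional group code; default all five groups.
#' @return Numeric in [0, 1] (or a named length-5 vector).
#' @export
occupancy_probability <- function(traj, group = NULL) {
  stopifnot(inherits(traj, "bond_trajectory"))
  if (is.null(traj$q) || nrow(traj$q) == 0L)
    stop("empty trajectory: no recorded samples to average over")
  p <- colMeans(traj$q)
  if (is.null(group)) return(p)
  if (!group %in% names(p)) stop(sprintf("unknown size group '%s'", group))
  p[[group]]
}

#' Assemble a bond trajectory from a mask matrix
#'
#' @param mask Logical matrix, samples in rows, positions in columns.
#' @param times Optional sample times; defaults to the sample index.
#' @return A \code{bond_trajectory} with per-sample group occupancy
#'   fractions precomputed.
#' @export
as_bond_trajectory <- function(mask, times = seq_len(nrow(mask))) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  q <- t(apply(mask, 1L, occupancy_fraction))
  if (nrow(mask) == 1L) q <- matrix(q, nrow = 1L, dimnames = list(NULL, bubble_size_groups()$group))
  structure(
    list(times = times, q = q, mask = mask, energy = NULL, final_state = NULL,
         n = ncol(mask), m = nrow(mask), record_stride = 1L),
    class = "bond_trajectory"
  )
}
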