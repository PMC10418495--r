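# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a random duplex with prescribed per-region A-T fractions
#'
#' Emulates the composition structure of a real gene: each region gets
#' \code{round(fraction * size)} A-T pairs at random positions (so the
#' realized fraction is within 1/(2 size) of the target), with A vs T and
#' G vs C chosen uniformly. Deterministic given the seed; the caller's RNG
#' state is left untouched.
#'
#' @param n Pair count.
#' @param at_fraction Numeric vector of per-region A-T fraction targets in
#'   [0, 1] (recycled to the region count).
#' @param partition A \code{\link{region_partition}} for \code{n}; default
#'   one region spanning the whole sequence.
#' @param seed Integer seed (mandatory).
#' @return A \code{\link{gene_duplex}}.
#' @export
generate_sequence <- function(n, at_fraction, partition = region_partition(1L, n),
                              seed) {
  stopifnot(!missing(seed), is.numeric(seed))
  n <- as.integer(n)
  if (partition$end[nrow(partition)] != n)
    stop("partition does not cover 1..n")
  at_fraction <- rep_len(at_fraction, nrow(partition))
  if (any(at_fraction < 0 | at_fraction > 1))
    stop("at_fraction targets must lie in [0, 1]")
  with_seed(seed, {
    base1 <- character(n)
    for (r in seq_len(nrow(partition))) {
      idx <- partition$start[r]:partition$end[r]
      size <- length(idx)
      k <- as.integer(round(at_fraction[r] * size))
      at_pos <- if (k > 0) sample(idx, k) else integer(0)
      base1[idx] <- sample(c("G", "C"), size, replace = TRUE)
      if (k > 0) base1[at_pos] <- sample(c("A", "T"), k, replace = TRUE)
    }
    gene_duplex(base1)
  })
}

#' Prescribed bond-state mask series
#'
#' Deterministic mask generators for exercising the bubble statistics
#' without running any dynamics.
#'
#' @param n Positions per sample.
#' @param m Number of samples.
#' @param law One of \code{"constant"} (a fixed mask every sample; default
#'   all intact), \code{"alternating"} (a checkerboard over position and
#'   sample index), \code{"random"} (iid Bernoulli(p), seeded).
#' @param value Logical vector of length n for \code{law = "constant"}.
#' @param p Break probability for \code{law = "random"}.
#' @param seed Seed, mandatory for \code{law = "random"}.
#' @return A \code{bond_trajectory} (see \code{\link{as_bond_trajectory}}).
#' @export
generate_mask_series <- function(n, m, law = c("constant", "alternating", "random"),
                                 value = rep(FALSE, n), p = 0.5, seed = NULL) {
  law <- match.arg(law)
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 1L, m >= 1L)
  mask <- switch(law,
    constant = {
      stopifnot(length(value) == n)
      matrix(as.logical(value), nrow = m, ncol = n, byrow = TRUE)
    },
    alternating = outer(seq_len(m), seq_len(n), function(j, i) (i + j) %% 2L == 0L),
    random = {
      if (is.null(seed)) stop("law = 'random' requires an explicit seed")
      stopifnot(p >= 0, p <= 1)
      with_seed(seed, matrix(stats::runif(m * n) < p, nrow = m, ncol = n))
    }
  )
  as_bond_trajectory(mask)
}

#' Load the packaged summary tables
#'
#' Reads the packaged printed summary tables: the Maximum-range and
#' Minimum-range member counts with A-T tallies per energy x region x size
#' group, and the three-region base composition of the modelled gene. File
#' integrity is verified against the packaged MD5 manifest.
#'
#' @return List: \code{maximum} and \code{minimum} (cell data frames with
#'   columns \code{table}, \code{energy}, \code{region}, \code{group},
#'   \code{n}, \code{at}, \code{all_closed}), \code{composition} (region
#'   sizes and A-T / G-C percentages).
#' @export
load_packaged_tables <- function() {
  dir <- system.file("extdata", package = "dnabubbles", mustWork = TRUE)
  manifest <- utils::read.delim(file.path(dir, "tables_manifest.tsv"),
                                stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    got <- unname(tools::md5sum(f))
    if (!identical(got, manifest$md5[i]))
      stop(sprintf("packaged table checksum mismatch for %s", manifest$file[i]))
  }
  read_cells <- function(file, table) {
    x <- utils::read.delim(file.path(dir, file), stringsAsFactors = FALSE,
                           colClasses = c(energy = "character"))
    x$all_closed <- as.logical(x$all_closed)
    cbind(table = table, x, stringsAsFactors = FALSE)
  }
  list(
    maximum = read_cells("table_maximum_range.tsv", "Maximum"),
    minimum = read_cells("table_minimum_range.tsv", "Minimum"),
    composition = utils::read.delim(file.path(dir, "table_composition.tsv"),
                                    stringsAsFactors = FALSE)
  )
}
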