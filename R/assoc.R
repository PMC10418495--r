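#' Yates-corrected chi-squared test for a 2x2 table
#'
#' Implements the shortcut form
#' \code{N * (|ad - bc| - N/2)^2 / (NA * NB * NS * NF)} with the
#' conventional clamp: when \code{|ad - bc| <= N/2} the continuity
#' correction would overshoot and the statistic is floored at 0. The
#' unclamped (literal) value is also returned for audit. The p-value comes
#' from the chi-squared distribution with 1 degree of freedom.
#'
#' @param a,b,c,d Cell counts (row A: a, b; row B: c, d), or pass a 2x2
#'   matrix as \code{a}.
#' @return List: \code{statistic}, \code{p.value}, \code{dof} (1),
#'   \code{statistic_unclamped}.
#' @export
yates_chi2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    b <- a[1L, 2L]; c <- a[2L, 1L]; d <- a[2L, 2L]; a <- a[1L, 1L]
  }
  cells <- as.numeric(c(a, b, c, d))
  stopifnot(all(cells >= 0), all(is.finite(cells)))
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  NA_ <- a + b; NB <- c + d; NS <- a + c; NF <- b + d
  N <- NA_ + NB
  if (NA_ == 0 || NB == 0 || NS == 0 || NF == 0)
    stop("yates_chi2: a zero margin makes the statistic undefined")
  delta <- abs(a * d - b * c)
  raw <- N * (delta - N / 2)^2 / (NA_ * NB * NS * NF)
  stat <- if (delta <= N / 2) 0 else raw
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       dof = 1L, statistic_unclamped = raw)
}

#' Pearson chi-squared for a 3x2 table with Bonferroni pairwise follow-up
#'
#' Omnibus Pearson statistic on the 3x2 table (2 degrees of freedom), plus
#' the three pairwise 2x2 comparisons (Yates-corrected), each with its
#' p-value multiplied by 3 (capped at 1).
#'
#' @param tab Numeric 3x2 matrix of counts (rows: groups, e.g. gene
#'   regions; columns: in-range vs rest).
#' @return List: \code{statistic}, \code{dof} (2), \code{p.value},
#'   \code{pairwise} (data frame: \code{comparison}, \code{statistic},
#'   \code{p.value}, \code{p.adjusted}).
#' @export
chi2_3x2_bonferroni <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 3L, ncol(tab) == 2L, all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi2_3x2_bonferroni: zero margin")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  pairs <- utils::combn(3L, 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    y <- yates_chi2(tab[i, 1L], tab[i, 2L], tab[j, 1L], tab[j, 2L])
    data.frame(
      comparison = paste(rownames(tab)[i] %||% i, rownames(tab)[j] %||% j, sep = " vs "),
      statistic = y$statistic, p.value = y$p.value,
      p.adjusted = min(1, 3 * y$p.value), stringsAsFactors = FALSE)
  })
  list(statistic = stat, dof = 2L,
       p.value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       pairwise = do.call(rbind, pw))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom (delegated to \code{stats::kruskal.test}). The
#' degenerate all-tied case, where the tie correction is 0/0, returns
#' H = 0, p = 1.
#'
#' @param samples List of k >= 2 non-empty numeric vectors.
#' @return List: \code{statistic} (H), \code{p.value}, \code{dof}.
#' @export
kruskal_wallis <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L,
            all(vapply(samples, length, integer(1L)) >= 1L))
  values <- unlist(samples, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p.value = 1, dof = length(samples) - 1L))
  kt <- stats::kruskal.test(samples)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       dof = unname(kt$parameter))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' asymptotic t approximation (via \code{stats::cor.test}).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: \code{rho}, \code{p.value}.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(rank(x))) == 1L || length(unique(rank(y))) == 1L)
    stop("spearman_rank: zero variance in ranks, correlation undefined")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Build a 2x2 region-comparison table from range cells
#'
#' The recipe used for comparing how many of a region's pairs fall into a
#' range: for each of the two regions, the first column is the summed
#' member count over the selected energies/groups, and the second column is
#' the remainder against either the region's length in pairs
#' (\code{margin = "region_size"}) or the summed counts of the other
#' selection (\code{margin = "range_counts"}, where the columns are the two
#' ranges themselves). Which margins produced any specific published
#' p-value is not asserted; both recipes are provided.
#'
#' @param cells Cell table (see \code{\link{aggregate_range_cells}}).
#' @param regions Character vector of exactly two region names.
#' @param region_sizes Named vector of region pair counts (required for
#'   \code{margin = "region_size"}).
#' @param groups,energies Optional filters.
#' @param margin Margin recipe.
#' @return 2x2 numeric matrix with region row names.
#' @export
range_contingency <- function(cells, regions, region_sizes = NULL,
                              groups = NULL, energies = NULL,
                              margin = c("region_size", "range_counts")) {
  margin <- match.arg(margin)
  stopifnot(length(regions) == 2L)
  counts <- vapply(regions, function(r)
    aggregate_range_cells(cells, regions = r, groups = groups,
                          energies = energies)$n, numeric(1L))
  if (margin == "region_size") {
    if (is.null(region_sizes) || !all(regions %in% names(region_sizes)))
      stop("region_sizes must name every compared region")
    rest <- region_sizes[regions] - counts
  } else {
    tabs <- unique(cells$table)
    if (length(tabs) < 2L)
      stop("range_counts margin needs cells from both ranges (Maximum and Minimum)")
    counts <- vapply(regions, function(r)
      aggregate_range_cells(cells[cells$table == tabs[1L], ], regions = r,
                            groups = groups, energies = energies)$n, numeric(1L))
    rest <- vapply(regions, function(r)
      aggregate_range_cells(cells[cells$table == tabs[2L], ], regions = r,
                            groups = groups, energies = energies)$n, numeric(1L))
  }
  out <- cbind(counts, rest)
  dimnames(out) <- list(regions, NULL)
  out
}
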