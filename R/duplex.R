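DNA_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

#' Construct a base-pair duplex from one strand
#'
#' A duplex holds the explicit strand (chain 1), its Watson-Crick complement
#' (chain 2), and the pair kind at each 1-based position. Only the four
#' unambiguous DNA letters are accepted: this model has no notion of
#' degenerate bases or mismatches.
#'
#' @param sequence Character scalar (e.g. \code{"ATGC"}) or character vector
#'   of single letters; case-insensitive.
#' @return An object of class \code{gene_duplex} with elements \code{base1},
#'   \code{base2} (complement), \code{pair} (one of \code{"AT"}, \code{"TA"},
#'   \code{"GC"}, \code{"CG"}), and \code{n}.
#' @examples
#' d <- gene_duplex("ATGC")
#' d$pair
#' @export
gene_duplex <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence[1L]) != 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  base1 <- toupper(as.character(sequence))
  if (length(base1) == 0L)
    stop("empty sequence: a duplex needs at least 2 base pairs")
  bad <- which(!base1 %in% names(DNA_COMPLEMENT))
  if (length(bad))
    stop(sprintf("invalid base '%s' at position %d: only A/C/G/T are supported",
                 base1[bad[1L]], bad[1L]))
  n <- length(base1)
  if (n < 2L)
    stop("a duplex needs at least 2 base pairs (the chain-end equations need distinct ends)")
  base2 <- unname(DNA_COMPLEMENT[base1])
  structure(
    list(base1 = base1, base2 = base2, pair = paste0(base1, base2), n = n),
    class = "gene_duplex"
  )
}

#' @export
print.gene_duplex <- function(x, ...) {
  cat(sprintf("<gene_duplex> %d base pairs; A-T %.1f%%\n",
              x$n, 100 * mean(x$base1 %in% c("A", "T"))))
  invisible(x)
}

#' Read a duplex from a single-record FASTA
#'
#' @param fasta Path to a FASTA file, or a character scalar containing FASTA
#'   text (starting with \code{">"}).
#' @return A \code{\link{gene_duplex}}.
#' @details The file must contain exactly one record over the unambiguous
#'   alphabet \code{A/C/G/T} (case-insensitive). Ambiguity codes such as
#'   \code{N} are rejected with the offending position named.
#' @export
read_duplex <- function(fasta) {
  stopifnot(is.character(fasta), length(fasta) == 1L)
  path <- fasta
  if (startsWith(trimws(fasta), ">")) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(fasta, path)
  } else if (!file.exists(fasta)) {
    stop(sprintf("FASTA file not found: %s", fasta))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA contains no records")
  if (length(set) > 1L)
    stop(sprintf("FASTA must contain exactly one record, found %d", length(set)))
  gene_duplex(as.character(set[[1L]]))
}

#' Is each pair an A-T pair?
#'
#' @param duplex A \code{\link{gene_duplex}}.
#' @return Logical vector of length \code{n}: \code{TRUE} where the pair is
#'   A-T or T-A, \code{FALSE} for G-C / C-G.
#' @export
is_at_pair <- function(duplex) {
  stopifnot(inherits(duplex, "gene_duplex"))
  duplex$base1 %in% c("A", "T")
}

#' Define a contiguous region partition
#'
#' Regions are 1-based, inclusive on both ends, non-overlapping, and must
#' jointly cover \code{1..n}.
#'
#' @param start,end Integer vectors of region starts and ends (inclusive).
#' @param name Region names; defaults to Roman numerals.
#' @return An object of class \code{region_partition} (a data frame with
#'   columns \code{name}, \code{start}, \code{end}).
#' @export
region_partition <- function(start, end, name = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end), length(start) >= 1L)
  if (is.null(name)) name <- as.character(utils::as.roman(seq_along(start)))
  if (any(end < start)) stop("region end before start")
  if (start[1L] != 1L) stop("partition must start at position 1")
  if (length(start) > 1L && any(start[-1L] != end[-length(end)] + 1L))
    stop("regions must be contiguous (no gaps or overlaps)")
  structure(
    data.frame(name = as.character(name), start = start, end = end,
               stringsAsFactors = FALSE),
    class = c("region_partition", "data.frame")
  )
}

#' Default three-region gene partition
#'
#' Promoter (I) 1-49, coding region (II) 50-619, termination sequence (III)
#' 620-980: the partition used for the interferon alpha-17 gene.
#'
#' @param n Total pair count; must be at least 620 so region III is non-empty.
#' @return A \code{\link{region_partition}} with regions I, II, III.
#' @export
default_region_partition <- function(n = 980L) {
  n <- as.integer(n)
  if (n < 620L) stop("default partition needs n >= 620; supply region_partition() explicitly")
  region_partition(start = c(1L, 50L, 620L), end = c(49L, 619L, n),
                   name = c("I", "II", "III"))
}

#' Map positions to regions
#'
#' @param duplex A \code{\link{gene_duplex}}.
#' @param partition A \code{\link{region_partition}} covering \code{1..n}.
#' @return Factor of length \code{n} with the region name of every position,
#'   levels in partition order.
#' @export
partition_regions <- function(duplex, partition) {
  stopifnot(inherits(duplex, "gene_duplex"), inherits(partition, "region_partition"))
  if (partition$end[nrow(partition)] != duplex$n)
    stop(sprintf("partition covers 1..%d but the duplex has %d pairs",
                 partition$end[nrow(partition)], duplex$n))
  out <- character(duplex$n)
  for (r in seq_len(nrow(partition)))
    out[partition$start[r]:partition$end[r]] <- partition$name[r]
  factor(out, levels = partition$name)
}

#' Per-region base-pair composition
#'
#' @param duplex A \code{\link{gene_duplex}}.
#' @param partition A \code{\link{region_partition}}.
#' @return Data frame with one row per region: \code{region}, \code{n_pairs},
#'   \code{at_count}, \code{gc_count}, \code{at_pct}, \code{gc_pct}
#'   (percentages of the region, unrounded).
#' @export
composition_table <- function(duplex, partition) {
  reg <- partition_regions(duplex, partition)
  at <- is_at_pair(duplex)
  n_pairs <- as.integer(table(reg))
  at_count <- as.integer(tapply(at, reg, sum))
  data.frame(
    region = levels(reg),
    n_pairs = n_pairs,
    at_count = at_count,
    gc_count = n_pairs - at_count,
    at_pct = 100 * at_count / n_pairs,
    gc_pct = 100 * (n_pairs - at_count) / n_pairs,
    stringsAsFactors = FALSE
  )
}

#' Round half away from zero
#'
#' Presentation rounding used for the percentage tables (\code{round()} in R
#' rounds half to even, which is not how the summary tables are printed).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
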