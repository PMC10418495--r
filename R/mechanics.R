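BASES <- c("A", "T", "G", "C")
PAIR_KINDS <- c("AT", "GC")

#' Per-base mechanical parameter set
#'
#' Collects the per-letter and per-pair-kind mechanical coefficients of the
#' torsional model: rotational inertia \code{I} (kg m^2), the distance
#' \code{R} from each base's centre of inertia to the sugar-phosphate
#' backbone (m), the backbone torsional constant \code{K} (N m), the
#' environmental dissipation coefficient \code{beta} (N m s), the hydrogen
#' bond elastic constant \code{k12} per pair kind (N/m), and the critical
#' (break) energy \code{Ecr} per pair kind (N m). A-T and T-A pairs share
#' \code{k12}/\code{Ecr}, likewise G-C and C-G: the bond strength belongs
#' to the pair kind, not to the strand orientation.
#'
#' @param inertia,radius,torsion,dissipation Named numeric vectors over
#'   \code{A,T,G,C}; \code{torsion} may be a single unnamed value (uniform).
#' @param bond,ecr Named numeric vectors over \code{AT,GC}.
#' @return Object of class \code{base_mechanics}.
#' @seealso \code{\link{default_base_mechanics}}
#' @export
base_mechanics <- function(inertia, radius, torsion, dissipation, bond, ecr) {
  need <- function(x, keys, what) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, length(keys)), keys)
    miss <- setdiff(keys, names(x))
    if (length(miss))
      stop(sprintf("base_mechanics: missing %s entry for '%s'", what, miss[1L]))
    x <- x[keys]
    if (any(!is.finite(x)) || any(x <= 0))
      stop(sprintf("base_mechanics: %s entries must be strictly positive", what))
    x
  }
  structure(
    list(
      inertia = need(inertia, BASES, "inertia"),
      radius = need(radius, BASES, "radius"),
      torsion = need(torsion, BASES, "torsion"),
      dissipation = need(dissipation, BASES, "dissipation"),
      bond = need(bond, PAIR_KINDS, "bond"),
      ecr = need(ecr, PAIR_KINDS, "ecr")
    ),
    class = "base_mechanics"
  )
}

#' Default mechanical parameter table
#'
#' Reads the packaged default coefficients
#' (\code{inst/extdata/base_mechanics_default.tsv}): representative values
#' used in the torsional pendulum-chain model literature for DNA. They are a
#' documented, overridable default, not measurements; substitute your own
#' table via \code{\link{base_mechanics}} or \code{\link{read_base_mechanics}}
#' for quantitative work on a specific gene.
#'
#' @return A \code{\link{base_mechanics}}.
#' @export
default_base_mechanics <- function() {
  path <- system.file("extdata", "base_mechanics_default.tsv",
                      package = "dnabubbles", mustWork = TRUE)
  read_base_mechanics(path)
}

#' Read a mechanical parameter table from a key-value TSV
#'
#' Keys follow \code{inertia.A}, \code{radius.A}, \code{torsion.K} (uniform)
#' or \code{torsion.A}.., \code{dissipation.A}.., \code{bond.AT},
#' \code{bond.GC}, \code{ecr.AT}, \code{ecr.GC}. A \code{kD} key, if present,
#' is ignored here (it belongs to the isotope specification).
#'
#' @param path TSV file with columns \code{key} and \code{value}.
#' @return A \code{\link{base_mechanics}}.
#' @export
read_base_mechanics <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(tab)))
    stop("parameter table needs 'key' and 'value' columns")
  kv <- setNames(as.numeric(tab$value), tab$key)
  base_mechanics_from_keys(kv)
}

base_mechanics_from_keys <- function(kv) {
  pick <- function(prefix, keys) {
    out <- kv[paste0(prefix, ".", keys)]
    names(out) <- keys
    out[!is.na(out)]
  }
  torsion <- pick("torsion", BASES)
  if (length(torsion) == 0L && !is.na(kv["torsion.K"]))
    torsion <- unname(kv["torsion.K"])
  base_mechanics(
    inertia = pick("inertia", BASES),
    radius = pick("radius", BASES),
    torsion = torsion,
    dissipation = pick("dissipation", BASES),
    bond = pick("bond", PAIR_KINDS),
    ecr = pick("ecr", PAIR_KINDS)
  )
}

#' Single-substitution isotope specification
#'
#' Marks at most one pair as carrying a deuterium (2H) hydrogen bond. The
#' substitution strengthens that pair's bond: its elastic constant and its
#' critical energy are both multiplied by \code{kD}. Inertia and dissipation
#' are not altered (the mass effect of one 2H on a whole base is negligible
#' at this level of description).
#'
#' @param position 1-based substituted position, or \code{NULL} for the
#'   all-protium baseline.
#' @param kD Deuterium-to-protium bond strength ratio (default 1.05: the
#'   deuterium bond is 5\% stronger).
#' @return Object of class \code{isotope_spec}.
#' @export
isotope_spec <- function(position = NULL, kD = 1.05) {
  if (!is.null(position)) {
    position <- as.integer(position)
    stopifnot(length(position) == 1L, position >= 1L)
  }
  stopifnot(is.numeric(kD), length(kD) == 1L, kD > 0)
  structure(list(position = position, kD = kD), class = "isotope_spec")
}

#' Expand per-base parameters to per-pair arrays
#'
#' Builds the length-\code{n} coefficient arrays the integrator consumes.
#' Chain 1 holds the input strand's base at each position, chain 2 its
#' complement. When an isotope substitution is present, exactly two entries
#' change relative to the baseline: \code{k12[i]} and \code{Ecr[i]} are
#' multiplied by \code{kD} at the substituted position.
#'
#' @param duplex A \code{\link{gene_duplex}}.
#' @param base_mech A \code{\link{base_mechanics}}.
#' @param iso An \code{\link{isotope_spec}} (default: no substitution).
#' @param Ecr Optional uniform critical energy (N m) overriding both pair
#'   kinds' \code{ecr} entries; this is how a scanned energy-grid value is
#'   applied.
#' @return Object of class \code{pair_mechanics}: numeric arrays
#'   \code{I1, I2, R1, R2, K1, K2, beta1, beta2, k12, Ecr} of length
#'   \code{n}, plus \code{n} and \code{substituted}.
#' @export
build_pair_mechanics <- function(duplex, base_mech = default_base_mechanics(),
                                 iso = isotope_spec(), Ecr = NULL) {
  stopifnot(inherits(duplex, "gene_duplex"), inherits(base_mech, "base_mechanics"),
            inherits(iso, "isotope_spec"))
  kind <- ifelse(duplex$base1 %in% c("A", "T"), "AT", "GC")
  k12 <- unname(base_mech$bond[kind])
  ecr <- if (is.null(Ecr)) unname(base_mech$ecr[kind]) else {
    stopifnot(is.numeric(Ecr), length(Ecr) == 1L, Ecr > 0)
    rep(Ecr, duplex$n)
  }
  if (!is.null(iso$position)) {
    if (iso$position > duplex$n)
      stop(sprintf("substituted position %d exceeds n = %d", iso$position, duplex$n))
    k12[iso$position] <- iso$kD * k12[iso$position]
    ecr[iso$position] <- iso$kD * ecr[iso$position]
  }
  structure(
    list(
      I1 = unname(base_mech$inertia[duplex$base1]),
      I2 = unname(base_mech$inertia[duplex$base2]),
      R1 = unname(base_mech$radius[duplex$base1]),
      R2 = unname(base_mech$radius[duplex$base2]),
      K1 = unname(base_mech$torsion[duplex$base1]),
      K2 = unname(base_mech$torsion[duplex$base2]),
      beta1 = unname(base_mech$dissipation[duplex$base1]),
      beta2 = unname(base_mech$dissipation[duplex$base2]),
      k12 = k12,
      Ecr = ecr,
      n = duplex$n,
      substituted = iso$position
    ),
    class = "pair_mechanics"
  )
}
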