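# Independent brute-force oracles. These deliberately re-derive each quantity
# with the most naive algorithm available so they share no code with the
# package implementation.

# maximal broken runs by explicit position scan
runs_brute <- function(mask) {
  mask <- as.logical(mask)
  starts <- integer(0); lens <- integer(0)
  i <- 1L
  while (i <= length(mask)) {
    if (mask[i]) {
      j <- i
      while (j < length(mask) && mask[j + 1L]) j <- j + 1L
      starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, length = lens)
}

# group occupancy by per-length enumeration
occupancy_brute <- function(mask, lo, hi) {
  r <- runs_brute(mask)
  tot <- 0L
  for (k in seq_len(nrow(r)))
    if (r$length[k] >= lo && r$length[k] <= hi) tot <- tot + r$length[k]
  tot / length(mask)
}

group_bounds <- function() {
  list(OS = c(1, 1), g1 = c(2, 4), g2 = c(5, 10), g3 = c(11, 30), g4 = c(31, Inf))
}

# extremum-range membership by scanning every position with the branch
# inequalities written out directly
bj_members_brute <- function(Pi, P0, side) {
  Pimax <- max(Pi); Pimin <- min(Pi)
  members <- integer(0)
  if (side == "max") {
    if (!(Pimax > P0 && P0 >= Pimin && Pimin >= 0)) return(members)
    t10 <- Pimax - 1 / 10 * (Pimax - Pimin)
    use10 <- t10 >= P0 + 1 / 2 * (Pimax - P0)
    for (i in seq_along(Pi)) {
      ok <- if (use10) Pi[i] >= t10 else Pi[i] >= Pimax - 1 / 4 * (Pimax - P0)
      if (ok) members <- c(members, i)
    }
  } else {
    if (!(Pimin > 0 && Pimax != Pimin)) {
      if (Pimin == 0) for (i in seq_along(Pi)) if (Pi[i] == 0) members <- c(members, i)
      return(members)
    }
    t10 <- Pimin + 1 / 10 * (Pimax - Pimin)
    use10 <- t10 <= P0 - 1 / 2 * (P0 - Pimin)
    for (i in seq_along(Pi)) {
      ok <- if (use10) Pi[i] <= t10 else Pi[i] <= Pimin + 1 / 4 * (P0 - Pimin)
      if (ok) members <- c(members, i)
    }
  }
  members
}

# tie-corrected Kruskal-Wallis H from the textbook rank formula
kw_brute <- function(samples) {
  x <- unlist(samples)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(samples)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# small deterministic duplex + mechanics for dynamics tests
toy_mechanics <- function(seq = "ATGCAT", Ecr = 0.250e-22, position = NULL,
                          kD = 1.05) {
  d <- gene_duplex(seq)
  iso <- if (is.null(position)) isotope_spec() else isotope_spec(position, kD)
  build_pair_mechanics(d, default_base_mechanics(), iso = iso, Ecr = Ecr)
}

# forcing strong enough to break bonds on short chains (the default-scale
# drive barely deflects a 6-mer); used only to exercise the threshold rule
toy_forcing <- function(F0 = 1e-20) forcing_spec(F0 = F0)
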