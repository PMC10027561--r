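# Independent oracles used to freeze expected values.

# Natural isotope abundances, restated independently of the package
# constants (same IUPAC sources).
.ORACLE_AB <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205)
)

# Brute-force isotope envelope: exhaustive enumeration of isotope
# placements by integer mass shift (13C, 2H, 15N, 17O count 1; 18O
# counts 2), probabilities from binomial/multinomial mass functions.
oracleIsotopeEnvelope <- function(f, n = 5L) {
  cnt <- function(el) if (el %in% names(f)) f[[el]] else 0L
  C <- cnt("C"); H <- cnt("H"); N <- cnt("N"); O <- cnt("O")
  out <- numeric(n)
  for (c13 in 0:min(C, n - 1)) for (h2 in 0:min(H, n - 1))
    for (n15 in 0:min(N, n - 1)) for (o17 in 0:min(O, n - 1))
      for (o18 in 0:min(O, (n - 1) %/% 2)) {
        s <- c13 + h2 + n15 + o17 + 2 * o18
        if (s > n - 1 || o17 + o18 > O) next
        p <- stats::dbinom(c13, C, .ORACLE_AB$C[2]) *
          stats::dbinom(h2, H, .ORACLE_AB$H[2]) *
          stats::dbinom(n15, N, .ORACLE_AB$N[2]) *
          stats::dmultinom(c(O - o17 - o18, o17, o18), prob = .ORACLE_AB$O)
        out[s + 1] <- out[s + 1] + p
      }
  out / out[1]
}

# Closed-form Welch t test with Satterthwaite degrees of freedom.
oracleWelch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Minimal target list over arbitrary expected m/z values (for matcher
# edge cases that need controlled spacings).
toyTargets <- function(names, mz) {
  tab <- scLipidFlow:::.parseSpeciesTable(names)
  tab$expected_mz <- mz
  tab$is_internal_standard <- rep(FALSE, nrow(tab))
  tab$is_class <- rep(NA_character_, nrow(tab))
  tab$out_of_range <- mz < 640 | mz > 850
  methods::new("TargetList", entries = tab)
}
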