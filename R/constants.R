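# Physical constants: monoisotopic masses and natural isotope abundances
# (IUPAC/CODATA values, vendored so results are bit-stable across platforms).

.MONO_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)

.NOMINAL_MASS <- c(C = 12L, H = 1L, N = 14L, O = 16L, P = 31L)

.PROTON_MASS   <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990946

# Mass difference between 13C and 12C; isotopologue peaks of CHNOP lipids are
# spaced by almost exactly this amount because carbon dominates the envelope.
.C13_SHIFT <- 1.0033548378

# Per-element isotopologue abundance by integer mass shift (index 1 = +0).
# Rows normalised to sum to 1; phosphorus is monoisotopic.
.ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  P = 1.0
)

# Elemental composition of the protonated phosphocholine head-group fragment,
# the reporter ion selected by the precursor ion scan.
.PHOSPHOCHOLINE_FRAGMENT <- c(C = 5L, H = 15L, N = 1L, O = 4L, P = 1L)
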