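#' Parse a sum-composition lipid name
#'
#' Accepts the field's shorthand: `"PC 34:1"` (diacyl), `"PC O-38:5"`
#' (ether-linked), `"SM 34:1"` (sphingoid), and defined-acyl internal
#' standard names such as `"PC 17:0/17:0"`, which collapse to the summed
#' composition (here PC 34:0) while retaining the defined-acyl display
#' name.
#'
#' @param name a single species name.
#' @return a [LipidSpecies-class] object.
#' @examples
#' parseSpeciesName("PC 34:1")
#' parseSpeciesName("PC O-38:5")
#' parseSpeciesName("PC 17:0/17:0")
#' @export
parseSpeciesName <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("species name must be a single non-empty string")
  name <- trimws(name)

  m <- regmatches(name, regexec("^([A-Za-z]+)\\s+(.*)$", name))[[1]]
  if (length(m) != 3L)
    stop("malformed species name: '", name, "'")
  cls <- m[2]
  rest <- m[3]
  if (!cls %in% c("PC", "SM"))
    stop("unknown lipid class token: '", cls, "'")

  ether <- grepl("^O-", rest)
  if (ether) {
    if (cls == "SM")
      stop("ether linkage token 'O-' is not valid for SM: '", name, "'")
    rest <- sub("^O-", "", rest)
  }

  cd <- "([0-9]+):([0-9]+)"
  if (grepl(paste0("^", cd, "/", cd, "$"), rest)) {
    m2 <- regmatches(rest, regexec(paste0("^", cd, "/", cd, "$"), rest))[[1]]
    carbons <- as.integer(m2[2]) + as.integer(m2[4])
    dbs <- as.integer(m2[3]) + as.integer(m2[5])
    display <- paste(cls, if (ether) paste0("O-", rest) else rest)
  } else if (grepl(paste0("^", cd, "$"), rest)) {
    m2 <- regmatches(rest, regexec(paste0("^", cd, "$"), rest))[[1]]
    carbons <- as.integer(m2[2])
    dbs <- as.integer(m2[3])
    display <- sprintf("%s %s%d:%d", cls, if (ether) "O-" else "", carbons, dbs)
  } else {
    stop("malformed carbons:double-bonds token: '", rest, "'")
  }

  new("LipidSpecies",
      lipidClass = cls,
      linkage = if (cls == "SM") "sphingoid" else if (ether) "ether" else "diacyl",
      totalCarbons = carbons,
      totalDoubleBonds = dbs,
      displayName = display)
}

.parseSpeciesTable <- function(names) {
  sp <- lapply(names, parseSpeciesName)
  data.frame(
    name = names,
    lipid_class = vapply(sp, function(s) s@lipidClass, ""),
    linkage = vapply(sp, function(s) s@linkage, ""),
    carbons = vapply(sp, function(s) s@totalCarbons, 0L),
    double_bonds = vapply(sp, function(s) s@totalDoubleBonds, 0L),
    stringsAsFactors = FALSE
  )
}

#' Elemental formula of a sum-composition species
#'
#' Assembles the CHNOP composition from the class backbone plus side
#' chains: a diacyl PC with C carbons and D double bonds is
#' C(C+8) H(2C-2D+16) N O8 P (glycerophosphocholine backbone + two
#' esterified acyls); an ether PC replaces one ester bond (one O fewer,
#' two H more); an SM is C(C+5) H(2C-2D+13) N2 O6 P (sphingoid base,
#' amide-linked acyl, phosphocholine).
#'
#' @param species a [LipidSpecies-class] or a name accepted by
#'   [parseSpeciesName()].
#' @return named integer vector over `c("C","H","N","O","P")`.
#' @examples
#' lipidFormula("PC 34:1") # C42 H82 N O8 P
#' @export
lipidFormula <- function(species) {
  if (is.character(species)) species <- parseSpeciesName(species)
  stopifnot(is(species, "LipidSpecies"))
  C <- species@totalCarbons
  D <- species@totalDoubleBonds
  f <- switch(paste(species@lipidClass, species@linkage),
    "PC diacyl" = c(C = C + 8L, H = 2L * C - 2L * D + 16L, N = 1L, O = 8L, P = 1L),
    "PC ether"  = c(C = C + 8L, H = 2L * C - 2L * D + 18L, N = 1L, O = 7L, P = 1L),
    "SM sphingoid" = c(C = C + 5L, H = 2L * C - 2L * D + 13L, N = 2L, O = 6L, P = 1L)
  )
  .checkFormula(f)
  f
}

.checkFormula <- function(f) {
  if (!is.numeric(f) || is.null(names(f)) ||
      !all(names(f) %in% names(.MONO_MASS)))
    stop("formula must be a named count vector over C,H,N,O,P")
  if (any(f < 0)) stop("element counts must be non-negative")
  if (is.na(f["C"]) || f["C"] < 1) stop("formula must contain at least one carbon")
  invisible(f)
}

#' Format an elemental formula as a Hill-style string
#' @param formula named element-count vector.
#' @export
formulaString <- function(formula) {
  .checkFormula(formula)
  ord <- c("C", "H", "N", "O", "P")
  parts <- vapply(ord, function(el) {
    n <- if (el %in% names(formula)) formula[[el]] else 0
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, "")
  paste(parts[nzchar(parts)], collapse = "")
}

#' Monoisotopic neutral mass of a formula
#' @param formula named element-count vector (or species name/object).
#' @export
monoisotopicMass <- function(formula) {
  if (is.character(formula) || is(formula, "LipidSpecies"))
    formula <- lipidFormula(formula)
  .checkFormula(formula)
  sum(.MONO_MASS[names(formula)] * formula)
}

#' Protonated-adduct m/z
#'
#' Only the \[M+H\]+ adduct is supported: precursor-ion-scan detection of
#' the m/z 184 phosphocholine fragment in positive mode implies
#' protonated choline lipids.
#'
#' @param x a formula vector, [LipidSpecies-class], or species name.
#' @param adduct adduct label; only `"[M+H]+"`.
#' @return m/z in Da (monoisotopic, full double precision).
#' @examples
#' adductMz("PC 34:1") # 760.585, printed as 760.6 at unit resolution
#' @export
adductMz <- function(x, adduct = "[M+H]+") {
  if (!identical(adduct, "[M+H]+"))
    stop("unsupported adduct: ", adduct)
  monoisotopicMass(x) + .PROTON_MASS
}

#' Nominal (integer) m/z of the protonated adduct
#'
#' Sum of integer element masses plus one for the proton. PC species
#' (one nitrogen) have even nominal \[M+H\]+ m/z and SM species (two
#' nitrogens) odd, so the two classes never collide within 0.5 Da.
#'
#' @inheritParams adductMz
#' @export
nominalAdductMz <- function(x) {
  if (is.character(x) || is(x, "LipidSpecies")) x <- lipidFormula(x)
  .checkFormula(x)
  as.integer(sum(.NOMINAL_MASS[names(x)] * x) + 1L)
}

#' m/z of the phosphocholine reporter fragment
#'
#' The C5H15NO4P+ cation selected by the precursor ion scan; its nominal
#' m/z is 184.
#' @export
phosphocholineFragmentMz <- function() {
  sum(.MONO_MASS[names(.PHOSPHOCHOLINE_FRAGMENT)] * .PHOSPHOCHOLINE_FRAGMENT) -
    .ELECTRON_MASS
}

# Truncated polynomial product: coefficients of (a*b) up to degree n-1.
.polyMulTrunc <- function(a, b, n) {
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- n - i + 1L
    if (jmax < 1L) break
    idx <- seq_len(min(jmax, length(b)))
    out[i + idx - 1L] <- out[i + idx - 1L] + a[i] * b[idx]
  }
  out
}

.polyPowTrunc <- function(p, k, n) {
  res <- c(1, numeric(n - 1L))
  base <- c(p, numeric(max(0L, n - length(p))))[seq_len(n)]
  while (k > 0L) {
    if (k %% 2L == 1L) res <- .polyMulTrunc(res, base, n)
    base <- .polyMulTrunc(base, base, n)
    k <- k %/% 2L
  }
  res
}

#' Isotopologue envelope of a formula
#'
#' Relative abundances of the M+0, M+1, ... isotopologues (by integer
#' mass shift), computed by multinomial convolution of natural isotope
#' abundances per element and normalised so M+0 = 1. The M+2 entry is the
#' correction factor used by [deisotope()]; beyond M+4 contributions are
#' below 0.5% for lipids in the scan range, hence the default truncation.
#'
#' @param formula named element-count vector, species or species name.
#' @param n number of isotopologues to return (>= 3).
#' @return numeric vector of length `n`, `M+0` normalised to 1.
#' @examples
#' isotopeEnvelope(c(C = 1))[2] # 13C/12C abundance ratio, ~0.0108
#' @export
isotopeEnvelope <- function(formula, n = 5L) {
  if (is.character(formula) || is(formula, "LipidSpecies"))
    formula <- lipidFormula(formula)
  .checkFormula(formula)
  n <- as.integer(n)
  if (n < 3L) stop("n must be >= 3")
  env <- c(1, numeric(n - 1L))
  for (el in names(formula)) {
    k <- as.integer(formula[[el]])
    if (k == 0L) next
    env <- .polyMulTrunc(env, .polyPowTrunc(.ISOTOPE_ABUNDANCE[[el]], k, n), n)
  }
  env / env[1L]
}

# ---- target lists ----------------------------------------------------------

.DEFAULT_PC_DIACYL <- c(
  "28:0", "30:0", "30:1", "32:0", "32:1", "32:2", "34:1", "34:2", "34:3",
  "34:4", "36:1", "36:2", "36:3", "36:4", "36:5", "38:2", "38:3", "38:4",
  "38:5", "38:6", "38:7", "40:4", "40:5", "40:6", "40:7", "40:8", "42:10",
  "44:12"
)
.DEFAULT_PC_ETHER <- c(
  "30:0", "32:0", "32:1", "34:1", "34:2", "34:3", "36:2", "36:3", "36:4",
  "36:5", "38:4", "38:5", "38:6", "38:7", "40:6", "40:7"
)
.DEFAULT_SM <- c(
  "32:1", "33:1", "34:0", "34:1", "34:2", "35:1", "36:1", "36:2", "38:1",
  "39:1", "40:1", "40:2", "41:1", "41:2", "42:1", "42:2", "42:3"
)

#' Name of the per-class internal standards
#'
#' PC 17:0/17:0 (sum composition PC 34:0) and dihydrosphingomyelin 12:0
#' (sum composition SM 30:0), the exogenous species spiked into every
#' sorted well. Endogenous PC 34:0 / SM 30:0 are excluded from the
#' default target list because they are isobaric with these standards at
#' unit resolution.
#' @export
internalStandardNames <- function() c(PC = "PC 17:0/17:0", SM = "SM 30:0")

.buildTargetList <- function(names, is_flag, is_class, expected_mz = NULL) {
  tab <- .parseSpeciesTable(names)
  if (is.null(expected_mz)) expected_mz <- rep(NA_real_, nrow(tab))
  computed <- vapply(names, function(nm) adductMz(nm), 0.0)
  tab$expected_mz <- ifelse(is.na(expected_mz), computed, expected_mz)
  tab$is_internal_standard <- is_flag
  tab$is_class <- is_class
  tab$out_of_range <- tab$expected_mz < 640 | tab$expected_mz > 850
  rownames(tab) <- NULL
  new("TargetList", entries = tab)
}

#' Packaged default PC/SM target list
#'
#' The species grid used for target matching when no list is supplied:
#' diacyl PC (28:0 through 44:12), ether PC O- (30:0 through 40:7), SM
#' (32:1 through 42:3) and the two internal standards, 63 entries in all.
#' Isobaric odd-chain diacyl names are reported as ether-linked only;
#' entries whose \[M+H\]+ falls outside the 640-850 acquisition window
#' (PC 44:12) are retained but flagged out of range.
#'
#' @return a [TargetList-class].
#' @export
defaultTargetList <- function() {
  nm <- c(paste("PC", .DEFAULT_PC_DIACYL),
          paste("PC", paste0("O-", .DEFAULT_PC_ETHER)),
          paste("SM", .DEFAULT_SM),
          unname(internalStandardNames()))
  n <- length(nm)
  is_flag <- c(rep(FALSE, n - 2L), TRUE, TRUE)
  is_class <- c(rep(NA_character_, n - 2L), "PC", "SM")
  .buildTargetList(nm, is_flag, is_class)
}

#' Read a target list from CSV
#'
#' Expected columns: `name` (required), `expected_mz`,
#' `is_internal_standard`, `is_class` (optional). Missing expected m/z
#' values are computed from the elemental formula; entries outside the
#' 640-850 window are retained but flagged.
#'
#' @param path CSV file path.
#' @return a [TargetList-class].
#' @export
loadTargetList <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"name" %in% names(df))
    stop("target list must have a 'name' column")
  if (anyDuplicated(df$name))
    stop("duplicate target names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  mz <- if ("expected_mz" %in% names(df)) as.numeric(df$expected_mz) else NULL
  is_flag <- if ("is_internal_standard" %in% names(df))
    as.logical(df$is_internal_standard) else rep(FALSE, nrow(df))
  is_flag[is.na(is_flag)] <- FALSE
  is_class <- if ("is_class" %in% names(df)) {
    cl <- as.character(df$is_class)
    cl[!nzchar(cl) | is.na(cl)] <- NA_character_
    cl
  } else rep(NA_character_, nrow(df))
  .buildTargetList(df$name, is_flag, is_class, expected_mz = mz)
}

#' Write a target list to CSV
#' @param tl a [TargetList-class].
#' @param path output CSV path.
#' @export
writeTargetList <- function(tl, path) {
  e <- targetEntries(tl)
  out <- data.frame(name = e$name,
                    expected_mz = e$expected_mz,
                    is_internal_standard = e$is_internal_standard,
                    is_class = ifelse(is.na(e$is_class), "", e$is_class))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
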