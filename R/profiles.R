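#' Cell lipidome profile for the plate simulator
#'
#' A `CellProfile` describes the mean PC and SM composition of one cell
#' type, its per-cell class totals, the cell-to-cell biological
#' variability, and how docosahexaenoic acid (DHA) supplementation
#' perturbs it. DHA (22:6 n-3) incorporation enriches PC species carrying
#' at least `dhaMinDb` (default 6) carbon-carbon double bonds; under the
#' `"DHA"` treatment these species' mean fractions are multiplied by
#' `dhaShift` and the composition renormalised.
#'
#' @param name profile label (e.g. `"C2C12"`).
#' @param pc,sm named non-negative vectors of mean fractions per species
#'   (names must parse via [parseSpeciesName()] and belong to the right
#'   class); each is renormalised to sum to 1.
#' @param perCellPcFmol,perCellSmFmol mean per-cell class totals (fmol).
#' @param cvBiological lognormal cell-to-cell coefficient of variation
#'   applied to class totals and species fractions.
#' @param dhaShift multiplier applied to polyunsaturated (>= `dhaMinDb`
#'   double bonds) PC species under DHA treatment.
#' @param dhaMinDb double-bond threshold defining DHA-containing species.
#' @return an object of class `CellProfile`.
#' @export
cellProfile <- function(name, pc, sm,
                        perCellPcFmol = 20, perCellSmFmol = 4,
                        cvBiological = 0.25, dhaShift = 3, dhaMinDb = 6L) {
  checkClass <- function(x, want) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("composition vectors must be named by species")
    if (any(x < 0)) stop("composition fractions must be non-negative")
    for (nm in names(x)) {
      sp <- parseSpeciesName(nm)
      if (sp@lipidClass != want)
        stop("species '", nm, "' is not of class ", want)
    }
    x / sum(x)
  }
  stopifnot(perCellPcFmol > 0, perCellSmFmol > 0,
            cvBiological >= 0, dhaShift > 0)
  structure(list(
    name = name,
    pc = checkClass(pc, "PC"),
    sm = checkClass(sm, "SM"),
    perCellPcFmol = perCellPcFmol,
    perCellSmFmol = perCellSmFmol,
    cvBiological = cvBiological,
    dhaShift = dhaShift,
    dhaMinDb = as.integer(dhaMinDb)
  ), class = "CellProfile")
}

#' @export
print.CellProfile <- function(x, ...) {
  cat(sprintf(
    "CellProfile '%s': %d PC + %d SM species; %.3g fmol PC, %.3g fmol SM per cell; CV %.2f\n",
    x$name, length(x$pc), length(x$sm), x$perCellPcFmol, x$perCellSmFmol,
    x$cvBiological))
  invisible(x)
}

# Mean compositions for the packaged profiles. Fractions are of class
# total and renormalised by cellProfile(); values are plausible
# mammalian-culture compositions, with the prostate lines pinned to the
# published PC 34:1 shares (LNCaP ~0.48, PC3 ~0.26 of total PC).
.pcNames <- function(x) paste("PC", names(x))
.smNames <- function(x) paste("SM", names(x))

.C2C12_PC <- c(
  "28:0" = .008, "30:0" = .012, "30:1" = .008, "32:0" = .040, "32:1" = .050,
  "32:2" = .012, "34:1" = .170, "34:2" = .120, "34:3" = .022, "34:4" = .008,
  "36:1" = .065, "36:2" = .100, "36:3" = .040, "36:4" = .042, "36:5" = .012,
  "38:2" = .010, "38:3" = .022, "38:4" = .042, "38:5" = .020, "38:6" = .016,
  "38:7" = .008, "40:4" = .008, "40:5" = .009, "40:6" = .012, "40:7" = .008,
  "40:8" = .006, "42:10" = .004, "44:12" = .002,
  "O-30:0" = .006, "O-32:0" = .008, "O-32:1" = .008, "O-34:1" = .013,
  "O-34:2" = .010, "O-34:3" = .007, "O-36:2" = .008, "O-36:3" = .008,
  "O-36:4" = .012, "O-36:5" = .008, "O-38:4" = .008, "O-38:5" = .014,
  "O-38:6" = .008, "O-38:7" = .005, "O-40:6" = .007, "O-40:7" = .005
)

.HEPG2_PC <- c(
  "28:0" = .006, "30:0" = .018, "30:1" = .012, "32:0" = .048, "32:1" = .075,
  "32:2" = .016, "34:1" = .210, "34:2" = .095, "34:3" = .020, "34:4" = .006,
  "36:1" = .060, "36:2" = .085, "36:3" = .038, "36:4" = .050, "36:5" = .014,
  "38:2" = .008, "38:3" = .020, "38:4" = .048, "38:5" = .024, "38:6" = .028,
  "38:7" = .006, "40:4" = .006, "40:5" = .008, "40:6" = .016, "40:7" = .007,
  "40:8" = .005, "42:10" = .003, "44:12" = .001,
  "O-30:0" = .004, "O-32:0" = .006, "O-32:1" = .006, "O-34:1" = .009,
  "O-34:2" = .007, "O-34:3" = .005, "O-36:2" = .006, "O-36:3" = .006,
  "O-36:4" = .009, "O-36:5" = .006, "O-38:4" = .006, "O-38:5" = .008,
  "O-38:6" = .006, "O-38:7" = .004, "O-40:6" = .005, "O-40:7" = .004
)

.C2C12_SM <- c(
  "32:1" = .035, "33:1" = .030, "34:0" = .045, "34:1" = .330, "34:2" = .055,
  "35:1" = .020, "36:1" = .095, "36:2" = .040, "38:1" = .040, "39:1" = .015,
  "40:1" = .075, "40:2" = .030, "41:1" = .030, "41:2" = .018, "42:1" = .080,
  "42:2" = .082, "42:3" = .035
)

.HEPG2_SM <- c(
  "32:1" = .050, "33:1" = .020, "34:0" = .035, "34:1" = .380, "34:2" = .045,
  "35:1" = .015, "36:1" = .080, "36:2" = .035, "38:1" = .035, "39:1" = .010,
  "40:1" = .060, "40:2" = .025, "41:1" = .035, "41:2" = .015, "42:1" = .090,
  "42:2" = .070, "42:3" = .025
)

# Shared prostate template for the non-34:1 share of PC; per line the
# PC 34:1 fraction is pinned and the remainder distributed per template.
.PROSTATE_PC_TEMPLATE <- c(
  "30:0" = .020, "32:0" = .060, "32:1" = .090, "32:2" = .020, "34:2" = .140,
  "34:3" = .030, "36:1" = .120, "36:2" = .160, "36:3" = .060, "36:4" = .070,
  "36:5" = .015, "38:2" = .012, "38:3" = .040, "38:4" = .060, "38:5" = .030,
  "38:6" = .025, "40:6" = .015, "40:7" = .008, "O-34:1" = .020,
  "O-36:4" = .020, "O-38:5" = .015
)

.PROSTATE_SM <- c(
  "32:1" = .040, "33:1" = .020, "34:0" = .040, "34:1" = .360, "34:2" = .050,
  "36:1" = .090, "36:2" = .040, "38:1" = .040, "40:1" = .070, "40:2" = .025,
  "41:1" = .030, "42:1" = .090, "42:2" = .075, "42:3" = .030
)

# Line-specific multiplicative tilts: cell lineages differ broadly across
# their lipidome, not in a single species, so each line perturbs many
# species of the shared template. DU145 and PNT1 share most of their tilt
# (their lines are near-indistinguishable by PC/SM profile).
.PROSTATE_PC_TILT <- list(
  LNCaP = c("32:0" = 1.3, "32:1" = 1.5, "34:2" = 1.2, "36:1" = 0.8,
            "36:2" = 0.9, "36:4" = 0.8, "38:4" = 0.7, "38:5" = 0.8,
            "38:6" = 0.8, "O-34:1" = 0.7, "O-36:4" = 0.7, "O-38:5" = 0.7),
  PC3   = c("32:0" = 0.7, "32:1" = 0.8, "34:2" = 0.9, "36:1" = 1.2,
            "36:2" = 1.1, "36:4" = 1.4, "38:4" = 1.4, "38:5" = 1.3,
            "38:6" = 1.4, "40:6" = 1.3, "O-34:1" = 1.4, "O-36:4" = 1.4,
            "O-38:5" = 1.4),
  DU145 = c("32:0" = 1.1, "34:2" = 0.8, "36:2" = 1.3, "36:3" = 1.2,
            "38:3" = 1.2, "38:4" = 1.0, "O-34:1" = 1.1, "36:5" = 1.2),
  PNT1  = c("32:0" = 1.0, "34:2" = 0.8, "36:2" = 1.3, "36:3" = 1.1,
            "38:3" = 1.3, "38:4" = 1.1, "O-34:1" = 1.1, "36:5" = 1.1)
)

.PROSTATE_SM_TILT <- list(
  LNCaP = c("34:1" = 1.2, "36:1" = 0.8, "42:1" = 0.8, "42:2" = 0.8,
            "40:1" = 0.9),
  PC3   = c("34:1" = 0.8, "36:1" = 1.2, "42:1" = 1.3, "42:2" = 1.2,
            "34:2" = 1.2),
  DU145 = c("34:1" = 1.0, "36:1" = 1.1, "42:1" = 1.1, "38:1" = 1.2),
  PNT1  = c("34:1" = 1.0, "36:1" = 1.1, "42:1" = 1.0, "38:1" = 1.2)
)

.applyTilt <- function(x, tilt) {
  x[names(tilt)] <- x[names(tilt)] * tilt
  x
}

.prostatePc <- function(line, frac341) {
  tmpl <- .applyTilt(.PROSTATE_PC_TEMPLATE, .PROSTATE_PC_TILT[[line]])
  tmpl <- tmpl / sum(tmpl) * (1 - frac341)
  c(tmpl, "34:1" = frac341)
}

.prostateSm <- function(line) {
  sm <- .applyTilt(.PROSTATE_SM, .PROSTATE_SM_TILT[[line]])
  sm / sum(sm)
}

.prostateProfile <- function(line, frac341) {
  pc <- .prostatePc(line, frac341)
  sm <- .prostateSm(line)
  cellProfile(line,
              pc = stats::setNames(pc, .pcNames(pc)),
              sm = stats::setNames(sm, .smNames(sm)))
}

#' Packaged default cell profiles
#'
#' Six cell-type profiles drive the packaged simulation scenarios:
#' `C2C12` (myoblast-like) and `HepG2` (hepatocyte-like) for the DHA
#' supplementation experiment, and four prostate profiles with PC 34:1
#' pinned at published shares of total PC (`LNCaP` 0.48, `PC3` 0.26,
#' `DU145` 0.35, `PNT1` 0.33; the latter two deliberately similar, as the
#' corresponding lines co-cluster).
#'
#' @return named list of [cellProfile()] objects.
#' @export
defaultProfiles <- function() {
  prof <- list(
    C2C12 = cellProfile("C2C12",
      pc = stats::setNames(.C2C12_PC, .pcNames(.C2C12_PC)),
      sm = stats::setNames(.C2C12_SM, .smNames(.C2C12_SM))),
    HepG2 = cellProfile("HepG2",
      pc = stats::setNames(.HEPG2_PC, .pcNames(.HEPG2_PC)),
      sm = stats::setNames(.HEPG2_SM, .smNames(.HEPG2_SM))),
    LNCaP = .prostateProfile("LNCaP", 0.48),
    PC3 = .prostateProfile("PC3", 0.26),
    DU145 = .prostateProfile("DU145", 0.35),
    PNT1 = .prostateProfile("PNT1", 0.33)
  )
  prof
}

# ---- plate layouts ---------------------------------------------------------

.plateWellIds <- function(n) {
  ids <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  if (n > length(ids)) stop("plate holds at most 96 wells")
  ids[seq_len(n)]
}

.layoutRow <- function(role, cell_line, treatment, n_cells, is_fmol) {
  data.frame(role = role,
             cell_line = if (is.null(cell_line)) NA_character_ else cell_line,
             treatment = if (is.null(treatment)) NA_character_ else treatment,
             n_cells = n_cells,
             is_pc_fmol = is_fmol, is_sm_fmol = is_fmol,
             stringsAsFactors = FALSE)
}

#' Validate a plate-layout table
#'
#' Checks the role vocabulary, cell counts per role (blanks 0, single
#' cells 1, fifty-cell wells 50) and positive internal-standard spikes
#' for sorted wells.
#'
#' @param layout a plate-layout `data.frame` (see [dhaExperimentLayout()]).
#' @return the layout, invisibly; errors describe the offending wells.
#' @export
validatePlateLayout <- function(layout) {
  need <- c("well_id", "role", "cell_line", "treatment", "n_cells",
            "is_pc_fmol", "is_sm_fmol")
  if (!all(need %in% names(layout)))
    stop("layout must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(layout$well_id))
    stop("duplicate well ids in layout")
  ok_roles <- c("extraction_blank", "bulk", "fifty_cells", "single_cell")
  bad <- !layout$role %in% ok_roles
  if (any(bad))
    stop("unknown well role(s): ", paste(unique(layout$role[bad]), collapse = ", "))
  chk <- function(role, n) {
    w <- layout$role == role & layout$n_cells != n
    if (any(w)) stop(role, " wells must have n_cells = ", n, ": ",
                     paste(layout$well_id[w], collapse = ", "))
  }
  chk("extraction_blank", 0L); chk("single_cell", 1L); chk("fifty_cells", 50L)
  sorted <- layout$role %in% c("fifty_cells", "single_cell")
  if (any(sorted & (layout$is_pc_fmol <= 0 | layout$is_sm_fmol <= 0)))
    stop("sorted wells must have positive internal-standard spikes")
  invisible(layout)
}

#' Plate layouts for the packaged experiment shapes
#'
#' `dhaExperimentLayout()` reproduces the DHA supplementation design:
#' for each of 2 cell lines x 2 treatments (CON/DHA), 3 extraction
#' blanks, 3 fifty-cell wells and 18 single-cell wells -- a full 96-well
#' plate. `prostatePanelLayout()` covers 4 prostate lines with 3
#' fifty-cell and 18 single-cell wells each plus shared blanks.
#' `bulkComparisonLayout()` builds the bulk-extract versus fifty-cell
#' comparison for one line/treatment. Internal standards are spiked at
#' 1000 fmol into fifty-cell (and bulk/blank) wells and 1.38 fmol into
#' single-cell wells.
#'
#' @param lines cell-line labels (must match profile names).
#' @param nSingle,nFifty,nBlank,nBulk well counts per group.
#' @return a plate-layout `data.frame` with one row per well.
#' @export
dhaExperimentLayout <- function(lines = c("C2C12", "HepG2"),
                                nSingle = 18L, nFifty = 3L, nBlank = 3L) {
  rows <- list()
  for (line in lines) for (trt in c("CON", "DHA")) {
    rows <- c(rows, list(
      .layoutRow("extraction_blank", NULL, NULL, 0L, 1000)[rep(1, nBlank), ],
      .layoutRow("fifty_cells", line, trt, 50L, 1000)[rep(1, nFifty), ],
      .layoutRow("single_cell", line, trt, 1L, 1.38)[rep(1, nSingle), ]))
  }
  out <- do.call(rbind, rows)
  out <- cbind(well_id = .plateWellIds(nrow(out)), out)
  rownames(out) <- NULL
  validatePlateLayout(out)
  out
}

#' @rdname dhaExperimentLayout
#' @export
prostatePanelLayout <- function(lines = c("LNCaP", "PC3", "DU145", "PNT1"),
                                nSingle = 18L, nFifty = 3L, nBlank = 6L) {
  rows <- list(.layoutRow("extraction_blank", NULL, NULL, 0L, 1000)[rep(1, nBlank), ])
  for (line in lines) {
    rows <- c(rows, list(
      .layoutRow("fifty_cells", line, "CON", 50L, 1000)[rep(1, nFifty), ],
      .layoutRow("single_cell", line, "CON", 1L, 1.38)[rep(1, nSingle), ]))
  }
  out <- do.call(rbind, rows)
  out <- cbind(well_id = .plateWellIds(nrow(out)), out)
  rownames(out) <- NULL
  validatePlateLayout(out)
  out
}

#' @rdname dhaExperimentLayout
#' @param line,treatment group simulated in the bulk comparison.
#' @param bulkCells cell-equivalents loaded in a bulk-extract well.
#' @export
bulkComparisonLayout <- function(line = "C2C12", treatment = "CON",
                                 nBulk = 3L, nFifty = 3L, nBlank = 3L,
                                 bulkCells = 500L) {
  out <- rbind(
    .layoutRow("extraction_blank", NULL, NULL, 0L, 1000)[rep(1, nBlank), ],
    .layoutRow("bulk", line, treatment, as.integer(bulkCells), 1000)[rep(1, nBulk), ],
    .layoutRow("fifty_cells", line, treatment, 50L, 1000)[rep(1, nFifty), ])
  out <- cbind(well_id = .plateWellIds(nrow(out)), out)
  rownames(out) <- NULL
  validatePlateLayout(out)
  out
}
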