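#' Rendering and noise parameters for the plate simulator
#'
#' Defaults emulate a unit-resolution triple-quadrupole precursor ion
#' scan: Gaussian peaks of 0.6 Da FWHM on a 0.05 Da profile grid over
#' 640-850 m/z, a flat electronic baseline with Gaussian noise, and a
#' Poisson-like shot-noise term with sd proportional to the square root
#' of intensity. The response factor converts fmol to integrated area
#' (one value for all species: quantification is relative, against one
#' internal standard per class, with no species response correction).
#' Baseline noise is sized so single-cell base peaks land in the upper
#' half of the S/N 10-100 range (~85) and ~1% species straddle the S/N 4
#' detection threshold. Two contaminant peaks (678.51, coincident with
#' PC 28:0, and 725.40, matching no target) model solvent/extraction
#' background and appear in every well, which is what extraction-blank
#' subtraction corrects.
#'
#' @param mzStep profile grid spacing (Da).
#' @param mzRange acquisition window (Da).
#' @param fwhm Gaussian peak full width at half maximum (Da).
#' @param responsePerFmol integrated area units per fmol.
#' @param baselineLevel flat baseline offset (intensity units).
#' @param baselineSd Gaussian baseline noise sd.
#' @param shotFactor shot-noise scale; per-point sd is
#'   `shotFactor * sqrt(intensity)`.
#' @param technicalCv per-well, per-species multiplicative technical
#'   variability (lognormal CV) of the measured response, emulating
#'   shot-to-shot infusion and spray fluctuation. Without it, wells
#'   integrating many cells (fifty-cell, bulk) would be unrealistically
#'   precise and any tiny systematic processing bias would register as a
#'   group difference.
#' @param nIso isotopologues rendered per species (M+0 ... M+(nIso-1)).
#' @param contaminants `data.frame(mz, area)` of background peaks
#'   rendered in every well (no isotopologues).
#' @param mode `"profile"` or `"centroid"` output.
#' @return a list of rendering parameters.
#' @export
simParams <- function(mzStep = 0.05, mzRange = c(640, 850), fwhm = 0.6,
                      responsePerFmol = 1000, baselineLevel = 150,
                      baselineSd = 70, shotFactor = 1, technicalCv = 0.05,
                      nIso = 5L,
                      contaminants = data.frame(mz = c(678.51, 725.40),
                                                area = c(500, 350)),
                      mode = "profile") {
  stopifnot(mzStep > 0, fwhm > 0, responsePerFmol > 0, baselineLevel >= 0,
            baselineSd >= 0, shotFactor >= 0, technicalCv >= 0, nIso >= 3,
            mode %in% c("profile", "centroid"))
  list(mzStep = mzStep, mzRange = mzRange, fwhm = fwhm,
       responsePerFmol = responsePerFmol, baselineLevel = baselineLevel,
       baselineSd = baselineSd, shotFactor = shotFactor,
       technicalCv = technicalCv, nIso = as.integer(nIso),
       contaminants = contaminants, mode = mode)
}

#' Zero-noise rendering parameters
#'
#' Convenience wrapper: [simParams()] with baseline, baseline noise and
#' shot noise all zero, used for deterministic recovery checks.
#' @param ... overrides passed to [simParams()].
#' @export
noiselessParams <- function(...) {
  simParams(baselineLevel = 0, baselineSd = 0, shotFactor = 0,
            technicalCv = 0, ...)
}

# Lognormal draw with mean m and coefficient of variation cv.
.rlnormCv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Draw a per-well lipid composition
#'
#' Draws true amounts (fmol) for all species of a profile: per-cell PC
#' and SM class totals and per-species fractions vary lognormally with
#' CV `profile$cvBiological`, fractions are renormalised per class, and
#' a well's amounts are the sum over its `nCells` cells. Under `"DHA"`
#' treatment the mean fractions of PC species with >= `profile$dhaMinDb`
#' double bonds are multiplied by `profile$dhaShift` before
#' renormalisation, so the summed polyunsaturated fraction rises at the
#' expense of the rest of the class.
#'
#' @param profile a [cellProfile()] object.
#' @param treatment `"CON"` or `"DHA"`.
#' @param nCells number of cells deposited in the well.
#' @return named vector of true amounts (fmol) per species.
#' @export
makeComposition <- function(profile, treatment = "CON", nCells = 1L) {
  stopifnot(inherits(profile, "CellProfile"),
            treatment %in% c("CON", "DHA"), nCells >= 1)
  pcMean <- profile$pc
  if (treatment == "DHA") {
    db <- vapply(names(pcMean),
                 function(nm) parseSpeciesName(nm)@totalDoubleBonds, 0L)
    pcMean[db >= profile$dhaMinDb] <- pcMean[db >= profile$dhaMinDb] * profile$dhaShift
    pcMean <- pcMean / sum(pcMean)
  }
  cv <- profile$cvBiological
  drawClass <- function(fracMean, totalMean) {
    tot <- .rlnormCv(nCells, totalMean, cv)
    out <- numeric(length(fracMean))
    for (i in seq_len(nCells)) {
      f <- .rlnormCv(length(fracMean), fracMean, cv)
      out <- out + tot[i] * f / sum(f)
    }
    stats::setNames(out, names(fracMean))
  }
  c(drawClass(pcMean, profile$perCellPcFmol),
    drawClass(profile$sm, profile$perCellSmFmol))
}

#' Render a direct-infusion spectrum from true amounts
#'
#' Each species contributes Gaussian peaks at its protonated m/z and the
#' following isotopologues (spaced by the 13C shift), with areas
#' proportional to amount x response factor x isotope envelope (M+0
#' normalised to 1). A flat baseline, Gaussian baseline noise and
#' signal-dependent shot noise are added; intensities are clipped at
#' zero. In centroid mode each isotopologue is emitted as an integrated
#' stick instead, with sticks closer than 0.02 Da merged (as a unit-
#' resolution instrument could not tell them apart).
#'
#' @param amounts named vector of true amounts (fmol); names must be in
#'   `targets`.
#' @param targets a [TargetList-class] providing expected m/z values.
#' @param params rendering parameters from [simParams()].
#' @param wellId label stored in the returned spectrum.
#' @return a [Spectrum-class].
#' @export
renderSpectrum <- function(amounts, targets = defaultTargetList(),
                           params = simParams(), wellId = "A1") {
  e <- targetEntries(targets)
  if (length(amounts)) {
    missing <- setdiff(names(amounts), e$name)
    if (length(missing))
      stop("species absent from target registry: ",
           paste(missing, collapse = ", "))
  }
  sticksMz <- numeric(0); sticksArea <- numeric(0)
  for (nm in names(amounts)) {
    if (amounts[[nm]] <= 0) next
    row <- e[e$name == nm, ]
    env <- isotopeEnvelope(nm, n = params$nIso)
    mzk <- row$expected_mz + (seq_along(env) - 1L) * .C13_SHIFT
    resp <- params$responsePerFmol *
      .rlnormCv(1L, 1, params$technicalCv)
    sticksMz <- c(sticksMz, mzk)
    sticksArea <- c(sticksArea, amounts[[nm]] * resp * env)
  }
  if (nrow(params$contaminants)) {
    sticksMz <- c(sticksMz, params$contaminants$mz)
    sticksArea <- c(sticksArea, params$contaminants$area)
  }
  keep <- sticksMz >= params$mzRange[1] - 2 & sticksMz <= params$mzRange[2] + 2
  sticksMz <- sticksMz[keep]; sticksArea <- sticksArea[keep]

  if (params$mode == "centroid") {
    ord <- order(sticksMz)
    mz <- sticksMz[ord]; area <- sticksArea[ord]
    if (length(mz) > 1) {
      grp <- cumsum(c(1, diff(mz) > 0.02))
      mz <- as.numeric(tapply(mz * area, grp, sum) / tapply(area, grp, sum))
      area <- as.numeric(tapply(area, grp, sum))
    }
    inr <- mz >= params$mzRange[1] & mz <= params$mzRange[2]
    return(new("Spectrum", mz = mz[inr], intensity = area[inr],
               mode = "centroid", wellId = wellId))
  }

  axis <- seq(params$mzRange[1], params$mzRange[2], by = params$mzStep)
  y <- numeric(length(axis))
  sigma <- params$fwhm / (2 * sqrt(2 * log(2)))
  for (i in seq_along(sticksMz)) {
    lo <- findInterval(sticksMz[i] - 5 * sigma, axis) + 1L
    hi <- findInterval(sticksMz[i] + 5 * sigma, axis)
    if (hi < 1L || lo > length(axis)) next
    lo <- max(1L, lo); hi <- min(length(axis), hi)
    win <- lo:hi
    y[win] <- y[win] + sticksArea[i] *
      stats::dnorm(axis[win], mean = sticksMz[i], sd = sigma)
  }
  y <- y + params$baselineLevel
  if (params$baselineSd > 0)
    y <- y + stats::rnorm(length(y), 0, params$baselineSd)
  if (params$shotFactor > 0)
    y <- y + stats::rnorm(length(y), 0, params$shotFactor * sqrt(pmax(y, 0)))
  y <- pmax(y, 0)
  new("Spectrum", mz = axis, intensity = y, mode = "profile", wellId = wellId)
}

#' Simulate a full plate with ground truth
#'
#' Draws per-well compositions for every non-blank well from its
#' profile, spikes the internal standards at the layout's per-well
#' amounts (PC 17:0/17:0 and dihydro-SM 12:0), renders one spectrum per
#' well, and returns the spectra together with the true amounts. Blank
#' wells contain internal standard and contaminant background only.
#'
#' @param layout plate layout (see [dhaExperimentLayout()]).
#' @param profiles named list of [cellProfile()] objects covering every
#'   cell line in the layout.
#' @param targets a [TargetList-class]; must contain one PC and one SM
#'   internal standard.
#' @param params rendering parameters from [simParams()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `spectra` (named list of [Spectrum-class]), `truth`
#'   (`data.frame` of `well_id`, `species`, `fmol`, including IS) and
#'   `layout`.
#' @export
simulatePlate <- function(layout, profiles = defaultProfiles(),
                          targets = defaultTargetList(),
                          params = simParams(), seed = 1L) {
  validatePlateLayout(layout)
  isName <- internalStandardNames()
  e <- targetEntries(targets)
  for (cls in c("PC", "SM")) {
    if (sum(e$is_internal_standard & !is.na(e$is_class) & e$is_class == cls) != 1)
      stop("target list must contain exactly one ", cls, " internal standard")
  }
  needed <- setdiff(unique(stats::na.omit(layout$cell_line)), names(profiles))
  if (length(needed))
    stop("no profile defined for cell line(s): ", paste(needed, collapse = ", "))

  set.seed(as.integer(seed))
  spectra <- vector("list", nrow(layout))
  names(spectra) <- layout$well_id
  truth <- vector("list", nrow(layout))
  isPC <- e$name[e$is_internal_standard & e$is_class == "PC"]
  isSM <- e$name[e$is_internal_standard & e$is_class == "SM"]

  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    amounts <- c(stats::setNames(w$is_pc_fmol, isPC),
                 stats::setNames(w$is_sm_fmol, isSM))
    if (w$role != "extraction_blank") {
      prof <- profiles[[w$cell_line]]
      trt <- if (is.na(w$treatment)) "CON" else w$treatment
      amounts <- c(amounts, makeComposition(prof, trt, nCells = w$n_cells))
    }
    spectra[[i]] <- renderSpectrum(amounts, targets, params, wellId = w$well_id)
    truth[[i]] <- data.frame(well_id = w$well_id, species = names(amounts),
                             fmol = unname(amounts), stringsAsFactors = FALSE)
  }
  list(spectra = spectra, truth = do.call(rbind, truth), layout = layout)
}
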