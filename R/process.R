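# Running mean with half-width h and truncated end windows.
.runmean <- function(y, h) {
  if (h < 1L) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Robust noise estimate for a profile spectrum
#'
#' Estimates the baseline noise standard deviation as
#' `1.4826 * MAD(first differences) / sqrt(2)` over the signal-free part
#' of the trace: regions whose locally averaged intensity (2 Da window)
#' lies in the lowest 50% of the spectrum. Selecting regions by their
#' local average, rather than individual low samples, excludes peaks
#' without truncating the noise distribution; first differencing removes
#' the baseline level and slow drifts; `sqrt(2)` converts the difference
#' sd back to the per-point sd; the MAD ignores the few differences that
#' straddle region edges.
#'
#' @param spectrum a profile-mode [Spectrum-class] with >= 100 points.
#' @return noise sd in intensity units (0 for an all-zero spectrum).
#' @export
estimateNoise <- function(spectrum) {
  stopifnot(is(spectrum, "Spectrum"))
  y <- specIntensity(spectrum)
  mz <- specMz(spectrum)
  if (length(y) < 100)
    stop("noise estimation needs at least 100 samples")
  if (all(y == 0)) return(0)
  step <- stats::median(diff(mz))
  ys <- .runmean(y, max(1L, floor(1 / step)))
  low <- ys <= stats::quantile(ys, 0.5)
  d <- diff(y[low])
  stats::mad(d, constant = 1.4826) / sqrt(2)
}

#' Boxcar-smooth a profile spectrum
#'
#' Moving average over a window of the given m/z width; windows are
#' truncated at the spectrum ends. Total integrated intensity over the
#' interior is conserved (the average is a convolution with a unit-mass
#' kernel).
#'
#' @param spectrum profile-mode [Spectrum-class].
#' @param window smoothing window width (Da).
#' @return the smoothed [Spectrum-class].
#' @export
smoothSpectrum <- function(spectrum, window = 0.3) {
  stopifnot(is(spectrum, "Spectrum"), window > 0)
  if (specMode(spectrum) == "centroid")
    stop("centroid spectra are already integrated; skip smoothing")
  y <- specIntensity(spectrum)
  mz <- specMz(spectrum)
  step <- if (length(mz) > 1) stats::median(diff(mz)) else window
  h <- max(0L, floor(window / step / 2))
  if (h == 0L) return(spectrum)
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  initialize(spectrum, intensity = sm)
}

# Flat baseline level: median intensity over the low-activity half of
# the trace (selected on a 2 Da running mean, as in estimateNoise), so
# that crowded spectra do not drag the estimate up with peak tails.
.baselineLevel <- function(y, mz) {
  step <- if (length(mz) > 1) stats::median(diff(mz)) else 1
  ys <- .runmean(y, max(1L, floor(1 / step)))
  stats::median(y[ys <= stats::quantile(ys, 0.5)])
}

#' Pick peaks from a spectrum
#'
#' For profile data the flat electronic baseline (direct infusion has no
#' chromatographic gradient) is estimated as the median intensity of the
#' low-activity half of the trace and subtracted; local maxima rising at least `snrThreshold` times the
#' noise sd above it are peak candidates. Low-prominence candidates --
#' noise bumps on the shoulder of a larger peak, whose height above the
#' higher of their two separating minima is below the threshold -- are
#' pruned iteratively. For each surviving peak the centroid is the
#' intensity-weighted mean m/z over the contiguous above-half-maximum
#' region, the area is the trapezoidal integral of baseline-subtracted
#' intensity between the flanking separating minima, and
#' `snr = height / noise`. Centroid spectra pass through as ready-made
#' peaks.
#'
#' @param spectrum a [Spectrum-class] (smoothed profile, or centroid).
#' @param noise noise sd; by default estimated from `spectrum` via
#'   [estimateNoise()]. Pass the estimate from the unsmoothed trace to
#'   keep S/N on the acquired-noise scale.
#' @param snrThreshold detection threshold for candidate maxima.
#' @return `data.frame` with columns `centroid_mz`, `area`, `height`,
#'   `snr`, ordered by m/z (zero rows if nothing exceeds threshold).
#' @export
pickPeaks <- function(spectrum, noise = NULL, snrThreshold = 3) {
  stopifnot(is(spectrum, "Spectrum"))
  y <- specIntensity(spectrum)
  mz <- specMz(spectrum)

  if (specMode(spectrum) == "centroid") {
    keep <- y > 0
    return(data.frame(centroid_mz = mz[keep], area = y[keep],
                      height = y[keep],
                      snr = rep(Inf, sum(keep))))
  }

  if (is.null(noise)) noise <- estimateNoise(spectrum)
  n <- length(y)
  empty <- data.frame(centroid_mz = numeric(0), area = numeric(0),
                      height = numeric(0), snr = numeric(0))
  if (n < 3) return(empty)

  yb <- y - .baselineLevel(y, mz)
  # with zero estimated noise a relative floor keeps numerical ripples
  # on peak flanks from being promoted to peaks of their own
  thr <- if (noise > 0) snrThreshold * noise else 1e-6 * max(yb, 0)
  cand <- which(yb[2:(n - 1)] > yb[1:(n - 2)] & yb[2:(n - 1)] >= yb[3:n]) + 1L
  cand <- cand[yb[cand] > thr]
  if (!length(cand)) return(empty)

  bounds <- function(cand) {
    k <- length(cand)
    sep <- integer(k + 1L)
    sep[1] <- 1L; sep[k + 1L] <- n
    if (k > 1) for (j in seq_len(k - 1L)) {
      rng <- cand[j]:cand[j + 1L]
      sep[j + 1L] <- rng[which.min(yb[rng])]
    }
    list(left = sep[seq_len(k)], right = sep[seq_len(k) + 1L])
  }
  repeat {
    b <- bounds(cand)
    prominence <- yb[cand] - pmax(yb[b$left], yb[b$right])
    drop <- prominence < thr
    if (!any(drop)) break
    cand <- cand[!drop]
    if (!length(cand)) return(empty)
  }

  b <- bounds(cand)
  out <- lapply(seq_along(cand), function(j) {
    L <- b$left[j]; R <- b$right[j]; apex <- cand[j]
    seg <- L:R
    resid <- yb[seg]
    h <- yb[apex]
    # contiguous above-half-max region around the apex
    above <- resid >= h / 2
    ai <- apex - L + 1L
    lo <- ai; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- ai; while (hi < length(seg) && above[hi + 1L]) hi <- hi + 1L
    w <- pmax(resid[lo:hi], 0)
    cen <- if (sum(w) > 0) sum(mz[seg[lo:hi]] * w) / sum(w) else mz[apex]
    area <- sum(diff(mz[seg]) * (resid[-1] + resid[-length(resid)]) / 2)
    c(cen, area, h)
  })
  out <- do.call(rbind, out)
  res <- data.frame(centroid_mz = out[, 1], area = out[, 2], height = out[, 3],
                    snr = if (noise > 0) out[, 3] / noise else rep(Inf, nrow(out)))
  res[res$area > 0, , drop = FALSE]
}

#' Match picked peaks to a target list
#'
#' Each target is matched to the nearest picked peak within the mass
#' tolerance (0.5 Da by default, matching unit-resolution processing);
#' a peak can satisfy at most one target. Conflicts are resolved
#' nearest-first; exact distance ties go to the lower expected m/z.
#' Unmatched targets keep a row with zero raw area.
#'
#' @param peaks peak table from [pickPeaks()].
#' @param targets a [TargetList-class].
#' @param tolerance match tolerance (Da).
#' @param wellId well label recorded in the output.
#' @return an annotated peak table: one row per target with columns
#'   `well_id`, `species`, `expected_mz`, `centroid_mz`, `raw_area`,
#'   `height`, `snr`, `matched`.
#' @export
matchTargets <- function(peaks, targets, tolerance = 0.5, wellId = NA_character_) {
  stopifnot(tolerance > 0)
  e <- targetEntries(targets)
  if (!nrow(e)) stop("empty target list")
  tab <- data.frame(
    well_id = wellId, species = e$name, expected_mz = e$expected_mz,
    centroid_mz = NA_real_, raw_area = 0, height = 0, snr = 0,
    matched = FALSE, stringsAsFactors = FALSE)

  if (nrow(peaks)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(e)), function(ti) {
      d <- abs(peaks$centroid_mz - e$expected_mz[ti])
      ok <- which(d <= tolerance)
      if (!length(ok)) return(NULL)
      data.frame(ti = ti, pi = ok, d = d[ok], tmz = e$expected_mz[ti])
    }))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$d, cand$tmz), ]
      usedT <- logical(nrow(e)); usedP <- logical(nrow(peaks))
      for (k in seq_len(nrow(cand))) {
        ti <- cand$ti[k]; pi <- cand$pi[k]
        if (usedT[ti] || usedP[pi]) next
        usedT[ti] <- TRUE; usedP[pi] <- TRUE
        tab$centroid_mz[ti] <- peaks$centroid_mz[pi]
        tab$raw_area[ti] <- peaks$area[pi]
        tab$height[ti] <- peaks$height[pi]
        tab$snr[ti] <- peaks$snr[pi]
        tab$matched[ti] <- TRUE
      }
    }
  }
  tab
}

#' Correct matched areas for isotopologue overlap (deisotoping)
#'
#' At unit resolution a target's peak absorbs the isotopologues of any
#' lighter co-detected species whose M+k (k >= 1) lands within the merge
#' tolerance of the target's m/z. The dominant case is the M+2 of the
#' species with one more double bond (monoisotopic m/z ~2.007 Da below,
#' two 13C shifts, landing 0.009 Da off the target); because SM species
#' carry two nitrogens their monoisotopic peaks also sit ~0.06 Da above
#' the M+1 of a PC species one nominal mass unit below, so cross-class
#' M+1 overlap is corrected too. Working in ascending expected-m/z
#' order, each species' raw area is reduced by
#' `sum(deisotoped_area(S') * rk(S'))` over all matched interferers S'
#' and shifts k, where `rk` is S''s M+k/M+0 envelope ratio; results are
#' clamped at zero (with a warning). Same-class M+1 never triggers: PC
#' and SM targets of one class are at least 2 Da apart, so their M+1
#' peaks fall between targets and stay unmatched. Applying the
#' correction to already-deisotoped output is a no-op.
#'
#' @param table annotated peak table from [matchTargets()].
#' @param targets the [TargetList-class] the table was matched against.
#' @param mergeTolerance how close (Da) an interfering isotopologue must
#'   land to the target m/z to be considered merged into its peak at
#'   unit resolution.
#' @param nIso isotopologue shifts considered per interferer.
#' @return the table with columns `deisotoped_area` and
#'   `subtracted_area` added (rows in ascending expected m/z).
#' @export
deisotope <- function(table, targets = defaultTargetList(),
                      mergeTolerance = 0.15, nIso = 5L) {
  tab <- table[order(table$expected_mz), , drop = FALSE]
  tab$deisotoped_area <- tab$raw_area
  tab$subtracted_area <- 0
  env <- lapply(tab$species, isotopeEnvelope, n = nIso)

  for (i in seq_len(nrow(tab))) {
    if (!tab$matched[i]) next
    corr <- 0
    js <- which(tab$matched & tab$expected_mz < tab$expected_mz[i] - 0.5)
    for (j in js) {
      shift <- tab$expected_mz[i] - tab$expected_mz[j]
      k <- round(shift / .C13_SHIFT)
      if (k < 1 || k > nIso - 1L) next
      if (abs(shift - k * .C13_SHIFT) > mergeTolerance) next
      corr <- corr + tab$deisotoped_area[j] * env[[j]][k + 1L]
    }
    if (corr == 0) next
    newArea <- tab$raw_area[i] - corr
    if (newArea < 0) {
      warning("deisotoping clamped ", tab$species[i], " to zero area")
      newArea <- 0
    }
    tab$deisotoped_area[i] <- newArea
    tab$subtracted_area[i] <- min(corr, tab$raw_area[i])
  }
  rownames(tab) <- NULL
  tab
}

#' Apply the detection filters
#'
#' A species passes if its S/N is at least `minSnr` (default 4) and its
#' deisotoped area is at least `minIntensityPct` percent (default 0.1%)
#' of the well's largest deisotoped species area. Failing rows keep
#' their areas but are flagged out of quantification, with the failed
#' criterion recorded in `filter_reason`.
#'
#' @param table deisotoped annotated peak table.
#' @param minIntensityPct minimum intensity, percent of base species.
#' @param minSnr minimum signal-to-noise ratio.
#' @return the table with `pass_filters` and `filter_reason` columns.
#' @export
applyFilters <- function(table, minIntensityPct = 0.1, minSnr = 4) {
  stopifnot(minIntensityPct > 0, minSnr > 0)
  base <- max(table$deisotoped_area, 0)
  snrOk <- table$snr >= minSnr
  intOk <- table$deisotoped_area >= minIntensityPct / 100 * base
  reason <- character(nrow(table))
  reason[!snrOk] <- "snr"
  reason[!intOk] <- ifelse(nzchar(reason[!intOk]), "snr;min_intensity",
                           "min_intensity")
  table$pass_filters <- snrOk & intOk & table$matched
  reason[!table$matched & !nzchar(reason)] <- "unmatched"
  table$filter_reason <- ifelse(table$pass_filters, "", reason)
  table
}

#' Process one spectrum through the full detection chain
#'
#' Runs the unit-resolution processing stage end to end: noise
#' estimation on the acquired trace, boxcar smoothing, peak picking,
#' 0.5 Da target matching, M+2 deisotoping and the minimum-intensity /
#' S/N filters.
#'
#' @param spectrum a [Spectrum-class].
#' @param targets a [TargetList-class].
#' @param tolerance match tolerance (Da).
#' @param smoothWindow boxcar window (Da); ignored for centroid data.
#' @param minIntensityPct,minSnr filter thresholds (see [applyFilters()]).
#' @return filtered annotated peak table (one row per target).
#' @export
processSpectrum <- function(spectrum, targets = defaultTargetList(),
                            tolerance = 0.5, smoothWindow = 0.3,
                            minIntensityPct = 0.1, minSnr = 4) {
  if (specMode(spectrum) == "profile") {
    noise <- estimateNoise(spectrum)
    spectrum <- smoothSpectrum(spectrum, smoothWindow)
  } else noise <- 0
  peaks <- pickPeaks(spectrum, noise = noise)
  tab <- matchTargets(peaks, targets, tolerance = tolerance,
                      wellId = wellId(spectrum))
  tab <- deisotope(tab, targets)
  applyFilters(tab, minIntensityPct = minIntensityPct, minSnr = minSnr)
}

#' Process a list of spectra
#'
#' @param spectra named list of [Spectrum-class] objects.
#' @param ... passed to [processSpectrum()].
#' @return a single annotated peak table covering all wells.
#' @export
processWells <- function(spectra, ...) {
  do.call(rbind, lapply(spectra, processSpectrum, ...))
}
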