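test_that("boxcar smoothing conserves area and leaves constants alone", {
  mz <- seq(640, 660, 0.05)
  const <- new("Spectrum", mz = mz, intensity = rep(5, length(mz)),
               mode = "profile", wellId = "w")
  expect_equal(specIntensity(smoothSpectrum(const, 0.3)),
               rep(5, length(mz)))

  spike <- rep(0, length(mz)); spike[200] <- 100
  sp <- new("Spectrum", mz = mz, intensity = spike, mode = "profile",
            wellId = "w")
  sm <- smoothSpectrum(sp, 0.3)
  expect_equal(sum(specIntensity(sm)), sum(spike), tolerance = 1e-3)
  expect_lt(max(specIntensity(sm)), 100)
})

test_that("smoothing a noisy gaussian barely moves its centroid", {
  pn <- simParams(contaminants = noContam())
  shifts <- vapply(1:10, function(i) {
    set.seed(100 + i)
    sp <- renderSpectrum(c("SM 36:1" = 3), params = pn)
    noise <- estimateNoise(sp)
    pk <- pickPeaks(smoothSpectrum(sp, 0.3), noise = noise)
    pk <- pk[order(-pk$height), ]
    abs(pk$centroid_mz[1] - adductMz("SM 36:1"))
  }, 0.0)
  expect_lt(max(shifts), 0.02)
})

test_that("noise estimation is robust and unbiased", {
  mz <- seq(640, 850, 0.05)
  ests <- vapply(1:100, function(i) {
    set.seed(i)
    s <- new("Spectrum", mz = mz,
             intensity = pmax(stats::rnorm(length(mz), 100, 10), 0),
             mode = "profile", wellId = "w")
    estimateNoise(s)
  }, 0.0)
  expect_true(all(ests > 8.5 & ests < 11.5))

  # a few tall peaks do not inflate the estimate
  set.seed(5)
  y <- stats::rnorm(length(mz), 100, 10)
  for (c0 in c(700, 750, 800))
    y <- y + 5e4 * stats::dnorm(mz, c0, 0.25)
  s <- new("Spectrum", mz = mz, intensity = pmax(y, 0), mode = "profile",
           wellId = "w")
  expect_true(estimateNoise(s) > 8.5 && estimateNoise(s) < 11.5)

  zero <- new("Spectrum", mz = mz, intensity = rep(0, length(mz)),
              mode = "profile", wellId = "w")
  expect_equal(estimateNoise(zero), 0)
  short <- new("Spectrum", mz = 1:50, intensity = rep(1, 50),
               mode = "profile", wellId = "w")
  expect_error(estimateNoise(short), "100 samples")
})

test_that("peak picking finds isolated and barely-resolved peaks", {
  pn <- noiselessParams(contaminants = noContam())
  sp <- renderSpectrum(c("PC 34:1" = 1), params = pn)
  pk <- pickPeaks(sp, noise = 0)
  expect_lt(abs(pk$centroid_mz[1] - adductMz("PC 34:1")), 0.01)

  # flat noise only: nothing with snr >= 4
  set.seed(21)
  mz <- seq(640, 850, 0.05)
  noiseOnly <- new("Spectrum", mz = mz,
                   intensity = pmax(stats::rnorm(length(mz), 100, 10), 0),
                   mode = "profile", wellId = "w")
  pk2 <- pickPeaks(noiseOnly)
  expect_equal(sum(pk2$snr >= 4), 0)

  # two gaussians one double-bond apart (2.0157 Da, FWHM 0.6) resolve
  sigma <- 0.6 / (2 * sqrt(2 * log(2)))
  y <- 1000 * stats::dnorm(mz, 745, sigma) + 800 * stats::dnorm(mz, 747.0157, sigma)
  two <- new("Spectrum", mz = mz, intensity = y, mode = "profile", wellId = "w")
  pk3 <- pickPeaks(two, noise = 0)
  expect_equal(nrow(pk3), 2)
  expect_equal(pk3$centroid_mz, c(745, 747.0157), tolerance = 1e-4)
})

test_that("targets match the nearest peak within 0.5 Da, ties to lower m/z", {
  tl <- defaultTargetList()
  mkPeaks <- function(mz) data.frame(centroid_mz = mz, area = 100,
                                     height = 50, snr = 10)
  t1 <- matchTargets(mkPeaks(760.30), tl, wellId = "w")
  expect_true(t1$matched[t1$species == "PC 34:1"])
  t2 <- matchTargets(mkPeaks(761.20), tl, wellId = "w")
  expect_false(t2$matched[t2$species == "PC 34:1"])
  expect_equal(t2$raw_area[t2$species == "PC 34:1"], 0)

  # one peak exactly midway between two targets 0.8 Da apart
  toy <- toyTargets(c("PC 34:1", "PC 34:2"), c(760.0, 760.8))
  t3 <- matchTargets(mkPeaks(760.4), toy, wellId = "w")
  expect_true(t3$matched[t3$expected_mz == 760.0])
  expect_false(t3$matched[t3$expected_mz == 760.8])

  expect_error(matchTargets(mkPeaks(700), toyTargets(character(0), numeric(0))),
               "empty target list")
})

test_that("deisotoping subtracts the neighbour M+2 and clamps at zero", {
  r2 <- oracleIsotopeEnvelope(c(C = 42, H = 80, N = 1, O = 8, P = 1))[3]
  tab <- data.frame(
    well_id = "w",
    species = c("PC 34:2", "PC 34:1"),
    expected_mz = c(adductMz("PC 34:2"), adductMz("PC 34:1")),
    centroid_mz = c(adductMz("PC 34:2"), adductMz("PC 34:1")),
    raw_area = c(1000, 500), height = c(1, 1), snr = c(10, 10),
    matched = TRUE)
  out <- deisotope(tab)
  expect_equal(out$deisotoped_area[out$species == "PC 34:2"], 1000)
  expect_equal(out$deisotoped_area[out$species == "PC 34:1"],
               500 - 1000 * r2, tolerance = 1e-9)

  # no matched lighter neighbour: unchanged
  lone <- tab[2, ]
  expect_equal(deisotope(lone)$deisotoped_area, 500)

  # correction larger than the raw area: clamp to zero with a warning
  tab$raw_area <- c(10000, 500)
  expect_warning(out2 <- deisotope(tab), "clamped")
  expect_equal(out2$deisotoped_area[out2$species == "PC 34:1"], 0)
})

test_that("deisotoping corrects cross-class M+1 overlap and is idempotent", {
  # SM 38:1 sits ~0.065 Da above the M+1 of PC 34:2
  r1 <- oracleIsotopeEnvelope(c(C = 42, H = 80, N = 1, O = 8, P = 1))[2]
  tab <- data.frame(
    well_id = "w",
    species = c("PC 34:2", "SM 38:1"),
    expected_mz = c(adductMz("PC 34:2"), adductMz("SM 38:1")),
    centroid_mz = NA, raw_area = c(1000, 600), height = 1, snr = 10,
    matched = TRUE)
  out <- deisotope(tab)
  expect_equal(out$deisotoped_area[out$species == "SM 38:1"],
               600 - 1000 * r1, tolerance = 1e-9)

  fx <- singleCellFixture()
  one <- fx$tabs[fx$tabs$well_id == fx$layout$well_id[5], ]
  once <- one[order(one$expected_mz), ]
  twice <- suppressWarnings(deisotope(deisotope(one)))
  again <- suppressWarnings(deisotope(one))
  expect_equal(twice$deisotoped_area, again$deisotoped_area, tolerance = 1e-12)
})

test_that("detection filters apply the S/N and relative-intensity cuts", {
  tab <- data.frame(
    well_id = "w", species = c("PC 34:1", "PC 34:2", "PC 36:2"),
    expected_mz = 1:3, centroid_mz = 1:3,
    raw_area = c(10000, 500, 0.1), deisotoped_area = c(10000, 500, 0.1),
    snr = c(100, 3.9, 50), matched = TRUE)
  out <- applyFilters(tab)
  expect_true(out$pass_filters[1])
  expect_false(out$pass_filters[2])
  expect_equal(out$filter_reason[2], "snr")
  expect_false(out$pass_filters[3])  # 0.1 of 10000 is 0.001% < 0.1%
  expect_equal(out$filter_reason[3], "min_intensity")

  tab$snr <- c(100, 50, 50); tab$deisotoped_area <- c(10000, 500, 20)
  out2 <- applyFilters(tab)
  expect_true(all(out2$pass_filters))
  expect_identical(out2$raw_area, tab$raw_area)
})

test_that("raising the S/N threshold never admits new species", {
  fx <- singleCellFixture()
  one <- fx$tabs[fx$tabs$well_id == fx$layout$well_id[7], ]
  prev <- NULL
  for (thr in c(2, 4, 8, 16)) {
    pass <- applyFilters(one, minSnr = thr)
    set <- pass$species[pass$pass_filters]
    if (!is.null(prev)) expect_true(all(set %in% prev))
    prev <- set
  }
})

test_that("pipeline S/N agrees with truth on single-cell spectra", {
  fx <- singleCellFixture()
  params <- simParams()
  singles <- fx$layout$well_id[fx$layout$role == "single_cell"]
  trueNoise <- sqrt(params$baselineSd^2 +
                      params$shotFactor^2 * params$baselineLevel)
  sigma <- params$fwhm / (2 * sqrt(2 * log(2)))
  ok <- vapply(singles[1:5], function(wid) {
    tab <- fx$tabs[fx$tabs$well_id == wid, ]
    base <- tab[which.max(tab$snr), ]
    truth <- fx$sim$truth
    tf <- truth$fmol[truth$well_id == wid & truth$species == base$species]
    trueHeight <- tf * params$responsePerFmol / (sigma * sqrt(2 * pi))
    abs(base$snr / (trueHeight / trueNoise) - 1) < 0.3
  }, TRUE)
  expect_true(all(ok))
})

test_that("noiseless processing recovers amounts proportionally", {
  prof <- defaultProfiles()$C2C12
  prof$cvBiological <- 0
  amt <- c(makeComposition(prof, "CON", nCells = 50),
           stats::setNames(c(1000, 1000), internalStandardNames()))
  pn <- noiselessParams(contaminants = noContam())
  sp <- renderSpectrum(amt, params = pn, wellId = "w")
  tab <- suppressWarnings(processSpectrum(sp))
  m <- merge(tab, data.frame(species = names(amt), true = unname(amt)))

  # species sitting on the M+1 of a large cross-class interferer are
  # corrected from a ~10x larger area and cannot be recovered to percent
  # precision at unit resolution; exclude them from the 2% bound
  e <- targetEntries(defaultTargetList())
  shift <- 1.0033548378
  overlapped <- vapply(seq_len(nrow(e)), function(i) {
    d <- e$expected_mz[i] - e$expected_mz - shift
    any(abs(d) <= 0.15 & e$name != e$name[i])
  }, TRUE)
  clean <- m$species %in% e$name[!overlapped]

  cls <- ifelse(grepl("^SM", m$species), "SM", "PC")
  classTotal <- stats::ave(m$true, cls, FUN = sum)
  big <- m$true >= 0.01 * classTotal & m$matched & clean
  resp <- m$deisotoped_area[big] / m$true[big]
  expect_gte(sum(big), 8)
  expect_lt(max(resp) / min(resp), 1.02 / 0.98)
})
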