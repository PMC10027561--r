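.mkTable <- function(species, deiso, snr = 50, pass = TRUE, well = "w") {
  data.frame(well_id = well, species = species,
             expected_mz = vapply(species, adductMz, 0.0),
             centroid_mz = NA_real_, raw_area = deiso,
             deisotoped_area = deiso, snr = snr, matched = TRUE,
             pass_filters = pass,
             filter_reason = ifelse(pass, "", "snr"))
}

.isnames <- unname(internalStandardNames())

test_that("extraction-blank subtraction is a clamped mean difference", {
  smp <- .mkTable(c("PC 34:1", "PC 34:2", .isnames), c(100, 20, 500, 400))
  b1 <- .mkTable(c("PC 34:1", "PC 34:2", .isnames), c(40, 35, 480, 410))
  b2 <- .mkTable(c("PC 34:1", "PC 34:2", .isnames), c(20, 25, 520, 390))
  out <- subtractBackground(smp, list(b1, b2))
  expect_equal(out$corrected_area[out$species == "PC 34:1"], 100 - 30)
  expect_equal(out$corrected_area[out$species == "PC 34:2"], 0)  # clamped
  # internal standards are never blank-subtracted
  expect_equal(out$corrected_area[out$species == .isnames[1]], 500)
  expect_error(subtractBackground(smp, list()), "at least one blank")

  # a blank subtracted against the blank set goes to ~zero
  self <- subtractBackground(b1, list(b1, b2))
  nonIS <- !self$species %in% .isnames
  expect_true(all(self$corrected_area[nonIS] <= 15))
  expect_equal(subtractBackground(b1, list(b1))$corrected_area[1], 0)
})

test_that("internal-standard ratioing yields the spiked scale", {
  fifty <- list(well_id = "F1", is_pc_fmol = 1000, is_sm_fmol = 1000)
  single <- list(well_id = "S1", is_pc_fmol = 1.38, is_sm_fmol = 1.38)
  tab <- .mkTable(c("PC 34:1", "PC 36:2", "SM 34:1", .isnames),
                  c(800, 400, 300, 800, 600))
  tab$corrected_area <- tab$deisotoped_area

  q50 <- quantifyWell(tab, fifty)
  expect_equal(unname(q50["PC 34:1"]), 1000)        # equal areas
  expect_equal(unname(q50["PC 36:2"]), 500)         # half the IS area
  # SM species ratio against the SM standard even though the PC IS is larger
  expect_equal(unname(q50["SM 34:1"]), 300 / 600 * 1000)

  q1 <- quantifyWell(tab, single)
  expect_equal(unname(q1["PC 34:1"]), 1.38)

  # failed IS peak leaves the well unquantifiable
  bad <- tab
  bad$pass_filters[bad$species == .isnames[1]] <- FALSE
  expect_warning(expect_null(quantifyWell(bad, fifty)), "unquantifiable")

  # species failing filters are reported as zero, not dropped
  part <- tab
  part$pass_filters[part$species == "PC 36:2"] <- FALSE
  expect_equal(unname(quantifyWell(part, fifty)["PC 36:2"]), 0)
})

test_that("percent composition sums to 100 and ignores global scale", {
  mat <- matrix(c(6, 3, 1, 2, 12, 6, 2, 4), nrow = 4,
                dimnames = list(c("PC 34:1", "PC 34:2", "SM 34:1", "SM 36:1"),
                                c("w1", "w2")))
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(fmol = mat))
  qt <- new("QuantTable", se)
  pct <- percentComposition(qt, "class_PC")
  expect_equal(colSums(pct), c(w1 = 100, w2 = 100))
  expect_equal(pct["PC 34:1", "w1"], 6 / 9 * 100)
  # doubling every amount leaves percentages unchanged
  expect_equal(pct[, "w1"], pct[, "w2"])

  one <- new("QuantTable", SummarizedExperiment::SummarizedExperiment(
    assays = list(fmol = mat["SM 34:1", , drop = FALSE])))
  expect_equal(unname(percentComposition(one, "class_SM")[1, ]), c(100, 100))
  expect_error(percentComposition(one, "class_PC"), "no quantified species")
})

test_that("polyunsaturation summary isolates the >= 6 double-bond pool", {
  mat <- matrix(c(5, 3, 2, 1), nrow = 4,
                dimnames = list(c("PC 34:1", "PC 38:6", "PC 40:7", "SM 34:1"),
                                "w1"))
  qt <- new("QuantTable",
            SummarizedExperiment::SummarizedExperiment(assays = list(fmol = mat)))
  expect_equal(unname(polyunsaturationSummary(qt)), 5 / 10)
  low <- new("QuantTable", SummarizedExperiment::SummarizedExperiment(
    assays = list(fmol = mat[c("PC 34:1", "SM 34:1"), , drop = FALSE])))
  expect_equal(unname(polyunsaturationSummary(low)), 0)
  hi <- new("QuantTable", SummarizedExperiment::SummarizedExperiment(
    assays = list(fmol = mat["PC 38:6", , drop = FALSE])))
  expect_equal(unname(polyunsaturationSummary(hi)), 1)
})

test_that("quantification is linear and invariant to response rescaling", {
  prof <- defaultProfiles()$HepG2
  prof$cvBiological <- 0
  pn <- noiselessParams(contaminants = noContam())
  layoutRow <- list(well_id = "w", is_pc_fmol = 1000, is_sm_fmol = 1000)
  blank <- suppressWarnings(processSpectrum(renderSpectrum(
    stats::setNames(c(1000, 1000), .isnames), params = pn, wellId = "b")))

  quantify1 <- function(k, gain = 1) {
    amt <- c(makeComposition(prof, "CON", nCells = 50) * k,
             stats::setNames(c(1000, 1000), .isnames))
    sp <- renderSpectrum(amt, params = pn, wellId = "w")
    sp@intensity <- sp@intensity * gain
    tab <- suppressWarnings(processSpectrum(sp))
    tab <- subtractBackground(tab, list(blank))
    quantifyWell(tab, layoutRow)
  }
  q1 <- quantify1(1)
  q3 <- quantify1(3)
  # species on a cross-class M+1 collision are dominated by the
  # overlap correction, not by their own signal; judge linearity on the
  # directly measured ones
  e <- targetEntries(defaultTargetList())
  shift <- 1.0033548378
  onM1 <- vapply(seq_len(nrow(e)), function(i)
    any(abs(e$expected_mz[i] - e$expected_mz - shift) <= 0.15 &
          e$name != e$name[i]), TRUE)
  keep <- q1 > 0.01 * sum(q1) & names(q1) %in% e$name[!onM1]
  expect_equal(unname(q3[keep] / q1[keep]), rep(3, sum(keep)),
               tolerance = 0.01)

  # a global instrument-response rescaling of the spectrum cancels out
  qg <- quantify1(1, gain = 2.5)
  expect_equal(unname(qg[keep]), unname(q1[keep]), tolerance = 1e-6)
})

test_that("single-cell amounts recover ground truth within tolerance", {
  fx <- singleCellFixture()
  a <- SummarizedExperiment::assay(fx$qt, "fmol")
  truth <- fx$sim$truth
  singles <- fx$layout$well_id[fx$layout$role == "single_cell"]
  singles <- intersect(singles, colnames(a))
  expect_gte(length(singles), 8)
  errs <- c()
  for (wid in singles) {
    tw <- truth[truth$well_id == wid, ]
    tw <- tw[!tw$species %in% .isnames, ]
    tot <- sum(tw$fmol)
    major <- tw[tw$fmol >= 0.05 * tot, ]
    est <- a[major$species, wid]
    errs <- c(errs, abs(est - major$fmol) / major$fmol)
  }
  expect_lte(stats::median(errs), 0.20)
})

test_that("wells-by-species matrix transposes the fmol assay", {
  fx <- singleCellFixture()
  m <- quantMatrix(fx$qt)
  expect_equal(dim(m), rev(dim(fx$qt)))
  expect_equal(m["A4", "PC 34:1"],
               SummarizedExperiment::assay(fx$qt, "fmol")["PC 34:1", "A4"])
})
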