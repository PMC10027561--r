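# Shared simulated fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# One C2C12 group: 3 extraction blanks, 3 fifty-cell and 10 single-cell
# wells under default noise, processed through the full detection chain.
singleCellFixture <- function() {
  .cached("singleCell", function() {
    layout <- rbind(
      bulkComparisonLayout("C2C12", "CON", nBulk = 0, nFifty = 3, nBlank = 3),
      local({
        l <- dhaExperimentLayout(lines = "C2C12", nSingle = 10, nFifty = 0,
                                 nBlank = 0)
        l <- l[l$treatment == "CON", ]
        l$well_id <- paste0("B", seq_len(nrow(l)))
        l
      }))
    layout$well_id <- make.unique(layout$well_id)
    validatePlateLayout(layout)
    sim <- simulatePlate(layout, seed = 42)
    tabs <- suppressWarnings(processWells(sim$spectra))
    qt <- quantifyPlate(tabs, layout)
    list(layout = layout, sim = sim, tabs = tabs, qt = qt)
  })
}

# Four prostate lines x 12 single cells + blanks, quantified; used by
# the embedding and heterogeneity checks.
prostateFixture <- function() {
  .cached("prostate", function() {
    layout <- prostatePanelLayout(nSingle = 12, nFifty = 0, nBlank = 3)
    sim <- simulatePlate(layout, seed = 7)
    tabs <- suppressWarnings(suppressMessages(processWells(sim$spectra)))
    qt <- quantifyPlate(tabs, layout)
    list(layout = layout, sim = sim, tabs = tabs, qt = qt)
  })
}

noContam <- function() data.frame(mz = numeric(0), area = numeric(0))
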