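#' Run configuration
#'
#' Nested list of paths and parameters steering the three pipeline
#' stages. Defaults are the workflow's standard settings (0.5 Da
#' tolerance, 0.1% minimum intensity, S/N >= 4, perplexity ~ sqrt(N),
#' alpha 0.05), so a bare run reproduces the standard analysis shape.
#' `readRunConfig()` loads a YAML file and merges it over the defaults.
#'
#' @return nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    paths = list(targets = NULL, layout = NULL, spectra_dir = "spectra",
                 out_dir = "."),
    sim = list(scenario = "dha_experiment", format = "tsv"),
    processing = list(tolerance = 0.5, min_snr = 4, min_intensity_pct = 0.1,
                      smooth_window = 0.3),
    quant = list(blank_aggregation = "mean"),
    stats = list(degree = 2, ci = 0.95, perplexity = NULL, alpha = 0.05),
    seed = 1L
  )
}

#' @rdname defaultRunConfig
#' @param path YAML configuration file.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]]))
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge2(cfg, user)
  .checkRunConfig(cfg)
  cfg
}

.checkRunConfig <- function(cfg) {
  p <- cfg$processing
  stopifnot(p$tolerance > 0, p$tolerance <= 1.0, p$min_snr > 0,
            p$min_intensity_pct > 0, p$smooth_window > 0)
  invisible(cfg)
}

.loadTargets <- function(cfg) {
  if (is.null(cfg$paths$targets)) defaultTargetList()
  else loadTargetList(cfg$paths$targets)
}

#' Simulate a plate dataset onto disk
#'
#' Builds the layout for the requested scenario (`"dha_experiment"`:
#' 2 cell lines x 2 treatments x (3 blanks + 3 fifty-cell + 18
#' single-cell wells); `"prostate_panel"`: 4 prostate lines x (3
#' fifty-cell + 18 single-cell) + blanks; `"custom"`: layout read from
#' `config$paths$layout`), simulates every well and writes spectra,
#' `layout.csv`, `ground_truth.csv` and a `manifest.yaml` echoing the
#' configuration under `outDir`.
#'
#' @param outDir output directory.
#' @param scenario one of `"dha_experiment"`, `"prostate_panel"`,
#'   `"custom"`.
#' @param seed integer seed.
#' @param config run configuration (see [defaultRunConfig()]).
#' @param params rendering parameters (see [simParams()]).
#' @return the simulation result of [simulatePlate()], invisibly.
#' @export
runSimulate <- function(outDir, scenario = c("dha_experiment",
                                             "prostate_panel", "custom"),
                        seed = 1L, config = defaultRunConfig(),
                        params = simParams()) {
  scenario <- match.arg(scenario)
  layout <- switch(scenario,
    dha_experiment = dhaExperimentLayout(),
    prostate_panel = prostatePanelLayout(),
    custom = {
      if (is.null(config$paths$layout))
        stop("custom scenario needs config$paths$layout")
      readPlateLayout(config$paths$layout)
    })
  targets <- .loadTargets(config)
  sim <- simulatePlate(layout, profiles = defaultProfiles(),
                       targets = targets, params = params, seed = seed)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  writeSpectra(sim$spectra, file.path(outDir, "spectra"),
               format = config$sim$format)
  writePlateLayout(sim$layout, file.path(outDir, "layout.csv"))
  utils::write.csv(sim$truth, file.path(outDir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- config
  manifest$seed <- as.integer(seed)
  manifest$sim$scenario <- scenario
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  message("simulated ", nrow(layout), " wells (", scenario, ") into ", outDir)
  invisible(sim)
}

#' Process a simulated or acquired plate on disk
#'
#' Runs the detection chain (smooth, pick, match, deisotope, filter) on
#' every spectrum under `dir/spectra`, subtracts extraction blanks and
#' quantifies against the internal standards, logging per-well species
#' counts. Writes `peak_table.csv`, `quant_long.csv` and
#' `quant_wide.csv` (wells x species) under `dir`.
#'
#' @param dir dataset directory (as written by [runSimulate()]).
#' @param config run configuration.
#' @return the [QuantTable-class], invisibly.
#' @export
runProcess <- function(dir, config = defaultRunConfig()) {
  layout <- readPlateLayout(file.path(dir, "layout.csv"))
  targets <- .loadTargets(config)
  spectra <- readSpectra(file.path(dir, "spectra"))
  missing <- setdiff(layout$well_id, names(spectra))
  if (length(missing))
    stop("no spectrum found for wells: ", paste(missing, collapse = ", "))
  p <- config$processing
  tabs <- lapply(layout$well_id, function(wid) {
    tab <- processSpectrum(spectra[[wid]], targets,
                           tolerance = p$tolerance,
                           smoothWindow = p$smooth_window,
                           minIntensityPct = p$min_intensity_pct,
                           minSnr = p$min_snr)
    message(sprintf("well %s [%s]: %d/%d species pass filters", wid,
                    layout$role[layout$well_id == wid],
                    sum(tab$pass_filters), nrow(tab)))
    tab
  })
  names(tabs) <- layout$well_id
  full <- do.call(rbind, tabs)
  writePeakTable(full, file.path(dir, "peak_table.csv"))

  qt <- quantifyPlate(tabs, layout, targets,
                      aggregate = config$quant$blank_aggregation)
  if (ncol(qt) == 0) {
    warning("no quantifiable sample wells; empty quantification table")
  }
  a <- SummarizedExperiment::assay(qt, "fmol")
  long <- data.frame(well_id = rep(colnames(a), each = nrow(a)),
                     species = rep(rownames(a), times = ncol(a)),
                     fmol = as.vector(a))
  utils::write.csv(long, file.path(dir, "quant_long.csv"), row.names = FALSE,
                   quote = FALSE)
  wide <- cbind(data.frame(well_id = colnames(a)), as.data.frame(t(a)))
  utils::write.csv(wide, file.path(dir, "quant_wide.csv"), row.names = FALSE)
  invisible(qt)
}

.readQuantWide <- function(dir) {
  wide <- utils::read.csv(file.path(dir, "quant_wide.csv"),
                          check.names = FALSE)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$well_id
  mat
}

#' Heterogeneity analysis of a processed plate
#'
#' Reads the quantification table written by [runProcess()] and emits
#' the heterogeneity reports: per-group CV-versus-mean analyses over
#' single cells, Welch comparisons for the contrasts the layout supports
#' (bulk vs fifty-cell within line/treatment; CON vs DHA over single
#' cells within line), PCA scores/loadings and (for >= 8 single cells) a
#' t-SNE embedding, plus static plots. All outputs land under `dir`.
#'
#' @param dir dataset directory holding `quant_wide.csv` + `layout.csv`.
#' @param seed seed for the t-SNE stage.
#' @param config run configuration.
#' @return list of the computed reports, invisibly.
#' @export
runAnalyze <- function(dir, seed = 1L, config = defaultRunConfig()) {
  layout <- readPlateLayout(file.path(dir, "layout.csv"))
  mat <- .readQuantWide(dir)
  info <- layout[match(rownames(mat), layout$well_id), ]
  stats_cfg <- config$stats
  out <- list()

  singles <- info$role == "single_cell"
  groups <- interaction(info$cell_line, info$treatment, drop = TRUE)

  # CV-vs-mean per single-cell group
  cvReports <- list()
  for (g in levels(droplevels(groups[singles]))) {
    rows <- singles & groups == g
    if (sum(rows, na.rm = TRUE) < 3) next
    cvr <- cvMeanAnalysis(mat[which(rows), , drop = FALSE],
                          degree = stats_cfg$degree, ci = stats_cfg$ci)
    cvReports[[g]] <- cvr
    utils::write.csv(cvr$species,
                     file.path(dir, paste0("cv_mean_", gsub("[^A-Za-z0-9]", "_", g), ".csv")),
                     row.names = FALSE)
  }
  out$cv_mean <- cvReports

  # Welch contrasts: bulk vs fifty within line/treatment; CON vs DHA singles
  welchReports <- list()
  for (g in levels(droplevels(groups))) {
    bulkRows <- which(info$role == "bulk" & groups == g)
    fiftyRows <- which(info$role == "fifty_cells" & groups == g)
    if (length(bulkRows) >= 2 && length(fiftyRows) >= 2) {
      # compare composition (percent of total), the relative-intensity scale
      pct <- function(m) m / rowSums(m) * 100
      welchReports[[paste0("bulk_vs_fifty.", g)]] <-
        welchCompare(pct(mat[bulkRows, , drop = FALSE]),
                     pct(mat[fiftyRows, , drop = FALSE]),
                     alpha = stats_cfg$alpha)
    }
  }
  for (line in unique(stats::na.omit(info$cell_line))) {
    conRows <- which(singles & info$cell_line == line & info$treatment == "CON")
    dhaRows <- which(singles & info$cell_line == line & info$treatment == "DHA")
    if (length(conRows) >= 2 && length(dhaRows) >= 2) {
      welchReports[[paste0("con_vs_dha.", line)]] <-
        welchCompare(mat[conRows, , drop = FALSE],
                     mat[dhaRows, , drop = FALSE], alpha = stats_cfg$alpha)
    }
  }
  for (nm in names(welchReports))
    utils::write.csv(welchReports[[nm]],
                     file.path(dir, paste0("welch_", gsub("[^A-Za-z0-9]", "_", nm), ".csv")),
                     row.names = FALSE)
  out$welch <- welchReports

  # Embeddings over single cells, on the relative-intensity scale
  # (percent of each cell's total): per-cell totals carry cell-size
  # variability that would otherwise dominate every component.
  if (sum(singles) >= 3) {
    smat <- mat[which(singles), , drop = FALSE]
    tot <- rowSums(smat)
    smat <- smat[tot > 0, , drop = FALSE] / tot[tot > 0] * 100
    pca <- pcaEmbed(smat)
    scores <- data.frame(well_id = rownames(smat),
                         cell_line = info$cell_line[singles],
                         treatment = info$treatment[singles],
                         pca$scores[, seq_len(min(4, ncol(pca$scores)))])
    utils::write.csv(scores, file.path(dir, "pca_scores.csv"), row.names = FALSE)
    out$pca <- pca
    if (sum(singles) >= 8) {
      coords <- tsneEmbed(smat, perplexity = stats_cfg$perplexity, seed = seed)
      tsne <- data.frame(well_id = rownames(smat),
                         cell_line = info$cell_line[singles],
                         treatment = info$treatment[singles], coords)
      utils::write.csv(tsne, file.path(dir, "tsne.csv"), row.names = FALSE)
      out$tsne <- tsne
    } else message("fewer than 8 single cells; skipping t-SNE")
    .analysisPlots(dir, out)
  }
  invisible(out)
}

.analysisPlots <- function(dir, out) {
  grDevices::pdf(file.path(dir, "analysis_plots.pdf"), width = 7, height = 6)
  on.exit(grDevices::dev.off())
  for (g in names(out$cv_mean)) {
    sp <- out$cv_mean[[g]]$species
    ord <- order(sp$mean)
    graphics::plot(sp$mean, sp$cv, log = "x", pch = 19,
                   col = ifelse(sp$outlier, "red", "grey30"),
                   xlab = "mean amount (fmol)", ylab = "CV (%)",
                   main = paste("CV vs mean:", g))
    graphics::lines(sp$mean[ord], sp$fit[ord], col = "blue")
    graphics::lines(sp$mean[ord], sp$lwr[ord], col = "blue", lty = 2)
    graphics::lines(sp$mean[ord], sp$upr[ord], col = "blue", lty = 2)
  }
  if (!is.null(out$pca)) {
    sc <- out$pca$scores
    graphics::plot(sc[, 1], sc[, 2], pch = 19,
                   xlab = sprintf("PC1 (%.1f%%)", 100 * out$pca$varianceFraction[1]),
                   ylab = sprintf("PC2 (%.1f%%)", 100 * out$pca$varianceFraction[2]),
                   main = "PCA of single cells")
  }
  if (!is.null(out$tsne)) {
    cols <- as.integer(factor(out$tsne$cell_line))
    graphics::plot(out$tsne$tsne1, out$tsne$tsne2, pch = 19, col = cols,
                   xlab = "t-SNE 1", ylab = "t-SNE 2",
                   main = "t-SNE of single cells")
  }
}

#' Run the full pipeline
#'
#' [runSimulate()], [runProcess()] and [runAnalyze()] in sequence; with
#' a fixed seed the whole chain is byte-stable across runs.
#'
#' @inheritParams runSimulate
#' @export
runPipeline <- function(outDir, scenario = "dha_experiment", seed = 1L,
                        config = defaultRunConfig(), params = simParams()) {
  runSimulate(outDir, scenario, seed = seed, config = config, params = params)
  runProcess(outDir, config = config)
  runAnalyze(outDir, seed = seed, config = config)
}
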