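#' Read and write spectra
#'
#' Spectra interchange in two formats: plain two-column TSV peak lists
#' (`mz`, `intensity`, one file per well, well id taken from the file
#' name) and mzML via the Bioconductor `mzR` package when installed (one
#' spectrum per file for writing; all spectra of a file on reading, well
#' ids from `<file>#<scan>` unless the file holds a single spectrum).
#'
#' @param path file to read, or a directory of `.tsv` files.
#' @param mode spectrum mode to stamp on TSV input (`"profile"` or
#'   `"centroid"`).
#' @return `readSpectra()` returns a named list of [Spectrum-class].
#' @export
readSpectra <- function(path, mode = "profile") {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tsv|mzML)$", full.names = TRUE)
    if (!length(files)) stop("no spectrum files found under ", path)
    out <- list()
    for (f in files) out <- c(out, readSpectra(f, mode = mode))
    return(out)
  }
  if (grepl("\\.mzML$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh))
    n <- nrow(mzR::header(fh))
    base <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
    out <- lapply(seq_len(n), function(i) {
      p <- mzR::peaks(fh, i)
      wid <- if (n == 1) base else paste0(base, "#", i)
      new("Spectrum", mz = p[, 1], intensity = pmax(p[, 2], 0),
          mode = mode, wellId = wid)
    })
    names(out) <- vapply(out, wellId, "")
    return(out)
  }
  df <- utils::read.delim(path, comment.char = "#")
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("TSV spectrum needs 'mz' and 'intensity' columns: ", path)
  wid <- sub("\\.tsv$", "", basename(path))
  sp <- new("Spectrum", mz = df$mz, intensity = pmax(df$intensity, 0),
            mode = mode, wellId = wid)
  stats::setNames(list(sp), wid)
}

#' @rdname readSpectra
#' @param spectra named list of [Spectrum-class] objects.
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"mzML"`.
#' @return `writeSpectra()` returns the written paths, invisibly.
#' @export
writeSpectra <- function(spectra, dir, format = c("tsv", "mzML")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (format == "tsv") {
      paths[i] <- file.path(dir, paste0(wellId(sp), ".tsv"))
      utils::write.table(
        data.frame(mz = specMz(sp), intensity = specIntensity(sp)),
        paths[i], sep = "\t", row.names = FALSE, quote = FALSE)
    } else {
      if (!requireNamespace("mzR", quietly = TRUE))
        stop("writing mzML requires the mzR package")
      paths[i] <- file.path(dir, paste0(wellId(sp), ".mzML"))
      hdr <- .mzmlHeader(sp)
      mzR::writeMSData(list(cbind(specMz(sp), specIntensity(sp))),
                       paths[i], header = hdr)
    }
  }
  invisible(paths)
}

.mzmlHeader <- function(sp) {
  mz <- specMz(sp); y <- specIntensity(sp)
  data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = length(mz), totIonCurrent = sum(y),
    retentionTime = 0, basePeakMZ = if (length(mz)) mz[which.max(y)] else 0,
    basePeakIntensity = if (length(y)) max(y) else 0,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(mz), highMZ = max(mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("well=", wellId(sp)),
    centroided = specMode(sp) == "centroid", ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = min(mz),
    scanWindowUpperLimit = max(mz), stringsAsFactors = FALSE)
}

#' Read/write plate layout tables
#'
#' CSV columns: `well_id, role, cell_line, treatment, n_cells,
#' is_pc_fmol, is_sm_fmol`.
#'
#' @param path CSV path.
#' @export
readPlateLayout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("cell_line", "treatment"))
    if (col %in% names(df)) df[[col]][df[[col]] %in% c("", "NA")] <- NA_character_
  validatePlateLayout(df)
  df
}

#' @rdname readPlateLayout
#' @param layout plate-layout `data.frame`.
#' @export
writePlateLayout <- function(layout, path) {
  validatePlateLayout(layout)
  utils::write.csv(layout, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write an annotated peak table to CSV
#'
#' Emits the documented column set (`well_id, species, expected_mz,
#' centroid_mz, raw_area, deisotoped_area, snr, pass_filters,
#' filter_reason`, plus `corrected_area` when present).
#'
#' @param table annotated peak table.
#' @param path CSV path.
#' @export
writePeakTable <- function(table, path) {
  cols <- c("well_id", "species", "expected_mz", "centroid_mz", "raw_area",
            "deisotoped_area", "snr", "pass_filters", "filter_reason")
  if ("corrected_area" %in% names(table)) cols <- c(cols, "corrected_area")
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
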