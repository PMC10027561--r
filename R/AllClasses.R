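#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

#' Sum-composition lipid species
#'
#' A lipid identified at the sum-composition level: class (PC or SM),
#' linkage, total fatty-acyl (or sphingoid + acyl) carbons, and total
#' carbon-carbon double bonds. This is the level of structural detail a
#' class-specific precursor ion scan can deliver; sn-position, individual
#' acyl chains and double-bond positions are deliberately not modelled.
#'
#' @slot lipidClass `"PC"` or `"SM"`.
#' @slot linkage `"diacyl"`, `"ether"` (PC O-), or `"sphingoid"` (SM).
#' @slot totalCarbons integer, total side-chain carbons (>= 20).
#' @slot totalDoubleBonds integer, total C=C double bonds.
#' @slot displayName canonical name, e.g. `"PC 34:1"`; defined-acyl
#'   internal-standard names such as `"PC 17:0/17:0"` are retained verbatim.
#'
#' @seealso [parseSpeciesName()], [lipidFormula()], [adductMz()]
#' @export
setClass("LipidSpecies",
  representation(
    lipidClass = "character",
    linkage = "character",
    totalCarbons = "integer",
    totalDoubleBonds = "integer",
    displayName = "character"
  )
)

setValidity("LipidSpecies", function(object) {
  msg <- character()
  if (!object@lipidClass %in% c("PC", "SM"))
    msg <- c(msg, "lipidClass must be 'PC' or 'SM'")
  if (!object@linkage %in% c("diacyl", "ether", "sphingoid"))
    msg <- c(msg, "linkage must be 'diacyl', 'ether' or 'sphingoid'")
  if (object@lipidClass == "SM" && object@linkage != "sphingoid")
    msg <- c(msg, "SM species must have sphingoid linkage")
  if (object@lipidClass == "PC" && object@linkage == "sphingoid")
    msg <- c(msg, "PC species cannot have sphingoid linkage")
  if (object@totalCarbons < 20L)
    msg <- c(msg, "totalCarbons must be >= 20")
  if (object@totalDoubleBonds < 0L ||
      object@totalDoubleBonds > object@totalCarbons / 2)
    msg <- c(msg, "totalDoubleBonds must be in [0, totalCarbons/2]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LipidSpecies", function(object) {
  cat(sprintf("LipidSpecies: %s (%s %s, C%d:%d)\n",
              object@displayName, object@lipidClass, object@linkage,
              object@totalCarbons, object@totalDoubleBonds))
})

#' Target list of PC/SM species for precursor-ion-scan matching
#'
#' Wraps a table of lipid targets with their expected protonated m/z and
#' internal-standard annotation. Picked peaks are matched against this
#' list within a mass tolerance (0.5 Da by default).
#'
#' @slot entries a `data.frame` with columns `name`, `lipid_class`,
#'   `linkage`, `carbons`, `double_bonds`, `expected_mz`,
#'   `is_internal_standard`, `is_class`, `out_of_range`.
#'
#' @seealso [defaultTargetList()], [loadTargetList()]
#' @export
setClass("TargetList", representation(entries = "data.frame"))

setValidity("TargetList", function(object) {
  e <- object@entries
  need <- c("name", "lipid_class", "linkage", "carbons", "double_bonds",
            "expected_mz", "is_internal_standard", "is_class", "out_of_range")
  if (!all(need %in% names(e)))
    return(paste("entries must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$name))
    return("target names must be unique")
  bad <- !e$out_of_range &
    (e$expected_mz < 640 - 1e-9 | e$expected_mz > 850 + 1e-9)
  if (any(bad))
    return("entries outside 640-850 m/z must be flagged out_of_range")
  is_rows <- e[e$is_internal_standard, , drop = FALSE]
  if (any(is.na(is_rows$is_class)))
    return("internal-standard entries must declare is_class")
  TRUE
})

setMethod("show", "TargetList", function(object) {
  e <- object@entries
  cat(sprintf(
    "TargetList with %d entries (%d PC, %d SM; %d internal standards, %d out of range)\n",
    nrow(e), sum(e$lipid_class == "PC"), sum(e$lipid_class == "SM"),
    sum(e$is_internal_standard), sum(e$out_of_range)))
})

setMethod("length", "TargetList", function(x) nrow(x@entries))

#' @describeIn TargetList-class target entries as a `data.frame`.
#' @param tl a `TargetList`.
#' @export
targetEntries <- function(tl) {
  stopifnot(is(tl, "TargetList"))
  tl@entries
}

#' Direct-infusion spectrum of one well
#'
#' One well's precursor-ion-scan intensity trace over the 640-850 m/z
#' acquisition window, either as a dense profile or as integrated
#' centroids.
#'
#' @slot mz strictly increasing m/z axis (Da).
#' @slot intensity non-negative intensities, same length as `mz`.
#' @slot mode `"profile"` or `"centroid"`.
#' @slot wellId plate well identifier (e.g. `"A1"`).
#'
#' @export
setClass("Spectrum",
  representation(
    mz = "numeric",
    intensity = "numeric",
    mode = "character",
    wellId = "character"
  )
)

setValidity("Spectrum", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must have equal length")
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0))
    return("mz axis must be strictly increasing")
  if (any(object@intensity < 0))
    return("intensities must be non-negative")
  if (!object@mode %in% c("profile", "centroid"))
    return("mode must be 'profile' or 'centroid'")
  TRUE
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum [%s, %s]: %d points, m/z %.2f-%.2f, base intensity %.3g\n",
              object@wellId, object@mode, length(object@mz),
              min(object@mz), max(object@mz),
              if (length(object@intensity)) max(object@intensity) else NA_real_))
})

#' Spectrum accessors
#'
#' @param x a [Spectrum-class] object.
#' @return `specMz()` and `specIntensity()` return numeric vectors;
#'   `specMode()` and `wellId()` return length-1 characters.
#' @export
specMz <- function(x) { stopifnot(is(x, "Spectrum")); x@mz }

#' @rdname specMz
#' @export
specIntensity <- function(x) { stopifnot(is(x, "Spectrum")); x@intensity }

#' @rdname specMz
#' @export
specMode <- function(x) { stopifnot(is(x, "Spectrum")); x@mode }

#' @rdname specMz
#' @export
wellId <- function(x) { stopifnot(is(x, "Spectrum")); x@wellId }

#' Wells-by-species table of relative quantities
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with lipid species
#' as rows, wells as columns, a single `"fmol"` assay of internal-standard
#' relative quantities, the plate layout as `colData`, and the
#' internal-standard provenance (which IS, spiked amount and measured area
#' per well and class) in `metadata(x)$is_provenance`.
#'
#' @export
setClass("QuantTable", contains = "SummarizedExperiment")

setValidity("QuantTable", function(object) {
  if (!"fmol" %in% SummarizedExperiment::assayNames(object))
    return("QuantTable must carry a 'fmol' assay")
  a <- SummarizedExperiment::assay(object, "fmol")
  if (any(a < -1e-9, na.rm = TRUE))
    return("fmol amounts must be non-negative")
  TRUE
})

#' @describeIn QuantTable-class wells-by-species amount matrix (wells in
#'   rows), the orientation the heterogeneity statistics expect.
#' @param qt a `QuantTable`.
#' @export
quantMatrix <- function(qt) {
  stopifnot(is(qt, "QuantTable"))
  t(SummarizedExperiment::assay(qt, "fmol"))
}
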