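#' Subtract extraction-blank background
#'
#' Per species, the corrected area is
#' `max(0, deisotoped_area - aggregated blank deisotoped_area)` where the
#' aggregate is the mean (or median) over the batch's extraction blanks.
#' Internal-standard rows are left untouched: blanks are spiked with IS
#' too, so subtracting them there would destroy the quantification
#' reference.
#'
#' @param table annotated peak table of one sample well (filtered).
#' @param blanks list of annotated peak tables from extraction blanks.
#' @param targets the [TargetList-class] used for matching (identifies
#'   IS rows).
#' @param aggregate `"mean"` or `"median"`.
#' @return the table with a `corrected_area` column.
#' @export
subtractBackground <- function(table, blanks, targets = defaultTargetList(),
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!length(blanks)) stop("background subtraction needs at least one blank")
  if (is.data.frame(blanks)) blanks <- list(blanks)
  e <- targetEntries(targets)
  agg <- if (aggregate == "mean") mean else stats::median
  blankArea <- vapply(table$species, function(sp) {
    vals <- vapply(blanks, function(b) {
      v <- b$deisotoped_area[b$species == sp]
      if (length(v)) v[1] else 0
    }, 0.0)
    agg(vals)
  }, 0.0)
  isIS <- e$is_internal_standard[match(table$species, e$name)]
  isIS[is.na(isIS)] <- FALSE
  table$corrected_area <- ifelse(isIS, table$deisotoped_area,
                                 pmax(0, table$deisotoped_area - blankArea))
  table
}

#' Internal-standard relative quantification of one well
#'
#' Converts background-corrected areas to relative amounts:
#' `fmol(species) = corrected_area / corrected_area(class IS) *
#' spiked_fmol(class)`, with PC species (diacyl and ether) ratioed
#' against the PC internal standard and SM species against the SM one.
#' Species failing the detection filters are reported as 0. If either
#' class IS failed the filters the well is unquantifiable and `NULL` is
#' returned with a warning.
#'
#' @param table annotated peak table with `corrected_area` (see
#'   [subtractBackground()]).
#' @param well one-row slice of the plate layout (needs `is_pc_fmol`,
#'   `is_sm_fmol`, `well_id`).
#' @param targets the [TargetList-class] used for matching.
#' @return named vector of fmol per endogenous species (attribute
#'   `is_area` records the IS areas used), or `NULL` if unquantifiable.
#' @export
quantifyWell <- function(table, well, targets = defaultTargetList()) {
  e <- targetEntries(targets)
  info <- e[match(table$species, e$name), ]
  isRows <- which(info$is_internal_standard)
  isArea <- c(PC = NA_real_, SM = NA_real_)
  for (k in isRows) {
    cls <- info$is_class[k]
    if (!table$pass_filters[k]) {
      warning("well ", well$well_id, " unquantifiable: ", cls,
              " internal standard failed filters")
      return(NULL)
    }
    isArea[cls] <- table$corrected_area[k]
  }
  if (any(is.na(isArea))) {
    warning("well ", well$well_id, " unquantifiable: internal standard missing")
    return(NULL)
  }
  spike <- c(PC = well$is_pc_fmol, SM = well$is_sm_fmol)
  endo <- which(!info$is_internal_standard)
  fmol <- vapply(endo, function(k) {
    if (!table$pass_filters[k]) return(0)
    cls <- info$lipid_class[k]
    table$corrected_area[k] / isArea[[cls]] * spike[[cls]]
  }, 0.0)
  out <- stats::setNames(fmol, table$species[endo])
  attr(out, "is_area") <- isArea
  out
}

#' Quantify a processed plate into a QuantTable
#'
#' Applies extraction-blank subtraction and internal-standard
#' quantification to every non-blank well of a processed plate and
#' assembles the result into a [QuantTable-class] (species x wells,
#' `fmol` assay, layout in `colData`). Unquantifiable wells are dropped
#' with a warning.
#'
#' @param tables annotated peak tables: either one `data.frame` covering
#'   all wells (with `well_id`) or a named list per well.
#' @param layout plate layout covering all wells.
#' @param targets the [TargetList-class] used for matching.
#' @param aggregate blank aggregation, `"mean"` or `"median"`.
#' @return a [QuantTable-class]; wells are columns in layout order.
#' @export
quantifyPlate <- function(tables, layout, targets = defaultTargetList(),
                          aggregate = "mean") {
  validatePlateLayout(layout)
  if (is.data.frame(tables))
    tables <- split(tables, tables$well_id)
  blankIds <- layout$well_id[layout$role == "extraction_blank"]
  blanks <- tables[intersect(blankIds, names(tables))]
  sampleIds <- layout$well_id[layout$role != "extraction_blank"]
  sampleIds <- intersect(sampleIds, names(tables))

  e <- targetEntries(targets)
  speciesNames <- e$name[!e$is_internal_standard]
  mat <- matrix(NA_real_, nrow = length(speciesNames), ncol = length(sampleIds),
                dimnames = list(speciesNames, sampleIds))
  prov <- list()
  for (wid in sampleIds) {
    w <- layout[layout$well_id == wid, ]
    tab <- subtractBackground(tables[[wid]], blanks, targets,
                              aggregate = aggregate)
    fmol <- quantifyWell(tab, w, targets)
    if (is.null(fmol)) next
    mat[names(fmol), wid] <- fmol
    ia <- attr(fmol, "is_area")
    prov[[wid]] <- data.frame(well_id = wid, is_class = names(ia),
                              is_name = unname(internalStandardNames()[names(ia)]),
                              is_area = unname(ia),
                              is_fmol = c(w$is_pc_fmol, w$is_sm_fmol))
  }
  quantified <- colnames(mat)[colSums(is.na(mat)) == 0]
  mat <- mat[, quantified, drop = FALSE]
  cd <- layout[match(quantified, layout$well_id), ]
  rownames(cd) <- cd$well_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fmol = mat),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(is_provenance = do.call(rbind, prov))
  )
  new("QuantTable", se)
}

.speciesClass <- function(names) {
  vapply(names, function(nm) parseSpeciesName(nm)@lipidClass, "")
}

#' Percent composition per well
#'
#' Expresses each species' amount as a percent of the scope total within
#' its well: total PC (diacyl + ether), total SM, or all quantified
#' species. Percentages are invariant to any per-well rescaling of
#' areas, so they apply equally to wells quantified in fmol and wells
#' compared as relative intensity.
#'
#' @param qt a [QuantTable-class].
#' @param scope `"class_PC"`, `"class_SM"`, or `"total"`.
#' @return matrix of percentages (species x wells); each column sums to
#'   100 (NA for wells with zero total in scope).
#' @export
percentComposition <- function(qt, scope = c("class_PC", "class_SM", "total")) {
  scope <- match.arg(scope)
  a <- SummarizedExperiment::assay(qt, "fmol")
  cls <- .speciesClass(rownames(a))
  keep <- switch(scope,
    class_PC = cls == "PC",
    class_SM = cls == "SM",
    total = rep(TRUE, nrow(a)))
  if (!any(keep)) stop("no quantified species in scope ", scope)
  sub <- a[keep, , drop = FALSE]
  tot <- colSums(sub)
  pct <- sweep(sub, 2, tot, "/") * 100
  pct[, tot == 0] <- NA_real_
  pct
}

#' Polyunsaturated fraction of the PC pool per well
#'
#' Fraction of total quantified PC carried by species with at least
#' `dbThreshold` carbon-carbon double bonds -- with the default 6, the
#' docosahexaenoic-acid-containing species whose enrichment marks DHA
#' supplementation.
#'
#' @param qt a [QuantTable-class].
#' @param dbThreshold double-bond count defining polyunsaturated species.
#' @return named numeric vector, one fraction in `[0, 1]` per well.
#' @export
polyunsaturationSummary <- function(qt, dbThreshold = 6L) {
  a <- SummarizedExperiment::assay(qt, "fmol")
  sp <- lapply(rownames(a), parseSpeciesName)
  isPC <- vapply(sp, function(s) s@lipidClass == "PC", TRUE)
  highDb <- vapply(sp, function(s) s@totalDoubleBonds >= dbThreshold, TRUE)
  pcTot <- colSums(a[isPC, , drop = FALSE])
  puTot <- colSums(a[isPC & highDb, , drop = FALSE])
  out <- ifelse(pcTot > 0, puTot / pcTot, 0)
  stats::setNames(out, colnames(a))
}
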