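#' CV-versus-mean heterogeneity analysis
#'
#' For each species, computes the coefficient of variation (sd/mean, %)
#' across the wells of one group and regresses CV on the (log10) mean
#' amount with an ordinary-least-squares polynomial. Species whose CV
#' falls outside the pointwise confidence interval of the fitted line at
#' their mean are flagged as unusually homogeneous (below) or
#' heterogeneous (above) relative to the abundance trend; in
#' counting-limited data the CV falls with the mean, so the band is a
#' curve, not a constant. A prediction interval is returned alongside
#' for reference but is not used for flagging.
#'
#' @param mat wells x species amount matrix (one group of wells).
#' @param degree polynomial degree (default 2; 0 fits a horizontal line).
#' @param ci confidence level for the pointwise interval (default 0.95).
#' @param logMean regress on log10(mean) rather than mean.
#' @return list of class `CvMeanReport`: `species` (`data.frame` with
#'   `mean`, `cv`, `fit`, `lwr`, `upr`, `outlier`, `side`), `fit` (the
#'   `lm`), `degree`, `ci`, `excluded` (species with zero mean).
#' @export
cvMeanAnalysis <- function(mat, degree = 2L, ci = 0.95, logMean = TRUE) {
  stopifnot(is.matrix(mat) || is.data.frame(mat))
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("need at least 3 wells per species")
  m <- colMeans(mat)
  s <- apply(mat, 2, stats::sd)
  excluded <- colnames(mat)[m <= 0]
  if (length(excluded))
    message("excluding ", length(excluded), " species with zero mean: ",
            paste(excluded, collapse = ", "))
  keep <- m > 0
  if (sum(keep) < 5) stop("need at least 5 species with positive mean")
  m <- m[keep]; s <- s[keep]
  cv <- s / m * 100
  x <- if (logMean) log10(m) else m
  df <- data.frame(cv = cv, x = x)
  fit <- if (degree >= 1) {
    stats::lm(cv ~ stats::poly(x, degree = degree, raw = TRUE), data = df)
  } else stats::lm(cv ~ 1, data = df)
  conf <- stats::predict(fit, interval = "confidence", level = ci)
  # in-sample prediction bands are reported for reference; silence the
  # "future responses" note predict.lm emits for them
  pred <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = ci))
  side <- ifelse(cv > conf[, "upr"], "above",
                 ifelse(cv < conf[, "lwr"], "below", "within"))
  report <- data.frame(
    species = names(m), mean = unname(m), cv = unname(cv),
    fit = conf[, "fit"], lwr = conf[, "lwr"], upr = conf[, "upr"],
    pred_lwr = pred[, "lwr"], pred_upr = pred[, "upr"],
    outlier = side != "within", side = side,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(species = report, fit = fit, degree = degree, ci = ci,
                 logMean = logMean, excluded = excluded),
            class = "CvMeanReport")
}

#' @export
print.CvMeanReport <- function(x, ...) {
  cat(sprintf("CvMeanReport: %d species, degree-%d fit on %s, %g%% CI; %d outliers (%d above)\n",
              nrow(x$species), x$degree,
              if (x$logMean) "log10(mean)" else "mean",
              100 * x$ci, sum(x$species$outlier),
              sum(x$species$side == "above")))
  invisible(x)
}

#' Welch comparison of two well groups per species
#'
#' Unpaired two-sided t test with Welch's correction
#' (Satterthwaite degrees of freedom) per species, flagged at the raw
#' alpha (no multiple-testing correction, matching the convention of
#' reporting raw P < 0.05); Benjamini-Hochberg q-values are emitted
#' alongside for transparency. Species constant in both groups with
#' equal means get p = 1 by convention.
#'
#' @param groupA,groupB wells x species matrices with identical columns.
#' @param alpha significance threshold on the raw p-value.
#' @return `data.frame` with per-species group means, `t`, `df`, `p`,
#'   `q`, `significant`.
#' @export
welchCompare <- function(groupA, groupB, alpha = 0.05) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (!identical(colnames(groupA), colnames(groupB)))
    stop("groups must cover the same species, in the same order")
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("need at least 2 wells per group")
  res <- lapply(seq_len(ncol(groupA)), function(j) {
    a <- groupA[, j]; b <- groupB[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      return(data.frame(mean_a = mean(a), mean_b = mean(b),
                        t = if (eq) 0 else Inf,
                        df = NA_real_, p = if (eq) 1 else 0))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out <- cbind(species = colnames(groupA), out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Principal component analysis of a well-by-species matrix
#'
#' Centred and scaled PCA via singular-value decomposition. Constant
#' species (zero variance) cannot be scaled and are dropped with a
#' message. Loadings are returned both raw and as per-species
#' correlations with each component, the form used in loading plots.
#'
#' @param mat wells x species matrix.
#' @param scale,center passed to the decomposition (defaults follow the
#'   scaled-and-centred convention).
#' @return list with `scores` (wells x components), `loadings`,
#'   `correlations`, `varianceFraction` (non-increasing), `dropped`.
#' @export
pcaEmbed <- function(mat, scale = TRUE, center = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("PCA needs at least 3 wells")
  if (anyNA(mat)) stop("matrix must not contain missing values")
  dropped <- character(0)
  if (scale) {
    sds <- apply(mat, 2, stats::sd)
    dropped <- colnames(mat)[sds == 0]
    if (length(dropped)) {
      message("dropping ", length(dropped), " constant species before scaling")
      mat <- mat[, sds > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(mat, center = center, scale. = scale)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  corr <- sweep(pc$rotation, 2, pc$sdev, "*")
  if (scale) corr <- corr else
    corr <- sweep(corr, 1, apply(mat, 2, stats::sd), "/")
  list(scores = pc$x, loadings = pc$rotation, correlations = corr,
       varianceFraction = varFrac, dropped = dropped, prcomp = pc)
}

#' t-SNE embedding of a well-by-species matrix
#'
#' Two-dimensional t-distributed stochastic neighbour embedding with the
#' perplexity set to ~sqrt(N) by default (N = number of wells, minimum
#' 2) and exact (theta = 0) gradients; other settings follow the Rtsne
#' defaults, which do not standardise species individually (set
#' `scale = TRUE` to z-score species first). The embedding is
#' deterministic for a given seed.
#'
#' @param mat wells x species matrix with at least 8 wells.
#' @param perplexity t-SNE perplexity; default `round(sqrt(N))`. Values
#'   >= N/3 are reduced with a warning.
#' @param seed integer seed for the embedding initialisation.
#' @param scale centre and scale species before embedding (default
#'   `FALSE`, the Rtsne convention).
#' @return N x 2 matrix of coordinates, rownames = well ids.
#' @export
tsneEmbed <- function(mat, perplexity = NULL, seed = 1L, scale = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 8) stop("too few wells for t-SNE (need >= 8); consider pcaEmbed()")
  if (is.null(perplexity)) perplexity <- max(2L, round(sqrt(n)))
  if (perplexity >= n / 3) {
    newP <- max(2L, floor((n - 1) / 3))
    warning("perplexity ", perplexity, " too large for ", n,
            " wells; reduced to ", newP)
    perplexity <- newP
  }
  X <- mat
  if (scale) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 0, drop = FALSE])
  }
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, theta = 0,
                      check_duplicates = FALSE, pca = TRUE, max_iter = 1000)
  out <- fit$Y
  rownames(out) <- rownames(mat)
  colnames(out) <- c("tsne1", "tsne2")
  attr(out, "perplexity") <- perplexity
  out
}
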