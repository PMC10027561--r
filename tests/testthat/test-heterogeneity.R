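# Synthetic wells-by-species matrix with CV falling as mean rises,
# mimicking counting-limited single-cell abundances.
.cvTrendMatrix <- function(nWells = 20, nSpecies = 40, seed = 31,
                           inflate = integer(0), factor = 5) {
  set.seed(seed)
  means <- 10^seq(-1, 1.5, length.out = nSpecies)
  cv <- 0.15 + 0.5 / sqrt(means)
  cv[inflate] <- cv[inflate] * factor
  mat <- sapply(seq_len(nSpecies), function(j) {
    sdlog <- sqrt(log(1 + cv[j]^2))
    stats::rlnorm(nWells, log(means[j]) - sdlog^2 / 2, sdlog)
  })
  colnames(mat) <- sprintf("sp%02d", seq_len(nSpecies))
  mat
}

test_that("CV falls with mean and constant species have zero CV", {
  mat <- .cvTrendMatrix()
  mat[, 1] <- 2  # constant species
  cvr <- cvMeanAnalysis(mat)
  sp <- cvr$species
  expect_equal(sp$cv[sp$species == "sp01"], 0)
  expect_lt(stats::cor(sp$mean, sp$cv, method = "spearman"), 0)
})

test_that("CV analysis holds on pipeline-simulated single cells", {
  fx <- singleCellFixture()
  m <- quantMatrix(fx$qt)
  info <- fx$layout[match(rownames(m), fx$layout$well_id), ]
  singles <- info$role == "single_cell"
  cvr <- suppressMessages(cvMeanAnalysis(m[singles, ]))
  expect_lt(stats::cor(cvr$species$mean, cvr$species$cv,
                       method = "spearman"), 0)
})

test_that("a species with inflated biological CV is flagged above the band", {
  mat <- .cvTrendMatrix(inflate = 25, factor = 5)
  cvr <- cvMeanAnalysis(mat)
  row <- cvr$species[cvr$species$species == "sp25", ]
  expect_true(row$outlier)
  expect_equal(row$side, "above")
})

test_that("degree 0 gives a flat band and wider CIs shrink the flag set", {
  mat <- .cvTrendMatrix()
  r0 <- cvMeanAnalysis(mat, degree = 0)
  expect_equal(length(unique(round(r0$species$fit, 9))), 1)
  expect_equal(unique(r0$species$fit), mean(r0$species$cv), tolerance = 1e-9)

  flagged <- vapply(c(0.90, 0.95, 0.99), function(ci)
    sum(cvMeanAnalysis(mat, ci = ci)$species$outlier), 0L)
  expect_true(all(diff(flagged) <= 0))

  # species at zero are excluded with a notice
  mat0 <- mat; mat0[, 2] <- 0
  expect_message(r <- cvMeanAnalysis(mat0), "zero mean")
  expect_false("sp02" %in% r$species$species)
})

test_that("Welch comparison matches the closed-form oracle", {
  A <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "s"))
  B <- matrix(c(4, 5, 6), ncol = 1, dimnames = list(NULL, "s"))
  out <- welchCompare(A, B)
  expect_equal(out$t, -3.6742346, tolerance = 1e-6)
  expect_equal(out$df, 4)
  expect_equal(out$p, 0.0213116, tolerance = 1e-5)

  same <- welchCompare(A, A)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(17)
  for (i in 1:100) {
    a <- stats::rnorm(sample(2:8, 1), sd = stats::runif(1, 0.5, 3))
    b <- stats::rnorm(sample(2:8, 1), mean = stats::runif(1, -1, 1))
    got <- welchCompare(matrix(a, dimnames = list(NULL, "s")),
                        matrix(b, dimnames = list(NULL, "s")))
    want <- oracleWelch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }

  # both groups constant: p = 1 when equal, 0 when different
  C1 <- matrix(rep(2, 3), dimnames = list(NULL, "s"))
  C2 <- matrix(rep(5, 3), dimnames = list(NULL, "s"))
  expect_equal(welchCompare(C1, C1)$p, 1)
  expect_equal(welchCompare(C1, C2)$p, 0)
})

test_that("bulk and fifty-cell wells from one profile rarely differ", {
  layout <- bulkComparisonLayout("C2C12", "CON")
  sim <- simulatePlate(layout, seed = 101)
  tabs <- suppressWarnings(processWells(sim$spectra))
  qt <- quantifyPlate(tabs, layout)
  m <- quantMatrix(qt)
  pct <- m / rowSums(m) * 100
  info <- as.data.frame(SummarizedExperiment::colData(qt))
  A <- pct[info$role == "bulk", , drop = FALSE]
  B <- pct[info$role == "fifty_cells", , drop = FALSE]
  # compare species above 1% relative abundance, as in the published figure
  keep <- colMeans(rbind(A, B)) > 1
  out <- welchCompare(A[, keep], B[, keep])
  expect_gte(mean(!out$significant), 0.90)
})

test_that("PCA is well-ordered, scale-stable and reconstructs its input", {
  mat <- .cvTrendMatrix(nWells = 15, seed = 8)
  p <- pcaEmbed(mat)
  vf <- p$varianceFraction
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-9)

  # duplicating every well leaves the variance fractions unchanged
  # (compare the common leading ranks)
  p2 <- pcaEmbed(rbind(mat, mat))
  k <- seq_len(min(10, length(vf), length(p2$varianceFraction)))
  expect_equal(p2$varianceFraction[k], vf[k], tolerance = 1e-9)

  # scores x loadings' reproduces the scaled, centred matrix
  rec <- p$scores %*% t(p$loadings)
  expect_equal(rec, scale(mat)[, , drop = FALSE], tolerance = 1e-8,
               ignore_attr = TRUE)

  # two well-separated clusters split on component 1
  set.seed(9)
  cl <- rbind(matrix(stats::rnorm(10 * 6), 10),
              matrix(stats::rnorm(10 * 6, mean = 10), 10))
  colnames(cl) <- paste0("s", 1:6)
  sc <- pcaEmbed(cl)$scores[, 1]
  expect_true(max(sc[1:10]) < min(sc[11:20]) ||
                min(sc[1:10]) > max(sc[11:20]))

  con <- mat; con[, 3] <- 7
  expect_message(pd <- pcaEmbed(con), "constant species")
  expect_equal(pd$dropped, "sp03")
  expect_error(pcaEmbed(mat[1:2, ]), "at least 3 wells")
})

test_that("t-SNE follows the sqrt(N) perplexity rule deterministically", {
  mat <- .cvTrendMatrix(nWells = 72, seed = 12)
  t1 <- tsneEmbed(mat, seed = 4)
  expect_equal(attr(t1, "perplexity"), 8)  # round(sqrt(72))
  t2 <- tsneEmbed(mat, seed = 4)
  expect_identical(unclass(t1), unclass(t2))
  t3 <- tsneEmbed(mat, seed = 5)
  expect_false(identical(t1[, 1], t3[, 1]))

  small <- .cvTrendMatrix(nWells = 10, seed = 13)
  expect_warning(ts <- tsneEmbed(small, perplexity = 5, seed = 1),
                 "reduced to 3")
  expect_error(tsneEmbed(small[1:5, ]), "consider pcaEmbed")
})

test_that("prostate single cells cluster into the three broad groups", {
  fx <- prostateFixture()
  m <- quantMatrix(fx$qt)
  info <- fx$layout[match(rownames(m), fx$layout$well_id), ]
  singles <- info$role == "single_cell"
  pct <- m[singles, ] / rowSums(m[singles, ]) * 100
  coords <- tsneEmbed(pct, seed = 7)
  lines <- info$cell_line[singles]
  lab3 <- ifelse(lines %in% c("DU145", "PNT1"), "DU145/PNT1", lines)
  sil <- cluster::silhouette(as.integer(factor(lab3)), stats::dist(coords))
  expect_gt(mean(sil[, 3]), 0)
  expect_gte(length(unique(lab3)), 3)
})
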