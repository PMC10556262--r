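test_that("RGB to OD transform matches its closed form", {
  white <- array(255, c(1, 1, 3))
  expect_equal(as.vector(rgbToOd(white)), c(0, 0, 0))
  px <- array(255, c(1, 1, 3)); px[1, 1, 2] <- 25.5
  expect_equal(rgbToOd(px)[1, 1, 2], 1.0)
  expect_error(rgbToOd(matrix(1, 2, 2)), "RGB")

  # every representable 8-bit level round-trips exactly
  lev <- 0:255
  od <- -log10(pmax(lev, 1) / 255)
  arr <- array(0, c(length(od), 1, 3)); arr[, 1, 1] <- od
  back <- rgbToOd(odToRgb(arr, quantize = TRUE))
  expect_equal(back[, 1, 1], od, tolerance = 1e-12)
  # arbitrary OD <= 1.5 is recovered within half a quantisation gap
  odg <- seq(0, 1.5, by = 1e-4)
  arrg <- array(0, c(length(odg), 1, 3)); arrg[, 1, 1] <- odg
  backg <- rgbToOd(odToRgb(arrg, quantize = TRUE))
  halfGap <- log10(8.5 / 8)          # worst half-step around level 8
  expect_lt(max(abs(backg[, 1, 1] - odg)), halfGap + 1e-9)
})

test_that("deconvolution inverts Beer-Lambert composition", {
  sm <- hdabStainMatrix()
  od <- array(0, c(2, 2, 3))
  od[1, 1, ] <- 0.7 * sm@values["hematoxylin", ]
  res <- deconvolve(od, sm)
  expect_equal(res$concentrations[1, 1, ], c(hematoxylin = 0.7, dab = 0,
                                             residual = 0), tolerance = 1e-12)
  expect_equal(max(abs(res$concentrations[2, , ])), 0)
  expect_false(res$clipped)

  # round trip on a random nonnegative field
  set.seed(4)
  conc <- array(runif(30 * 30 * 3, 0, 1.2), c(30, 30, 3))
  back <- deconvolve(composeOd(conc, sm), sm)$concentrations
  expect_lt(max(abs(back - conc)), 1e-9)

  expect_error(stainMatrix(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)),
                           c("a", "b", "c")), "condition")
})

test_that("nucleus detection finds rendered nuclei with high overlap", {
  blank <- matrix(0, 64, 64)
  expect_equal(max(detectNuclei(blank)), 0)

  sl <- renderSlides(makeCellTable(25), width = 448, height = 448,
                     hormones = character(0), seed = 11)
  conc <- deconvolve(rgbToOd(sl$he), heStainMatrix())$concentrations
  nuc <- detectNuclei(conc[, , "hematoxylin"])
  m <- matchLabels(sl$nucleusMask, nuc)
  expect_equal(m$n_detected, 25)
  expect_true(all(m$iou > 0.8))
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.95)
})

test_that("watershed splitting separates touching nuclei", {
  # dumbbell: two equal circles touching on an OD image
  img <- matrix(0, 80, 44)
  xy <- expand.grid(x = 1:80, y = 1:44)
  img[as.matrix(xy[(xy$x - 21)^2 + (xy$y - 22)^2 <= 100 |
                   (xy$x - 41)^2 + (xy$y - 22)^2 <= 100, ])] <- 0.8
  pOn <- detectionParams(watershed = TRUE)
  pOff <- detectionParams(watershed = FALSE)
  expect_equal(max(detectNuclei(img, pOn)), 2)
  expect_equal(max(detectNuclei(img, pOff)), 1)
})

test_that("cell expansion is a nearest-nucleus Voronoi dilation", {
  # single circular nucleus radius 5 um, expansion 5 um -> disc radius 10 um
  nx <- 121
  nuc <- matrix(0L, nx, nx)
  nuc[rasterDisc(20, nx) > 0] <- 1L        # 20 px = 5 um at 0.25 um/px
  cell <- expandCells(nuc, expansion_um = 5, pixel_size = 0.25)
  areaUm <- sum(cell > 0) * 0.25^2
  expect_lt(abs(areaUm - pi * 100) / (pi * 100), 0.05)
  expect_true(all(cell[nuc > 0] == 1L))    # cell contains nucleus

  # zero expansion is the identity
  expect_identical(expandCells(nuc, 0, 0.25), nuc)

  # two equal nuclei 8 um apart: boundary on the perpendicular bisector
  m <- matrix(0L, 60, 100)
  xy <- expand.grid(r = 1:60, c = 1:100)
  m[as.matrix(xy[(xy$c - 34)^2 + (xy$r - 30)^2 <= 36, ])] <- 1L
  m[as.matrix(xy[(xy$c - 66)^2 + (xy$r - 30)^2 <= 36, ])] <- 2L
  cells <- expandCells(m, expansion_um = 10, pixel_size = 0.25)
  cols1 <- which(cells == 1L, arr.ind = TRUE)[, 2]
  cols2 <- which(cells == 2L, arr.ind = TRUE)[, 2]
  expect_lte(max(cols1), 50 + 1)
  expect_gte(min(cols2), 50 - 1)
  expect_equal(sum(cells == 1L), sum(cells == 2L))  # symmetric split
})

test_that("per-cell intensity applies the nuclear DAB correction", {
  nuc <- matrix(0L, 41, 41); nuc[rasterDisc(6, 41) > 0] <- 1L
  cell <- expandCells(nuc, expansion_um = 2, pixel_size = 0.25)
  ch <- matrix(0, 41, 41)
  ch[cell > 0 & nuc == 0] <- 0.5
  r <- perCellIntensity(ch, nuc, cell)
  expect_equal(r$corrected, 0.5)
  ch2 <- matrix(0.3, 41, 41)
  r2 <- perCellIntensity(ch2, nuc, cell)
  expect_equal(r2$corrected_raw, 0, tolerance = 1e-12)

  # nucleus-only cell: corrected value flagged missing
  r3 <- perCellIntensity(ch, nuc, nuc)
  expect_true(is.na(r3$corrected))

  # rendered positive cell with cytoplasm OD 0.6, nucleus OD 0.1
  ct <- makeCellTable(3, dab_cyto = 0.6, dab_nuc = 0.1, hormones = "GH")
  sl <- renderSlides(ct, width = 256, height = 256, hormones = "GH",
                     seed = 5)
  dab <- deconvolve(rgbToOd(sl$ihc$GH), hdabStainMatrix())$concentrations
  pc <- perCellIntensity(dab[, , "dab"], sl$nucleusMask, sl$cellMask)
  expect_true(all(abs(pc$corrected - 0.5) < 0.05))
})

test_that("region fractions are proportions over tissue", {
  m <- matrix(0L, 10, 10)
  m[1:60] <- 1L; m[61:90] <- 2L; m[91:100] <- 3L
  expect_equal(regionFractions(m),
               c(tumor = 0.6, stroma = 0.3, hemorrhage = 0.1))
  expect_equal(sum(regionFractions(m)), 1, tolerance = 1e-9)
  onlyTumor <- matrix(c(0L, 1L), 4, 4)
  expect_equal(unname(regionFractions(onlyTumor)), c(1, 0, 0))
  expect_error(regionFractions(matrix(0L, 4, 4)), "background")

  # generator links stroma burden to risk tier; rank test detects it
  coh <- generateCohort(cohortConfig(
    n_patients = 220, p_mc2 = 0.5, cells_per_patient = c(5L, 8L),
    subtype_probs = c("GH" = 0.25, "PRL" = 0.25, "GH+PRL" = 0, "TSH" = 0.25,
                      "GH+TSH" = 0, "PRL+TSH" = 0, "GH+PRL+TSH" = 0.25,
                      "PIT1" = 0), seed = 12))
  pat <- patients(coh)
  hi <- pat$stroma_frac[pat$tier == "high"]
  lo <- pat$stroma_frac[pat$tier == "low"]
  expect_gte(length(hi), 40); expect_gte(length(lo), 40)
  expect_lt(wilcox.test(hi, lo, alternative = "greater")$p.value, 0.05)

  # rendered region masks carry approximately the requested fractions
  sl <- renderSlides(makeCellTable(4), width = 160, height = 160,
                     hormones = character(0), stroma_frac = 0.25, seed = 3)
  fr <- regionFractions(sl$regionMask)
  expect_gt(fr["stroma"], 0.15)
})
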