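#' Names of the thirteen per-cell morphometric features
#'
#' Six nucleus shape features, the same six for the expanded cell, and
#' the nucleus-to-cell area ratio, in the fixed order used throughout the
#' package.
#' @return character vector of length 13.
#' @export
morphFeatureNames <- function() {
  c(paste0("nucleus_", c("area", "perimeter", "circularity", "maxcaliper",
                         "mincaliper", "eccentricity")),
    paste0("cell_", c("area", "perimeter", "circularity", "maxcaliper",
                      "mincaliper", "eccentricity")),
    "nucleus_cell_ratio")
}

#' Names of the 39 aggregated patient features
#'
#' Each of the thirteen morphometric features expanded as mean, 25th and
#' 75th percentile, in feature order.
#' @return character vector of length 39.
#' @export
patientFeatureNames <- function() {
  as.vector(t(outer(morphFeatureNames(), c("mean", "q25", "q75"),
                    paste, sep = "_")))
}

# closed traced contour of a binary mask (marching squares), smoothed by
# a circular moving average to undo the staircase bias of rasterisation
.tracedContour <- function(mask, window = 5) {
  cl <- contourLines(x = seq_len(nrow(mask)), y = seq_len(ncol(mask)),
                     z = mask, levels = 0.5)
  if (length(cl) == 0) stop("mask has no boundary")
  cl <- cl[[which.max(vapply(cl, function(c) length(c$x), 1))]]
  x <- cl$x; y <- cl$y; n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  half <- window %/% 2
  idx <- (outer(seq_len(n), -half:half, "+") - 1) %% n + 1
  cbind(rowMeans(matrix(x[idx], n)), rowMeans(matrix(y[idx], n)))
}

.polygonLength <- function(p) {
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

# min caliper width over convex-hull edges (rotating calipers)
.minFeret <- function(hull) {
  h <- nrow(hull)
  if (h < 3) return(sqrt(max(stats::dist(hull)^2, 0)) * (h == 2))
  w <- Inf
  for (i in seq_len(h)) {
    j <- i %% h + 1
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    d <- abs((hull[, 1] - hull[i, 1]) * e[2] -
             (hull[, 2] - hull[i, 2]) * e[1]) / len
    w <- min(w, max(d))
  }
  w
}

#' Shape descriptors of a single segmented object
#'
#' Computes the six shape features of one connected binary object: area
#' (pixel count), perimeter (length of the traced, corner-smoothed
#' sub-pixel contour; a raw pixel-edge perimeter would bias circularity
#' by up to ~27\%), circularity \eqn{4\pi A / P^2}, maximum and minimum
#' Feret (caliper) diameters over the convex hull of the pixel centres,
#' and eccentricity \eqn{\sqrt{1 - (b/a)^2}} of the moment-equivalent
#' ellipse.  Lengths scale with \code{pixel_size}, areas with its square.
#'
#' @param mask logical or 0/1 matrix containing exactly one 4-connected
#'   object of at least 9 pixels.
#' @param pixel_size micrometres per pixel.
#' @param object_id identifier used in error messages.
#' @return named numeric vector: area, perimeter, circularity,
#'   maxcaliper, mincaliper, eccentricity.
#' @examples
#' xy <- expand.grid(1:41, 1:41)
#' disc <- matrix((xy[, 1] - 21)^2 + (xy[, 2] - 21)^2 <= 15^2, 41)
#' shapeDescriptors(disc)["circularity"]
#' @export
shapeDescriptors <- function(mask, pixel_size = 1, object_id = "object") {
  mask <- (mask > 0) * 1
  npx <- sum(mask)
  if (npx < 9)
    stop("object '", object_id, "': mask empty or below 9 pixels")
  ncomp <- max(EBImage::bwlabel(EBImage::Image(mask)))
  if (ncomp != 1)
    stop("object '", object_id, "': mask must be a single connected object")

  area <- npx * pixel_size^2
  per <- .polygonLength(.tracedContour(mask)) * pixel_size
  pts <- which(mask > 0, arr.ind = TRUE)
  hull <- pts[chull(pts), , drop = FALSE]
  dmax <- sqrt(max(as.matrix(stats::dist(hull))^2)) * pixel_size
  dmin <- .minFeret(hull) * pixel_size
  ev <- eigen(cov(pts), symmetric = TRUE, only.values = TRUE)$values
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  c(area = area, perimeter = per, circularity = 4 * pi * area / per^2,
    maxcaliper = dmax, mincaliper = dmin, eccentricity = ecc)
}

#' Nucleus-to-cell area ratio
#'
#' @param nucleus_area,cell_area areas in consistent units; the cell must
#'   be at least as large as its nucleus (it contains it).
#' @return ratio in (0, 1]; vectorised.
#' @export
nucleusCellRatio <- function(nucleus_area, cell_area) {
  if (any(nucleus_area <= 0)) stop("nucleus area must be positive")
  if (any(cell_area < nucleus_area))
    stop("mask inconsistency: cell smaller than its nucleus")
  nucleus_area / cell_area
}

#' Morphometry of a segmented slide
#'
#' Applies \code{\link{shapeDescriptors}} to every nucleus and cell of a
#' labelled segmentation and assembles the 13-feature per-cell table.
#'
#' @param nucleusLabels,cellLabels aligned label matrices (same ids).
#' @param pixel_size micrometres per pixel.
#' @return data.frame with \code{label} and the 13 features of
#'   \code{\link{morphFeatureNames}}.
#' @export
segmentationMorphometry <- function(nucleusLabels, cellLabels,
                                    pixel_size = 0.25) {
  labs <- sort(setdiff(unique(as.vector(nucleusLabels)), 0L))
  rows <- lapply(labs, function(l) {
    nf <- shapeDescriptors(nucleusLabels == l, pixel_size,
                           object_id = paste0("nucleus_", l))
    cf <- shapeDescriptors(cellLabels == l, pixel_size,
                           object_id = paste0("cell_", l))
    out <- c(nf, cf, nucleusCellRatio(nf["area"], cf["area"]))
    names(out) <- morphFeatureNames()
    out
  })
  df <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(label = labs), df)
}

#' Aggregate per-cell features to the 39-feature patient vector
#'
#' For each of the thirteen morphometric features, the arithmetic mean
#' and the 25th/75th percentiles (linear interpolation between order
#' statistics) over the patient's cells — 39 features per patient, in the
#' fixed order of \code{\link{patientFeatureNames}}.
#'
#' @param cellFeatures data.frame holding the 13 feature columns of
#'   \code{\link{morphFeatureNames}} (extra columns ignored), at least
#'   one row.
#' @return named numeric vector of length 39.
#' @export
aggregatePatient <- function(cellFeatures) {
  feats <- morphFeatureNames()
  missing <- setdiff(feats, names(cellFeatures))
  if (length(missing) > 0)
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  if (nrow(cellFeatures) < 1) stop("at least one cell required")
  out <- unlist(lapply(feats, function(f) {
    v <- cellFeatures[[f]]
    c(mean(v), quantile(v, c(0.25, 0.75), names = FALSE, type = 7))
  }))
  setNames(out, patientFeatureNames())
}

#' Aggregate a multi-patient cell table to the patient feature matrix
#'
#' @param cells data.frame with a \code{patient_id} column and the 13
#'   feature columns, or a named list of per-patient tables.
#' @return data.frame: \code{patient_id} plus the 39 feature columns.
#' @export
aggregatePatients <- function(cells) {
  if (is.data.frame(cells))
    cells <- split(cells, cells$patient_id)
  mat <- t(vapply(cells, aggregatePatient, numeric(39)))
  cbind(data.frame(patient_id = names(cells)), as.data.frame(mat))
}
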