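#' Nucleus detection parameters
#'
#' Defaults mirror a threshold-plus-split nuclear detector on the
#' haematoxylin OD channel: Gaussian smoothing (1.5 px), a fixed OD
#' threshold of 0.15 with an Otsu fallback when the fixed threshold
#' yields nothing, hole filling, an optional distance-transform watershed
#' to split touching nuclei, and an area filter of 10-400 square
#' micrometres.
#'
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param od_threshold haematoxylin OD threshold.
#' @param min_area,max_area retained nucleus area range (square
#'   micrometres).
#' @param watershed split touching nuclei by distance-transform
#'   watershed.
#' @param expansion_um cytoplasmic expansion radius used by
#'   \code{\link{expandCells}}.
#' @param pixel_size micrometres per pixel.
#' @return a validated list of class \code{detectionParams}.
#' @export
detectionParams <- function(smooth_sigma = 1.5, od_threshold = 0.15,
                            min_area = 10, max_area = 400,
                            watershed = TRUE, expansion_um = 2.5,
                            pixel_size = 0.25) {
  if (min_area >= max_area) stop("min_area must be below max_area")
  if (any(c(smooth_sigma, od_threshold, min_area, max_area,
            expansion_um, pixel_size) <= 0) && expansion_um != 0)
    stop("detection parameters must be positive")
  structure(list(smooth_sigma = smooth_sigma, od_threshold = od_threshold,
                 min_area = min_area, max_area = max_area,
                 watershed = watershed, expansion_um = expansion_um,
                 pixel_size = pixel_size),
            class = c("detectionParams", "list"))
}

#' Detect nuclei on a haematoxylin OD channel
#'
#' Gaussian smoothing, OD thresholding (fixed threshold, Otsu fallback if
#' it selects nothing or everything), hole filling, 4-connected labelling,
#' optional distance-transform watershed splitting, and filtering of
#' components to the configured area range.  Labels are renumbered
#' consecutively from 1.
#'
#' @param hchannel single-channel nonnegative matrix (haematoxylin OD or
#'   concentration).
#' @param params a \code{\link{detectionParams}}.
#' @return integer label matrix (0 = background); empty masks are allowed.
#' @seealso \code{\link{expandCells}}, \code{\link{perCellIntensity}}
#' @export
detectNuclei <- function(hchannel, params = detectionParams()) {
  if (length(dim(hchannel)) != 2 || any(hchannel < 0, na.rm = TRUE))
    stop("expected a single-channel nonnegative image")
  sm <- EBImage::gblur(hchannel, sigma = params$smooth_sigma)
  bw <- sm > params$od_threshold
  if (all(bw) || !any(bw)) {
    rng <- range(sm)
    if (diff(rng) > 0) {
      thr <- EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)),
                           range = c(0, 1))
      bw <- (sm - rng[1]) / diff(rng) > thr
    }
  }
  if (!any(bw)) return(matrix(0L, nrow(hchannel), ncol(hchannel)))
  bw <- EBImage::fillHull(EBImage::Image(bw * 1))
  lab <- if (params$watershed) {
    EBImage::watershed(EBImage::distmap(bw), tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)),
                nrow(hchannel), ncol(hchannel))
  .filterByArea(lab, params$min_area, params$max_area, params$pixel_size)
}

# drop labels outside [min,max] um^2 and renumber 1..n
.filterByArea <- function(lab, min_area, max_area, pixel_size) {
  if (max(lab) == 0) return(lab)
  px2 <- pixel_size^2
  sizes <- tabulate(lab, nbins = max(lab)) * px2
  keep <- which(sizes >= min_area & sizes <= max_area)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

#' Expand nuclei into cell territories
#'
#' Each nucleus is dilated outward up to the expansion radius; where two
#' nuclei compete, pixels are assigned to the nearest nucleus (Euclidean
#' distance to the nucleus boundary), so the cell boundary lies on the
#' equidistance line.  Ties are broken toward the lower label id.  Every
#' cell contains its nucleus and cells are pairwise disjoint.
#'
#' @param nucleusLabels integer label matrix from
#'   \code{\link{detectNuclei}}.
#' @param expansion_um expansion radius in micrometres (0 returns the
#'   nucleus mask unchanged).
#' @param pixel_size micrometres per pixel.
#' @return integer cell label matrix with the same label ids.
#' @export
expandCells <- function(nucleusLabels, expansion_um = 2.5,
                        pixel_size = 0.25) {
  nlab <- max(nucleusLabels)
  if (expansion_um == 0 || nlab == 0) return(nucleusLabels)
  rpx <- expansion_um / pixel_size
  best <- matrix(Inf, nrow(nucleusLabels), ncol(nucleusLabels))
  out <- matrix(0L, nrow(nucleusLabels), ncol(nucleusLabels))
  for (l in seq_len(nlab)) {
    # distance from every pixel to the nearest pixel of nucleus l
    d <- EBImage::distmap(EBImage::Image((nucleusLabels != l) * 1))
    d <- matrix(as.numeric(EBImage::imageData(d)),
                nrow(nucleusLabels), ncol(nucleusLabels))
    upd <- d <= rpx & d < best       # strict <: ties keep the lower label
    out[upd] <- l
    best[upd] <- d[upd]
  }
  out
}

#' Per-cell stain intensity with nuclear correction
#'
#' Means of a stain channel over the nucleus and the cytoplasm (cell
#' minus nucleus) of every cell, and the nucleus-corrected value
#' cytoplasm minus nucleus (reported raw and clipped at zero) used to
#' suppress false-positive DAB calls from nonspecific nuclear signal.
#'
#' @param channel numeric matrix (stain concentration or OD).
#' @param nucleusLabels,cellLabels aligned label matrices; cells must
#'   contain their nuclei.
#' @return data.frame with one row per label: \code{label},
#'   \code{nucleus_mean}, \code{cytoplasm_mean}, \code{corrected_raw},
#'   \code{corrected} (clipped at 0; \code{NA} when the cytoplasm is
#'   empty).
#' @export
perCellIntensity <- function(channel, nucleusLabels, cellLabels) {
  if (!all(dim(channel) == dim(nucleusLabels)) ||
      !all(dim(channel) == dim(cellLabels)))
    stop("channel and label masks must share dimensions")
  nlab <- max(cellLabels)
  if (nlab == 0)
    return(data.frame(label = integer(), nucleus_mean = numeric(),
                      cytoplasm_mean = numeric(), corrected_raw = numeric(),
                      corrected = numeric()))
  meanBy <- function(vals, labs) {
    s <- rowsum(vals, labs)
    n <- tabulate(labs, nbins = nlab)
    m <- rep(NA_real_, nlab)
    present <- as.integer(rownames(s))
    m[present] <- s[, 1] / n[present]
    m
  }
  inNuc <- nucleusLabels > 0
  cyto <- cellLabels > 0 & !inNuc
  nucMean <- meanBy(channel[inNuc], nucleusLabels[inNuc])
  cytMean <- if (any(cyto)) meanBy(channel[cyto], cellLabels[cyto])
             else rep(NA_real_, nlab)
  raw <- cytMean - nucMean
  data.frame(label = seq_len(nlab), nucleus_mean = nucMean,
             cytoplasm_mean = cytMean, corrected_raw = raw,
             corrected = pmax(raw, 0))
}

#' Tissue-region area fractions
#'
#' Proportions of tumor, stroma and hemorrhage over the non-background
#' pixels of a region mask.
#'
#' @param regionMask integer matrix coded 0 = background, 1 = tumor,
#'   2 = stroma, 3 = hemorrhage.
#' @return named numeric vector (tumor, stroma, hemorrhage) summing to 1.
#' @export
regionFractions <- function(regionMask) {
  if (!all(regionMask %in% 0:3))
    stop("region mask must be coded 0..3")
  n <- tabulate(regionMask[regionMask > 0], nbins = 3)
  if (sum(n) == 0) stop("no tissue in region mask (all background)")
  setNames(n / sum(n), c("tumor", "stroma", "hemorrhage"))
}
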