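#' Render synthetic H&E and IHC slides for one patient
#'
#' Draws the patient's cells as non-overlapping ellipses (nucleus plus a
#' concentric cytoplasmic ring) on a white canvas, placed by dart throwing
#' with bounded retries.  Per-pixel stain concentrations (haematoxylin in
#' nuclei, eosin in cytoplasm on the H&E slide, DAB in cytoplasm/nucleus
#' of each hormone slide at the per-cell OD levels recorded in the cell
#' table) are composed into RGB through the Beer-Lambert model, so colour
#' deconvolution can invert the rendering exactly (up to 8-bit
#' quantisation when \code{quantize = TRUE}).
#'
#' @param cells per-cell table with columns \code{cell_id}, \code{a_um},
#'   \code{b_um}, \code{theta} and, for each hormone slide requested,
#'   \code{<hormone>_dab_cyto} / \code{<hormone>_dab_nuc} (as produced by
#'   \code{\link{generateCohort}}).
#' @param width,height canvas size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param expansion_um cytoplasmic expansion radius (micrometres).
#' @param hormones hormone slides to render (default GH, PRL, TSH; set to
#'   \code{character()} for H&E only).
#' @param hematoxylin_od nuclear haematoxylin OD level (per-cell jitter sd
#'   \code{hematoxylin_sd}).
#' @param hematoxylin_sd per-cell jitter of the nuclear OD.
#' @param eosin_od cytoplasmic eosin OD on the H&E slide.
#' @param stroma_frac,hemorrhage_frac target fractions of tissue covered
#'   by stroma / hemorrhage blobs in the region mask.
#' @param margin_px extra clearance enforced between cells, in pixels.
#' @param max_tries dart-throwing retries per cell before failing.
#' @param quantize quantise RGB output to 8-bit levels.
#' @param seed integer seed (placement and jitter).
#' @return list with \code{he} (RGB array), \code{ihc} (named list of RGB
#'   arrays), \code{nucleusMask} and \code{cellMask} (integer label
#'   matrices matching rendered cells one-to-one, label = row index into
#'   \code{placement}), \code{regionMask} (0 background, 1 tumor,
#'   2 stroma, 3 hemorrhage), and \code{placement} (cell_id, centre
#'   coordinates in pixels).
#' @examples
#' coh <- generateCohort(cohortConfig(n_patients = 1,
#'   cells_per_patient = c(20L, 20L), seed = 2))
#' sl <- renderSlides(cellTables(coh)[[1]], width = 320, height = 320)
#' max(sl$nucleusMask)   # 20 rendered nuclei
#' @export
renderSlides <- function(cells, width = 512, height = 512,
                         pixel_size = 0.25, expansion_um = 2.5,
                         hormones = c("GH", "PRL", "TSH"),
                         hematoxylin_od = 0.8, hematoxylin_sd = 0.04,
                         eosin_od = 0.25,
                         stroma_frac = 0, hemorrhage_frac = 0,
                         margin_px = 4, max_tries = 2000,
                         quantize = TRUE, seed = 1L) {
  k <- nrow(cells)
  if (is.null(k) || k < 1) stop("at least one cell required")
  set.seed(seed)

  aN <- cells$a_um / pixel_size
  bN <- cells$b_um / pixel_size
  aC <- aN + expansion_um / pixel_size
  bC <- bN + expansion_um / pixel_size
  theta <- cells$theta
  # conservative outer radius (circumscribed circle of the cell ellipse)
  rOut <- aC
  if (any(2 * rOut + 2 > width) || any(2 * rOut + 2 > height))
    stop("cell larger than canvas")

  cx <- cy <- rep(NA_real_, k)
  for (i in order(-rOut)) {         # place the largest cells first
    done <- which(!is.na(cx))
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      x <- runif(1, rOut[i] + 1, width - rOut[i])
      y <- runif(1, rOut[i] + 1, height - rOut[i])
      if (length(done) == 0 ||
          all((x - cx[done])^2 + (y - cy[done])^2 >
              (rOut[i] + rOut[done] + margin_px)^2)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("cell placement failed after ", max_tries,
           " tries (too many cells for canvas)")
  }

  nucMask <- matrix(0L, height, width)
  cellMask <- matrix(0L, height, width)
  hConc <- matrix(0, height, width)      # nuclear haematoxylin
  eConc <- matrix(0, height, width)      # cytoplasmic eosin
  dConc <- lapply(hormones, function(h) matrix(0, height, width))
  names(dConc) <- hormones
  hOD <- pmax(rnorm(k, hematoxylin_od, hematoxylin_sd), 0.2)

  for (i in seq_len(k)) {
    r <- ceiling(aC[i]) + 1
    xs <- max(1, floor(cx[i] - r)):min(width, ceiling(cx[i] + r))
    ys <- max(1, floor(cy[i] - r)):min(height, ceiling(cy[i] + r))
    dx <- outer(rep(1, length(ys)), xs - cx[i])
    dy <- outer(ys - cy[i], rep(1, length(xs)))
    u <- dx * cos(theta[i]) + dy * sin(theta[i])
    v <- -dx * sin(theta[i]) + dy * cos(theta[i])
    inNuc <- (u / aN[i])^2 + (v / bN[i])^2 <= 1
    inCell <- (u / aC[i])^2 + (v / bC[i])^2 <= 1
    sub <- cbind(rep(ys, length(xs))[as.vector(inCell)],
                 rep(xs, each = length(ys))[as.vector(inCell)])
    cellMask[sub] <- i
    subN <- cbind(rep(ys, length(xs))[as.vector(inNuc)],
                  rep(xs, each = length(ys))[as.vector(inNuc)])
    nucMask[subN] <- i
    hConc[subN] <- hOD[i]
    ring <- inCell & !inNuc
    subR <- cbind(rep(ys, length(xs))[as.vector(ring)],
                  rep(xs, each = length(ys))[as.vector(ring)])
    eConc[subR] <- eosin_od
    for (h in hormones) {
      dConc[[h]][subR] <- cells[[paste0(h, "_dab_cyto")]][i]
      dConc[[h]][subN] <- cells[[paste0(h, "_dab_nuc")]][i]
    }
  }

  zeros <- matrix(0, height, width)
  toRgb <- function(c1, c2, sm) {
    conc <- array(c(c1, c2, zeros), c(height, width, 3))
    odToRgb(composeOd(conc, sm), quantize = quantize)
  }
  he <- toRgb(hConc, eConc, heStainMatrix())
  ihc <- lapply(hormones, function(h)
    toRgb(hConc, dConc[[h]], hdabStainMatrix()))
  names(ihc) <- hormones

  regionMask <- .makeRegionMask(height, width, stroma_frac, hemorrhage_frac)

  list(he = he, ihc = ihc, nucleusMask = nucMask, cellMask = cellMask,
       regionMask = regionMask,
       placement = data.frame(cell_id = cells$cell_id, cx = cx, cy = cy))
}

# tissue disc with stroma / hemorrhage blobs carved out of tumor
.makeRegionMask <- function(height, width, stroma_frac, hemorrhage_frac) {
  dy <- outer(seq_len(height) - (height + 1) / 2, rep(1, width))
  dx <- outer(rep(1, height), seq_len(width) - (width + 1) / 2)
  rr <- sqrt(dx^2 + dy^2)
  tissue <- rr <= 0.48 * min(height, width)
  mask <- matrix(0L, height, width)
  mask[tissue] <- 1L
  nTis <- sum(tissue)
  addBlobs <- function(mask, frac, label) {
    if (frac <= 0) return(mask)
    target <- frac * nTis
    tries <- 0
    while (sum(mask == label) < target && tries < 200) {
      tries <- tries + 1
      bx <- runif(1, 1, width); by <- runif(1, 1, height)
      br <- runif(1, 0.04, 0.10) * min(height, width)
      blob <- (dx + (width + 1) / 2 - bx)^2 +
              (dy + (height + 1) / 2 - by)^2 <= br^2
      mask[blob & tissue] <- label
    }
    mask
  }
  mask <- addBlobs(mask, stroma_frac, 2L)
  addBlobs(mask, hemorrhage_frac, 3L)
}
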