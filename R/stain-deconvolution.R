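#' Construct a stain matrix
#'
#' Rows are per-stain optical-density vectors in RGB order; they are
#' L2-normalised on construction.
#'
#' @param values 3 x 3 numeric matrix, one stain per row.
#' @param stains character vector of three stain names (defaults to the
#'   rownames of \code{values}).
#' @return a \code{\linkS4class{StainMatrix}}
#' @examples
#' stainMatrix(diag(3), c("r", "g", "b"))
#' @export
stainMatrix <- function(values, stains = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(stains))
    stop("stain names required")
  rownames(values) <- stains
  colnames(values) <- c("R", "G", "B")
  nrm <- sqrt(rowSums(values^2))
  if (any(nrm == 0)) stop("zero-length stain vector")
  new("StainMatrix", values = values / nrm)
}

# residual vector orthogonal to two stain vectors
.residualVector <- function(u, v) {
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  w / sqrt(sum(w^2))
}

#' Default haematoxylin / eosin / residual stain vectors
#'
#' The standard published H&E optical-density vectors with an orthogonal
#' residual channel.
#' @return a \code{\linkS4class{StainMatrix}}
#' @export
heStainMatrix <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  stainMatrix(rbind(h, e, .residualVector(h, e)),
              c("hematoxylin", "eosin", "residual"))
}

#' Default haematoxylin / DAB / residual stain vectors
#'
#' The standard published H-DAB optical-density vectors with an orthogonal
#' residual channel, for immunohistochemistry slides.
#' @return a \code{\linkS4class{StainMatrix}}
#' @export
hdabStainMatrix <- function() {
  h <- c(0.65, 0.70, 0.29)
  d <- c(0.27, 0.57, 0.78)
  stainMatrix(rbind(h, d, .residualVector(h, d)),
              c("hematoxylin", "dab", "residual"))
}

#' Convert an 8-bit RGB image to optical density
#'
#' Beer-Lambert transform \eqn{OD = -\log_{10}(\max(I, 1)/255)} per
#' channel, with white (255) mapping to OD 0 and the darkest
#' representable value (1) to \eqn{\log_{10} 255 \approx 2.407}.
#'
#' @param rgb numeric array \code{h x w x 3} with values in [0, 255]
#'   (integer-quantised or not).
#' @return numeric array of the same shape with OD values in
#'   \eqn{[0, \log_{10} 255]}.
#' @seealso \code{\link{odToRgb}}, \code{\link{deconvolve}}
#' @examples
#' rgbToOd(array(255, c(2, 2, 3)))   # all-zero OD
#' @export
rgbToOd <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("expected an h x w x 3 RGB array")
  -log10(pmax(rgb, 1) / 255)
}

#' Convert optical density back to RGB
#'
#' Inverse of \code{\link{rgbToOd}}; with \code{quantize = TRUE} the
#' result is rounded to 8-bit levels.
#'
#' @param od numeric array \code{h x w x 3} of nonnegative OD.
#' @param quantize round to integer 8-bit levels (default TRUE).
#' @return numeric array with values in [0, 255].
#' @export
odToRgb <- function(od, quantize = TRUE) {
  rgb <- 255 * 10^(-od)
  if (quantize) rgb <- round(rgb)
  rgb
}

#' Colour deconvolution of an OD image
#'
#' Solves, per pixel, the linear Beer-Lambert mixing model
#' \eqn{OD = c^T M} for the stain concentration vector \eqn{c}, where the
#' rows of \eqn{M} are the unit stain vectors.  Negative concentrations
#' (noise outside the stain simplex) are clipped to zero and the clipping
#' is reported.
#'
#' @param od numeric array \code{h x w x 3} of OD values.
#' @param stains a \code{\linkS4class{StainMatrix}}.
#' @return list with \code{concentrations} (array \code{h x w x 3}, third
#'   dimension named by stain), \code{clippedFraction} (fraction of
#'   entries clipped), and \code{clipped} (logical).
#' @examples
#' sm <- hdabStainMatrix()
#' od <- array(0, c(1, 1, 3)); od[1, 1, ] <- 0.7 * sm@values["hematoxylin", ]
#' deconvolve(od, sm)$concentrations[1, 1, ]   # (0.7, 0, 0)
#' @export
deconvolve <- function(od, stains) {
  stopifnot(is(stains, "StainMatrix"))
  if (length(dim(od)) != 3 || dim(od)[3] != 3)
    stop("expected an h x w x 3 OD array")
  M <- stains@values
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular stain matrix: ", conditionMessage(e)))
  d <- dim(od)
  flat <- matrix(od, ncol = 3)
  conc <- flat %*% Minv
  nneg <- sum(conc < -1e-12)
  conc[conc < 0] <- 0
  out <- array(conc, d)
  dimnames(out) <- list(NULL, NULL, rownames(M))
  list(concentrations = out,
       clippedFraction = nneg / length(conc),
       clipped = nneg > 0)
}

#' Compose stain concentrations into an OD image
#'
#' Forward Beer-Lambert mixing: \eqn{OD = c^T M}.  Inverse of
#' \code{\link{deconvolve}} for nonnegative concentration fields.
#'
#' @param concentrations numeric array \code{h x w x 3} (stain order must
#'   match the stain matrix rows).
#' @param stains a \code{\linkS4class{StainMatrix}}.
#' @return OD array \code{h x w x 3}.
#' @export
composeOd <- function(concentrations, stains) {
  stopifnot(is(stains, "StainMatrix"))
  d <- dim(concentrations)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an h x w x 3 concentration array")
  array(matrix(concentrations, ncol = 3) %*% stains@values, d)
}
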