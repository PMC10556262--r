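#' @import methods
#' @importFrom stats quantile sd cor rnorm rlnorm runif rexp rbinom cov
#'   pchisq pt pnorm setNames aggregate dist
#' @importFrom utils write.csv read.csv head
#' @importFrom grDevices contourLines chull
#' @importFrom mclust Mclust mclustBIC
NULL

#' Stain vector matrix for colour deconvolution
#'
#' Holds three unit-length optical-density (OD) vectors, one per stain
#' (rows), in RGB order (columns).  Under the Beer-Lambert model the OD of
#' a pixel is the concentration-weighted sum of the stain vectors, so an
#' invertible \code{StainMatrix} lets \code{\link{deconvolve}} unmix the
#' per-pixel OD into per-stain concentrations.
#'
#' @slot values 3 x 3 numeric matrix; rows are stains (unit L2 norm), with
#'   rownames naming the stains and columns named R, G, B.
#'
#' @seealso \code{\link{stainMatrix}}, \code{\link{heStainMatrix}},
#'   \code{\link{hdabStainMatrix}}, \code{\link{deconvolve}}
#' @export
setClass("StainMatrix", representation(values = "matrix"))

setValidity("StainMatrix", function(object) {
  M <- object@values
  if (!is.numeric(M) || !identical(dim(M), c(3L, 3L)))
    return("stain matrix must be numeric 3 x 3")
  if (is.null(rownames(M)) || anyDuplicated(rownames(M)))
    return("rows must carry unique stain names")
  nrm <- sqrt(rowSums(M^2))
  if (any(abs(nrm - 1) > 1e-9))
    return("each stain vector must have unit L2 norm")
  sv <- svd(M)$d
  if (sv[3] <= 0 || sv[1] / sv[3] >= 1e6)
    return("stain matrix is ill-conditioned (condition number >= 1e6)")
  TRUE
})

#' @describeIn StainMatrix display the stain vectors
#' @param object a \code{StainMatrix}
#' @export
setMethod("show", "StainMatrix", function(object) {
  cat("StainMatrix with stains:", paste(rownames(object@values),
      collapse = ", "), "\n")
  print(round(object@values, 4))
})

#' Synthetic cohort of silent PIT1-lineage tumors
#'
#' Container returned by \code{\link{generateCohort}}: a per-patient table,
#' per-patient per-cell tables (analytic morphometry plus per-hormone DAB
#' optical densities and ground-truth positivity flags), a survival table,
#' and the generating configuration.  Ground truth (phenotype, subtype,
#' risk tier) lives in the patient table, so recovery of the labels by the
#' analysis pipeline can be scored exactly.
#'
#' @slot patients data.frame, one row per patient: \code{patient_id},
#'   \code{phenotype} (\code{regular}/\code{aggressive}), \code{subtype},
#'   \code{tier}, \code{stroma_frac}, synthetic clinical flags and
#'   \code{n_cells}.
#' @slot cells named list of data.frames (one per patient) with cell
#'   geometry, the 13 morphometric features, and per-hormone
#'   \code{<h>_dab_cyto}, \code{<h>_dab_nuc}, \code{<h>_pos} columns.
#' @slot survival data.frame: \code{patient_id}, \code{time_years},
#'   \code{event}.
#' @slot config the \code{cohortConfig} list used for generation.
#'
#' @seealso \code{\link{generateCohort}}, \code{\link{cohortConfig}}
#' @export
setClass("SyntheticCohort",
  representation(patients = "data.frame", cells = "list",
                 survival = "data.frame", config = "list"))

setValidity("SyntheticCohort", function(object) {
  p <- object@patients
  if (nrow(p) != length(object@cells))
    return("one cell table per patient required")
  if (nrow(p) != nrow(object@survival))
    return("one survival row per patient required")
  if (nrow(p) > 0 && !setequal(p$patient_id, names(object@cells)))
    return("cell table names must match patient ids")
  TRUE
})

#' @describeIn SyntheticCohort summary display
#' @param object a \code{SyntheticCohort}
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  p <- object@patients
  cat("SyntheticCohort:", nrow(p), "patients,",
      sum(vapply(object@cells, nrow, 1L)), "cells\n")
  if (nrow(p) > 0) {
    cat("  phenotypes: ", paste(names(table(p$phenotype)),
        table(p$phenotype), sep = "=", collapse = ", "), "\n")
    cat("  tiers:      ", paste(names(table(p$tier)),
        table(p$tier), sep = "=", collapse = ", "), "\n")
  }
})

#' @rdname SyntheticCohort
#' @param object a \code{SyntheticCohort}
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))

#' @rdname SyntheticCohort
#' @export
setMethod("patients", "SyntheticCohort", function(object) object@patients)

#' @rdname SyntheticCohort
#' @export
setGeneric("cellTables", function(object) standardGeneric("cellTables"))

#' @rdname SyntheticCohort
#' @export
setMethod("cellTables", "SyntheticCohort", function(object) object@cells)

#' @rdname SyntheticCohort
#' @export
setGeneric("survivalData", function(object) standardGeneric("survivalData"))

#' @rdname SyntheticCohort
#' @export
setMethod("survivalData", "SyntheticCohort", function(object) object@survival)

#' Fitted Gaussian finite mixture model
#'
#' Result of \code{\link{fitGmmBIC}}: the mixture minimising the Bayesian
#' information criterion in the convention \eqn{BIC = p \ln n - 2 \ln L}
#' (lower is better; \eqn{p} is the free-parameter count), over a sweep of
#' component counts and covariance families.
#'
#' @slot K integer, selected number of components.
#' @slot family character, selected covariance family (one of
#'   \code{spherical}, \code{diagonal}, \code{tied}, \code{full}).
#' @slot modelName underlying mclust parameterisation name.
#' @slot weights mixing proportions (sum to 1).
#' @slot means d x K matrix of component means.
#' @slot loglik maximised log-likelihood.
#' @slot bic BIC of the selected model (minimised convention).
#' @slot bicTable data.frame of BIC for every (K, family) candidate.
#' @slot labels integer vector of hard assignments (max posterior).
#' @slot mclustFit the underlying mclust fit (list form), kept for
#'   posterior prediction.
#' @seealso \code{\link{fitGmmBIC}}, \code{\link{assignMC}}
#' @export
setClass("GmmFit",
  representation(K = "integer", family = "character", modelName = "character",
                 weights = "numeric", means = "matrix", loglik = "numeric",
                 bic = "numeric", bicTable = "data.frame",
                 labels = "integer", mclustFit = "list"))

setValidity("GmmFit", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("mixture weights must sum to 1")
  if (length(object@labels) > 0 &&
      (min(object@labels) < 1 || max(object@labels) > object@K))
    return("labels must lie in 1..K")
  if (!is.finite(object@bic)) return("BIC must be finite")
  TRUE
})

#' @describeIn GmmFit display selected model and BIC
#' @param object a \code{GmmFit}
#' @export
setMethod("show", "GmmFit", function(object) {
  cat("GmmFit: K =", object@K, ", family =", object@family,
      sprintf("(%s), BIC = %.2f, logLik = %.2f\n",
              object@modelName, object@bic, object@loglik))
  cat("  component sizes:", paste(tabulate(object@labels, object@K),
      collapse = ", "), "\n")
})
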