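#' Z-score a feature matrix
#'
#' Centres every column to mean 0 and scales to unit standard deviation
#' (n - 1 denominator).  Zero-variance columns carry no clustering
#' information and are dropped with a warning.
#'
#' @param x numeric matrix or data.frame with at least two rows.
#' @return numeric matrix of the retained, standardised columns.
#' @export
standardizeFeatures <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least two rows required")
  sds <- apply(x, 2, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (all(drop)) stop("all columns have zero variance")
  if (any(drop))
    warning("dropping zero-variance columns: ",
            paste(colnames(x)[drop], collapse = ", "))
  scale(x[, !drop, drop = FALSE])
}

.familyModels <- function(family, d) {
  if (d == 1)
    return(switch(family, spherical = c("E", "V"), diagonal = c("E", "V"),
                  tied = "E", full = "V"))
  switch(family,
         spherical = c("EII", "VII"),
         diagonal  = c("EEI", "VVI"),
         tied      = "EEE",
         full      = "VVV",
         stop("unknown covariance family: ", family))
}

.modelFamily <- function(modelName) {
  map <- c(E = "tied", V = "full", X = "spherical",
           EII = "spherical", VII = "spherical", EEI = "diagonal",
           VVI = "diagonal", EEE = "tied", VVV = "full",
           XII = "spherical", XXI = "diagonal", XXX = "full")
  unname(map[modelName])
}

#' Fit Gaussian mixtures and select by BIC
#'
#' Fits EM for every combination of component count and covariance
#' family (spherical, diagonal, tied and full covariances) and returns
#' the model minimising \eqn{BIC = p \ln n - 2 \ln L}, where \eqn{p}
#' counts the free parameters.  Fitting is delegated to the mclust EM
#' machinery with its deterministic model-based hierarchical
#' initialisation, so results are reproducible regardless of seed; the
#' \code{seed} and \code{restarts} arguments are accepted for interface
#' stability and forwarded to the RNG for any stochastic fallback.
#' Degenerate candidates (singular components) are skipped with a
#' warning.
#'
#' @param x numeric matrix (rows = observations); must have more rows
#'   than \code{max(K)}.
#' @param K integer vector of component counts to sweep (subset of 1-9).
#' @param families covariance families to sweep.
#' @param seed integer seed.
#' @param restarts retained for interface compatibility.
#' @return a \code{\linkS4class{GmmFit}}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100), ncol = 2),
#'            matrix(rnorm(100, 6), ncol = 2))
#' fitGmmBIC(x, K = 1:3)@K
#' @export
fitGmmBIC <- function(x, K = 1:5,
                      families = c("spherical", "diagonal", "tied", "full"),
                      seed = 1L, restarts = 5L) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (!all(K %in% 1:9)) stop("K must lie in 1..9")
  if (n <= max(K)) stop("need more rows than the largest K")
  set.seed(seed)
  models <- unique(unlist(lapply(families, .familyModels, d = d)))
  fit <- mclust::Mclust(x, G = K, modelNames = models, verbose = FALSE)
  if (is.null(fit)) stop("no mixture candidate could be fitted")
  # mclust maximises 2 lnL - p ln n; flip sign to the minimised convention
  bicArr <- -fit$BIC
  tab <- expand.grid(K = as.integer(rownames(bicArr)),
                     model = colnames(bicArr), stringsAsFactors = FALSE)
  tab$family <- .modelFamily(tab$model)
  tab$bic <- as.vector(bicArr)
  nfail <- sum(!is.finite(tab$bic))
  if (nfail > 0)
    warning(nfail, " degenerate (K, family) candidates skipped")
  tab <- tab[is.finite(tab$bic), , drop = FALSE]
  new("GmmFit",
      K = as.integer(fit$G), family = .modelFamily(fit$modelName),
      modelName = fit$modelName,
      weights = as.numeric(fit$parameters$pro),
      means = matrix(fit$parameters$mean, ncol = fit$G),
      loglik = as.numeric(fit$loglik),
      bic = as.numeric(-fit$bic),
      bicTable = tab[order(tab$bic), ],
      labels = as.integer(fit$classification),
      mclustFit = unclass(fit))
}

#' Name morphology clusters MC1 / MC2
#'
#' MC2 is the cluster whose members have the larger average of the
#' nucleus max-caliper mean-feature — the enlarged, pleomorphic
#' phenotype; MC1 is the other.  When the BIC-selected model has a
#' component count other than two, the best two-component model from the
#' same sweep is refitted for naming (with a message), since the
#' morphological dichotomy is the object of interest.
#'
#' @param fit a \code{\linkS4class{GmmFit}} from \code{\link{fitGmmBIC}}.
#' @param x the feature matrix (or data.frame) the model was fitted on;
#'   must contain a \code{nucleus_maxcaliper_mean} column.
#' @return factor of MC1/MC2 labels, one per row of \code{x}.
#' @export
assignMC <- function(fit, x) {
  xm <- as.matrix(x)
  cal <- x[["nucleus_maxcaliper_mean"]]
  if (is.null(cal) && "nucleus_maxcaliper_mean" %in% colnames(xm))
    cal <- xm[, "nucleus_maxcaliper_mean"]
  if (is.null(cal))
    stop("x must carry a nucleus_maxcaliper_mean column")
  labels <- fit@labels
  if (fit@K != 2L) {
    message("selected K = ", fit@K,
            "; refitting the best K = 2 model for MC naming")
    fams <- unique(fit@bicTable$family)
    fit2 <- fitGmmBIC(xm[, colnames(xm) != "", drop = FALSE], K = 2L,
                      families = if (length(fams)) fams else
                        c("spherical", "diagonal", "tied", "full"))
    labels <- fit2@labels
  }
  m <- tapply(cal, labels, mean)
  mc2 <- as.integer(names(m)[which.max(m)])
  factor(ifelse(labels == mc2, "MC2", "MC1"), levels = c("MC1", "MC2"))
}

#' Pairwise correlation-distance matrix
#'
#' \eqn{D_{ij} = 1 - r(x_i, x_j)} with Pearson correlation between the
#' rows; symmetric, zero diagonal, values in [0, 2].
#'
#' @param x numeric matrix with at least two columns per row.
#' @return n x n numeric matrix.
#' @export
correlationDistanceMatrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least two columns required")
  sds <- apply(x, 1, sd)
  if (any(sds == 0))
    stop("zero-variance row(s): ",
         paste(which(sds == 0), collapse = ", "))
  D <- 1 - cor(t(x))
  diag(D) <- 0
  D
}

#' Within- and between-cluster correlation distances
#'
#' Mean correlation distance over within-cluster and between-cluster
#' pairs (i < j) — the heatmap summary of cluster tightness and
#' separation.
#'
#' @param D distance matrix from \code{\link{correlationDistanceMatrix}}.
#' @param labels cluster labels, one per row of \code{D}; at least two
#'   clusters with two or more members each.
#' @return list: \code{within}, \code{between}.
#' @export
separationSummary <- function(D, labels) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("need at least two clusters with at least two members")
  n <- nrow(D)
  same <- outer(labels, labels, "==")
  up <- upper.tri(D)
  list(within = mean(D[up & same]), between = mean(D[up & !same]))
}
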