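#' DAB intensity bin thresholds
#'
#' Thresholds on the nucleus-corrected DAB optical density mapping each
#' cell to an intensity bin: 0 negative, 1 weak, 2 intermediate,
#' 3 strong.  Defaults follow the common weak/moderate/strong OD
#' convention of cell-detection software (0.2 / 0.4 / 0.6) and are
#' configurable.
#'
#' @param t1,t2,t3 increasing positive thresholds.
#' @return list of class \code{intensityBins}.
#' @export
intensityBins <- function(t1 = 0.2, t2 = 0.4, t3 = 0.6) {
  if (!(0 < t1 && t1 < t2 && t2 < t3))
    stop("thresholds must satisfy 0 < t1 < t2 < t3")
  structure(list(t1 = t1, t2 = t2, t3 = t3),
            class = c("intensityBins", "list"))
}

#' Bin corrected DAB OD into intensity levels
#'
#' Right-closed bins: OD of exactly \code{t1} is negative, exactly
#' \code{t2} is weak, and so on; only values strictly above a threshold
#' move up a bin.
#'
#' @param od numeric vector of corrected DAB OD (clipped at 0).
#' @param bins an \code{\link{intensityBins}}.
#' @return integer vector of bins in \{0, 1, 2, 3\}.
#' @export
binIntensity <- function(od, bins = intensityBins()) {
  if (any(!is.finite(od))) stop("OD values must be finite")
  as.integer(od > bins$t1) + as.integer(od > bins$t2) +
    as.integer(od > bins$t3)
}

#' Allred score of one hormone stain
#'
#' Proportion score PS (0; 1 for up to 1\% positive cells; 2 up to 10\%;
#' 3 up to one third; 4 up to two thirds; 5 above), intensity score IS
#' (mean bin over positive cells, rounded half-up; 0 when no cell is
#' positive), total TS = PS + IS with the eight attainable values
#' \{0, 2, 3, 4, 5, 6, 7, 8\}.  The stain is called positive when
#' TS exceeds 3 \emph{and} more than 5\% of cells stain — the second
#' criterion guards against entrapped normal pituitary cells inflating a
#' focal strong signal.
#'
#' @param bins integer vector of per-cell intensity bins (0-3).
#' @return list: \code{f} (positive-cell fraction), \code{PS}, \code{IS},
#'   \code{TS}, \code{positive}.
#' @seealso \code{\link{hScore}}, \code{\link{percentageCall}}
#' @export
allredScore <- function(bins) {
  if (length(bins) == 0) stop("at least one cell required")
  f <- mean(bins >= 1)
  PS <- if (f == 0) 0L else if (f <= 0.01) 1L else if (f <= 0.10) 2L else
        if (f <= 1 / 3) 3L else if (f <= 2 / 3) 4L else 5L
  IS <- if (f == 0) 0L else
        as.integer(floor(mean(bins[bins >= 1]) + 0.5))
  TS <- PS + IS
  list(f = f, PS = PS, IS = IS, TS = TS,
       positive = TS > 3 && f > 0.05)
}

#' H-score of one hormone stain
#'
#' \eqn{1 \cdot pct_{weak} + 2 \cdot pct_{intermediate} + 3 \cdot
#' pct_{strong}} with percentages of all cells (range 0-300); positive
#' when the score exceeds 5.
#'
#' @param bins integer vector of per-cell intensity bins (0-3).
#' @return list: \code{score}, \code{positive}.
#' @export
hScore <- function(bins) {
  if (length(bins) == 0) stop("at least one cell required")
  pct <- 100 * vapply(1:3, function(b) mean(bins == b), 1)
  s <- sum(pct * 1:3)
  list(score = s, positive = s > 5)
}

#' Percentage positivity call of one hormone stain
#'
#' Percent of cells with any staining (bin >= 1); positive when strictly
#' above 10\%.
#'
#' @param bins integer vector of per-cell intensity bins (0-3).
#' @return list: \code{percent}, \code{positive}.
#' @export
percentageCall <- function(bins) {
  if (length(bins) == 0) stop("at least one cell required")
  p <- 100 * mean(bins >= 1)
  list(percent = p, positive = p > 10)
}

#' Map GH/PRL/TSH positivity to the eight staining subtypes
#'
#' Bijective map from the three positivity booleans to GH, PRL, TSH,
#' GH+PRL, GH+TSH, PRL+TSH, GH+PRL+TSH, or PIT1 (all negative), and the
#' immunostaining cluster: IC1 for GH, PRL and GH+PRL; IC2 for every
#' subtype containing TSH and for the all-negative PIT1 subtype.
#'
#' @param gh,prl,tsh logical vectors of per-patient positivity.
#' @return data.frame with \code{subtype} and \code{ic}.
#' @examples
#' assignSubtype(FALSE, FALSE, FALSE)   # PIT1, IC2
#' @export
assignSubtype <- function(gh, prl, tsh) {
  n <- length(gh)
  stopifnot(length(prl) == n, length(tsh) == n)
  subtype <- character(n)
  for (i in seq_len(n)) {
    pos <- c("GH", "PRL", "TSH")[c(gh[i], prl[i], tsh[i])]
    subtype[i] <- if (length(pos) == 0) "PIT1" else
      paste(pos, collapse = "+")
  }
  data.frame(subtype = subtype,
             ic = ifelse(subtype %in% c("GH", "PRL", "GH+PRL"),
                         "IC1", "IC2"))
}

#' Score all hormone stains of a cohort
#'
#' Bins each patient's per-cell corrected DAB OD for GH, PRL and TSH,
#' applies the three scoring systems, and assigns the subtype and
#' immunostaining cluster from the positivity rule of choice.
#'
#' @param cells named list of per-patient cell tables (or a single
#'   data.frame with \code{patient_id}) holding
#'   \code{<hormone>_dab_cyto} and \code{<hormone>_dab_nuc} columns; the
#'   corrected OD used for binning is cytoplasm minus nucleus, clipped at
#'   zero.
#' @param bins an \code{\link{intensityBins}}.
#' @param rule which positivity rule drives subtyping: \code{allred}
#'   (default), \code{percent} or \code{hscore}.
#' @return list with \code{calls} (one row per patient x hormone:
#'   fraction, PS, IS, TS, h_score, percent and the three positivity
#'   flags) and \code{subtypes} (patient_id, subtype, ic).
#' @export
scoreStains <- function(cells, bins = intensityBins(),
                        rule = c("allred", "percent", "hscore")) {
  rule <- match.arg(rule)
  if (is.data.frame(cells)) cells <- split(cells, cells$patient_id)
  rows <- list()
  pos <- list()
  for (pid in names(cells)) {
    df <- cells[[pid]]
    pvec <- setNames(logical(3), .hormones)
    for (h in .hormones) {
      od <- pmax(df[[paste0(h, "_dab_cyto")]] -
                 df[[paste0(h, "_dab_nuc")]], 0)
      b <- binIntensity(od, bins)
      al <- allredScore(b); hs <- hScore(b); pc <- percentageCall(b)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, hormone = h, f = al$f, PS = al$PS, IS = al$IS,
        TS = al$TS, h_score = hs$score, percent = pc$percent,
        positive_allred = al$positive, positive_hscore = hs$positive,
        positive_percent = pc$positive)
      pvec[h] <- switch(rule, allred = al$positive,
                        percent = pc$positive, hscore = hs$positive)
    }
    pos[[pid]] <- pvec
  }
  calls <- do.call(rbind, rows)
  pm <- do.call(rbind, pos)
  subtypes <- cbind(data.frame(patient_id = names(cells)),
                    assignSubtype(pm[, "GH"], pm[, "PRL"], pm[, "TSH"]))
  list(calls = calls, subtypes = subtypes)
}
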