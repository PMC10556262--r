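#' Yates-corrected chi-square test for a 2x2 table
#'
#' \deqn{\chi^2 = N (\max(0, |ad - bc| - N/2))^2 /
#'   [(a+b)(c+d)(a+c)(b+d)]}
#' with the continuity correction clamped at zero, so exactly
#' proportional tables (ad = bc) give a statistic of 0 and p = 1.  A
#' zero margin makes the test undefined; p = 1 is returned with a
#' warning.
#'
#' @param a,b,c,d nonnegative cell counts (rows = variable, columns =
#'   group: a/c positives, b/d negatives).
#' @return list: \code{chisq}, \code{df} (1), \code{p}.
#' @examples
#' chisqYates(10, 109, 9, 18)$p   # ~0.0016
#' @export
chisqYates <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be nonnegative with positive total")
  N <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warning("zero margin: chi-square test undefined, returning p = 1")
    return(list(chisq = 0, df = 1L, p = 1))
  }
  stat <- N * max(0, abs(a * d - b * c) - N / 2)^2 / prod(margins)
  list(chisq = stat, df = 1L,
       p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Pearson chi-square test for an r x c table
#'
#' Plain \eqn{\sum (O - E)^2 / E} without continuity correction, as used
#' for tables larger than 2x2.
#'
#' @param tab r x c matrix of nonnegative counts; no all-zero row or
#'   column.
#' @return list: \code{chisq}, \code{df} = (r-1)(c-1), \code{p}.
#' @export
chisqRxC <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has an all-zero row or column")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Two-sample t-test from raw values or summary statistics
#'
#' Accepts either raw per-group vectors or the (mean, sd, n) summaries
#' typical of published tables; computes the pooled-variance or Welch
#' statistic with a two-sided p-value.
#'
#' @param x,y raw numeric vectors (used when \code{summary} is NULL).
#' @param summary optional list
#'   \code{list(mean = c(m1, m2), sd = c(s1, s2), n = c(n1, n2))}.
#' @param pooled use the pooled-variance statistic (default Welch).
#' @return list: \code{t}, \code{df}, \code{p}.
#' @examples
#' twoSampleT(summary = list(mean = c(43.6, 39.3), sd = c(14.2, 13.2),
#'                           n = c(119, 27)))$p
#' @export
twoSampleT <- function(x = NULL, y = NULL, summary = NULL,
                       pooled = FALSE) {
  if (is.null(summary)) {
    if (length(x) < 2 || length(y) < 2)
      stop("at least two observations per group required")
    summary <- list(mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)),
                    n = c(length(x), length(y)))
  }
  m <- summary$mean; s <- summary$sd; n <- summary$n
  if (any(n < 2)) stop("at least two observations per group required")
  if (any(s <= 0)) stop("group standard deviations must be positive")
  if (pooled) {
    sp2 <- ((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) / (sum(n) - 2)
    tt <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
    df <- sum(n) - 2
  } else {
    v <- s^2 / n
    tt <- (m[1] - m[2]) / sqrt(sum(v))
    df <- sum(v)^2 / sum(v^2 / (n - 1))
  }
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Percent agreement and Cohen's kappa
#'
#' Raw agreement fraction between two label vectors and Cohen's kappa,
#' \eqn{(p_o - p_e) / (1 - p_e)} with the expected agreement \eqn{p_e}
#' from the marginal label frequencies.
#'
#' @param a,b equal-length label vectors.
#' @return list: \code{agreement}, \code{kappa}.
#' @export
agreementStats <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (length(a) == 0) stop("empty label vectors")
  lev <- union(unique(a), unique(b))
  a <- factor(a, levels = lev); b <- factor(b, levels = lev)
  po <- mean(a == b)
  pe <- sum(prop.table(table(a)) * prop.table(table(b)))
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(agreement = po, kappa = kappa)
}

#' Cohort comparison table
#'
#' Builds the classical clinical comparison table: for each variable,
#' per-group "n (xx.x\%)" counts or "mean (sd)" summaries and a p-value
#' from the matching test — Yates-corrected chi-square for 2x2
#' cross-tabs, plain Pearson chi-square for larger tables, Welch t-test
#' for continuous variables across two groups, one-way ANOVA across
#' more.
#'
#' @param data data.frame of per-patient variables.
#' @param group name of the grouping column in \code{data}.
#' @param variables named character vector mapping variable names to
#'   their type, \code{"categorical"} or \code{"continuous"}.
#' @return data.frame with one row per variable (binary categorical) or
#'   per variable level, formatted per-group columns and a \code{p}
#'   column (full precision) plus \code{p_display} (3 decimals, "<0.001"
#'   below).
#' @export
buildCohortTable <- function(data, group, variables) {
  g <- factor(data[[group]])
  ng <- nlevels(g)
  rows <- list()
  fmtP <- function(p) if (p < 0.001) "<0.001" else sprintf("%.3f", p)
  for (v in names(variables)) {
    type <- variables[[v]]
    x <- data[[v]]
    if (is.null(x)) stop("unknown variable: ", v)
    if (type == "categorical") {
      tab <- table(factor(x), g)
      test <- if (nrow(tab) == 2 && ncol(tab) == 2)
        chisqYates(tab[2, 1], tab[1, 1], tab[2, 2], tab[1, 2])
      else chisqRxC(tab)
      if (nrow(tab) == 2) {
        cells <- sprintf("%d (%.1f%%)", tab[2, ],
                         100 * tab[2, ] / colSums(tab))
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = rownames(tab)[2],
          as.data.frame(setNames(as.list(cells),
                                  paste0("g_", levels(g)))),
          p = test$p, p_display = fmtP(test$p))
      } else {
        for (l in seq_len(nrow(tab))) {
          cells <- sprintf("%d (%.1f%%)", tab[l, ],
                           100 * tab[l, ] / colSums(tab))
          rows[[length(rows) + 1]] <- data.frame(
            variable = v, level = rownames(tab)[l],
            as.data.frame(setNames(as.list(cells),
                                    paste0("g_", levels(g)))),
            p = if (l == 1) test$p else NA_real_,
            p_display = if (l == 1) fmtP(test$p) else "")
        }
      }
    } else if (type == "continuous") {
      cells <- vapply(levels(g), function(l)
        sprintf("%.1f (%.1f)", mean(x[g == l]), sd(x[g == l])), "")
      p <- if (ng == 2) {
        twoSampleT(x[g == levels(g)[1]], x[g == levels(g)[2]])$p
      } else {
        stats::anova(stats::lm(x ~ g))[["Pr(>F)"]][1]
      }
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = "",
        as.data.frame(setNames(as.list(cells),
                                paste0("g_", levels(g)))),
        p = p, p_display = fmtP(p))
    } else stop("unknown variable type for ", v, ": ", type)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published cross-tabulations of the reference cohort
#'
#' Cross-tabulated counts of aggressiveness indicators by morphology
#' cluster (MC1 n=119 / MC2 n=27), immunostaining cluster (IC1 n=68 /
#' IC2 n=78) and combined risk tier (low n=57 / medium n=73 / high
#' n=16) from the published reference cohort of 146 silent PIT1-lineage
#' tumors.  Each element gives the positive counts per group and the
#' group sizes; these are the inputs from which the cohort p-values are
#' recomputed (see \code{\link{chisqYates}}, \code{\link{chisqRxC}}).
#'
#' @return nested list with components \code{mc}, \code{ic}, \code{tier}
#'   (each a list of variables: \code{pos}, \code{n}) and \code{age}
#'   (per-group mean/sd/n summaries).
#' @export
referenceContingencyTables <- function() {
  list(
    mc = list(
      n = c(MC1 = 119, MC2 = 27),
      giant_tumor = c(10, 9),
      sphenoidal_clivus = c(7, 7),
      suprasellar = c(9, 10),
      multiple_surgeries = c(5, 5),
      tenacious = c(32, 9),
      ki67_high = c(4, 3)),
    ic = list(
      n = c(IC1 = 68, IC2 = 78),
      giant_tumor = c(1, 18),
      sphenoidal_clivus = c(5, 9),
      suprasellar = c(5, 14),
      tenacious = c(12, 29),
      ki67_high = c(1, 6)),
    tier = list(
      n = c(low = 57, medium = 73, high = 16),
      giant_tumor = c(1, 9, 9),
      sphenoidal_clivus = c(3, 6, 5),
      suprasellar = c(2, 10, 7),
      multiple_surgeries = c(1, 4, 5),
      tenacious = c(11, 22, 8),
      ki67_high = c(1, 3, 3)),
    age = list(
      mc = list(mean = c(43.6, 39.3), sd = c(14.2, 13.2), n = c(119, 27)),
      ic = list(mean = c(43.5, 42.3), sd = c(13.2, 14.9), n = c(68, 78))))
}

#' Recompute the reference cohort p-values
#'
#' Applies the 2x2 Yates-corrected test (two-group cross-tabs) and the
#' plain Pearson test (three-tier cross-tabs) to the published counts of
#' \code{\link{referenceContingencyTables}}.
#'
#' @return data.frame: grouping, variable, chisq, p.
#' @export
referenceCohortStats <- function() {
  ref <- referenceContingencyTables()
  rows <- list()
  for (grp in c("mc", "ic", "tier")) {
    block <- ref[[grp]]
    n <- block$n
    for (v in setdiff(names(block), "n")) {
      pos <- block[[v]]
      res <- if (length(n) == 2)
        chisqYates(pos[1], n[1] - pos[1], pos[2], n[2] - pos[2])
      else chisqRxC(rbind(pos, n - pos))
      rows[[length(rows) + 1]] <- data.frame(
        grouping = grp, variable = v, chisq = res$chisq, p = res$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
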