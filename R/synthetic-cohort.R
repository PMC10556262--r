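#' @keywords internal
.hormones <- c("GH", "PRL", "TSH")

#' @keywords internal
.subtypes <- c("GH", "PRL", "GH+PRL", "TSH", "GH+TSH", "PRL+TSH",
               "GH+PRL+TSH", "PIT1")

# which hormones stain positive in each of the eight subtypes
.subtypePositivity <- function(subtype) {
  if (subtype == "PIT1") return(setNames(rep(FALSE, 3), .hormones))
  setNames(.hormones %in% strsplit(subtype, "+", fixed = TRUE)[[1]],
           .hormones)
}

#' Configuration for the synthetic cohort generator
#'
#' Default values describe a cohort of silent PIT1-lineage tumors:
#' 120 patients, an 18.5\% prevalence of the aggressive (large-nucleus,
#' eccentric, pleomorphic) morphological phenotype, and subtype
#' frequencies matching the published cohort proportions of the eight
#' GH/PRL/TSH staining combinations.  Morphometric, staining and survival
#' parameters are documented in the package vignette.
#'
#' @param n_patients number of patients.
#' @param p_mc2 probability of the aggressive morphology phenotype.
#' @param subtype_probs named probability vector over the eight staining
#'   subtypes (GH, PRL, GH+PRL, TSH, GH+TSH, PRL+TSH, GH+PRL+TSH, PIT1);
#'   must sum to 1.
#' @param cells_per_patient integer range (min, max) of cells sampled per
#'   patient.
#' @param morph_params per-phenotype nucleus distributions: equivalent
#'   diameter mean/sd (micrometres), log axis-ratio mean/sd, between-patient
#'   diameter sd, and the cytoplasmic expansion radius in micrometres.
#' @param stain_params staining model: positive fraction for a positive
#'   hormone, residual positive fraction for a negative hormone, intensity
#'   bin probabilities for positive cells, DAB OD level per bin, per-cell OD
#'   noise sd, and nonspecific nuclear DAB OD.
#' @param survival_params baseline recurrence hazard (events/year) of the
#'   low tier, log-hazard increments of the medium and high tiers,
#'   administrative censoring horizon (years) and random censoring rate
#'   (events/year).
#' @param clinical_params per-tier probabilities of the synthetic
#'   aggressiveness indicators (giant tumor, suprasellar extension) and the
#'   per-tier mean stromal fraction (logit-normal).
#' @param pixel_size micrometres per pixel for rendered slides.
#' @param seed integer seed.
#' @return a validated list of class \code{cohortConfig}.
#' @seealso \code{\link{generateCohort}}
#' @export
cohortConfig <- function(
    n_patients = 120,
    p_mc2 = 27 / 146,
    subtype_probs = c("GH" = 24, "PRL" = 13, "GH+PRL" = 31, "TSH" = 8,
                      "GH+TSH" = 20, "PRL+TSH" = 7, "GH+PRL+TSH" = 20,
                      "PIT1" = 23) / 146,
    cells_per_patient = c(250L, 350L),
    morph_params = list(
      regular    = list(diam_mean = 7.0, diam_sd = 0.7,
                        logratio_mean = log(1.15), logratio_sd = 0.08),
      aggressive = list(diam_mean = 9.5, diam_sd = 1.3,
                        logratio_mean = log(1.70), logratio_sd = 0.25),
      patient_diam_sd = 0.45,
      expansion_um = 2.5),
    stain_params = list(
      pos_fraction = 0.5, neg_fraction = 0.01,
      bin_probs = c(0.15, 0.45, 0.40),
      bin_od = c(0.30, 0.50, 0.75),
      od_sd = 0.03, nuc_od = 0.05),
    survival_params = list(
      baseline = 0.03, log_hr_medium = log(3), log_hr_high = log(9),
      horizon = 6, censor_rate = 0.10),
    clinical_params = list(
      p_giant = c(low = 0.02, medium = 0.12, high = 0.55),
      p_suprasellar = c(low = 0.035, medium = 0.14, high = 0.44),
      stroma_logit_mean = c(low = -2.0, medium = -1.6, high = -1.2),
      stroma_logit_sd = 0.35),
    pixel_size = 0.25,
    seed = 1L) {
  cfg <- list(n_patients = n_patients, p_mc2 = p_mc2,
              subtype_probs = subtype_probs,
              cells_per_patient = as.integer(cells_per_patient),
              morph_params = morph_params, stain_params = stain_params,
              survival_params = survival_params,
              clinical_params = clinical_params,
              pixel_size = pixel_size, seed = as.integer(seed))
  .validateCohortConfig(cfg)
  class(cfg) <- c("cohortConfig", "list")
  cfg
}

.validateCohortConfig <- function(cfg) {
  sp <- cfg$subtype_probs
  if (!setequal(names(sp), .subtypes))
    stop("subtype_probs must be named with the eight subtypes")
  if (abs(sum(sp) - 1) > 1e-9)
    stop("subtype_probs must sum to 1")
  probs <- c(sp, cfg$p_mc2, cfg$stain_params$pos_fraction,
             cfg$stain_params$neg_fraction, cfg$stain_params$bin_probs)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  sv <- cfg$survival_params
  if (sv$baseline < 0 || sv$censor_rate < 0 || sv$horizon <= 0)
    stop("hazard parameters must be nonnegative, horizon positive")
  if (any(c(cfg$stain_params$bin_od, cfg$stain_params$nuc_od) < 0))
    stop("OD parameters must be nonnegative")
  if (cfg$n_patients < 0) stop("n_patients must be nonnegative")
  if (cfg$cells_per_patient[1] < 1 ||
      cfg$cells_per_patient[2] < cfg$cells_per_patient[1])
    stop("cells_per_patient must be an increasing range with min >= 1")
  invisible(TRUE)
}

# analytic shape descriptors of an ellipse with semi-axes a >= b
.ellipseFeatures <- function(a, b, prefix) {
  area <- pi * a * b
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  out <- data.frame(area = area, perimeter = per,
                    circularity = 4 * pi * area / per^2,
                    maxcaliper = 2 * a, mincaliper = 2 * b,
                    eccentricity = sqrt(1 - (b / a)^2))
  names(out) <- paste0(prefix, "_", names(out))
  out
}

# per-cell DAB draw for one hormone: positives get a bin level + noise,
# negatives sit at the nonspecific background
.drawHormone <- function(n, positive, sp) {
  f <- if (positive) sp$pos_fraction else sp$neg_fraction
  pos <- runif(n) < f
  bins <- rep(0L, n)
  if (positive) {
    bins[pos] <- sample.int(3L, sum(pos), replace = TRUE, prob = sp$bin_probs)
  } else {
    bins[pos] <- 1L
  }
  cyto <- ifelse(bins > 0, sp$bin_od[pmax(bins, 1L)], sp$nuc_od) +
    rnorm(n, 0, sp$od_sd)
  nuc <- sp$nuc_od + rnorm(n, 0, sp$od_sd / 2)
  data.frame(dab_cyto = pmax(cyto, 0), dab_nuc = pmax(nuc, 0),
             pos = pos, bin = bins)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws, per patient, a morphological phenotype (regular vs aggressive),
#' a staining subtype, per-cell nucleus/cell geometry with the thirteen
#' analytic shape features, per-cell per-hormone DAB optical densities,
#' synthetic clinical aggressiveness indicators, and a recurrence-time
#' record whose hazard increases across the low/medium/high risk tiers.
#' Everything is deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @examples
#' coh <- generateCohort(cohortConfig(n_patients = 4, seed = 1))
#' patients(coh)
#' @export
generateCohort <- function(config = cohortConfig()) {
  .validateCohortConfig(config)
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0) {
    return(new("SyntheticCohort",
      patients = data.frame(patient_id = character(), phenotype = character(),
                            subtype = character(), tier = character(),
                            stroma_frac = numeric(), giant_tumor = integer(),
                            suprasellar = integer(), n_cells = integer()),
      cells = list(),
      survival = data.frame(patient_id = character(), time_years = numeric(),
                            event = integer()),
      config = unclass(config)))
  }
  ids <- sprintf("P%03d", seq_len(n))
  phen <- ifelse(runif(n) < config$p_mc2, "aggressive", "regular")
  subtype <- sample(names(config$subtype_probs), n, replace = TRUE,
                    prob = config$subtype_probs)
  ic <- ifelse(subtype %in% c("GH", "PRL", "GH+PRL"), "IC1", "IC2")
  mc <- ifelse(phen == "aggressive", "MC2", "MC1")
  tier <- assignTier(mc, ic)

  mp <- config$morph_params
  sp <- config$stain_params
  cp <- config$clinical_params
  ncell <- sample(config$cells_per_patient[1]:config$cells_per_patient[2],
                  n, replace = TRUE)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    m <- mp[[phen[i]]]
    k <- ncell[i]
    pdiam <- rnorm(1, m$diam_mean, mp$patient_diam_sd)
    diam <- pmax(rnorm(k, pdiam, m$diam_sd), 2)
    q <- pmax(rlnorm(k, m$logratio_mean, m$logratio_sd), 1)
    a <- diam / 2 * sqrt(q)
    b <- diam / 2 / sqrt(q)
    theta <- runif(k, 0, pi)
    nuc <- .ellipseFeatures(a, b, "nucleus")
    cell <- .ellipseFeatures(a + mp$expansion_um, b + mp$expansion_um, "cell")
    df <- cbind(data.frame(patient_id = ids[i],
                           cell_id = sprintf("%s_c%04d", ids[i], seq_len(k)),
                           a_um = a, b_um = b, theta = theta),
                nuc, cell)
    df$nucleus_cell_ratio <- df$nucleus_area / df$cell_area
    posmap <- .subtypePositivity(subtype[i])
    for (h in .hormones) {
      hv <- .drawHormone(k, posmap[[h]], sp)
      names(hv) <- paste0(h, "_", names(hv))
      df <- cbind(df, hv)
    }
    cells[[i]] <- df
  }
  names(cells) <- ids

  stroma <- plogis(rnorm(n, cp$stroma_logit_mean[tier], cp$stroma_logit_sd))
  giant <- as.integer(runif(n) < cp$p_giant[tier])
  supra <- as.integer(runif(n) < cp$p_suprasellar[tier])

  surv <- generateSurvival(tier, config$survival_params,
                           seed = config$seed + 1L)
  surv <- data.frame(patient_id = ids, surv)

  pat <- data.frame(patient_id = ids, phenotype = phen, subtype = subtype,
                    tier = tier, stroma_frac = stroma, giant_tumor = giant,
                    suprasellar = supra, n_cells = ncell)
  new("SyntheticCohort", patients = pat, cells = cells, survival = surv,
      config = unclass(config))
}

#' Simulate recurrence times for risk tiers
#'
#' Exponential recurrence times with hazard
#' \eqn{\lambda(tier) = \lambda_0 \exp(\beta_{tier})}, independently
#' censored by the minimum of an exponential censoring draw and an
#' administrative horizon.
#'
#' @param tier character vector of tiers (\code{low}, \code{medium},
#'   \code{high}).
#' @param params list with \code{baseline}, \code{log_hr_medium},
#'   \code{log_hr_high}, \code{horizon}, \code{censor_rate} (see
#'   \code{\link{cohortConfig}}).
#' @param seed integer seed.
#' @return data.frame with \code{time_years} (> 0) and \code{event}
#'   (1 = recurrence observed, 0 = censored).
#' @export
generateSurvival <- function(tier, params, seed = 1L) {
  if (!all(tier %in% c("low", "medium", "high")))
    stop("tier must be one of low/medium/high")
  if (params$baseline < 0 || params$censor_rate < 0)
    stop("hazards must be nonnegative")
  set.seed(seed)
  n <- length(tier)
  inc <- c(low = 0, medium = params$log_hr_medium,
           high = params$log_hr_high)[tier]
  hazard <- params$baseline * exp(inc)
  trec <- ifelse(hazard > 0, rexp(n, pmax(hazard, 1e-300)), Inf)
  tcens <- pmin(if (params$censor_rate > 0) rexp(n, params$censor_rate)
                else rep(Inf, n), params$horizon)
  event <- as.integer(trec <= tcens)
  time <- pmax(pmin(trec, tcens), 1e-9)
  data.frame(time_years = time, event = event)
}
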