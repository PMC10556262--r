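# numeric columns serialized at 12 significant digits
.writeCsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 12)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full stratification pipeline on a synthetic cohort
#'
#' Executes the stages simulate, segment (optional), features, score,
#' cluster, stratify, stats and report in order, each stage consuming
#' the previous stage's outputs.  Per-stage seeds are derived
#' deterministically from the global seed (seed + stage index), so a
#' rerun with the same configuration and seed reproduces every artifact
#' exactly.
#'
#' By default the morphometric features come from the generator's
#' per-cell tables; setting \code{render_n > 0} additionally renders and
#' re-segments that many patients' slides through the imaging stage
#' (deconvolution, nucleus detection, cell expansion, morphometry) as an
#' imaging-chain validation.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed global seed (defaults to \code{config$seed}).
#' @param outdir optional output directory; when given, every stage
#'   artifact is written (CSV/JSON) together with a manifest.
#' @param render_n number of patients to route through the rendered
#'   imaging stage.
#' @param render_cells cells rendered per slide in the imaging stage.
#' @param embed compute the t-SNE embedding (visualisation only).
#' @param bins DAB \code{\link{intensityBins}} for scoring.
#' @return object of class \code{pitdiaRun}: a list with the cohort,
#'   patient features, stain calls, cluster fit and labels, risk
#'   assignments, survival analyses, cohort table, per-patient report
#'   and manifest.
#' @seealso \code{\link{pipelineReport}}
#' @export
runPipeline <- function(config = cohortConfig(), seed = config$seed,
                        outdir = NULL, render_n = 0L, render_cells = 30L,
                        embed = TRUE, bins = intensityBins()) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  # -- simulate -------------------------------------------------------
  config$seed <- as.integer(seed)
  cohort <- generateCohort(config)
  pat <- patients(cohort)
  n <- nrow(pat)
  if (n < 10) stop("pipeline requires at least 10 patients")
  cells <- cellTables(cohort)
  surv <- survivalData(cohort)

  # -- segment (optional imaging-chain validation) --------------------
  segment <- NULL
  if (render_n > 0) {
    set.seed(seed + 2L)
    segment <- lapply(pat$patient_id[seq_len(min(render_n, n))],
                      function(pid) {
      sl <- renderSlides(head(cells[[pid]], render_cells),
                         width = 448, height = 448,
                         pixel_size = config$pixel_size,
                         expansion_um = config$morph_params$expansion_um,
                         seed = seed + 2L + match(pid, pat$patient_id))
      conc <- deconvolve(rgbToOd(sl$he), heStainMatrix())$concentrations
      nuc <- detectNuclei(conc[, , "hematoxylin"],
                          detectionParams(pixel_size = config$pixel_size))
      cellm <- expandCells(nuc, config$morph_params$expansion_um,
                           config$pixel_size)
      morph <- segmentationMorphometry(nuc, cellm, config$pixel_size)
      list(patient_id = pid, n_truth = max(sl$nucleusMask),
           n_detected = max(nuc), morphometry = morph)
    })
    names(segment) <- pat$patient_id[seq_len(min(render_n, n))]
  }

  # -- features -------------------------------------------------------
  features <- aggregatePatients(cells)
  features <- features[match(pat$patient_id, features$patient_id), ]

  # -- score ----------------------------------------------------------
  scores <- scoreStains(cells, bins = bins)
  scores$subtypes <- scores$subtypes[
    match(pat$patient_id, scores$subtypes$patient_id), ]

  # -- cluster --------------------------------------------------------
  set.seed(seed + 5L)
  X <- standardizeFeatures(as.matrix(features[, -1]))
  rownames(X) <- features$patient_id
  fit <- fitGmmBIC(X, seed = seed + 5L)
  mc <- assignMC(fit, as.data.frame(X))
  D <- correlationDistanceMatrix(X)
  sep <- if (nlevels(droplevels(mc)) >= 2 && min(table(mc)) >= 2)
    separationSummary(D, mc) else NULL
  embedding <- if (embed) tsneEmbed(X, seed = seed + 6L) else NULL

  # -- stratify -------------------------------------------------------
  risk <- data.frame(patient_id = pat$patient_id, mc = as.character(mc),
                     ic = scores$subtypes$ic,
                     subtype = scores$subtypes$subtype)
  risk$tier <- as.character(assignTier(risk$mc, risk$ic))
  sv <- merge(surv, risk, by = "patient_id")
  tierF <- factor(sv$tier, levels = c("low", "medium", "high"))
  survAnalysis <- list(
    km = kmCurve(sv$time_years, sv$event, sv$tier),
    rfs4 = tryCatch(rfsAt(sv$time_years, sv$event, sv$tier, 4),
                    error = function(e) NULL),
    logrank = tryCatch(logrankTest(sv$time_years, sv$event, sv$tier),
                       error = function(e) list(flagged = TRUE,
                                                reason = conditionMessage(e))),
    hr_tier = tryCatch(coxHR(sv$time_years, sv$event, droplevels(tierF)),
                       error = function(e) list(flagged = TRUE,
                                                reason = conditionMessage(e))),
    hr_mc = tryCatch(coxHR(sv$time_years, sv$event,
                           factor(sv$mc, c("MC1", "MC2"))),
                     error = function(e) list(flagged = TRUE,
                                              reason = conditionMessage(e))),
    hr_ic = tryCatch(coxHR(sv$time_years, sv$event,
                           factor(sv$ic, c("IC1", "IC2"))),
                     error = function(e) list(flagged = TRUE,
                                              reason = conditionMessage(e))))

  # -- stats ----------------------------------------------------------
  statsData <- merge(pat, risk[, c("patient_id", "tier")],
                     by = "patient_id", suffixes = c("_true", ""))
  cohortTable <- tryCatch(
    buildCohortTable(statsData, "tier",
                     c(giant_tumor = "categorical",
                       suprasellar = "categorical",
                       stroma_frac = "continuous")),
    error = function(e) NULL)

  # -- report ---------------------------------------------------------
  report <- data.frame(
    patient_id = pat$patient_id, mc = risk$mc, ic = risk$ic,
    subtype = risk$subtype, tier = risk$tier,
    phenotype_true = pat$phenotype, subtype_true = pat$subtype,
    tier_true = pat$tier)
  confusion <- table(truth = report$tier_true, reported = report$tier)
  tierAgreement <- mean(report$tier == report$tier_true)

  manifest <- list(
    package = "PitDIA",
    version = as.character(utils::packageVersion("PitDIA")),
    seed = seed, n_patients = n,
    n_cells = sum(pat$n_cells),
    stages = list(simulate = n, segment = length(segment),
                  features = nrow(features), score = nrow(scores$calls),
                  cluster = length(mc), stratify = nrow(risk),
                  report = nrow(report)),
    selected_K = fit@K, selected_family = fit@family,
    tier_agreement = tierAgreement)

  run <- structure(list(
    cohort = cohort, segment = segment, features = features,
    scores = scores, fit = fit, mc = mc, distance = D,
    separation = sep, embedding = embedding, risk = risk,
    survival = survAnalysis, cohortTable = cohortTable,
    report = report, confusion = confusion,
    tierAgreement = tierAgreement, manifest = manifest),
    class = "pitdiaRun")

  if (!is.null(outdir)) .writeRunArtifacts(run, outdir)
  run
}

.writeRunArtifacts <- function(run, outdir) {
  p <- function(f) file.path(outdir, f)
  .writeCsv(patients(run$cohort), p("patients.csv"))
  .writeCsv(survivalData(run$cohort), p("survival.csv"))
  cellDir <- p("cells")
  if (!dir.exists(cellDir)) dir.create(cellDir)
  for (pid in names(cellTables(run$cohort)))
    .writeCsv(cellTables(run$cohort)[[pid]],
              file.path(cellDir, paste0("cells_", pid, ".csv")))
  .writeCsv(run$features, p("patient_features.csv"))
  .writeCsv(run$scores$calls, p("stain_calls.csv"))
  .writeCsv(run$scores$subtypes, p("subtypes.csv"))
  .writeCsv(data.frame(patient_id = run$features$patient_id,
                       mc = as.character(run$mc)), p("mc_labels.csv"))
  .writeCsv(run$fit@bicTable, p("bic_table.csv"))
  .writeCsv(as.data.frame(run$distance), p("distance_matrix.csv"))
  if (!is.null(run$embedding))
    .writeCsv(data.frame(patient_id = rownames(run$embedding),
                         run$embedding), p("embedding.csv"))
  .writeCsv(run$risk, p("risk.csv"))
  .writeCsv(run$survival$km, p("km_curves.csv"))
  hr <- run$survival[c("logrank", "hr_tier", "hr_mc", "hr_ic", "rfs4")]
  jsonlite::write_json(hr, p("hr_report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  if (!is.null(run$cohortTable))
    .writeCsv(run$cohortTable, p("cohort_table.csv"))
  .writeCsv(run$report, p("report.csv"))
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

#' @export
print.pitdiaRun <- function(x, ...) {
  cat("PitDIA pipeline run:", x$manifest$n_patients, "patients,",
      x$manifest$n_cells, "cells\n")
  cat("  clustering: K =", x$manifest$selected_K, "(",
      x$manifest$selected_family, "), MC2 =", sum(x$mc == "MC2"), "\n")
  cat("  tiers:", paste(names(table(x$risk$tier)), table(x$risk$tier),
      sep = "=", collapse = ", "), "\n")
  cat("  tier agreement with ground truth:",
      sprintf("%.1f%%", 100 * x$tierAgreement), "\n")
  invisible(x)
}

#' Per-patient and cohort summary of a pipeline run
#'
#' Assembles the final report: one row per patient (morphology cluster,
#' per-hormone calls, subtype, immunostaining cluster, risk tier, ground
#' truth where available) and the cohort-level summaries (Kaplan-Meier
#' curves per tier, hazard-ratio table, comparison table, tier confusion
#' matrix against ground truth).
#'
#' @param run a \code{pitdiaRun} from \code{\link{runPipeline}}.
#' @return list with \code{perPatient}, \code{kmCurves}, \code{hazard},
#'   \code{cohortTable}, \code{confusion}, \code{tierAgreement}.
#' @export
pipelineReport <- function(run) {
  stopifnot(inherits(run, "pitdiaRun"))
  list(perPatient = merge(run$report, run$scores$calls, by = "patient_id"),
       kmCurves = run$survival$km,
       hazard = run$survival[c("hr_tier", "hr_mc", "hr_ic")],
       cohortTable = run$cohortTable,
       confusion = run$confusion,
       tierAgreement = run$tierAgreement)
}
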