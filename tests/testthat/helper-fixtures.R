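# shared fixtures: rasterised shapes, hand-built cell tables, label matching

rasterDisc <- function(r, nx = 2 * r + 21, cx = (nx + 1) / 2,
                       cy = (nx + 1) / 2) {
  xy <- expand.grid(x = seq_len(nx), y = seq_len(nx))
  matrix(as.numeric((xy$x - cx)^2 + (xy$y - cy)^2 <= r^2), nx, nx)
}

rasterEllipse <- function(a, b, theta = 0, nx = 2 * a + 21) {
  xy <- expand.grid(x = seq_len(nx), y = seq_len(nx))
  dx <- xy$x - (nx + 1) / 2; dy <- xy$y - (nx + 1) / 2
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  matrix(as.numeric((u / a)^2 + (v / b)^2 <= 1), nx, nx)
}

# minimal hand-built cell table accepted by renderSlides()
makeCellTable <- function(k, diam_um = 7, ratio = 1.15,
                          dab_cyto = 0, dab_nuc = 0,
                          hormones = c("GH", "PRL", "TSH")) {
  a <- rep(diam_um / 2 * sqrt(ratio), k)
  b <- rep(diam_um / 2 / sqrt(ratio), k)
  df <- data.frame(cell_id = sprintf("c%03d", seq_len(k)),
                   a_um = a, b_um = b,
                   theta = seq(0, pi, length.out = k + 1)[seq_len(k)])
  for (h in hormones) {
    df[[paste0(h, "_dab_cyto")]] <- rep(dab_cyto, k)
    df[[paste0(h, "_dab_nuc")]] <- rep(dab_nuc, k)
  }
  df
}

# per-truth-object best IoU plus precision/recall of a detection
matchLabels <- function(truthMask, labMask) {
  nT <- max(truthMask); nD <- max(labMask)
  iou <- vapply(seq_len(nT), function(l) {
    gt <- truthMask == l
    cand <- setdiff(unique(labMask[gt]), 0)
    if (length(cand) == 0) return(0)
    max(vapply(cand, function(d) {
      dm <- labMask == d
      sum(gt & dm) / sum(gt | dm)
    }, 1))
  }, 1)
  matched <- sum(iou > 0.5)
  list(iou = iou, recall = matched / nT,
       precision = if (nD == 0) NA_real_ else matched / nD,
       n_detected = nD)
}

smallConfig <- function(n = 20, seed = 1, ...) {
  cohortConfig(n_patients = n, cells_per_patient = c(60L, 80L),
               seed = seed, ...)
}
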