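#' Two-dimensional t-SNE embedding
#'
#' Exact (dense) t-distributed stochastic neighbour embedding for
#' cohort-scale inputs (n of order 10^2): per-point Gaussian bandwidths
#' calibrated to the target perplexity by bisection, symmetrised input
#' affinities, Student-t output kernel, and gradient descent with early
#' exaggeration and momentum.  The embedding is for visualisation only;
#' no downstream computation in the package depends on it.
#'
#' @param x numeric matrix (rows = observations, n >= 10).
#' @param seed integer seed; the same seed reproduces the embedding
#'   exactly.
#' @param perplexity effective neighbourhood size (default 10, suited to
#'   cohorts of ~100 patients); must be below the number of rows.
#' @param max_iter gradient-descent iterations.
#' @return n x 2 matrix of coordinates, or NULL (with a warning) when
#'   n < 10.
#' @export
tsneEmbed <- function(x, seed = 1L, perplexity = 10, max_iter = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) {
    warning("t-SNE skipped: fewer than 10 observations")
    return(NULL)
  }
  if (perplexity >= n)
    stop("perplexity must be smaller than the number of observations")
  set.seed(seed)

  D2 <- as.matrix(dist(x))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi))
        (lo + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5; eta <- 100
  for (it in seq_len(max_iter)) {
    ex <- if (it <= 100) 4 else 1
    if (it == 251) momentum <- 0.8
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  dimnames(Y) <- list(rownames(x), c("tsne1", "tsne2"))
  Y
}
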