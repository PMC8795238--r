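# Small shared numerical helpers.

#' Column-wise z-score of a matrix
#'
#' Genes with zero variance get a zero z-score rather than NaN so that
#' downstream set scores stay defined on degenerate fixtures.
#'
#' @param x numeric matrix (cells x genes).
#' @return matrix of the same shape, each column centered and scaled.
#' @keywords internal
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over a fixed histogram of intensities
#' in [0, 1]. Used as the default per-channel stain positivity threshold.
#'
#' @param img numeric matrix with values in [0, 1].
#' @param n_bins histogram resolution.
#' @return scalar threshold in (0, 1).
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L) return(max(v, 0))
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[n_bins]
  between <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Symmetric fixed-point ICA
#'
#' Compact FastICA-style rotation (tanh contrast, symmetric decorrelation)
#' used to spread a whitened low-dimensional embedding into statistically
#' independent axes before trajectory construction.
#'
#' @param x numeric matrix (observations x variables), will be whitened.
#' @param n_comp number of independent components to extract.
#' @param max_iter,tol iteration control.
#' @param seed integer seed for the random initial rotation.
#' @return observations x n_comp matrix of independent components.
#' @keywords internal
fast_ica <- function(x, n_comp = 2L, max_iter = 200L, tol = 1e-6, seed = 12345L) {
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  sv <- svd(x, nu = 0, nv = n_comp)
  keep <- sv$d[seq_len(n_comp)] > 1e-10
  if (!all(keep)) return(x[, seq_len(n_comp), drop = FALSE])
  # whitened data: n x n_comp with identity covariance
  z <- x %*% sv$v %*% diag(1 / sv$d[seq_len(n_comp)], n_comp) * sqrt(nrow(x))
  set.seed(seed)
  w <- matrix(rnorm(n_comp * n_comp), n_comp)
  sym_decor <- function(w) {
    e <- eigen(w %*% Matrix::t(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% Matrix::t(e$vectors) %*% w
  }
  w <- sym_decor(w)
  for (i in seq_len(max_iter)) {
    wz <- z %*% Matrix::t(w)
    g <- tanh(wz)
    gp <- 1 - g^2
    w1 <- (Matrix::t(g) %*% z) / nrow(z) - diag(colMeans(gp), n_comp) %*% w
    w1 <- sym_decor(w1)
    delta <- max(abs(abs(diag(w1 %*% Matrix::t(w))) - 1))
    w <- w1
    if (delta < tol) break
  }
  z %*% Matrix::t(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  stop(msg, call. = FALSE)
}
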