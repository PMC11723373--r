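# EEG spectral-image preprocessing: FFT band power, low-pass masking,
# electrode-grid imaging with cubic-spline interpolation, normalization and
# ZCA whitening.

#' Band power of one EEG segment
#'
#' Each channel is treated as an independent measurement: the segment is
#' detrended (per-channel mean removed), transformed by FFT, and the squared
#' DFT magnitudes are summed over the one-sided frequency bins falling inside
#' each band.
#' @param segment numeric matrix `[n_channels, n_samples]`
#' @param bands data.frame as from [band_definitions()]
#' @param fs sampling rate (Hz)
#' @param detrend subtract the per-channel mean before the FFT
#' @return matrix `[n_bands, n_channels]` of non-negative powers
#' @export
band_power <- function(segment, bands = band_definitions(), fs,
                       detrend = TRUE) {
  segment <- as.matrix(segment)
  if (ncol(segment) < 2L) stop("segment needs at least 2 samples")
  if (any(bands$hi_hz >= fs / 2)) stop("band extends to or beyond Nyquist")
  if (any(bands$lo_hz <= 0) || any(bands$lo_hz >= bands$hi_hz))
    stop("invalid band bounds")
  x <- t(segment)
  if (detrend) x <- sweep(x, 2, colMeans(x))
  X <- stats::mvfft(x)
  n <- nrow(X)
  f <- (seq_len(n) - 1) * fs / n
  onesided <- f <= fs / 2
  p <- Mod(X)^2
  out <- matrix(0, nrow = nrow(bands), ncol = nrow(segment),
                dimnames = list(bands$name, rownames(segment)))
  for (b in seq_len(nrow(bands))) {
    sel <- onesided & f >= bands$lo_hz[b] & f <= bands$hi_hz[b]
    out[b, ] <- colSums(p[sel, , drop = FALSE])
  }
  out
}

#' Low-pass mask on a two-sided DFT spectrum
#'
#' Zeroes all bins whose frequency magnitude exceeds `cutoff_hz`; bins at or
#' below the cutoff are unchanged. Operates on the complex output of
#' [stats::mvfft()] (columns = channels).
#' @param spectrum complex matrix `[n, n_channels]`
#' @param cutoff_hz cutoff frequency (at most Nyquist)
#' @param fs sampling rate
#' @export
lowpass_mask <- function(spectrum, cutoff_hz, fs) {
  spectrum <- as.matrix(spectrum)
  if (cutoff_hz > fs / 2 + 1e-12) stop("cutoff above Nyquist")
  n <- nrow(spectrum)
  k <- seq_len(n) - 1
  fmag <- pmin(k, n - k) * fs / n
  spectrum[fmag > cutoff_hz, ] <- 0
  spectrum
}

#' Electrode grid layout for the 23-channel bipolar montage
#'
#' Maps each bipolar channel to a cell of a 5x5 scalp grid (rows front to
#' back, columns left to right), preserving spatial adjacency when the
#' per-band channel-power vector is rendered as a 2-D field. Read from the
#' bundled layout table unless a custom table is supplied.
#' @param path optional CSV with columns `channel`, `row`, `col`
#' @param n_grid grid side length
#' @return list with `cell_channel` (length `n_grid^2`, channel index per
#'   cell in column-major order; unoccupied cells borrow the nearest
#'   occupied cell) and the layout table
#' @export
grid_layout <- function(path = NULL, n_grid = 5L) {
  if (is.null(path))
    path <- system.file("extdata", "chb23_grid.csv", package = "seizcast",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "row", "col") %in% names(tab)))
  if (any(tab$row < 1 | tab$row > n_grid | tab$col < 1 | tab$col > n_grid))
    stop("layout rows/cols outside the grid")
  occ <- matrix(NA_integer_, n_grid, n_grid)
  for (r in seq_len(nrow(tab))) {
    if (!is.na(occ[tab$row[r], tab$col[r]])) stop("duplicate grid cell in layout")
    occ[tab$row[r], tab$col[r]] <- r
  }
  cell_channel <- integer(n_grid * n_grid)
  t <- 0L
  for (cl in seq_len(n_grid)) for (rw in seq_len(n_grid)) {
    t <- t + 1L
    if (!is.na(occ[rw, cl])) { cell_channel[t] <- occ[rw, cl]; next }
    d2 <- (tab$row - rw)^2 + (tab$col - cl)^2
    cell_channel[t] <- which.min(d2)   # nearest occupied cell's channel
  }
  list(cell_channel = cell_channel, table = tab, n_grid = n_grid)
}

#' Cubic-spline upsampling matrix
#'
#' Interpolation operator from `n_src` grid knots to `n_out` evenly spaced
#' positions spanning the same extent, using natural cubic splines (exact at
#' the knots; reproduces constant and linear fields exactly).
#' @keywords internal
interp_matrix <- function(n_src, n_out) {
  xt <- seq(1, n_src, length.out = n_out)
  A <- matrix(0, n_out, n_src)
  for (j in seq_len(n_src)) {
    e <- numeric(n_src); e[j] <- 1
    A[, j] <- stats::splinefun(seq_len(n_src), e, method = "natural")(xt)
  }
  A
}

#' Convert band powers to a spectral image
#'
#' Arranges each band's channel-power vector on the electrode grid and
#' resamples it to `out_size` x `out_size` by bicubic (cubic-spline)
#' interpolation. Band (third-dimension) order is fixed as theta, alpha,
#' beta.
#' @param powers matrix `[3, n_channels]` as from [band_power()]
#' @param out_size output resolution (default 64)
#' @param layout a [grid_layout()]
#' @return numeric array `[out_size, out_size, 3]`
#' @export
to_spectral_image <- function(powers, out_size = 64L, layout = grid_layout()) {
  powers <- as.matrix(powers)
  if (nrow(powers) != 3L) stop("powers must have 3 band rows")
  if (any(!is.finite(powers))) stop("non-finite band powers")
  arr <- array(powers, dim = c(3, ncol(powers), 1))
  images_from_powers(arr, out_size = out_size, layout = layout)[, , , 1]
}

#' Batch conversion of band powers to spectral images
#'
#' @param powers array `[3, n_channels, n_segments]`
#' @return array `[out_size, out_size, 3, n_segments]`
#' @keywords internal
images_from_powers <- function(powers, out_size = 64L, layout = grid_layout(),
                               A = NULL) {
  d <- dim(powers)
  ng <- layout$n_grid
  if (is.null(A)) A <- interp_matrix(ng, out_size)
  m <- d[3] * 3L
  # grid fields, column-major cells: [ng^2, 3 * nseg]
  G <- matrix(aperm(powers[, layout$cell_channel, , drop = FALSE], c(2, 1, 3)),
              nrow = ng * ng, ncol = m)
  # vec(A P A') = (A kron A) vec(P): one matrix product for the whole batch
  AA <- kronecker(A, A)
  array(AA %*% G, dim = c(out_size, out_size, 3, d[3]))
}

#' Batched band power over all windows of a signal stretch
#'
#' Equivalent to calling [band_power()] on consecutive `win`-sample windows
#' (trailing remainder dropped), evaluated with a banded sub-DFT as matrix
#' products. Frequencies above `lowpass_hz` are excluded up front, which is
#' the frequency-domain low-pass step.
#' @param x numeric matrix `[n_channels, n_samples]`
#' @param win window length in samples
#' @return array `[n_bands, n_channels, n_windows]`
#' @keywords internal
batch_band_power <- function(x, win, fs, bands = band_definitions(),
                             lowpass_hz = 30) {
  nseg <- ncol(x) %/% win
  if (nseg < 1L) return(array(0, dim = c(nrow(bands), nrow(x), 0)))
  f <- (seq_len(win) - 1) * fs / win
  sel <- which(f >= min(bands$lo_hz) & f <= min(max(bands$hi_hz), lowpass_hz) &
               f <= fs / 2)
  ang <- -2 * pi * outer(f[sel] / fs * win, (seq_len(win) - 1) / win)
  Fr <- cos(ang); Fi <- sin(ang)
  B <- matrix(0, nrow(bands), length(sel))
  for (b in seq_len(nrow(bands)))
    B[b, ] <- as.numeric(f[sel] >= bands$lo_hz[b] & f[sel] <= bands$hi_hz[b])
  out <- array(0, dim = c(nrow(bands), nrow(x), nseg))
  for (ch in seq_len(nrow(x))) {
    S <- matrix(x[ch, seq_len(nseg * win)], nrow = win)
    P <- (Fr %*% S)^2 + (Fi %*% S)^2
    out[, ch, ] <- B %*% P
  }
  out
}

# ---- normalization and ZCA whitening -------------------------------------

#' Fit a per-feature normalizer
#'
#' Standardization (zero mean, unit variance per pixel over the fitting set)
#' by default; min-max scaling to [0, 1] as an alternative.
#' @param X numeric matrix `[N, D]`
#' @export
fit_normalizer <- function(X, method = c("standard", "minmax")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "standard") {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd < 1e-12] <- 1
    structure(list(method = method, center = mu, scale = sd),
              class = "seiz_normalizer")
  } else {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    rg <- hi - lo; rg[rg < 1e-12] <- 1
    structure(list(method = method, center = lo, scale = rg),
              class = "seiz_normalizer")
  }
}

#' @export
predict.seiz_normalizer <- function(object, newdata, ...) {
  sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
}

#' Fit a ZCA whitening transform
#'
#' Zero-phase component analysis: W = V (Lambda + eps)^(-1/2) V', the unique
#' symmetric whitening transform (closest to the identity map among all
#' whitening transforms). Stored in thin eigenbasis form so that
#' high-dimensional pixel spaces never require the full D x D matrix.
#' Directions outside the span of the fitting covariance (unavoidable when
#' there are fewer images than pixels) are passed through unscaled.
#' @param X numeric matrix `[N, D]` (rows = flattened images), `N >= 2`
#' @param epsilon eigenvalue regularization; with `epsilon = 0` a
#'   rank-deficient covariance is an error
#' @return object of class `zca_transform`
#' @export
fit_zca <- function(X, epsilon = 1e-5) {
  X <- as.matrix(X)
  N <- nrow(X); D <- ncol(X)
  if (N < 2L) stop("ZCA needs at least 2 samples")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2 / (N - 1)
  if (epsilon == 0) {
    if (length(lambda) < D || min(lambda) < 1e-12 * max(lambda, 1e-300))
      stop("singular covariance with epsilon = 0; increase epsilon")
  }
  structure(list(mean = mu, V = sv$v, lambda = lambda, epsilon = epsilon,
                 dim = D),
            class = "zca_transform")
}

#' Apply (or invert) a ZCA whitening transform
#' @param object a [fit_zca()] transform
#' @param newdata matrix `[N, D]`
#' @param inverse undo the whitening
#' @export
predict.zca_transform <- function(object, newdata, inverse = FALSE, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$dim) stop("dimension mismatch")
  eps <- object$epsilon
  lam <- object$lambda
  # directions outside the span of the fitting covariance pass unscaled:
  # with fewer samples than pixels the formula's eps^(-1/2) factor would
  # blow up any out-of-span component of new data
  if (!inverse) {
    Xc <- sweep(X, 2, object$mean)
    fac <- 1 / sqrt(lam + eps)
    proj <- Xc %*% object$V
    proj %*% (t(object$V) * (fac - 1)) + Xc
  } else {
    fac <- sqrt(lam + eps)
    proj <- X %*% object$V
    Y <- proj %*% (t(object$V) * (fac - 1)) + X
    sweep(Y, 2, object$mean, "+")
  }
}

#' Dense matrix form of a ZCA transform (small dimensions only)
#' @export
as.matrix.zca_transform <- function(x, ...) {
  if (x$dim > 4096) stop("transform too large to materialize")
  fac <- 1 / sqrt(x$lambda + x$epsilon)
  x$V %*% (t(x$V) * (fac - 1)) + diag(1, x$dim)
}
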