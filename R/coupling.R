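# Cross-region coupling: imaginary coherence (undirected, zero-lag
# insensitive), generalized partial directed coherence from VAR fits
# (directed), and band-limited cross-correlation.

#' Imaginary coherence spectrum
#'
#' Cross- and auto-spectra are Welch-averaged over non-overlapping
#' Hann-tapered windows; the statistic is the squared imaginary part of
#' the cross-spectrum normalized by the auto-spectra:
#' `C_XY(f) = Im(P_XY(f))^2 / (P_XX(f) * P_YY(f))`.
#' Because only the imaginary part enters, zero-time-lag (volume
#' conduction) synchrony contributes nothing. `squared = FALSE` gives the
#' unsquared variant `|Im(coherency)|`.
#'
#' @param x,y Equal-length simultaneous signals (µV).
#' @param fs Sampling rate (Hz).
#' @param segment_length Welch window (s).
#' @param squared Use the squared form (default) or |Im(coherency)|.
#' @return A `coherence_spectrum`: freqs, coherence in [0, 1).
#' @export
imaginary_coherence <- function(x, y, fs, segment_length = 1,
                                squared = TRUE) {
  if (length(x) != length(y)) stop("signals must be simultaneous (equal length)")
  L <- round(segment_length * fs)
  nw <- floor(length(x) / L)
  if (nw < 8) stop("need >= 8 windows; supply longer signals")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / L))
  half <- floor(L / 2)
  Pxx <- Pyy <- numeric(half + 1)
  Pxy <- complex(half + 1)
  for (j in seq_len(nw)) {
    idx <- ((j - 1) * L + 1):(j * L)
    X <- stats::fft((x[idx] - mean(x[idx])) * w)[1:(half + 1)]
    Y <- stats::fft((y[idx] - mean(y[idx])) * w)[1:(half + 1)]
    Pxx <- Pxx + Mod(X)^2
    Pyy <- Pyy + Mod(Y)^2
    Pxy <- Pxy + X * Conj(Y)
  }
  denom <- Pxx * Pyy
  co <- ifelse(denom > 0,
               if (squared) Im(Pxy / nw)^2 / (Pxx / nw) / (Pyy / nw)
               else abs(Im((Pxy / nw) / sqrt((Pxx / nw) * (Pyy / nw)))),
               NA_real_)
  structure(list(freqs = (0:half) * fs / L, coherence = co,
                 n_segments = nw, squared = squared),
            class = "coherence_spectrum")
}

# Daubechies-4 (4-tap) scaling filter
.db4_h <- c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604)

dwt_step <- function(x, h) {
  g <- rev(h) * c(1, -1, 1, -1)
  n <- length(x)
  xx <- c(x, x[1:2])                       # periodic extension
  idx <- seq(1, n, by = 2)
  a <- d <- numeric(n / 2)
  for (k in 0:3) {
    a <- a + h[k + 1] * xx[idx + k]
    d <- d + g[k + 1] * xx[idx + k]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h) {
  g <- rev(h) * c(1, -1, 1, -1)
  n <- 2 * length(a)
  x <- numeric(n)
  aa <- c(a[length(a)], a)                 # periodic wrap
  dd <- c(d[length(d)], d)
  for (i in seq_along(a)) {
    pos <- (2 * (i - 1) - 2):(2 * (i - 1) + 1)  # taps land on pos+1 (mod n)
    for (k in 0:3) {
      j <- (2 * (i - 1) + k) %% n + 1
      x[j] <- x[j] + h[k + 1] * a[i] + g[k + 1] * d[i]
    }
  }
  x
}

#' Wavelet shrinkage denoising
#'
#' Periodic Daubechies-4 discrete wavelet transform over `levels` levels;
#' detail coefficients are soft-thresholded at the universal threshold
#' `sigma * sqrt(2 log N)` with `sigma` estimated from the finest-level
#' details (MAD / 0.6745). Band-limited oscillatory content (4-30 Hz at
#' typical rates) passes nearly unchanged while broadband noise shrinks.
#'
#' @param x Numeric signal (length >= 64; internally padded by reflection
#'   to a multiple of `2^levels`).
#' @param levels Decomposition depth (default 5).
#' @return Denoised signal, same length as `x`.
#' @export
wavelet_denoise <- function(x, levels = 5) {
  n0 <- length(x)
  if (n0 < 64) stop("need >= 64 samples")
  block <- 2^levels
  pad <- (block - n0 %% block) %% block
  xx <- if (pad > 0) c(x, rev(x)[1:pad]) else x
  h <- .db4_h
  approx <- xx
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    st <- dwt_step(approx, h)
    approx <- st$a
    details[[l]] <- st$d
  }
  sigma <- stats::median(abs(details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(xx)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (l in seq_len(levels)) details[[l]] <- soft(details[[l]])
  for (l in rev(seq_len(levels))) approx <- idwt_step(approx, details[[l]], h)
  approx[1:n0]
}

#' Least-squares VAR fit with BIC order selection
#'
#' Stacks the lagged regressions of all supplied segments and fits a
#' vector autoregression by ordinary least squares for each order up to
#' `max_order`, choosing the order minimizing the Bayesian information
#' criterion. The fit must be stable (companion-matrix spectral
#' radius < 1).
#'
#' @param segments A matrix (variables x time) or list of such matrices.
#' @param max_order Largest order tried.
#' @param order Fixed order (skips selection) if non-NULL.
#' @return A `var_fit`: `A` (d x d x p coefficient array), `Sigma`
#'   (noise covariance), `p`, `bic` (per tried order), `radius`.
#' @export
fit_var <- function(segments, max_order = 20, order = NULL) {
  if (!is.list(segments)) segments <- list(segments)
  segments <- lapply(segments, function(s) {
    if (is.vector(s)) s <- matrix(s, nrow = 1)
    s - rowMeans(s)
  })
  d <- nrow(segments[[1]])
  if (any(vapply(segments, function(s) stats::sd(as.vector(s)), 1) == 0))
    stop("degenerate (constant) segment; covariance is singular")
  build <- function(p) {
    Ys <- NULL; Xs <- NULL
    for (s in segments) {
      Tn <- ncol(s)
      if (Tn <= p + d) next
      Y <- t(s[, (p + 1):Tn, drop = FALSE])
      X <- do.call(cbind, lapply(seq_len(p), function(r)
        t(s[, (p + 1 - r):(Tn - r), drop = FALSE])))
      Ys <- rbind(Ys, Y); Xs <- rbind(Xs, X)
    }
    list(Y = Ys, X = Xs)
  }
  orders <- if (is.null(order)) seq_len(max_order) else order
  bics <- rep(NA_real_, length(orders))
  best <- NULL
  for (oi in seq_along(orders)) {
    p <- orders[oi]
    bx <- build(p)
    if (is.null(bx$Y) || nrow(bx$Y) < 10 * p * d) next
    cf <- tryCatch(qr.solve(bx$X, bx$Y), error = function(e) NULL)
    if (is.null(cf)) next
    resid <- bx$Y - bx$X %*% cf
    N <- nrow(bx$Y)
    Sig <- crossprod(resid) / (N - p * d)
    det_s <- det(Sig)
    if (!is.finite(det_s) || det_s <= 0) next
    bics[oi] <- log(det_s) + log(N) * p * d^2 / N
    if (is.null(best) || bics[oi] < best$bic_val) {
      A <- array(0, c(d, d, p))
      for (r in seq_len(p))
        A[, , r] <- t(cf[((r - 1) * d + 1):(r * d), , drop = FALSE])
      best <- list(A = A, Sigma = Sig, p = p, bic_val = bics[oi])
    }
  }
  if (is.null(best)) stop("VAR fit failed for every order (too little data?)")
  # companion-matrix stability
  p <- best$p
  comp <- matrix(0, d * p, d * p)
  for (r in seq_len(p)) comp[1:d, ((r - 1) * d + 1):(r * d)] <- best$A[, , r]
  if (p > 1) comp[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  radius <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (radius >= 1)
    stop("unstable VAR fit (companion spectral radius ", round(radius, 4), ")")
  structure(list(A = best$A, Sigma = best$Sigma, p = p,
                 bic = stats::setNames(bics, orders), radius = radius),
            class = "var_fit")
}

#' Generalized partial directed coherence
#'
#' From a fitted VAR, `Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs)` and
#' `pi_ij(f) = (|Abar_ij(f)| / sigma_i) /
#'             sqrt(sum_k |Abar_kj(f)|^2 / sigma_k^2)`,
#' the influence of source j on target i at frequency f, normalized so
#' that `sum_i pi_ij(f)^2 = 1` for every source and frequency (noise
#' variances `sigma_k^2` from the fit's residual covariance diagonal).
#'
#' @param fit A `var_fit`.
#' @param freqs Frequencies (Hz).
#' @param fs Sampling rate of the fitted data (Hz).
#' @return A `gpdc_result`: freqs, `pi` array (target i x source j x f),
#'   var_order, noise_variances.
#' @export
gpdc <- function(fit, freqs, fs) {
  d <- nrow(fit$Sigma)
  s2 <- diag(fit$Sigma)
  if (any(s2 <= 0) || det(fit$Sigma) <= 0) stop("singular noise covariance")
  pi_arr <- array(NA_real_, c(d, d, length(freqs)))
  for (fi in seq_along(freqs)) {
    z <- exp(-1i * 2 * pi * freqs[fi] * seq_len(fit$p) / fs)
    Abar <- diag(d) + 0i
    for (r in seq_len(fit$p)) Abar <- Abar - fit$A[, , r] * z[r]
    W <- Mod(Abar)^2 / s2            # weighted |Abar_ij|^2 / sigma_i^2
    denom <- sqrt(colSums(W))
    pi_arr[, , fi] <- sqrt(W) / rep(denom, each = d)
  }
  structure(list(freqs = freqs, pi = pi_arr, var_order = fit$p,
                 noise_variances = s2), class = "gpdc_result")
}

#' Band-mean gPDC between two directions
#'
#' @param g A `gpdc_result` for a 2-variable fit (1 = x, 2 = y).
#' @param band A [band_definition()].
#' @return Named vector: `x_to_y`, `y_to_x` band means.
#' @export
gpdc_band_means <- function(g, band) {
  sel <- g$freqs >= band$f_low & g$freqs < band$f_high
  c(x_to_y = mean(g$pi[2, 1, sel]), y_to_x = mean(g$pi[1, 2, sel]))
}

#' Directed coupling report over oscillatory epochs
#'
#' Restricts the two signals to detected oscillatory events, and for each
#' event: decimates to the analysis rate, wavelet-denoises, fits a VAR
#' (BIC order selection) and evaluates gPDC; band means are averaged
#' across events, per direction.
#'
#' @param x,y Simultaneous signals (µV), e.g. hippocampal and prelimbic.
#' @param fs Sampling rate (Hz).
#' @param events Event data frame (start/stop in s) from
#'   [detect_oscillations()].
#' @param bands Bands to summarize (default theta/beta).
#' @param analysis_fs VAR analysis rate (Hz, default 200).
#' @param max_order Maximum VAR order.
#' @param denoise Apply [wavelet_denoise()] per segment (default TRUE).
#' @return List with `per_band` (matrix band x direction), `n_events`,
#'   `var_orders`, and per-event band means in `per_event`.
#' @export
directed_coupling_report <- function(x, y, fs, events,
                                     bands = default_bands()[c("theta", "beta")],
                                     analysis_fs = 200, max_order = 20,
                                     denoise = TRUE) {
  dec <- round(fs / analysis_fs)
  if (dec < 1) dec <- 1
  per_event <- list()
  var_orders <- integer(0)
  for (i in seq_len(nrow(events))) {
    idx <- max(1, round(events$start[i] * fs)):min(length(x),
                                                   round(events$stop[i] * fs))
    if (length(idx) < 2 * fs) next
    seg <- rbind(x[idx], y[idx])
    # denoise at the native rate (where the wavelet basis compresses the
    # oscillation well), then decimate to the VAR analysis rate
    if (denoise) seg <- t(apply(seg, 1, wavelet_denoise))
    if (dec > 1) {
      r <- recording(seg, fs, channel_depths = c(0, 100), region = "pair")
      seg <- downsample(r, fs / dec)$samples
    }
    fit <- tryCatch(fit_var(seg, max_order = max_order),
                    error = function(e) NULL)
    if (is.null(fit)) next
    g <- gpdc(fit, freqs = seq(1, min(45, fs / dec / 2 - 1), by = 0.5),
              fs = fs / dec)
    bm <- vapply(bands, function(b) gpdc_band_means(g, b), numeric(2))
    per_event[[length(per_event) + 1]] <- bm
    var_orders <- c(var_orders, fit$p)
  }
  if (length(per_event) < 3) stop("fewer than 3 usable oscillatory segments")
  arr <- simplify2array(per_event)   # direction x band x event
  per_band <- apply(arr, c(1, 2), mean)
  rownames(per_band) <- c("x_to_y", "y_to_x")
  list(per_band = t(per_band), n_events = length(per_event),
       var_orders = var_orders, per_event = arr)
}

#' Band-limited normalized cross-correlation
#'
#' Both signals are band-pass filtered, then the normalized
#' cross-correlation over lags in `[-max_lag, max_lag]` is returned; the
#' peak is at a positive lag when `y` lags `x`.
#'
#' @param x,y Simultaneous signals.
#' @param fs Sampling rate (Hz).
#' @param band A [band_definition()].
#' @param max_lag Maximum lag (s).
#' @return A `crosscorrelogram`: lags (s), correlation, peak_lag,
#'   peak_value.
#' @export
band_crosscorrelation <- function(x, y, fs, band = band_definition("theta", 4, 12),
                                  max_lag = 0.2) {
  bp <- function(v) {
    des <- butter_design(3, c(band$f_low, band$f_high) / (fs / 2), "pass")
    filtfilt(des$b, des$a, v, padlen = min(length(v) - 1,
                                           ceiling(3 * fs / band$f_low)))
  }
  xf <- bp(x); yf <- bp(y)
  cc <- stats::ccf(yf, xf, lag.max = round(max_lag * fs), plot = FALSE)
  lags <- as.vector(cc$lag) / fs
  vals <- as.vector(cc$acf)
  ipk <- which.max(abs(vals))
  structure(list(lags = lags, correlation = vals,
                 peak_lag = lags[ipk], peak_value = vals[ipk]),
            class = "crosscorrelogram")
}
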