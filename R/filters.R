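# --- Butterworth design ------------------------------------------------------
# Designed in zero-pole-gain form (analog lowpass prototype -> band transform
# -> bilinear transform), then expanded to transfer-function polynomials.
# Coefficients agree with scipy.signal.butter to ~1e-12.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth filter
#'
#' Returns transfer-function coefficients `b` (numerator) and `a`
#' (denominator) for a digital Butterworth filter obtained by bilinear
#' transform of the analog prototype.
#'
#' @param order Filter order (of the analog prototype; a band-pass has
#'   `2*order` poles).
#' @param w Critical frequency(ies) as a fraction of the Nyquist frequency,
#'   in (0, 1). Length 1 for "low"/"high", length 2 for "pass".
#' @param type One of "low", "high", "pass".
#' @return List with numeric vectors `b` and `a` (`a[1] == 1`).
#' @export
butter_design <- function(order, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  if (any(w <= 0) || any(w >= 1)) stop("critical frequencies must lie in (0, 1) of Nyquist")
  if (type == "pass" && (length(w) != 2 || w[1] >= w[2]))
    stop("band-pass needs w = c(low, high) with low < high")

  # analog lowpass prototype poles (Buttap), unit cutoff
  k0 <- seq_len(order)
  p <- exp(1i * pi * (2 * k0 + order - 1) / (2 * order))
  z <- complex(0)
  k <- 1

  fs2 <- 2  # internal sampling rate for bilinear transform
  warped <- 2 * fs2 * tan(pi * w / fs2)

  if (type == "low") {
    wo <- warped
    p <- p * wo
    k <- k * wo^order
  } else if (type == "high") {
    wo <- warped
    p_lp <- p
    p <- wo / p_lp
    k <- k * Re(prod(-p_lp))  # z_lp is empty for the prototype
    z <- rep(0 + 0i, order)
  } else {
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    p_lp <- p * bw / 2
    p <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
    z <- rep(0 + 0i, order)
    k <- k * bw^order
  }

  # bilinear transform zpk -> digital
  fs2x <- 2 * fs2
  z_d <- (fs2x + z) / (fs2x - z)
  p_d <- (fs2x + p) / (fs2x - p)
  k_d <- k * Re(prod(fs2x - z) / prod(fs2x - p))
  # zeros at infinity map to z = -1
  z_d <- c(z_d, rep(-1 + 0i, length(p_d) - length(z_d)))

  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a / a[1])
}

# direct-form IIR filter via stats::filter (convolution MA part + recursive
# AR); written to minimize large temporaries — signals here run to millions
# of samples
iir_filter <- function(b, a, x) {
  nb <- length(b)
  u <- unclass(stats::filter(x, b, method = "convolution", sides = 1))
  # sides = 1 leaves the first nb-1 values NA; fill them directly
  for (t in seq_len(min(nb - 1, length(x))))
    u[t] <- sum(b[1:t] * x[t:1])
  if (length(a) > 1) {
    u <- unclass(stats::filter(u, -a[-1], method = "recursive"))
  }
  attributes(u) <- NULL
  u
}

# one filtering pass with DC-offset compensation so that constant segments sit
# at the filter's steady state (suppresses start-up transients)
iir_filter_ss <- function(b, a, x) {
  g0 <- sum(b) / sum(a)
  if (abs(g0) < 0.5) {       # zero DC gain (high/band-pass): remove mean
    iir_filter(b, a, x - mean(x))
  } else {                   # low-pass: reference to the first sample
    x0 <- x[1]
    iir_filter(b, a, x - x0) + g0 * x0
  }
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forwards and backwards with odd-reflection edge
#' padding, giving zero phase distortion and squared magnitude response.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric signal.
#' @param padlen Edge padding length in samples; default scales with the
#'   filter's settling span.
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1, max(3 * (max(length(a), length(b)) - 1), 512L))
  if (padlen >= n) padlen <- n - 1
  # odd reflection about end points
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xx <- c(pre, x, post)
  if (length(xx) > 2^18) {
    # long signals: apply the squared magnitude response |H(f)|^2 in the
    # frequency domain (identical zero-phase response; the reflection
    # padding absorbs the circular wrap)
    mu <- if (abs(sum(b) / sum(a)) < 0.5) mean(xx) else 0
    m <- stats::nextn(length(xx), c(2, 3, 5))   # keep the FFT fast
    z <- c(xx - mu, numeric(m - length(xx)))
    # |H|^2 evaluated stably as a product over poles/zeros:
    # |e^{-iw} - r e^{i t}|^2 = 1 + r^2 - 2 r cos(w + t); every factor is
    # positive, so high-Q band edges cause no cancellation
    om <- 2 * pi * (0:(m - 1)) / m
    cw <- cos(om); sw <- sin(om)
    mag2 <- function(coef) {
      lead <- max(which(abs(coef) > 0))
      out <- rep(coef[lead]^2, m)
      if (lead > 1) for (w in polyroot(coef[1:lead])) {
        rho <- Mod(w); th <- Arg(w)
        out <- out * (1 + rho^2 - 2 * rho * (cw * cos(th) - sw * sin(th)))
      }
      out
    }
    H2 <- mag2(b) / mag2(a)
    y <- Re(stats::fft(stats::fft(z) * H2, inverse = TRUE))[seq_along(xx)] / m +
      mu * H2[1]
  } else {
    y <- iir_filter_ss(b, a, xx)
    y <- rev(iir_filter_ss(b, a, rev(y)))
  }
  y[(padlen + 1):(padlen + n)]
}

#' Analytic signal via the Hilbert transform
#'
#' @param x Real signal.
#' @return Complex vector `x + i*H(x)`; `Mod()` is the instantaneous
#'   envelope and `Arg()` the instantaneous phase (0 at signal peaks).
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# centered moving average via cumulative sums; edges handled by reflection
moving_average <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  if (width < 1) stop("width must be >= 1")
  if (width > n) stop("window longer than signal")
  half <- width %/% 2
  xx <- c(x[(half + 1):2], x, x[(n - 1):(n - (width - half - 1) - 1)])
  cs <- cumsum(c(0, xx))
  (cs[(width + 1):(width + n)] - cs[1:n]) / width
}
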