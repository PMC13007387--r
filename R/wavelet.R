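# Daubechies-4 (8-tap) scaling filter, normalized so sum(h) = sqrt(2).
DB4_H <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
           -0.0279837694169839, -0.1870348117188811, 0.0308413818359870,
           0.0328830116669829, -0.0105974017849973)

dwt_step <- function(a, h, g) {
  N <- length(a)
  L <- length(h)
  n2 <- N %/% 2L
  A <- numeric(n2); D <- numeric(n2)
  for (n in seq_len(n2)) {
    j <- ((2L * (n - 1L) + 0:(L - 1L)) %% N) + 1L
    A[n] <- sum(h * a[j])
    D[n] <- sum(g * a[j])
  }
  list(A = A, D = D)
}

idwt_step <- function(A, D, h, g) {
  n2 <- length(A)
  L <- length(h)
  N <- 2L * n2
  a <- numeric(N)
  for (n in seq_len(n2)) {
    j <- ((2L * (n - 1L) + 0:(L - 1L)) %% N) + 1L
    a[j] <- a[j] + h * A[n] + g * D[n]
  }
  a
}

#' Wavelet motion-artifact correction by interquartile fencing
#'
#' Multi-level periodized Daubechies-4 wavelet decomposition; within each
#' detail level, coefficients outside
#' `[Q1 - iqr_mult * IQR, Q3 + iqr_mult * IQR]` are set to zero before
#' reconstruction. Motion spikes and baseline jumps concentrate in few large
#' detail coefficients and are suppressed; smooth hemodynamics live in the
#' approximation band and pass through.
#'
#' Boundary handling: the line through the two endpoints is removed, the
#' series is extended to a dyadic length by odd (point-symmetric) reflection
#' with a linear correction that closes the periodic wrap, and the extension
#' is discarded after reconstruction. Levels with fewer than `min_coefs`
#' coefficients are left untouched (quartiles of a handful of coarse
#' coefficients are meaningless).
#'
#' @param x Numeric series (finite).
#' @param iqr_mult Fence half-width in IQR units (default 0.5; deliberately
#'   aggressive).
#' @param min_coefs Minimal number of coefficients for a level to be fenced.
#' @return Corrected series, same length as `x`.
#' @export
wavelet_motion_correct <- function(x, iqr_mult = 0.5, min_coefs = 64) {
  if (!all(is.finite(x)))
    stop_oxy("oxydrift_format", "non-finite values in input")
  stopifnot(iqr_mult > 0)
  n <- length(x)
  if (n < 16)
    stop_oxy("oxydrift_short", "series too short for wavelet correction (%d)", n)
  h <- DB4_H
  g <- (-1)^(0:(length(h) - 1L)) * rev(h)
  base <- seq(x[1], x[n], length.out = n)
  d <- x - base
  N <- 2^ceiling(log2(n))
  pad <- N - n
  if (pad > 0) {
    e <- -rev(d)[seq_len(pad)]                 # keeps the slope continuous
    e <- e - seq_len(pad) / pad * e[pad]       # close the periodic wrap at 0
    xe <- c(d, e)
  } else {
    xe <- d
  }
  J <- max(1L, floor(log2(N)) - 4L)
  a <- xe
  det <- vector("list", J)
  for (j in seq_len(J)) {
    s <- dwt_step(a, h, g)
    det[[j]] <- s$D
    a <- s$A
  }
  for (j in seq_len(J)) {
    dd <- det[[j]]
    if (length(dd) < min_coefs) next
    q <- quantile(dd, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    dd[dd < q[1] - iqr_mult * iqr | dd > q[2] + iqr_mult * iqr] <- 0
    det[[j]] <- dd
  }
  for (j in rev(seq_len(J))) a <- idwt_step(a, det[[j]], h, g)
  a[seq_len(n)] + base
}
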