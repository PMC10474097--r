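## Orthogonal discrete wavelet transform with Daubechies filters.
##
## Orthonormal scaling (low-pass reconstruction) filters; sum(h) = sqrt(2),
## sum(h^2) = 1.  The high-pass is the quadrature mirror g[k] =
## (-1)^k h[L-1-k].  The transform is applied in periodized form to a
## symmetrically padded copy of the signal: periodization makes the analysis
## operator exactly orthogonal (perfect reconstruction to machine
## precision), the symmetric pad keeps the wrap-around discontinuity away
## from the data so no spurious edge spikes appear after denoising.

.daubechies_filters <- list(
  db2 = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339,
          -0.12940952255126037),
  db4 = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.032883011666885197, -0.010597401785069032),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.097501605587323043, 0.027522865530305727, -0.03158203931748603,
          0.00055384220116149613, 0.0047772575109455108,
          -0.0010773010853084796),
  db8 = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
          0.58535468365420673, -0.015829105256349306, -0.28401554296154691,
          0.00047248457391328279, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
          -0.0048703529934515741, -0.00039174037337694705,
          0.00067544940645056933, -0.00011747678412476953),
  db10 = c(0.026670057900555554, 0.1881768000776915, 0.52720118893172563,
           0.68845903945360354, 0.28117234366057747, -0.24984642432731538,
           -0.19594627437737705, 0.12736934033579325, 0.093057364603572348,
           -0.071394147166397082, -0.029457536821875813, 0.033212674059341002,
           0.0036065535669561697, -0.010733175483330575, 0.0013953517470529011,
           0.0019924052951850561, -0.00068585669495971162,
           -0.00011646685512928545, 9.3588670320069592e-05,
           -1.3264202894521244e-05),
  db12 = c(0.013112257957229518, 0.10956627282118515, 0.37735513521421266,
           0.65719872257930712, 0.51588647842781565, -0.044763885653774628,
           -0.31617845375278553, -0.023779257256069726, 0.18247860592757967,
           0.0053595696743521503, -0.096432120096507076, 0.010849130255822185,
           0.041546277495084438, -0.01221864906974828, -0.012840825198300683,
           0.0067114990087955096, 0.0022486072409952378,
           -0.0021795036186277603, 6.5451282125095959e-06,
           0.00038865306282093143, -8.850410920820432e-05,
           -2.4241545757030785e-05, 1.2776952219379767e-05,
           -1.5290717580685109e-06),
  db14 = c(0.0064611534600879476, 0.062364758849398898, 0.25485026779262138,
           0.55430561794089384, 0.63118784910485681, 0.21867068775890652,
           -0.27168855227874805, -0.21803352999327605, 0.1383952138648066,
           0.1399890165844607, -0.086748411568169689, -0.071548955504046136,
           0.055237126259216042, 0.026981408307912916, -0.030185351540390634,
           -0.0056150495303569593, 0.012789493266333409,
           -0.00074621898926838497, -0.0038496388680221874,
           0.0010616910856067619, 0.00070802115423552786,
           -0.0003868319473129545, -4.1777245770372596e-05,
           6.8755042526975093e-05, -1.0337209184570774e-05,
           -4.3897049017813942e-06, 1.7249946753678127e-06,
           -1.7871399683113592e-07)
)

wavelet_filters <- function(name) {
  h <- .daubechies_filters[[name]]
  if (is.null(h)) {
    stop("pcgbeat_unknown_wavelet: '", name, "' (available: ",
         paste(names(.daubechies_filters), collapse = ", "), ")",
         call. = FALSE)
  }
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(h = h, g = g, length = L)
}

# One periodized analysis step; x must have even length.
dwt_step <- function(x, flt) {
  n <- length(x)
  m <- n %/% 2L
  idx0 <- 2L * (seq_len(m) - 1L)
  a <- numeric(m)
  d <- numeric(m)
  for (k in seq_len(flt$length)) {
    xi <- x[(idx0 + (k - 1L)) %% n + 1L]
    a <- a + flt$h[k] * xi
    d <- d + flt$g[k] * xi
  }
  list(a = a, d = d)
}

# Inverse of dwt_step (adjoint of the orthogonal analysis operator).
idwt_step <- function(a, d, flt) {
  m <- length(a)
  n <- 2L * m
  x <- numeric(n)
  idx0 <- 2L * (seq_len(m) - 1L)
  for (k in seq_len(flt$length)) {
    pos <- (idx0 + (k - 1L)) %% n + 1L
    contrib <- flt$h[k] * a + flt$g[k] * d
    # accumulate with possible repeated positions (m < L/2): use tapply-free loop
    x[pos] <- x[pos] + contrib
  }
  x
}

#' Multi-level periodized wavelet decomposition
#'
#' @param x Numeric vector with length divisible by `2^level`.
#' @param wavelet Daubechies filter name (e.g. `"db12"`).
#' @param level Decomposition depth.
#' @return List with `approx` (coarsest approximation) and `details` (list of
#'   detail coefficient vectors, finest scale first).
#' @keywords internal
#' @export
wavelet_decompose <- function(x, wavelet = "db12", level = 5L) {
  flt <- wavelet_filters(wavelet)
  n <- length(x)
  if (n %% 2L^level != 0L) {
    stop("pcgbeat_signal_too_short: length ", n,
         " not divisible by 2^", level, call. = FALSE)
  }
  if (n / 2L^level < 1L) {
    stop("pcgbeat_signal_too_short: signal too short for level ", level,
         call. = FALSE)
  }
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- dwt_step(a, flt)
    details[[j]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, wavelet = wavelet, level = level)
}

#' Reconstruct a signal from a [wavelet_decompose()] object
#'
#' @param dec Output of [wavelet_decompose()].
#' @return Numeric vector of the original length.
#' @keywords internal
#' @export
wavelet_reconstruct <- function(dec) {
  flt <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_len(dec$level))) {
    a <- idwt_step(a, dec$details[[j]], flt)
  }
  a
}

#' Wavelet-denoise a PCG signal
#'
#' Decomposes the signal to the requested depth (default db12, level 5),
#' soft-thresholds all detail coefficients with the universal threshold
#' `sigma * sqrt(2 * log(n))` — the noise scale `sigma` estimated from the
#' median absolute deviation of the finest detail level — and reconstructs.
#' The approximation band is left untouched.
#'
#' @param signal Numeric vector (or a previous stage's output).
#' @param wavelet Daubechies wavelet name.
#' @param level Decomposition depth.
#' @return A `pcg_filtered` object, same length as the input.
#' @export
wavelet_denoise <- function(signal, wavelet = "db12", level = 5L) {
  x <- as_samples(signal)
  n <- length(x)
  flt <- wavelet_filters(wavelet)  # validates the name up front
  if (n < flt$length * 2L^level) {
    stop("pcgbeat_signal_too_short: need at least ", flt$length * 2L^level,
         " samples for ", wavelet, " at level ", level, " (got ", n, ")",
         call. = FALSE)
  }
  block <- 2L^level
  # symmetric pad: keeps the periodic wrap-around away from the data and
  # rounds the length up to a multiple of 2^level
  pad <- flt$length * block
  total <- n + 2L * pad
  extra <- (block - total %% block) %% block
  lpad <- pad
  rpad <- pad + extra
  xp <- c(x[pmin(lpad:1, n)], x, x[pmax(n - (1:rpad) + 1L, 1L)])
  dec <- wavelet_decompose(xp, wavelet, level)
  sigma <- stats::mad(dec$details[[1]], center = 0)
  thr <- sigma * sqrt(2 * log(length(xp)))
  dec$details <- lapply(dec$details, soft_threshold, thr = thr)
  y <- wavelet_reconstruct(dec)[(lpad + 1):(lpad + n)]
  sr <- if (inherits(signal, "pcg_filtered")) signal$sample_rate else NA_real_
  filtered_signal(y, sr,
                  sprintf("wavelet denoise %s level %d", wavelet, level),
                  parent = signal)
}

soft_threshold <- function(w, thr) sign(w) * pmax(abs(w) - thr, 0)
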