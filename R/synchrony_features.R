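#' Names of the 36 synchrony features
#'
#' Nine measures (dtw, ddtw, cidtw, nli, coh, xcorr, cosd, hausd, sspd) on
#' each of the four per-dyad modalities (eda, temp, hr, rr), named
#' `sync_<measure>_<modality>`.
#' @return character vector of length 36.
#' @export
synchrony_feature_names <- function() {
  meas <- c("dtw", "ddtw", "cidtw", "nli", "coh", "xcorr", "cosd", "hausd", "sspd")
  mods <- c("eda", "temp", "hr", "rr")
  as.vector(t(outer(mods, meas, function(mo, me) paste0("sync_", me, "_", mo))))
}

#' Prepare a per-dyad signal pair for the synchrony measures
#'
#' Both series are decimated to the analysis grid by block averaging (when the
#' input rate is an integer multiple of `grid_rate`) and z-scored per interval
#' (zero mean, unit variance). Zero-variance series are flagged degenerate and
#' only centered, so distance measures remain defined.
#'
#' @param a,b equal-length numeric series for the two participants.
#' @param in_rate input sampling rate in Hz.
#' @param grid_rate analysis grid rate in Hz (default 4).
#' @param modality label: `"eda"`, `"temp"`, `"hr"` or `"rr"`.
#' @return object of class `signal_pair` with fields `a`, `b`, `grid_rate`,
#'   `modality`, `degenerate`.
#' @export
prepare_pair <- function(a, b, in_rate, grid_rate = 4, modality = "eda") {
  if (length(a) != length(b)) stop("series must have equal length")
  dec <- function(x) {
    f <- in_rate / grid_rate
    if (f <= 1) return(x)
    if (abs(f - round(f)) < 1e-9) {
      f <- as.integer(round(f))
      n <- (length(x) %/% f) * f
      return(colMeans(matrix(x[seq_len(n)], nrow = f)))
    }
    # non-integer factor: linear interpolation onto the analysis grid
    t_in <- (seq_along(x) - 1) / in_rate
    t_out <- seq(0, t_in[length(x)], by = 1 / grid_rate)
    stats::approx(t_in, x, t_out, rule = 2)$y
  }
  zsc <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) list(x = x - mean(x), degenerate = TRUE)
    else list(x = (x - mean(x)) / s, degenerate = FALSE)
  }
  za <- zsc(dec(a)); zb <- zsc(dec(b))
  if (length(za$x) < 8) stop("pair too short: need at least 8 samples")
  structure(list(a = za$x, b = zb$x, grid_rate = grid_rate,
                 modality = modality,
                 degenerate = za$degenerate || zb$degenerate),
            class = "signal_pair")
}

#' Dynamic time warping distance
#'
#' Classic DTW with absolute-difference local cost, symmetric steps and
#' unconstrained warping, normalized by the length of the optimal warping
#' path (diagonal-preferring traceback among minimal-cost paths).
#'
#' @param pair a [prepare_pair()] object, or a numeric vector (then `b` must
#'   be given).
#' @param b second series when `pair` is a plain vector.
#' @return non-negative normalized DTW distance.
#' @export
dtw_distance <- function(pair, b = NULL) {
  s <- as_pair_series(pair, b)
  r <- dtw_cost_cpp(s$a, s$b)
  r$cost / r$path_length
}

as_pair_series <- function(pair, b) {
  if (inherits(pair, "signal_pair")) list(a = pair$a, b = pair$b)
  else list(a = as.numeric(pair), b = as.numeric(b))
}

# derivative transform: d[i] = ((x[i]-x[i-1]) + (x[i+1]-x[i-1])/2)/2 for
# interior points, endpoints replicated
derivative_transform <- function(x) {
  n <- length(x)
  if (n < 3) stop("derivative transform needs length >= 3")
  d <- numeric(n)
  i <- 2:(n - 1)
  d[i] <- ((x[i] - x[i - 1]) + (x[i + 1] - x[i - 1]) / 2) / 2
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

#' Derivative DTW distance
#'
#' DTW (as in [dtw_distance()]) applied to the local-derivative transform of
#' both series, making the measure sensitive to shape (rising/falling trends)
#' rather than level; a constant offset between the series cancels exactly.
#'
#' @inheritParams dtw_distance
#' @return non-negative distance, or `NA` when a series is shorter than 3.
#' @export
derivative_dtw <- function(pair, b = NULL) {
  s <- as_pair_series(pair, b)
  if (length(s$a) < 3 || length(s$b) < 3) return(NA_real_)
  dtw_distance(derivative_transform(s$a), derivative_transform(s$b))
}

#' Complexity estimate of a series
#'
#' `CE(x) = sqrt(sum (x[i+1] - x[i])^2)`, the length-like complexity used by
#' the complexity-invariant DTW correction factor.
#' @param x numeric series of length >= 2.
#' @return non-negative scalar.
#' @export
complexity_estimate <- function(x) sqrt(sum(diff(x)^2))

#' Complexity-invariant DTW distance
#'
#' [dtw_distance()] multiplied by the correction factor
#' `CF = max(CE_a, CE_b) / min(CE_a, CE_b)`; `CF = 1` when both complexity
#' estimates are zero, and capped at `cf_cap` when exactly one is zero.
#'
#' @inheritParams dtw_distance
#' @param cf_cap cap applied when one series is constant and the other not.
#' @return non-negative distance.
#' @export
cid_dtw <- function(pair, b = NULL, cf_cap = 1e6) {
  s <- as_pair_series(pair, b)
  ca <- complexity_estimate(s$a); cb <- complexity_estimate(s$b)
  cf <- if (ca == 0 && cb == 0) 1
  else if (min(ca, cb) == 0) cf_cap
  else max(ca, cb) / min(ca, cb)
  dtw_distance(s$a, s$b) * cf
}

delay_embed <- function(x, m, tau) {
  n <- length(x) - (m - 1) * tau
  if (n < 1) stop("series too short to embed")
  sapply(0:(m - 1), function(j) x[(1:n) + j * tau])
}

#' Symmetric nonlinear interdependence
#'
#' Delay-embeds both series (dimension `m`, delay `tau`), finds each point's
#' `k` nearest neighbors under a Theiler exclusion window, and computes
#' `S(A|B) = mean_i R_i(A) / R_i(A|B)` where `R_i(A)` is the mean squared
#' distance to the true neighbors and `R_i(A|B)` uses the time indices of B's
#' neighbors; the symmetrized value `(S(A|B) + S(B|A)) / 2` is returned.
#' Values near 1 indicate strong state-space coupling.
#'
#' @inheritParams dtw_distance
#' @param m embedding dimension.
#' @param tau embedding delay in samples.
#' @param k number of nearest neighbors.
#' @param theiler Theiler exclusion window in samples.
#' @return symmetric interdependence, or `NA` when the series are too short.
#' @export
nonlinear_interdependence <- function(pair, b = NULL, m = 3, tau = 2, k = 4,
                                      theiler = 8) {
  s <- as_pair_series(pair, b)
  need <- (m - 1) * tau + k + theiler + 2
  if (length(s$a) < need || length(s$b) < need) return(NA_real_)
  ea <- delay_embed(s$a, m, tau)
  eb <- delay_embed(s$b, m, tau)
  sab <- nli_s_cpp(ea, eb, k, theiler)
  sba <- nli_s_cpp(eb, ea, k, theiler)
  (sab + sba) / 2
}

#' Band-averaged magnitude-squared coherence
#'
#' Welch-style windowed cross-spectral averaging (Hann window, 50% overlap)
#' followed by averaging the magnitude-squared coherence over the frequency
#' band `band` (default 0.01-0.5 Hz, covering the slow autonomic rhythms the
#' four modalities carry within 2-minute windows).
#'
#' @inheritParams dtw_distance
#' @param rate grid rate in Hz (taken from the pair when available).
#' @param window_s Welch window length in seconds.
#' @param band two-element frequency band in Hz.
#' @return coherence in `[0, 1]`, or `NA` when shorter than two windows.
#' @export
coherence <- function(pair, b = NULL, rate = NULL, window_s = 60,
                      band = c(0.01, 0.5)) {
  s <- as_pair_series(pair, b)
  if (is.null(rate)) rate <- if (inherits(pair, "signal_pair")) pair$grid_rate else 4
  n <- length(s$a)
  L <- round(window_s * rate)
  if (n < 2 * L) return(NA_real_)
  step <- L %/% 2
  starts <- seq(1, n - L + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  pxx <- pyy <- numeric(L)
  pxy <- complex(length.out = L)
  for (st in starts) {
    xa <- s$a[st:(st + L - 1)] * win
    xb <- s$b[st:(st + L - 1)] * win
    fa <- fft(xa); fb <- fft(xb)
    pxx <- pxx + Mod(fa)^2
    pyy <- pyy + Mod(fb)^2
    pxy <- pxy + fa * Conj(fb)
  }
  freqs <- (0:(L - 1)) * rate / L
  sel <- freqs >= band[1] & freqs <= band[2] & pxx > 0 & pyy > 0
  if (!any(sel)) return(NA_real_)
  msc <- Mod(pxy[sel])^2 / (pxx[sel] * pyy[sel])
  mean(msc)
}

#' Maximum-lag absolute cross-correlation
#'
#' Maximum over lags within `max_lag_s` of the absolute Pearson correlation
#' between the overlapping segments of the two series; the sign is discarded
#' so in-phase and anti-phase coupling score alike.
#'
#' @inheritParams coherence
#' @param max_lag_s lag range in seconds (default 10).
#' @return value in `[0, 1]`, or `NA` for a degenerate (zero-variance) pair.
#' @export
cross_correlation <- function(pair, b = NULL, rate = NULL, max_lag_s = 10) {
  s <- as_pair_series(pair, b)
  if (is.null(rate)) rate <- if (inherits(pair, "signal_pair")) pair$grid_rate else 4
  if (sd(s$a) == 0 || sd(s$b) == 0) return(NA_real_)
  n <- length(s$a)
  maxlag <- min(n - 3, round(max_lag_s * rate))
  best <- -Inf; best_lag <- 0
  for (l in -maxlag:maxlag) {
    if (l >= 0) { x <- s$a[1:(n - l)]; y <- s$b[(1 + l):n] }
    else { x <- s$a[(1 - l):n]; y <- s$b[1:(n + l)] }
    if (sd(x) == 0 || sd(y) == 0) next
    r <- abs(cor(x, y))
    if (r > best) { best <- r; best_lag <- l }
  }
  if (!is.finite(best)) return(NA_real_)
  structure(best, lag_s = best_lag / rate)
}

#' Cosine distance
#'
#' `1 - cos(angle)` between the two series viewed as vectors:
#' `1 - (a . b) / (|a| |b|)`; 0 for parallel, 1 for orthogonal, 2 for
#' antiparallel vectors.
#'
#' @inheritParams dtw_distance
#' @return value in `[0, 2]`, or `NA` when a norm is zero.
#' @export
cosine_distance <- function(pair, b = NULL) {
  s <- as_pair_series(pair, b)
  na <- sqrt(sum(s$a^2)); nb <- sqrt(sum(s$b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  1 - sum(s$a * s$b) / (na * nb)
}

# planar embedding used by hausdorff / sspd: points (t_i * lambda, x_i) with
# the time span scaled to the value range of the z-scored series
pair_points <- function(s, rate, time_scale = NULL) {
  n <- length(s$a)
  t <- (seq_len(n) - 1) / rate
  if (is.null(time_scale)) {
    zr <- max(diff(range(s$a)), diff(range(s$b)))
    if (zr == 0) zr <- 1
    time_scale <- zr / max(t[n], 1e-12)
  }
  list(ax = t * time_scale, ay = s$a, bx = t * time_scale, by = s$b)
}

#' Hausdorff distance between the two trajectories
#'
#' Symmetric Hausdorff (max-min) distance between the planar point sets
#' `{(t_i * lambda, a_i)}` and `{(t_i * lambda, b_i)}` with the time axis
#' scaled so the interval's time span matches the z-scored value range
#' (Euclidean point metric).
#'
#' @inheritParams coherence
#' @param time_scale optional explicit time-axis scale (units of value per
#'   second); by default derived from the value range.
#' @return non-negative distance.
#' @export
hausdorff_distance <- function(pair, b = NULL, rate = NULL, time_scale = NULL) {
  s <- as_pair_series(pair, b)
  if (is.null(rate)) rate <- if (inherits(pair, "signal_pair")) pair$grid_rate else 4
  p <- pair_points(s, rate, time_scale)
  hausdorff_cpp(p$ax, p$ay, p$bx, p$by)
}

#' Symmetric segment-path distance
#'
#' For every point of one trajectory, the minimum Euclidean distance to any
#' segment of the other is computed; the means in both directions are
#' averaged. Trajectories live in the same scaled `(t, value)` plane as
#' [hausdorff_distance()].
#'
#' @inheritParams hausdorff_distance
#' @return non-negative distance.
#' @export
sspd_distance <- function(pair, b = NULL, rate = NULL, time_scale = NULL) {
  s <- as_pair_series(pair, b)
  if (length(s$a) < 2 || length(s$b) < 2) stop("sspd needs length >= 2")
  if (is.null(rate)) rate <- if (inherits(pair, "signal_pair")) pair$grid_rate else 4
  p <- pair_points(s, rate, time_scale)
  (spd_cpp(p$ax, p$ay, p$bx, p$by) + spd_cpp(p$bx, p$by, p$ax, p$ay)) / 2
}

#' All nine synchrony measures for one prepared pair
#'
#' @param pair a [prepare_pair()] object.
#' @return named numeric vector `c(dtw, ddtw, cidtw, nli, coh, xcorr, cosd,
#'   hausd, sspd)`.
#' @export
synchrony_measures <- function(pair) {
  stopifnot(inherits(pair, "signal_pair"))
  c(dtw = dtw_distance(pair),
    ddtw = derivative_dtw(pair),
    cidtw = cid_dtw(pair),
    nli = nonlinear_interdependence(pair),
    coh = coherence(pair),
    xcorr = cross_correlation(pair),
    cosd = cosine_distance(pair),
    hausd = hausdorff_distance(pair),
    sspd = sspd_distance(pair))
}

#' The 36 synchrony features for one dyad-interval
#'
#' Builds the four per-dyad signal pairs -- EDA and temperature from the
#' channel samples, instantaneous heart rate and respiration rate from the
#' event trains -- and evaluates the nine synchrony measures on each.
#' A missing channel for either participant propagates as `NA` for that
#' modality's nine features.
#'
#' @param interval_signals `list(p1 = list(ecg, eda, resp, temp), p2 = ...)`.
#' @param sampling_rate input sampling rate in Hz.
#' @param duration interval duration in seconds.
#' @param grid_rate analysis grid rate in Hz.
#' @return named numeric vector of the 36 `sync_*` features.
#' @export
synchrony_features_for_interval <- function(interval_signals, sampling_rate,
                                            duration, grid_rate = 4) {
  out <- stats::setNames(rep(NA_real_, 36), synchrony_feature_names())
  rate_of <- function(ch, p, detect, kind) {
    tryCatch({
      x <- interval_signals[[p]][[ch]]
      if (is.null(x)) stop("missing channel")
      iv <- signal_interval(x, sampling_rate, ch)
      instantaneous_rate(detect(iv), grid_rate, duration, kind)$values
    }, error = function(e) NULL)
  }
  series <- list(
    eda = lapply(c("p1", "p2"), function(p) interval_signals[[p]][["eda"]]),
    temp = lapply(c("p1", "p2"), function(p) interval_signals[[p]][["temp"]]),
    hr = list(rate_of("ecg", "p1", detect_r_peaks, "heart"),
              rate_of("ecg", "p2", detect_r_peaks, "heart")),
    rr = list(rate_of("resp", "p1", detect_respiration_peaks, "respiration"),
              rate_of("resp", "p2", detect_respiration_peaks, "respiration")))
  in_rates <- c(eda = sampling_rate, temp = sampling_rate,
                hr = grid_rate, rr = grid_rate)
  for (mod in names(series)) {
    a <- series[[mod]][[1]]; b <- series[[mod]][[2]]
    if (is.null(a) || is.null(b)) next
    meas <- tryCatch({
      pr <- prepare_pair(a, b, in_rates[[mod]], grid_rate, mod)
      synchrony_measures(pr)
    }, error = function(e) NULL)
    if (!is.null(meas))
      out[paste0("sync_", names(meas), "_", mod)] <- meas
  }
  out
}
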