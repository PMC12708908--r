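#' Configuration for the synthetic dyad generator
#'
#' Builds the configuration object consumed by [generate_dyad()] and
#' [generate_cohort()]. The generator emulates the statistical structure the
#' downstream analysis assumes: two participants per dyad, four autonomic
#' channels (ECG, electrodermal activity, respiration, skin temperature),
#' twelve 2-minute intervals (an opening baseline, ten conversation intervals,
#' a closing baseline), inter-partner coupling through a shared latent driver,
#' and 1-9 self/observer ratings that depend on the latent affective state so
#' that feature-to-label regression has recoverable signal.
#'
#' @param n_dyads number of dyads in the cohort.
#' @param sampling_rate sampling rate of the generated signals in Hz.
#' @param interval_duration duration of each interval in seconds.
#' @param n_conversation_intervals number of conversation intervals between
#'   the two baselines.
#' @param coupling strength in `[0, 1]` of the shared latent driver mixed into
#'   each partner's within-interval autonomic driver. 0 = independent
#'   partners, 1 = fully shared driver.
#' @param divergence_sd standard deviation of the per-participant AR(1)
#'   divergence added to the dyad-level interval state, letting partners
#'   report similar but not identical impressions.
#' @param label_noise_sd standard deviation of Gaussian noise added to the
#'   latent state before it is mapped to an integer 1-9 rating.
#' @param label_weights list with elements `valence` and `arousal`, each a
#'   named vector of weights over the latent components `c(valence=, arousal=)`
#'   giving the contribution of each latent trajectory to that rating.
#' @param label_center,label_scale named vectors (`valence`, `arousal`) giving
#'   the affine latent-to-rating map: ratings are
#'   `center + scale * weighted latent`, rounded half-up and clipped to 1-9.
#'   Defaults place simulated conversations in the mildly pleasant, mildly
#'   energetic range typical of free-flowing dyadic conversation, with wider
#'   spread on arousal than valence.
#' @param scr_rate_base baseline skin-conductance-response rate in events per
#'   minute at neutral arousal.
#' @param seed master integer seed; per-dyad substreams are derived from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_dyads = 41,
                         sampling_rate = 100,
                         interval_duration = 120,
                         n_conversation_intervals = 10,
                         coupling = 0.6,
                         divergence_sd = 0.3,
                         label_noise_sd = 0.5,
                         label_weights = list(
                           valence = c(valence = 1, arousal = 0),
                           arousal = c(valence = 0, arousal = 1)),
                         label_center = c(valence = 6.9, arousal = 6.1),
                         label_scale = c(valence = 1.5, arousal = 1.9),
                         scr_rate_base = 4,
                         seed = 1L) {
  if (sampling_rate <= 0 || interval_duration <= 0)
    stop("configuration error: sampling_rate and interval_duration must be positive")
  if (n_dyads < 1) stop("configuration error: n_dyads must be >= 1")
  if (coupling < 0 || coupling > 1)
    stop("configuration error: coupling must lie in [0, 1]")
  if (label_noise_sd < 0)
    stop("configuration error: label_noise_sd must be >= 0")
  n_samp <- sampling_rate * interval_duration
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("configuration error: interval_duration x sampling_rate must be an integer")
  cfg <- list(n_dyads = as.integer(n_dyads),
              sampling_rate = sampling_rate,
              interval_duration = interval_duration,
              n_conversation_intervals = as.integer(n_conversation_intervals),
              coupling = coupling,
              divergence_sd = divergence_sd,
              label_noise_sd = label_noise_sd,
              label_weights = label_weights,
              label_center = label_center,
              label_scale = label_scale,
              scr_rate_base = scr_rate_base,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

round_half_up <- function(x) floor(x + 0.5)

clip19 <- function(x) pmin(9, pmax(1, x))

# stationary AR(1) with unit marginal variance
ar1_unit <- function(n, phi) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  if (n > 1) {
    innov_sd <- sqrt(1 - phi^2)
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov_sd * rnorm(1)
  }
  x
}

# band-limited unit-variance driver on a coarse grid: Gaussian-smoothed white
# noise, centered and scaled per interval
smooth_driver <- function(n, grid_rate, smooth_s = 1.5) {
  w <- rnorm(n)
  half <- max(1L, min(n, ceiling(3 * smooth_s * grid_rate)))
  k <- exp(-0.5 * ((-half:half) / (smooth_s * grid_rate))^2)
  k <- k / sum(k)
  z <- stats::filter(c(rev(w[seq_len(half)]), w, rev(w[n - seq_len(half) + 1])),
                     k, sides = 2)
  z <- as.numeric(z)[(half + 1):(half + n)]
  z <- z - mean(z)
  s <- sd(z)
  if (s > 0) z <- z / s
  z
}

# Map a latent value through the affine SAM scale: center + scale * latent.
latent_to_rating <- function(latent, center, scale)
  clip19(round_half_up(center + scale * latent))

scr_kernel <- function(fs, amplitude, rise_s = 1.2, tau_s = 3, len_s = 15) {
  n <- round(len_s * fs)
  t <- (seq_len(n) - 1) / fs
  y <- ifelse(t < rise_s,
              0.5 * (1 - cos(pi * t / rise_s)),
              exp(-(t - rise_s) / tau_s))
  amplitude * y
}

# One participant's four channels for one interval, given the scalar latent
# arousal `a` and valence `v` and the within-interval driver `z` on a 4 Hz
# grid. Arousal dominates the autonomic response; valence contributes a
# weaker level shift so both axes leave a physiological trace.
gen_channels <- function(a, v, z, fs, dur, scr_rate_base) {
  n <- round(fs * dur)
  tgrid <- seq(0, dur, length.out = length(z))
  zfun <- stats::approxfun(tgrid, z, rule = 2)
  ts <- (seq_len(n) - 1) / fs

  # ECG: narrow unit pulses at beat times from an arousal-modulated rate
  hr_fun <- function(t) pmax(40, 70 + 10 * a + 4 * v + 5 * zfun(t))
  beats <- numeric(0)
  t <- runif(1, 0, 60 / hr_fun(0))  # random phase of first beat
  while (t < dur) {
    beats <- c(beats, t)
    t <- t + 60 / hr_fun(t)
  }
  ecg <- rnorm(n, 0, 0.01)
  shape <- c(0.25, 0.6, 1, 0.6, 0.25)
  for (bt in beats) {
    idx <- round(bt * fs) + 1 + (-2:2)
    ok <- idx >= 1 & idx <= n
    ecg[idx[ok]] <- ecg[idx[ok]] + shape[ok]
  }

  # Respiration: oscillation with arousal/driver-modulated instantaneous rate
  rr <- pmax(6, 15 + 3 * a + 1 * v + 2 * zfun(ts))   # breaths/min
  phase <- cumsum(2 * pi * rr / 60 / fs)
  resp <- sin(phase) + rnorm(n, 0, 0.03)

  # EDA: tonic drift plus SCR bumps whose rate rises with arousal and driver
  lam_grid <- pmax(0.5, scr_rate_base + 2 * a + 2 * z) / 60   # events/s
  lam_max <- max(lam_grid)
  n_cand <- rpois(1, lam_max * dur)
  eda <- 5 + 0.3 * a + 0.25 * v + 0.002 * cumsum(rnorm(n)) + rnorm(n, 0, 0.003)
  if (n_cand > 0) {
    cand <- sort(runif(n_cand, 0, dur))
    lam_fun <- stats::approxfun(tgrid, lam_grid, rule = 2)
    keep <- runif(n_cand) < lam_fun(cand) / lam_max
    for (et in cand[keep]) {
      amp <- exp(rnorm(1, log(0.3), 0.4))
      kern <- scr_kernel(fs, amp)
      idx <- round(et * fs) + 1
      span <- idx:min(n, idx + length(kern) - 1)
      if (length(span) > 0 && span[1] <= n)
        eda[span] <- eda[span] + kern[seq_along(span)]
    }
  }

  # Temperature: slow drift around a mildly arousal-dependent level
  drift <- smooth_driver(length(z), 4, smooth_s = 10)
  temp <- 33 + 0.2 * a + 0.15 * v +
    0.15 * stats::approx(tgrid, drift, ts, rule = 2)$y + rnorm(n, 0, 0.002)

  list(ecg = ecg, eda = eda, resp = resp, temp = temp)
}

#' Generate one synthetic dyad recording
#'
#' Produces one dyad's twelve intervals (baseline, ten conversation intervals,
#' baseline) of two-participant, four-channel signals together with
#' per-interval self and observer ratings, participant characteristics and the
#' generative latent state. Partners share a within-interval latent driver
#' weighted by `coupling`; each participant's interval-level affective state is
#' the dyad state plus an AR(1) divergence term. Self-ratings are the
#' participant's latent state plus noise, affinely mapped, rounded half-up and
#' clipped to 1-9; observer ratings are the dyad-mean latent state mapped the
#' same way.
#'
#' @param config a [synth_config()] object.
#' @param dyad_index zero-based dyad index, `< n_dyads`; selects the dyad's
#'   deterministic random substream.
#' @return an object of class `dyad_record`: a list with elements `dyad_id`,
#'   `sampling_rate`, `interval_duration`, `signals` (list of 12 intervals,
#'   each `list(p1, p2)` of channel vectors), `ratings` (long data frame with
#'   self and observer streams), `characteristics` and `latent`.
#' @export
generate_dyad <- function(config, dyad_index = 0L) {
  stopifnot(inherits(config, "synth_config"))
  if (dyad_index < 0 || dyad_index >= config$n_dyads)
    stop("dyad_index must lie in [0, n_dyads)")
  dyad_index <- as.integer(dyad_index)
  set.seed(derive_seed(config$seed, dyad_index))
  fs <- config$sampling_rate
  dur <- config$interval_duration
  ncv <- config$n_conversation_intervals
  n_int <- ncv + 2L
  n4 <- max(16L, round(4 * dur))

  # dyad-level interval trajectories (conversation intervals only)
  V <- ar1_unit(ncv, 0.6)
  A <- ar1_unit(ncv, 0.6)
  # per-participant divergence
  div <- lapply(1:2, function(p)
    list(v = config$divergence_sd * ar1_unit(ncv, 0.5),
         a = config$divergence_sd * ar1_unit(ncv, 0.5)))

  latent <- do.call(rbind, lapply(1:2, function(p)
    data.frame(dyad_id = dyad_index, participant = p,
               interval_index = seq_len(ncv),
               valence = V + div[[p]]$v, arousal = A + div[[p]]$a)))

  # within-interval drivers and channels
  cpl <- config$coupling
  signals <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    conv <- i >= 2 && i <= ncv + 1
    j <- i - 1L
    zc <- smooth_driver(n4, 4)
    per_p <- lapply(1:2, function(p) {
      zp <- smooth_driver(n4, 4)
      z <- cpl * zc + (1 - cpl) * zp
      s <- sd(z)
      z <- (z - mean(z)) / (if (s > 0) s else 1)
      a <- if (conv) latent$arousal[latent$participant == p][j] else -1
      v <- if (conv) latent$valence[latent$participant == p][j] else 0
      gen_channels(a, v, z, fs, dur, config$scr_rate_base)
    })
    names(per_p) <- c("p1", "p2")
    signals[[i]] <- per_p
  }

  # ratings: self per participant, observer = dyad mean latent
  w <- config$label_weights
  ctr <- config$label_center
  scl <- config$label_scale
  self <- do.call(rbind, lapply(1:2, function(p) {
    lp <- latent[latent$participant == p, ]
    mk <- function(target) {
      lat <- w[[target]]["valence"] * lp$valence + w[[target]]["arousal"] * lp$arousal
      lat + rnorm(ncv, 0, config$label_noise_sd)
    }
    vpre <- mk("valence"); apre <- mk("arousal")
    data.frame(dyad_id = dyad_index, interval_index = seq_len(ncv),
               participant = p, rater = "self",
               valence = latent_to_rating(vpre, ctr[["valence"]], scl[["valence"]]),
               arousal = latent_to_rating(apre, ctr[["arousal"]], scl[["arousal"]]),
               valence_pre = ctr[["valence"]] + scl[["valence"]] * vpre,
               arousal_pre = ctr[["arousal"]] + scl[["arousal"]] * apre)
  }))
  obs_v <- w$valence["valence"] * V + w$valence["arousal"] * A
  obs_a <- w$arousal["valence"] * V + w$arousal["arousal"] * A
  observer <- data.frame(dyad_id = dyad_index, interval_index = seq_len(ncv),
                         participant = NA_integer_, rater = "observer",
                         valence = latent_to_rating(obs_v, ctr[["valence"]], scl[["valence"]]),
                         arousal = latent_to_rating(obs_a, ctr[["arousal"]], scl[["arousal"]]),
                         valence_pre = ctr[["valence"]] + scl[["valence"]] * obs_v,
                         arousal_pre = ctr[["arousal"]] + scl[["arousal"]] * obs_a)
  ratings <- rbind(self, observer)
  rownames(ratings) <- NULL

  characteristics <- do.call(rbind, lapply(1:2, function(p) {
    data.frame(
      dyad_id = dyad_index, participant = p,
      age = pmin(33, pmax(18, round_half_up(rnorm(1, 21.1, 3.8)))),
      gender = sample(c("male", "female", "nonbinary"), 1,
                      prob = c(0.44, 0.51, 0.05)),
      cognitive_empathy = pmin(95, pmax(19, rnorm(1, 55.7, 8.9))),
      affective_empathy = pmin(60, pmax(12, rnorm(1, 34.0, 5.4))),
      social_anxiety = pmin(60, pmax(12, rnorm(1, 39.8, 10.1))),
      depression = pmin(60, pmax(0, rnorm(1, 17.2, 11.4))))
  }))
  rownames(characteristics) <- NULL

  structure(list(dyad_id = dyad_index,
                 sampling_rate = fs,
                 interval_duration = dur,
                 n_conversation_intervals = ncv,
                 signals = signals,
                 ratings = ratings,
                 characteristics = characteristics,
                 latent = latent),
            class = "dyad_record")
}

#' Generate a cohort of synthetic dyads
#'
#' Calls [generate_dyad()] for dyad indices `0 .. n_dyads-1`, each with a
#' deterministic substream derived from the master seed, so cohorts are
#' reproducible and individual dyads can be regenerated in isolation.
#'
#' @param config a [synth_config()] object.
#' @return list of `dyad_record` objects of length `n_dyads`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lapply(seq_len(config$n_dyads) - 1L, function(i) generate_dyad(config, i))
}

#' @exportS3Method base::print
print.dyad_record <- function(x, ...) {
  cat(sprintf("<dyad_record %d: %d intervals x 2 participants x 4 channels @ %g Hz>\n",
              x$dyad_id, length(x$signals), x$sampling_rate))
  invisible(x)
}

#' Write a dyad record to tidy delimited text
#'
#' Writes three files into `dir`: `signals_dyad<ID>.csv` in long format
#' (`dyad_id, participant, interval_index, channel, time_s, value`),
#' `ratings_dyad<ID>.csv` and `characteristics_dyad<ID>.csv`. Interval index 0
#' is the opening baseline, 1..n the conversation intervals, n+1 the closing
#' baseline.
#'
#' @param record a `dyad_record`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_dyad_record <- function(record, dir) {
  stopifnot(inherits(record, "dyad_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- record$sampling_rate
  rows <- list()
  for (i in seq_along(record$signals)) {
    for (p in 1:2) {
      for (ch in c("ecg", "eda", "resp", "temp")) {
        v <- record$signals[[i]][[p]][[ch]]
        rows[[length(rows) + 1]] <- data.frame(
          dyad_id = record$dyad_id, participant = p,
          interval_index = i - 1L, channel = ch,
          time_s = (seq_along(v) - 1) / fs, value = v)
      }
    }
  }
  sig <- do.call(rbind, rows)
  paths <- file.path(dir, sprintf(c("signals_dyad%d.csv", "ratings_dyad%d.csv",
                                    "characteristics_dyad%d.csv"),
                                  record$dyad_id))
  write.csv(sig, paths[1], row.names = FALSE)
  write.csv(record$ratings, paths[2], row.names = FALSE)
  write.csv(record$characteristics, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a dyad's signals from the tidy long format
#'
#' Inverse of the signal part of [write_dyad_record()]: reads a long
#' delimited-text signals file and reassembles the per-interval channel
#' vectors.
#'
#' @param path path to a `signals_dyad*.csv` file.
#' @param sampling_rate sampling rate of the stored signals in Hz.
#' @return a list with elements `signals` (as in a `dyad_record`) and
#'   `dyad_id`.
#' @export
read_dyad_signals <- function(path, sampling_rate) {
  df <- read.csv(path)
  need <- c("dyad_id", "participant", "interval_index", "channel", "time_s", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("signals file missing columns: ", paste(miss, collapse = ", "))
  idx <- sort(unique(df$interval_index))
  signals <- lapply(idx, function(i) {
    per_p <- lapply(1:2, function(p) {
      out <- lapply(c("ecg", "eda", "resp", "temp"), function(ch) {
        sub <- df[df$interval_index == i & df$participant == p & df$channel == ch, ]
        sub$value[order(sub$time_s)]
      })
      names(out) <- c("ecg", "eda", "resp", "temp")
      out
    })
    names(per_p) <- c("p1", "p2")
    per_p
  })
  list(dyad_id = df$dyad_id[1], signals = signals)
}
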