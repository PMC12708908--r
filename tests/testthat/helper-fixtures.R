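# Shared fixtures, generated in code. Heavier objects are cached in this
# environment so they are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a triangular pulse train: unit pulses at `times` (s) on a flat baseline
make_pulse_signal <- function(times, fs, dur, width = 2, noise_sd = 0) {
  n <- round(fs * dur)
  x <- rnorm(n, 0, noise_sd)
  shape <- c(0.3, 0.7, 1, 0.7, 0.3)
  for (bt in times) {
    idx <- round(bt * fs) + 1 + (-2:2)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + shape[ok]
  }
  x
}

# a fabricated feature table with random feature values: fast stand-in for
# protocol-arithmetic and regression-plumbing checks that need no signals
make_fake_table <- function(n_dyads, seed = 1, n_int = 10,
                            labels = NULL, label_fun = NULL) {
  set.seed(seed)
  ind <- do.call(rbind, lapply(0:(n_dyads - 1), function(d)
    do.call(rbind, lapply(0:(n_int + 1), function(i)
      data.frame(dyad_id = d, interval_index = i, participant = 1:2,
                 matrix(rnorm(2 * 20), 2, 20,
                        dimnames = list(NULL, individual_feature_names())))))))
  syn <- do.call(rbind, lapply(0:(n_dyads - 1), function(d)
    data.frame(dyad_id = d, interval_index = 0:(n_int + 1),
               matrix(rnorm((n_int + 2) * 36), n_int + 2, 36,
                      dimnames = list(NULL, synchrony_feature_names())))))
  self_lab <- function(d, i, p, target) {
    if (!is.null(label_fun)) return(label_fun(d, i, p, target))
    if (!is.null(labels)) return(labels)
    sample(1:9, 1)
  }
  rat_self <- do.call(rbind, lapply(0:(n_dyads - 1), function(d)
    do.call(rbind, lapply(1:n_int, function(i)
      do.call(rbind, lapply(1:2, function(p)
        data.frame(dyad_id = d, interval_index = i, participant = p,
                   rater = "self",
                   valence = self_lab(d, i, p, "valence"),
                   arousal = self_lab(d, i, p, "arousal"))))))))
  rat_obs <- do.call(rbind, lapply(0:(n_dyads - 1), function(d)
    do.call(rbind, lapply(1:n_int, function(i)
      data.frame(dyad_id = d, interval_index = i, participant = NA_integer_,
                 rater = "observer",
                 valence = self_lab(d, i, NA, "valence"),
                 arousal = self_lab(d, i, NA, "arousal"))))))
  chars <- do.call(rbind, lapply(0:(n_dyads - 1), function(d)
    data.frame(dyad_id = d, participant = 1:2,
               age = sample(18:33, 2, TRUE),
               gender = sample(c("male", "female"), 2, TRUE),
               cognitive_empathy = runif(2, 19, 95),
               affective_empathy = runif(2, 12, 60),
               social_anxiety = runif(2, 12, 60),
               depression = runif(2, 0, 60))))
  dyadsync:::new_feature_table(ind, syn, rbind(rat_self, rat_obs), chars,
                               normalized = TRUE)
}

# fully extracted 41-dyad cohort feature table at a desk-scale sampling rate,
# baseline-normalized; the expensive shared fixture for recovery checks
cohort41_table <- function() {
  cached("cohort41_table", function() {
    cfg <- synth_config(n_dyads = 41, sampling_rate = 25, seed = 424242)
    cohort <- generate_cohort(cfg)
    ft <- extract_cohort_features(cohort)
    suppressWarnings(normalize_by_baseline(ft))
  })
}

# replace the self-rating labels of a table with an affine function of three
# extracted features plus Gaussian noise (or with feature-independent noise)
relabel_table <- function(table, seed, noise_sd = 0.5, independent = FALSE) {
  set.seed(seed)
  ind <- table$individual
  syn <- table$sync
  z <- function(x) {
    x[!is.finite(x)] <- mean(x[is.finite(x)])
    as.numeric(scale(x))
  }
  f1 <- z(ind$mean_hr); f2 <- z(ind$mean_eda)
  f3 <- z(syn$sync_dtw_hr[match(paste(ind$dyad_id, ind$interval_index),
                                paste(syn$dyad_id, syn$interval_index))])
  pre <- if (independent) rnorm(nrow(ind), 0, 1.8)
  else 1.2 * f1 + 0.9 * f2 + 0.7 * f3 + rnorm(nrow(ind), 0, noise_sd)
  lab <- pmin(9, pmax(1, floor(5 + pre + 0.5)))
  rat <- data.frame(dyad_id = ind$dyad_id, interval_index = ind$interval_index,
                    participant = ind$participant, rater = "self",
                    valence = lab, arousal = lab)
  out <- table
  out$ratings <- rat
  out
}
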