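test_that("DTW reproduces hand-enumerated warping paths and matches the oracle", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 1.0)
  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(sample(3:6, 1))
    b <- rnorm(sample(3:6, 1))
    got <- dyadsync:::dtw_cost_cpp(a, b)
    expect_equal(got$cost, oracle_dtw_cost(a, b), tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a), tolerance = 1e-12)
  }
})

test_that("derivative DTW uses the stated local-derivative transform", {
  d <- dyadsync:::derivative_transform(c(0, 1, 3))
  expect_equal(d[2], ((1 - 0) + (3 - 0) / 2) / 2)   # = 1.25
  expect_equal(d[1], d[2])
  expect_equal(d[3], d[2])
  set.seed(1)
  x <- rnorm(30)
  expect_equal(derivative_dtw(x, x), 0)
  expect_equal(derivative_dtw(x, x + 5), 0, tolerance = 1e-12)
  expect_true(is.na(derivative_dtw(c(1, 2), c(1, 2))))
})

test_that("complexity-invariant DTW applies the complexity ratio", {
  expect_equal(complexity_estimate(c(0, 1, 0)), sqrt(2), tolerance = 1e-12)
  a <- c(0, 1, 0, 1, 0)
  b2 <- c(0, 2, 0, 2, 0)   # CE doubled
  expect_equal(cid_dtw(a, b2), dtw_distance(a, b2) * 2, tolerance = 1e-12)
  expect_equal(cid_dtw(a, a), dtw_distance(a, a))
  # one constant series: capped factor
  expect_equal(cid_dtw(a, rep(1, 5)), dtw_distance(a, rep(1, 5)) * 1e6)
  expect_equal(cid_dtw(rep(2, 4), rep(3, 4)), dtw_distance(rep(2, 4), rep(3, 4)))
})

test_that("nonlinear interdependence is symmetric and maximal for identical series", {
  set.seed(2)
  x <- as.numeric(stats::filter(rnorm(220), rep(0.25, 4), sides = 1))
  x <- x[!is.na(x)]
  self_val <- nonlinear_interdependence(x, x)
  expect_equal(self_val, 1, tolerance = 1e-9)
  y <- as.numeric(stats::filter(rnorm(220), rep(0.25, 4), sides = 1))
  y <- y[!is.na(y)]
  v1 <- nonlinear_interdependence(x, y)
  expect_equal(v1, nonlinear_interdependence(y, x), tolerance = 1e-12)
  expect_lt(v1, self_val)
  expect_true(is.na(nonlinear_interdependence(rnorm(10), rnorm(10))))
})

test_that("independent white-noise pairs score below identical series on average", {
  set.seed(5)
  vals <- replicate(10, {
    a <- rnorm(200); b <- rnorm(200)
    nonlinear_interdependence(a, b)
  })
  expect_true(all(vals < 0.9))
  expect_gt(mean(vals), 0)
})

test_that("coherence is normalized and detects a shared narrowband rhythm", {
  set.seed(7)
  n <- 480
  tt <- (0:(n - 1)) / 4
  # slightly off-bin frequency: spectral leakage keeps every band bin
  # dominated by the (fully coherent) shared component at high SNR
  common <- sin(2 * pi * 0.095 * tt)
  a <- common + rnorm(n, 0, 1e-4)
  b <- common + rnorm(n, 0, 1e-4)
  expect_equal(coherence(a, a, rate = 4), 1.0, tolerance = 1e-9)
  val <- coherence(a, b, rate = 4)
  expect_gt(val, 0.8)
  for (seed in 1:5) {
    set.seed(seed)
    v <- coherence(rnorm(n), rnorm(n), rate = 4)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_true(is.na(coherence(rnorm(100), rnorm(100), rate = 4)))
})

test_that("cross-correlation takes the absolute maximum over lags and finds shifts", {
  set.seed(8)
  n <- 480
  a <- as.numeric(stats::filter(rnorm(n + 8), rep(1 / 8, 8), sides = 1))[9:(n + 8)]
  expect_equal(as.numeric(cross_correlation(a, a, rate = 4)), 1.0,
               tolerance = 1e-9)
  expect_equal(as.numeric(cross_correlation(a, -a, rate = 4)), 1.0,
               tolerance = 1e-9)
  b <- c(rep(a[1], 8), a[1:(n - 8)])   # delayed by 2 s at 4 Hz
  cc <- cross_correlation(a, b, rate = 4)
  expect_gt(as.numeric(cc), 0.95)
  expect_lte(abs(attr(cc, "lag_s") - 2), 0.25)
  expect_true(is.na(cross_correlation(rep(1, 100), rnorm(100), rate = 4)))
})

test_that("cosine distance spans parallel, orthogonal and antiparallel cases", {
  expect_equal(cosine_distance(c(1, 2, 3), c(2, 4, 6)), 0, tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 2), c(-1, -2)), 2, tolerance = 1e-12)
  expect_true(is.na(cosine_distance(c(0, 0), c(1, 2))))
})

test_that("Hausdorff and segment-path distances match brute-force oracles", {
  expect_equal(hausdorff_distance(c(0), c(3), rate = 4, time_scale = 1), 3)
  set.seed(9)
  for (rep in 1:6) {
    n <- sample(10:50, 1)
    a <- rnorm(n); b <- rnorm(n)
    t <- (0:(n - 1)) / 4
    lam <- 0.5
    A <- cbind(t * lam, a); B <- cbind(t * lam, b)
    expect_equal(hausdorff_distance(a, b, rate = 4, time_scale = lam),
                 oracle_hausdorff(A, B), tolerance = 1e-9)
    expect_equal(sspd_distance(a, b, rate = 4, time_scale = lam),
                 (oracle_spd(A, B) + oracle_spd(B, A)) / 2, tolerance = 1e-9)
  }
  # two horizontal parallel lines separated by d
  expect_equal(sspd_distance(rep(0, 10), rep(1.5, 10), rate = 4), 1.5,
               tolerance = 1e-9)
})

test_that("distance-type measures satisfy non-negativity, symmetry and identity", {
  set.seed(10)
  meas <- list(dtw = dtw_distance,
               ddtw = derivative_dtw,
               cidtw = cid_dtw,
               cosd = cosine_distance,
               hausd = function(a, b) hausdorff_distance(a, b, rate = 4),
               sspd = function(a, b) sspd_distance(a, b, rate = 4))
  for (rep in 1:5) {
    a <- rnorm(25); b <- rnorm(25)
    for (nm in names(meas)) {
      fun <- meas[[nm]]
      expect_gte(fun(a, b), 0)
      expect_equal(fun(a, b), fun(b, a), tolerance = 1e-9)
      expect_equal(fun(a, a), 0, tolerance = 1e-9)
    }
  }
})

test_that("pair preparation z-scores and decimates to the analysis grid", {
  a <- rnorm(1200, mean = 5, sd = 2)
  b <- rnorm(1200, mean = -3, sd = 0.5)
  pr <- prepare_pair(a, b, in_rate = 40, grid_rate = 4)
  expect_length(pr$a, 120)
  expect_equal(mean(pr$a), 0, tolerance = 1e-9)
  expect_equal(sd(pr$a), 1, tolerance = 1e-9)
  expect_false(pr$degenerate)
  pr2 <- prepare_pair(a, a, in_rate = 40, grid_rate = 4)
  expect_equal(pr2$a, pr2$b)
  prz <- prepare_pair(rep(2, 100), rnorm(100), in_rate = 4, grid_rate = 4)
  expect_true(prz$degenerate)
  expect_error(prepare_pair(1:5, 1:4, 4), "equal length")
})

test_that("a dyad-interval yields 36 synchrony features with correct propagation", {
  cfg <- synth_config(n_dyads = 1, sampling_rate = 40, seed = 21)
  d <- generate_dyad(cfg, 0)
  iv <- d$signals[[4]]
  f <- synchrony_features_for_interval(iv, 40, 120)
  expect_length(f, 36)
  expect_named(f, synchrony_feature_names())
  expect_true(all(is.finite(f)))
  # missing partner EDA: that modality's 9 features missing, others intact
  iv2 <- iv
  iv2$p2$eda <- NULL
  f2 <- synchrony_features_for_interval(iv2, 40, 120)
  eda_cols <- grep("_eda$", names(f2))
  expect_true(all(is.na(f2[eda_cols])))
  expect_true(all(is.finite(f2[-eda_cols])))
  # identical participants: distances 0, coherence and |xcorr| = 1
  iv3 <- iv
  iv3$p2 <- iv3$p1
  f3 <- synchrony_features_for_interval(iv3, 40, 120)
  for (m in c("dtw", "ddtw", "cidtw", "cosd", "hausd", "sspd"))
    expect_equal(unname(f3[paste0("sync_", m, "_eda")]), 0, tolerance = 1e-9)
  expect_equal(unname(f3["sync_coh_eda"]), 1, tolerance = 1e-9)
  expect_equal(unname(f3["sync_xcorr_eda"]), 1, tolerance = 1e-9)
})

test_that("synchrony measures respond to generative coupling", {
  sync_stats <- function(coupling, seed) {
    cfg <- synth_config(n_dyads = 20, sampling_rate = 25, coupling = coupling,
                        seed = seed)
    out <- vapply(generate_cohort(cfg), function(d) {
      per_int <- vapply(c(3, 6, 9), function(i) {
        rates <- lapply(c("p1", "p2"), function(p) {
          ivp <- signal_interval(d$signals[[i]][[p]]$ecg, 25, "ecg")
          instantaneous_rate(detect_r_peaks(ivp), 4, 120)$values
        })
        pr <- prepare_pair(rates[[1]], rates[[2]], 4, 4, "hr")
        c(dtw = dtw_distance(pr), coh = coherence(pr))
      }, numeric(2))
      rowMeans(per_int)
    }, numeric(2))
    rowMeans(out)
  }
  s1 <- sync_stats(1, 314)
  s0 <- sync_stats(0, 314)
  expect_lt(s1[["dtw"]], s0[["dtw"]])
  expect_gt(s1[["coh"]], s0[["coh"]])
})
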