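lin_only <- function(seed = 1) list(linear = model_config("linear",
                                                          penalty = "none",
                                                          seed = seed))

test_that("interval errors and their MA/RMS aggregates follow the definitions", {
  expect_equal(interval_error(6, 6), 0)
  expect_equal(interval_error(4.5, 6), -1.5)
  e <- c(rep(0, 9), 3)
  res <- data.frame(method = "m", unit = "u", estimate = 5 + e, reference = 5)
  s <- summarize_results(res)
  expect_equal(s$ma, 0.3)
  expect_equal(s$rms, 3 / sqrt(10), tolerance = 1e-9)
  expect_gte(s$rms, s$ma)
})

test_that("fold plans satisfy the split invariants for all three goals", {
  p1 <- fold_plan(1, NULL, 10)
  expect_equal(nrow(p1), 10)
  expect_true(all(p1$test != p1$valid))
  p2 <- fold_plan(2, 0:40)
  expect_equal(nrow(p2), 41)
  expect_true(all(p2$test != p2$valid))
  expect_setequal(p2$test, 0:40)
  p3 <- fold_plan(3, 0:34)
  expect_equal(nrow(p3), 35)
})

test_that("dyad-specific crossvalidation runs every participant through 10 folds", {
  ft <- make_fake_table(2, seed = 11)
  r <- run_goal(ft, 1, "valence", methods = lin_only(), selectors = "mrmr",
                ks = 3, master_seed = 1)
  expect_equal(sort(unique(r$results$fold)), 1:10)
  # 2 dyads x 2 participants x 10 intervals x 2 methods (linear + mbe)
  expect_equal(nrow(r$results), 2 * 2 * 10 * 2)
  expect_equal(length(unique(r$summary$unit)), 4)
  expect_true(all(r$summary$n == 10))
  expect_true(all(r$summary$rms >= r$summary$ma))
})

test_that("degenerate cohorts with constant ratings give zero error for every method", {
  ft <- make_fake_table(2, seed = 12, labels = 6)
  r <- run_goal(ft, 1, "valence", methods = lin_only(), selectors = "mrmr",
                ks = 3, master_seed = 1)
  expect_true(all(r$summary$ma == 0))
  expect_true(all(r$summary$rms == 0))
  ft4 <- make_fake_table(4, seed = 12, labels = 6)
  r2 <- run_goal(ft4, 2, "arousal", methods = lin_only(), selectors = "mrmr",
                 ks = 3, master_seed = 1)
  expect_true(all(r2$summary$ma == 0))
})

test_that("perturbing one dyad's labels leaves other dyads' fits and errors unchanged", {
  # dyad-specific estimation is fully isolated per dyad: another dyad's
  # labels can never leak into a unit's model or its measured error
  ft <- make_fake_table(4, seed = 13)
  base <- run_goal(ft, 1, "valence", methods = lin_only(), selectors = "mrmr",
                   ks = 3, master_seed = 2)
  ft2 <- ft
  sel <- ft2$ratings$dyad_id == 0 & ft2$ratings$rater == "self"
  set.seed(99)
  ft2$ratings$valence[sel] <- sample(1:9, sum(sel), replace = TRUE)
  pert <- run_goal(ft2, 1, "valence", methods = lin_only(), selectors = "mrmr",
                   ks = 3, master_seed = 2)
  s1 <- base$summary[base$summary$method == "linear", ]
  s2 <- pert$summary[pert$summary$method == "linear", ]
  s2 <- s2[match(s1$unit, s2$unit), ]
  keep <- !grepl("^0\\.", s1$unit)
  expect_equal(s1$rms[keep], s2$rms[keep], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s1$rms[!keep], s2$rms[!keep])))
})

test_that("Holm-Sidak adjustment is monotone and method comparison flags real gaps", {
  p <- c(0.04, 0.001, 0.3, 0.02)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))

  set.seed(14)
  units <- sprintf("u%02d", 1:40)
  base_err <- runif(40, 1, 2)
  sm <- rbind(
    data.frame(method = "good", unit = units, n = 10,
               ma = base_err - 1.0, rms = base_err - 1.0 + 0.1),
    data.frame(method = "bad1", unit = units, n = 10,
               ma = base_err, rms = base_err + 0.1),
    data.frame(method = "bad2", unit = units, n = 10,
               ma = base_err + rnorm(40, 0, 0.05),
               rms = base_err + 0.1 + rnorm(40, 0, 0.05)))
  cmp <- compare_methods(sm, "rms")
  expect_lt(cmp$omnibus_p, 0.001)
  good_rows <- cmp$pairwise$method_a == "good" | cmp$pairwise$method_b == "good"
  expect_true(all(cmp$pairwise$p_adj[good_rows] < 0.05))

  sm_same <- rbind(data.frame(method = "a", unit = units, n = 10,
                              ma = base_err, rms = base_err + 0.1),
                   data.frame(method = "b", unit = units, n = 10,
                              ma = base_err, rms = base_err + 0.1))
  cmp2 <- compare_methods(sm_same, "rms")
  expect_true(is.na(cmp2$omnibus_p) || cmp2$omnibus_p > 0.05)
  expect_true(all(cmp2$pairwise$p_adj == 1))
})

test_that("rating descriptives match an independent one-pass recomputation", {
  ft <- make_fake_table(4, seed = 15, labels = 7)
  d <- describe_ratings(ft)
  expect_equal(d$valence$pooled_mean, 7)
  expect_equal(d$valence$pooled_sd, 0)
  expect_equal(d$valence$range_mean, 0)
  expect_equal(d$valence$partner_diff_mean, 0)

  # constant 5 vs constant 7 partners: partner difference 2
  ft2 <- make_fake_table(1, seed = 16,
                         label_fun = function(d, i, p, target)
                           if (is.na(p)) 6 else if (p == 1) 5 else 7)
  d2 <- describe_ratings(ft2)
  expect_equal(d2$valence$partner_diff_mean, 2)
  expect_equal(d2$valence$pooled_mean, 6)

  ft3 <- make_fake_table(3, seed = 17)
  d3 <- describe_ratings(ft3)
  self <- ft3$ratings[ft3$ratings$rater == "self", ]
  # naive loops as the oracle
  acc <- c()
  for (i in seq_len(nrow(self))) acc <- c(acc, self$arousal[i])
  expect_equal(d3$arousal$pooled_mean, mean(acc), tolerance = 1e-12)
  rng <- c()
  for (dd in unique(self$dyad_id)) for (p in 1:2) {
    v <- self$arousal[self$dyad_id == dd & self$participant == p]
    rng <- c(rng, max(v) - min(v))
  }
  expect_equal(d3$arousal$range_mean, mean(rng), tolerance = 1e-12)
  pd <- c()
  for (dd in unique(self$dyad_id)) for (i in 1:10) {
    v <- self$arousal[self$dyad_id == dd & self$interval_index == i]
    pd <- c(pd, abs(v[1] - v[2]))
  }
  expect_equal(d3$arousal$partner_diff_mean, mean(pd), tolerance = 1e-12)
})

test_that("synchrony ablation changes only the synchrony columns and detects their value", {
  # labels carried by a synchrony feature: ablation must hurt
  sync_lab <- make_fake_table(12, seed = 18)
  z <- as.numeric(scale(sync_lab$sync$sync_dtw_eda))
  lab <- pmin(9, pmax(1, round(5 + 2.5 * z)))
  key <- paste(sync_lab$sync$dyad_id, sync_lab$sync$interval_index)
  rk <- paste(sync_lab$ratings$dyad_id, sync_lab$ratings$interval_index)
  sync_lab$ratings$valence <- lab[match(rk, key)]
  res <- ablate_synchrony(sync_lab, 2, "valence", methods = lin_only(),
                          selectors = "mrmr", ks = 3, master_seed = 3)
  a <- res$with_sync$summary; b <- res$no_sync$summary
  expect_lt(mean(a$rms[a$method == "linear"]), mean(b$rms[b$method == "linear"]))
  expect_lt(res$comparison$rms$p, 0.05)

  # labels carried by an individual feature: ablation is immaterial
  ind_lab <- make_fake_table(12, seed = 19)
  iz <- as.numeric(scale(ind_lab$individual$mean_hr))
  ilab <- pmin(9, pmax(1, round(5 + 2.5 * iz)))
  ik <- paste(ind_lab$individual$dyad_id, ind_lab$individual$interval_index,
              ind_lab$individual$participant)
  rk2 <- paste(ind_lab$ratings$dyad_id, ind_lab$ratings$interval_index,
               ind_lab$ratings$participant)
  ind_lab$ratings$valence <- ilab[match(rk2, ik)]
  ind_lab$ratings$valence[is.na(ind_lab$ratings$valence)] <- 5
  res2 <- ablate_synchrony(ind_lab, 2, "valence", methods = lin_only(),
                           selectors = "mrmr", ks = 3, master_seed = 3)
  expect_gt(res2$comparison$rms$p, 0.05)
})

test_that("characteristics augmentation is dyad-nonspecific only and inert when constant", {
  ft <- make_fake_table(6, seed = 20)
  ft$characteristics$age <- 25
  ft$characteristics$gender <- "female"
  for (nm in c("cognitive_empathy", "affective_empathy", "social_anxiety",
               "depression"))
    ft$characteristics[[nm]] <- 40
  expect_error(augment_characteristics(ft, 1, "valence"), "dyad-nonspecific")
  res <- augment_characteristics(ft, 2, "valence", methods = lin_only(),
                                 selectors = "mrmr", ks = 3, master_seed = 4)
  a <- res$plain$summary; b <- res$augmented$summary
  b <- b[match(paste(a$method, a$unit), paste(b$method, b$unit)), ]
  expect_equal(a$rms, b$rms, tolerance = 1e-6)
})

test_that("top-feature reporting returns k deterministic names and finds planted structure", {
  ft <- make_fake_table(10, seed = 21)
  # plant a dominant smooth manifold shared by several synchrony features,
  # carried in its purest form by one of them
  base <- as.numeric(scale(ft$sync$dyad_id * 10 + ft$sync$interval_index))
  ft$sync$sync_hausd_temp <- base
  mixed <- setdiff(grep("^sync_", names(ft$sync), value = TRUE),
                   "sync_hausd_temp")[1:14]
  for (nm in mixed) ft$sync[[nm]] <- 2 * base + ft$sync[[nm]]
  tf <- top_features(ft, "valence", "self", k = 5)
  expect_length(tf, 5)
  expect_identical(tf, top_features(ft, "valence", "self", k = 5))
  expect_true("sync_hausd_temp" %in% tf)
  tf3 <- top_features(ft, "arousal", "observer", k = 5)
  expect_length(tf3, 5)
})
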