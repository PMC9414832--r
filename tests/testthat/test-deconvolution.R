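target_for <- function(spec, rt = 0.5, ...) {
  target_compound("tgt", spec, rt = rt, ...)
}

test_that("reduced intensities normalize qualifiers by expected share", {
  ref <- new_spectrum(c(100, 120), c(1000, 500))        # Ri = 0.5 for 120
  tg <- target_compound("t", new_spectrum(c(100, 120, 140), c(1000, 500, 10)),
                        rt = 1,
                        qualifiers = data.frame(mz = c(120, 140),
                                                ri_expected = c(0.5, 0.01)))
  scan <- new_spectrum(c(100, 120, 140), c(10000, 5000, 100))
  expect_equal(reduced_intensities(scan, tg), c(1.0, 1.0))
  scan2 <- new_spectrum(c(100, 120, 140), c(10000, 4000, 100))
  expect_equal(reduced_intensities(scan2, tg), c(0.8, 1.0))
  scan3 <- new_spectrum(c(120, 140), c(5000, 100))      # main ion absent
  expect_error(reduced_intensities(scan3, tg), "undefined")
})

test_that("the average reduced-intensity deviation matches hand values", {
  expect_equal(delta_i(c(1, 1, 1)), 0)
  expect_equal(delta_i(c(1.0, 0.8, 1.2)), (0.2 + 0.2 + 0.4) / 3)
  expect_equal(delta_i(c(0.9, 1.1)), 0.2)
  expect_error(delta_i(1), "at least 2")
})

test_that("the deviation is invariant under permutation of the ions", {
  set.seed(31)
  for (rep in 1:25) {
    v <- runif(sample(2:6, 1), 0, 3)
    expect_equal(delta_i(sample(v)), delta_i(v))
  }
})

test_that("scan-to-scan variance weights the deviation by log10 abundance", {
  expect_equal(ssv(0, 12345), 0)
  expect_equal(ssv(0.5, 1e4), 2.0)
  expect_gt(ssv(2.0, 1e4), 7)             # 8 exceeds the default ceiling
  expect_error(ssv(0.5, 0), "positive")
})

test_that("Q-value measures percent ion-ratio agreement across the peak", {
  ref <- new_spectrum(c(100, 120, 140), c(1000, 500, 200))
  tg <- target_for(ref, rt = 0.1)
  mk_run <- function(fac) {
    mat <- matrix(rep(c(1000, 500 * fac, 200 * fac), each = 6), nrow = 6)
    new_chrom_run(seq(0.08, 0.13, by = 0.01), mat, mz = c(100L, 120L, 140L))
  }
  expect_equal(q_value(mk_run(1), tg, 1:6), 100)
  expect_equal(q_value(mk_run(1.1), tg, 1:6), 90)
  expect_equal(q_value(mk_run(2), tg, 1:6), 0)   # clamped at zero
  zero <- new_chrom_run(c(0.1, 0.2, 0.3), matrix(0, 3, 3),
                        mz = c(100L, 120L, 140L))
  expect_error(q_value(zero, tg, 1:3), "nonzero main")
})

test_that("Q-ratio deviation is the worst mean qualifier ratio error", {
  ref <- new_spectrum(c(100, 120, 140), c(1000, 500, 200))
  tg <- target_for(ref, rt = 0.1)
  mk_run <- function(f120, f140) {
    mat <- matrix(rep(c(1000, 500 * f120, 200 * f140), each = 6), nrow = 6)
    new_chrom_run(seq(0.08, 0.13, by = 0.01), mat, mz = c(100L, 120L, 140L))
  }
  expect_equal(q_ratio_deviation(mk_run(1, 1), tg, 1:6), 0)
  expect_equal(q_ratio_deviation(mk_run(1.3, 1), tg, 1:6), 0.3)
  expect_equal(q_ratio_deviation(mk_run(1, 1.15), tg, 1:6), 0.15)
})

test_that("a clean simulated peak passes all four criteria", {
  sp <- random_spectrum(5, 10)
  cmp <- planted_compound("A", sp, 0.5, 0.02, 1e6)
  cfg <- sim_config(duration = 1, seed = 42, baseline = 2, noise_sd = 1)
  sim <- simulate_run(list(cmp), cfg)
  res <- evaluate_target(sim$run, target_for(sp, rt = 0.5),
                         noise = estimate_noise(sim$run))
  expect_true(res$passed)
  expect_gt(res$q_value, 97)
  expect_lt(min(res$delta_i, na.rm = TRUE), 0.05)
  expect_gte(res$n_consecutive_pass, 5)
})

test_that("an interferent sharing a qualifier ion breaks the Q-ratio", {
  # coeluter adds 50% extra signal on one qualifier channel throughout
  ref <- new_spectrum(c(100, 120, 140), c(1000, 500, 200))
  tg <- target_for(ref, rt = 0.05)
  times <- seq(0.01, 0.1, by = 0.01)
  prof <- dnorm(times, 0.05, 0.015)
  mat <- cbind(1000 * prof, 500 * prof * 1.5, 200 * prof)
  run <- new_chrom_run(times, mat * 1e3, mz = c(100L, 120L, 140L))
  res <- evaluate_target(run, tg, rt_window = 0.05)
  expect_false(res$passed)
  expect_gt(res$q_ratio_dev, 0.20)
})

test_that("a peak spanning only four scans cannot qualify", {
  ref <- new_spectrum(c(100, 120, 140), c(1000, 500, 200))
  tg <- target_for(ref, rt = 0.05)
  mat <- matrix(0, nrow = 10, ncol = 3)
  mat[4:7, ] <- matrix(rep(c(1000, 500, 200), each = 4), nrow = 4)
  run <- new_chrom_run(seq(0.01, 0.1, by = 0.01), mat,
                       mz = c(100L, 120L, 140L))
  res <- evaluate_target(run, tg, rt_window = 0.05)
  expect_false(res$passed)
  expect_equal(res$n_consecutive_pass, 4L)
})

test_that("a target eluting outside the run yields a not-found result", {
  run <- new_chrom_run(c(0.1, 0.2, 0.3), matrix(1, 3, 3),
                       mz = c(100L, 120L, 140L))
  tg <- target_for(new_spectrum(c(100, 120, 140), c(1000, 500, 200)), rt = 9)
  res <- evaluate_target(run, tg, rt_window = 0.1)
  expect_false(res$passed)
  expect_null(res$region)
  expect_equal(res$abundance, 0)
})

test_that("uniform intensity scaling leaves ratios fixed, shifts SSV by log10(c)", {
  ref <- new_spectrum(c(100, 120, 140), c(1000, 480, 210))
  tg <- target_for(ref, rt = 0.05)
  set.seed(7)
  times <- seq(0.01, 0.1, by = 0.01)
  mat <- cbind(1000, 500, 200)[rep(1, 10), ] * dnorm(times, 0.05, 0.02) *
    matrix(runif(30, 0.9, 1.1), 10) * 1e3
  run <- new_chrom_run(times, mat, mz = c(100L, 120L, 140L))
  for (cc in c(0.1, 10)) {
    run2 <- new_chrom_run(times, mat * cc, mz = c(100L, 120L, 140L))
    expect_equal(q_value(run2, tg, 1:10), q_value(run, tg, 1:10))
    expect_equal(q_ratio_deviation(run2, tg, 1:10),
                 q_ratio_deviation(run, tg, 1:10))
    for (i in c(3, 5, 7)) {
      r1 <- reduced_intensities(run_scan(run, i)$spectrum, tg)
      r2 <- reduced_intensities(run_scan(run2, i)$spectrum, tg)
      expect_equal(r2, r1)
      a1 <- spectrum_intensity_at(run_scan(run, i)$spectrum, 100)
      expect_equal(ssv(delta_i(r2), a1 * cc),
                   ssv(delta_i(r1), a1) + delta_i(r1) * log10(cc))
    }
  }
})

test_that("evaluate_target agrees with a brute-force straight-line oracle", {
  crit <- match_criteria(min_consecutive_scans = 3)
  for (seed in 1:20) {
    set.seed(seed)
    n <- 8
    mzs <- c(100L, 120L, 140L, 160L)
    ref <- new_spectrum(mzs, c(1000, 500, 300, 150))
    tg <- target_compound("t", ref, rt = 0.05)
    mat <- matrix(runif(n * 4, 0, 2000), nrow = n)
    if (seed %% 3 == 0) mat[sample(n, 2), 1] <- 0   # some zero-main scans
    run <- new_chrom_run(seq(0.01, 0.08, by = 0.01), mat, mz = mzs)

    # --- independent straight-line evaluation -------------------------
    ri <- c(0.5, 0.3, 0.15)
    qual <- ok <- rep(FALSE, n)
    di <- de <- rep(NA_real_, n)
    for (t in 1:n) {
      amain <- mat[t, 1]
      if (amain <= 0) next
      ii <- c(mat[t, 2] / (ri[1] * amain), mat[t, 3] / (ri[2] * amain),
              mat[t, 4] / (ri[3] * amain))
      s <- 0
      for (a in 1:2) for (b in (a + 1):3) s <- s + abs(ii[a] - ii[b])
      di[t] <- s / 3
      de[t] <- di[t] * log10(amain)
      qual[t] <- all(abs(ii - 1) <= 0.20) && di[t] <= 0.20
    }
    best_len <- 0; best_start <- NA
    cur <- 0
    for (t in 1:n) {
      if (qual[t]) cur <- cur + 1 else cur <- 0
      if (cur > best_len) { best_len <- cur; best_start <- t - cur + 1 }
    }
    oracle_pass <- FALSE; oracle_q <- NA_real_
    if (best_len >= 3) {
      win <- best_start:(best_start + best_len - 1)
      devs <- c()
      mean_red <- c(0, 0, 0); nn <- 0
      for (t in win) {
        amain <- mat[t, 1]
        ii <- c(mat[t, 2] / (ri[1] * amain), mat[t, 3] / (ri[2] * amain),
                mat[t, 4] / (ri[3] * amain))
        devs <- c(devs, abs(1 - ii))
        mean_red <- mean_red + ii; nn <- nn + 1
      }
      oracle_q <- max(0, min(100, 100 - mean(100 * devs)))
      qr <- max(abs(mean_red / nn - 1))
      oracle_pass <- oracle_q >= 95 && qr <= 0.20 &&
        min(de[win]) <= 7
    }
    # ------------------------------------------------------------------
    res <- evaluate_target(run, tg, crit, rt_window = 0.1)
    expect_equal(res$passed, oracle_pass, info = paste("seed", seed))
    expect_equal(res$n_consecutive_pass, best_len, info = paste("seed", seed))
    if (best_len >= 3) {
      expect_equal(res$q_value, oracle_q, info = paste("seed", seed))
    }
  }
})

test_that("peak detection finds isolated and resolved peaks, not noise", {
  noise_sd <- 30
  # single Gaussian at SNR 100
  cmp <- planted_compound("A", random_spectrum(3, 10), 0.5, 0.02,
                          peak_total_for_snr(100, noise_sd, 0.02))
  cfg <- sim_config(duration = 1, seed = 8, baseline = 5, noise_sd = noise_sd)
  sim <- simulate_run(list(cmp), cfg)
  regions <- detect_peaks(sim$run)
  expect_length(regions, 1)
  apex_scan <- which.min(abs(sim$run$times - 0.5))
  expect_true(regions[[1]]$start_scan <= apex_scan &&
                apex_scan <= regions[[1]]$end_scan)

  # flat noise-only run
  sim0 <- simulate_run(list(), cfg)
  expect_length(detect_peaks(sim0$run), 0)

  # two Gaussians 5 sigma apart split at the valley
  cmp2 <- planted_compound("B", random_spectrum(4, 10), 0.6, 0.02,
                           peak_total_for_snr(100, noise_sd, 0.02))
  sim2 <- simulate_run(list(cmp, cmp2), cfg)
  regions2 <- detect_peaks(sim2$run)
  expect_length(regions2, 2)
  expect_lte(regions2[[1]]$end_scan, regions2[[2]]$start_scan)
})

test_that("invariant-scan selection finds constant windows", {
  noise_sd <- 5
  cmp <- planted_compound("A", random_spectrum(3, 12), 0.5, 0.02,
                          peak_total_for_snr(200, noise_sd, 0.02))
  cfg <- sim_config(duration = 1, seed = 8, baseline = 2, noise_sd = noise_sd)
  sim <- simulate_run(list(cmp), cfg)
  rg <- detect_peaks(sim$run)[[1]]
  inv <- select_invariant_scans(sim$run, rg)
  expect_false(is.null(inv))
  d <- scan_distance_matrix(sim$run, peak_region(min(inv), min(inv), max(inv)))
  expect_lte(max(d), 0.002)   # pairwise cosine >= 0.998 within the window

  # two coeluters offset 2 sigma: window sits where the leader dominates
  cmp2 <- planted_compound("B", random_spectrum(4, 12), 0.54, 0.02,
                           peak_total_for_snr(200, noise_sd, 0.02))
  sim2 <- simulate_run(list(cmp, cmp2), cfg)
  rg2 <- detect_peaks(sim2$run)[[1]]
  inv2 <- select_invariant_scans(sim2$run, rg2)
  expect_false(is.null(inv2))
  contrib <- sim2$truth$contributions
  share_A <- sum(contrib[inv2, "A"]) / sum(contrib[inv2, ])
  share_B <- sum(contrib[inv2, "B"]) / sum(contrib[inv2, ])
  expect_gt(max(share_A, share_B), 0.85)

  # a noise-only region has no invariant window
  sim0 <- simulate_run(list(), cfg)
  expect_null(select_invariant_scans(sim0$run, peak_region(100, 105, 110)))
})

test_that("average_spectrum is the per-m/z arithmetic mean", {
  mat <- rbind(c(10, 0), c(30, 4))
  run <- new_chrom_run(c(0.1, 0.2), mat, mz = c(100L, 200L))
  avg <- average_spectrum(run, 1:2)
  expect_equal(spectrum_intensity_at(avg, c(100, 200)), c(20, 2))
  expect_equal(average_spectrum(run, 1)$intensity, c(10))
  expect_error(average_spectrum(run, integer(0)), "at least one")
})

test_that("component subtraction conserves signal before clipping", {
  case <- make_coeluter_case(3)
  rg <- detect_peaks(case$run)[[1]]
  comp <- case$cmps[[1]]$spectrum
  sub <- subtract_component(case$run, rg, comp, base_peak(comp))
  idx <- rg$start_scan:rg$end_scan
  orig_sum <- sum(case$run$intensities[idx, ])
  resid_sum <- sum(sub$residual$intensities[idx, ])
  expect_equal(orig_sum, sub$subtracted_total + resid_sum - sub$clipped,
               tolerance = 1e-9)
  # scans outside the region are untouched
  outside <- setdiff(seq_len(n_scans(case$run)), idx)
  expect_identical(sub$residual$intensities[outside, ],
                   case$run$intensities[outside, ])
  expect_error(subtract_component(case$run, rg, comp, 9999), "anchor")
})

test_that("subtracting the true spectrum of a lone compound empties the region", {
  sp <- random_spectrum(6, 10)
  cmp <- planted_compound("A", sp, 0.5, 0.02, 1e6)
  cfg <- sim_config(duration = 1, seed = 2, baseline = 0, noise_sd = 0)
  sim <- simulate_run(list(cmp), cfg)
  apex <- which.min(abs(sim$run$times - 0.5))
  rg <- peak_region(apex - 40, apex, apex + 40)
  sub <- subtract_component(sim$run, rg, sp, base_peak(sp))
  expect_lt(max(tic(sub$residual)[rg$start_scan:rg$end_scan]),
            1e-6 * max(tic(sim$run)))
})

test_that("subtracting one coeluter reveals the other's spectrum", {
  spA <- random_spectrum(21, 12); spB <- random_spectrum(22, 14)
  cmps <- list(planted_compound("A", spA, 0.50, 0.02, 1e6),
               planted_compound("B", spB, 0.53, 0.02, 8e5))
  cfg <- sim_config(duration = 1, seed = 2, baseline = 0, noise_sd = 0)
  sim <- simulate_run(cmps, cfg)
  apexB <- which.min(abs(sim$run$times - 0.53))
  rg <- peak_region(apexB - 60, apexB, apexB + 40)
  sub <- subtract_component(sim$run, rg, spA, base_peak(spA))
  revealed <- run_scan(sub$residual, apexB)$spectrum
  expect_gt(spectrum_cosine(revealed, spB), 0.99)
})

test_that("background classification separates residual signal from noise", {
  cfg <- sim_config(duration = 0.5, seed = 5, baseline = 5, noise_sd = 20)
  # noiseless zero residual
  z <- simulate_run(list(), sim_config(duration = 0.5, seed = 1,
                                       baseline = 0, noise_sd = 0))
  nz <- noise_model(baseline_level = 10, baseline_mad = 2)
  expect_true(residual_is_background(z$run, peak_region(10, 20, 30), nz))

  # an unsubtracted compound at SNR 50 is not background
  cmp <- planted_compound("A", random_spectrum(9, 10), 0.25, 0.02,
                          peak_total_for_snr(50, 20, 0.02))
  sim <- simulate_run(list(cmp), cfg)
  ref <- simulate_run(list(), cfg)
  noise <- estimate_noise(ref$run)
  apex <- which.min(abs(sim$run$times - 0.25))
  expect_false(residual_is_background(sim$run,
                                      peak_region(apex - 20, apex, apex + 20),
                                      noise))

  # pure baseline draws classify as background in >= 99/100 seeded draws
  hits <- 0L
  for (s in 1:100) {
    draw <- simulate_run(list(), sim_config(duration = 0.25, seed = s,
                                            baseline = 5, noise_sd = 20))
    nm <- estimate_noise(draw$run)
    hits <- hits + residual_is_background(draw$run, peak_region(50, 75, 100), nm)
  }
  expect_gte(hits, 99L)
})

test_that("deconvolving a lone library compound returns exactly it", {
  sp <- random_spectrum(13, 10)
  cmp <- planted_compound("A", sp, 0.5, 0.02, 1e6)
  cfg <- sim_config(duration = 1, seed = 11, baseline = 5, noise_sd = 10)
  sim <- simulate_run(list(cmp), cfg)
  noise <- estimate_noise(sim$run)
  rg <- detect_peaks(sim$run, noise)[[1]]
  dec <- deconvolve_peak(sim$run, rg, truth_library(list(cmp)), noise = noise)
  expect_length(dec$components, 1)
  expect_equal(dec$components[[1]]$target$id, "A")
  expect_true(dec$background_reached)
})

test_that("a pure-noise region deconvolves to nothing", {
  cfg <- sim_config(duration = 0.5, seed = 17, baseline = 5, noise_sd = 20)
  sim <- simulate_run(list(), cfg)
  noise <- estimate_noise(sim$run)
  rg <- peak_region(100, 120, 140)
  dec <- deconvolve_peak(sim$run, rg, target_library(), noise = noise)
  expect_length(dec$components, 0)
  expect_identical(dec$residual$intensities, sim$run$intensities)
})
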