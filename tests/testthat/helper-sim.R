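# Shared simulation scenarios. SNR is referenced to the TIC trace: the apex
# TIC of a planted peak equals snr * sd(TIC noise), with
# sd(TIC noise) = sqrt(n_mz) * per-cell noise sd.

peak_total_for_snr <- function(snr, noise_sd, sigma, scan_rate = 12,
                               n_mz = 301) {
  dt <- 1 / (scan_rate * 60)
  snr * sqrt(n_mz) * noise_sd * sigma * sqrt(2 * pi) / dt
}

# 2-4 coeluting compounds, apex separation 0.5-2 sigma, SNR 30-300
make_coeluter_case <- function(seed, sigma = 0.025, noise_sd = 30) {
  set.seed(seed)
  k <- sample(2:4, 1)
  sep <- runif(k - 1, 0.5, 2) * sigma
  rts <- 0.5 + c(0, cumsum(sep))
  snr <- runif(k, 30, 300)
  totals <- peak_total_for_snr(snr, noise_sd, sigma)
  cmps <- lapply(seq_len(k), function(i)
    planted_compound(paste0("C", i),
                     random_spectrum(seed * 100 + i, sample(5:25, 1)),
                     rts[i], sigma, totals[i]))
  cfg <- sim_config(duration = 1.2, seed = seed, baseline = 5,
                    noise_sd = noise_sd)
  sim <- simulate_run(cmps, cfg)
  list(k = k, sep = sep, snr = snr, totals = totals, cmps = cmps,
       run = sim$run, truth = sim$truth)
}

# seven compounds whose apexes fall within a 0.15-min span
make_seven_component_case <- function(seed, sigma = 0.025, noise_sd = 30) {
  k <- 7
  rts <- 0.5 + seq(0, 0.15, length.out = k)
  set.seed(seed)
  snr <- runif(k, 50, 300)
  totals <- peak_total_for_snr(snr, noise_sd, sigma)
  cmps <- lapply(seq_len(k), function(i)
    planted_compound(paste0("C", i),
                     random_spectrum(seed * 1000 + i, sample(8:25, 1)),
                     rts[i], sigma, totals[i]))
  cfg <- sim_config(duration = 1.2, seed = seed, baseline = 5,
                    noise_sd = noise_sd)
  sim <- simulate_run(cmps, cfg)
  list(k = k, totals = totals, cmps = cmps, run = sim$run)
}

# deconvolve every detected region of a run against a library, collecting
# all components
deconvolve_run <- function(run, lib, noise = NULL, ...) {
  if (is.null(noise)) noise <- estimate_noise(run)
  comps <- list()
  bg <- TRUE
  for (rg in detect_peaks(run, noise)) {
    dec <- deconvolve_peak(run, rg, lib, noise = noise, ...)
    comps <- c(comps, dec$components)
    bg <- bg && dec$background_reached
  }
  list(components = comps, background_reached = bg)
}

# TRUE when every planted compound of a coeluter case is recovered with
# spectrum cosine >= cos_min and abundance relative error <= err_max
case_fully_recovered <- function(case, cos_min = 0.95, err_max = 0.10) {
  dec <- deconvolve_run(case$run, truth_library(case$cmps))
  got <- vapply(dec$components, function(cp) cp$target$id, character(1))
  for (i in seq_len(case$k)) {
    j <- match(paste0("C", i), got)
    if (is.na(j)) return(FALSE)
    cp <- dec$components[[j]]
    if (spectrum_cosine(cp$spectrum_est, case$cmps[[i]]$spectrum) < cos_min)
      return(FALSE)
    if (abs(cp$abundance - case$totals[i]) / case$totals[i] > err_max)
      return(FALSE)
  }
  TRUE
}

# expected library-entry count from campaign ground truth. A compound
# occurrence (original or carried copy) is "isolated" when no other
# occurrence sits within half a peak width (0.5 sigma) in the same cut --
# closer than that, components without prior spectra are not
# chromatographically distinguishable. Compounds with at least one isolated
# occurrence contribute one entry each; never-isolated compounds collapse
# into one entry per co-elution cluster.
expected_campaign_entries <- function(camp, sigma = 0.02) {
  ass <- camp$truth$assignment
  occ <- data.frame(id = ass$truth_id, cut = ass$cut, rt2 = ass$rt2)
  car <- ass[ass$carried, ]
  if (nrow(car)) occ <- rbind(occ, data.frame(id = car$truth_id,
                                              cut = car$cut + 1L,
                                              rt2 = car$rt2))
  ids <- unique(occ$id)
  iso <- stats::setNames(rep(FALSE, length(ids)), ids)
  partners <- list()
  for (k in seq_len(nrow(occ))) {
    same <- occ[occ$cut == occ$cut[k] & occ$id != occ$id[k], ]
    close <- same$id[abs(same$rt2 - occ$rt2[k]) < 0.5 * sigma]
    if (!length(close)) iso[occ$id[k]] <- TRUE
    partners[[occ$id[k]]] <- union(partners[[occ$id[k]]], close)
  }
  blended <- ids[!iso[ids]]
  clusters <- 0
  seen <- character(0)
  for (b in blended) {
    if (b %in% seen) next
    q <- b
    while (length(q)) {
      x <- q[1]; q <- q[-1]
      if (x %in% seen) next
      seen <- c(seen, x)
      q <- c(q, intersect(partners[[x]], blended))
    }
    clusters <- clusters + 1
  }
  sum(iso) + clusters
}

# a minimal 2-compound reference MSP text, written to a temp file
write_tiny_msp <- function(path) {
  writeLines(c(
    "Name: alpha-test-ketone",
    "CAS#: 000-00-1",
    "RI: 1102",
    "Num Peaks: 4",
    "93 999; 136 350; 77 120; 105 80;",
    "",
    "Name: beta-test-ester",
    "RI: 1240",
    "Num Peaks: 3",
    "88 999; 101 410; 70 150;",
    ""), path)
  path
}
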