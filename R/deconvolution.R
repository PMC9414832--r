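#' Match criteria for target qualification
#'
#' The four ion-ratio criteria that together affirm a target identification:
#' (1--2) the average reduced-intensity deviation must satisfy
#' `deltaI <= K + delta0 / A_main` and the abundance-weighted scan-to-scan
#' variance `deltaE = deltaI * log10(A_main)` must stay below `delta_e_max`,
#' over at least `min_consecutive_scans` consecutive scans with every
#' reduced intensity within `max_ion_deviation` of 1; (3) the Q-value
#' (percent agreement of observed vs expected ion ratios across the peak)
#' must be at least `q_value_min`; (4) the Q-ratio deviation of each
#' qualifier:main ratio across the peak must be within `q_ratio_tol`.
#'
#' @param K acceptable relative difference for the reduced-intensity
#'   deviation (default 0.20).
#' @param delta0 additive error attributable to instrument noise or
#'   background, in counts. `NULL` (default) derives it as three times the
#'   baseline MAD of the supplied noise model at evaluation time.
#' @param delta_e_max ceiling on the scan-to-scan variance (default 7).
#' @param min_consecutive_scans minimum consecutive qualifying scans
#'   (default 5).
#' @param max_ion_deviation per-ion tolerance on `|Ii - 1|` (default 0.20).
#' @param q_value_min minimum Q-value percent (default 95).
#' @param q_ratio_tol Q-ratio fractional tolerance (default 0.20).
#' @return An object of class `match_criteria`.
#' @export
match_criteria <- function(K = 0.20, delta0 = NULL, delta_e_max = 7,
                           min_consecutive_scans = 5L,
                           max_ion_deviation = 0.20,
                           q_value_min = 95, q_ratio_tol = 0.20) {
  stopifnot(K > 0, delta_e_max > 0, min_consecutive_scans >= 1,
            max_ion_deviation > 0, max_ion_deviation <= 1,
            q_value_min > 0, q_value_min <= 100,
            q_ratio_tol > 0, q_ratio_tol <= 1)
  if (!is.null(delta0)) stopifnot(delta0 >= 0)
  structure(list(K = K, delta0 = delta0, delta_e_max = delta_e_max,
                 min_consecutive_scans = as.integer(min_consecutive_scans),
                 max_ion_deviation = max_ion_deviation,
                 q_value_min = q_value_min, q_ratio_tol = q_ratio_tol),
            class = "match_criteria")
}

#' Peak region within a run
#'
#' @param start_scan,apex_scan,end_scan scan indices with
#'   `start <= apex <= end` and at least 3 scans in total.
#' @return An object of class `peak_region`.
#' @export
peak_region <- function(start_scan, apex_scan, end_scan) {
  start_scan <- as.integer(start_scan); apex_scan <- as.integer(apex_scan)
  end_scan <- as.integer(end_scan)
  stopifnot(start_scan <= apex_scan, apex_scan <= end_scan,
            end_scan - start_scan + 1L >= 3L)
  structure(list(start_scan = start_scan, apex_scan = apex_scan,
                 end_scan = end_scan), class = "peak_region")
}

#' Estimate a baseline noise model from a run
#'
#' Robust location/scale of the TIC: the baseline level is the median TIC and
#' the spread its median absolute deviation, computed over `window` (all
#' scans by default). Suitable when peaks occupy a minority of scans or when
#' an empty region of the run is supplied.
#'
#' @param run a `chrom_run`.
#' @param window optional integer vector of scan indices to estimate from.
#' @return An object of class `noise_model` with fields `baseline_level`,
#'   `baseline_mad` and `estimation_window`.
#' @export
estimate_noise <- function(run, window = NULL) {
  stopifnot(inherits(run, "chrom_run"))
  if (is.null(window)) window <- seq_len(n_scans(run))
  x <- tic(run)[window]
  structure(list(baseline_level = stats::median(x),
                 baseline_mad = stats::mad(x),
                 estimation_window = range(window)),
            class = "noise_model")
}

#' Noise model from known parameters
#'
#' @param baseline_level baseline TIC level in counts.
#' @param baseline_mad robust TIC spread in counts (>= 0).
#' @param estimation_window optional scan range the estimate came from.
#' @return A `noise_model`.
#' @export
noise_model <- function(baseline_level, baseline_mad,
                        estimation_window = c(NA_integer_, NA_integer_)) {
  stopifnot(baseline_mad >= 0)
  structure(list(baseline_level = baseline_level, baseline_mad = baseline_mad,
                 estimation_window = estimation_window), class = "noise_model")
}

# effective additive error term: explicit delta0, else 3 x baseline MAD
.delta0 <- function(criteria, noise) {
  if (!is.null(criteria$delta0)) return(criteria$delta0)
  if (!is.null(noise)) return(3 * noise$baseline_mad)
  0
}

#' Reduced ion intensities of one scan against a target
#'
#' Each qualifier ion intensity is normalized by its expected share of the
#' main-ion intensity: `Ii = Ai / (Ri * A_main)`. A scan whose ion ratios
#' match the reference exactly yields `Ii = 1` for every qualifier -- the
#' flatter the vector, the closer the observed ratios are to the expected
#' ones.
#'
#' @param scan_spectrum a `mass_spectrum` (one scan).
#' @param target a `target_compound`.
#' @return Numeric vector of reduced intensities, one per qualifier ion.
#' @export
reduced_intensities <- function(scan_spectrum, target) {
  a_main <- spectrum_intensity_at(scan_spectrum, target$main_ion)
  if (a_main <= 0) {
    stop("main-ion intensity is zero; reduced intensities are undefined")
  }
  ai <- spectrum_intensity_at(scan_spectrum, target$qualifiers$mz)
  ai / (target$qualifiers$ri_expected * a_main)
}

#' Average reduced-intensity deviation
#'
#' The mean absolute pairwise difference between the `N` reduced intensities
#' of a scan: the sum of `|Ii - Ij|` over all pairs divided by the number of
#' pairs `N(N-1)/2`. Zero iff all reduced intensities are equal; the closer
#' to zero, the better the spectral match.
#'
#' @param reduced numeric vector of reduced intensities (`N >= 2`).
#' @return The deviation (non-negative scalar).
#' @export
delta_i <- function(reduced) {
  n <- length(reduced)
  if (n < 2) stop("delta_i needs at least 2 reduced intensities")
  d <- abs(outer(reduced, reduced, "-"))
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
}

#' Scan-to-scan variance (SSV)
#'
#' Weights the reduced-intensity deviation by the decadic log of the main-ion
#' abundance: `deltaE = deltaI * log10(A_main)`. Tested against the
#' `delta_e_max` ceiling (7 by default).
#'
#' @param delta_i_value result of [delta_i()].
#' @param a_main main-ion abundance in counts (> 0).
#' @return The SSV value.
#' @export
ssv <- function(delta_i_value, a_main) {
  if (a_main <= 0) stop("ssv requires a positive main-ion abundance")
  delta_i_value * log10(a_main)
}

# internal: per-scan quantities for a target over given scan indices.
# Returns list of matrices/vectors; scans with zero main ion get NA rows.
.target_scan_stats <- function(run, target, scans) {
  qmz <- target$qualifiers$mz
  ri <- target$qualifiers$ri_expected
  main_col <- match(target$main_ion, run$mz)
  q_cols <- match(qmz, run$mz)
  if (is.na(main_col)) stop("target main ion outside the run's m/z grid")
  a_main <- run$intensities[scans, main_col]
  amat <- run$intensities[scans, q_cols, drop = FALSE]
  amat[, is.na(q_cols)] <- 0
  red <- sweep(amat, 2, ri, "/") / a_main       # Ii per scan x qualifier
  red[a_main <= 0, ] <- NA_real_
  n <- length(ri)
  di <- apply(red, 1, function(r) {
    if (anyNA(r)) return(NA_real_)
    d <- abs(outer(r, r, "-")); sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
  })
  de <- ifelse(a_main > 0, di * log10(pmax(a_main, .Machine$double.eps)), NA_real_)
  list(a_main = a_main, reduced = red, delta_i = di, delta_e = de)
}

#' Q-value of a target over a peak region
#'
#' Percent agreement between expected and observed ion ratios: 100 minus the
#' mean (over qualifying scans and qualifier ions) of
#' `100 * |Ri - ri(t)| / Ri`, where `ri(t) = Ai(t) / A_main(t)`, clamped to
#' `[0, 100]`. The closer to 100, the higher the certainty of the match.
#'
#' @param run a `chrom_run`.
#' @param target a `target_compound`.
#' @param scans integer vector of scan indices spanning the peak.
#' @return Q-value in `[0, 100]`.
#' @export
q_value <- function(run, target, scans) {
  st <- .target_scan_stats(run, target, scans)
  ok <- st$a_main > 0
  if (!any(ok)) stop("no scan in the region has nonzero main-ion intensity")
  # |Ri - ri|/Ri = |1 - ri/Ri| = |1 - Ii|
  dev <- abs(1 - st$reduced[ok, , drop = FALSE])
  max(0, min(100, 100 - mean(100 * dev)))
}

#' Q-ratio deviation of a target over a peak region
#'
#' For each qualifier, the observed qualifier:main intensity ratio is
#' averaged across the peak and compared with the expected ratio `Ri`; the
#' maximum fractional deviation over qualifiers is returned. An
#' identification passes when this is within the `q_ratio_tol` tolerance
#' (20% by default).
#'
#' @inheritParams q_value
#' @return Maximum fractional deviation (non-negative scalar).
#' @export
q_ratio_deviation <- function(run, target, scans) {
  st <- .target_scan_stats(run, target, scans)
  ok <- st$a_main > 0
  if (!any(ok)) stop("no scan in the region has nonzero main-ion intensity")
  # mean observed ratio / Ri = mean reduced intensity
  mean_red <- colMeans(st$reduced[ok, , drop = FALSE])
  max(abs(mean_red - 1))
}

#' Evaluate a target against a run
#'
#' Applies the four-part criterion: searches the scans within `rt_window`
#' minutes of the target's retention time for the longest stretch of
#' consecutive qualifying scans (nonzero main ion, every reduced intensity
#' within `max_ion_deviation` of 1, and `deltaI <= K + delta0/A_main`), then
#' checks window length, the SSV ceiling, the Q-value floor, and the Q-ratio
#' tolerance on that stretch. The matched region is the qualifying window
#' extended outward while the main-ion signal persists, and the integrated
#' abundance is the main-ion area over that region.
#'
#' @param run a `chrom_run`.
#' @param target a `target_compound`.
#' @param criteria a [match_criteria()].
#' @param rt_window half-width of the retention-time search window, minutes.
#' @param noise optional `noise_model` (supplies `delta0` when the criteria
#'   leave it `NULL`).
#' @param scans optional explicit scan indices to search (overrides
#'   `rt_window`).
#' @return An object of class `match_result` with fields `target_id`,
#'   `region` (`peak_region` or `NULL`), `scans` (searched indices),
#'   `reduced` (scan x qualifier matrix of reduced intensities -- the
#'   histogram data), `delta_i`, `delta_e` (per searched scan), `q_value`,
#'   `q_ratio_dev`, `n_consecutive_pass`, `passed` and `abundance`
#'   (main-ion area, counts x minutes).
#' @export
evaluate_target <- function(run, target, criteria = match_criteria(),
                            rt_window = 0.2, noise = NULL, scans = NULL) {
  stopifnot(inherits(run, "chrom_run"), inherits(target, "target_compound"))
  if (is.null(scans)) {
    scans <- which(abs(run$times - target$rt) <= rt_window)
  }
  empty <- structure(list(target_id = target$id, region = NULL,
                          scans = integer(0), reduced = NULL,
                          delta_i = numeric(0), delta_e = numeric(0),
                          q_value = NA_real_, q_ratio_dev = NA_real_,
                          n_consecutive_pass = 0L, passed = FALSE,
                          abundance = 0), class = "match_result")
  if (!length(scans)) return(empty)
  st <- .target_scan_stats(run, target, scans)
  d0 <- .delta0(criteria, noise)
  dev_ok <- apply(abs(st$reduced - 1) <= criteria$max_ion_deviation, 1, all)
  dev_ok[is.na(dev_ok)] <- FALSE
  di_ok <- !is.na(st$delta_i) &
    st$delta_i <= criteria$K + d0 / pmax(st$a_main, .Machine$double.eps)
  qualifying <- dev_ok & di_ok & st$a_main > 0
  rl <- rle(qualifying)
  best_len <- 0L; best_start <- NA_integer_
  pos <- 1L
  for (k in seq_along(rl$lengths)) {
    if (rl$values[k] && rl$lengths[k] > best_len) {
      best_len <- rl$lengths[k]; best_start <- pos
    }
    pos <- pos + rl$lengths[k]
  }
  res <- empty
  res$scans <- scans
  res$reduced <- st$reduced
  res$delta_i <- st$delta_i
  res$delta_e <- st$delta_e
  res$n_consecutive_pass <- best_len
  if (best_len < criteria$min_consecutive_scans) {
    # no qualifying window: still expose the ratio diagnostics over the
    # searched scans so a failing identification can be inspected
    if (any(st$a_main > 0)) {
      res$q_value <- q_value(run, target, scans)
      res$q_ratio_dev <- q_ratio_deviation(run, target, scans)
    }
    return(res)
  }
  win <- scans[best_start:(best_start + best_len - 1L)]
  res$q_value <- q_value(run, target, win)
  res$q_ratio_dev <- q_ratio_deviation(run, target, win)
  min_de <- min(st$delta_e[best_start:(best_start + best_len - 1L)], na.rm = TRUE)
  res$passed <- (res$q_value >= criteria$q_value_min) &&
    (res$q_ratio_dev <= criteria$q_ratio_tol) &&
    (min_de <= criteria$delta_e_max)
  # extend the region outward while the main-ion signal persists
  main_col <- match(target$main_ion, run$mz)
  amain_all <- run$intensities[, main_col]
  apex_local <- win[which.max(amain_all[win])]
  floor_level <- max(amain_all[apex_local] * 0.01,
                     if (!is.null(noise)) noise$baseline_mad else 0)
  lo <- min(win); hi <- max(win)
  while (lo > 1 && amain_all[lo - 1] > floor_level) lo <- lo - 1L
  while (hi < n_scans(run) && amain_all[hi + 1] > floor_level) hi <- hi + 1L
  if (hi - lo + 1L < 3L) { lo <- max(1L, lo - 1L); hi <- min(n_scans(run), hi + 1L) }
  res$region <- peak_region(lo, apex_local, hi)
  res$abundance <- sum(amain_all[lo:hi]) * .dt_min(run)
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result '%s': %s, Q=%.1f, Q-ratio dev=%.3f, %d consecutive>\n",
              x$target_id, if (isTRUE(x$passed)) "PASS" else "fail",
              x$q_value, x$q_ratio_dev, x$n_consecutive_pass))
  invisible(x)
}

# internal: Savitzky-Golay smoothed vector, window adapted to length
.smooth_tic <- function(x, n = 7L) {
  if (length(x) < 5) return(x)
  n <- min(n, if (length(x) %% 2) length(x) else length(x) - 1L)
  if (n < 5) return(x)
  p <- min(3L, n - 2L)
  as.numeric(signal::sgolayfilt(x, p = p, n = n))
}

#' Detect TIC peaks in a run
#'
#' Peaks are local maxima of the Savitzky-Golay-smoothed TIC that exceed
#' `baseline_level + 3 * baseline_mad`; each peak region extends until the
#' smoothed TIC returns to near baseline or to the local minimum between
#' adjacent apexes.
#'
#' @param run a `chrom_run` with at least 10 scans.
#' @param noise a `noise_model` (default estimated from the run).
#' @param valley_frac split two apexes into separate regions only when the
#'   valley between them drops below this fraction of the smaller apex
#'   height above baseline (default 0.5); heavily fused peaks stay in one
#'   region and are separated spectrally by [deconvolve_peak()].
#' @return List of `peak_region` objects (possibly empty).
#' @export
detect_peaks <- function(run, noise = NULL, valley_frac = 0.5) {
  stopifnot(inherits(run, "chrom_run"))
  if (n_scans(run) < 10) stop("peak detection needs at least 10 scans")
  if (is.null(noise)) noise <- estimate_noise(run)
  s <- .smooth_tic(tic(run))
  level <- noise$baseline_level
  thr <- level + 3 * noise$baseline_mad
  base_return <- level + noise$baseline_mad
  n <- length(s)
  above <- s > thr
  if (!any(above)) return(list())
  # contiguous above-threshold blobs, extended outward to baseline return
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  blobs <- cbind(starts[rl$values], ends[rl$values])
  for (k in seq_len(nrow(blobs))) {
    while (blobs[k, 1] > 1 && s[blobs[k, 1] - 1] > base_return) {
      blobs[k, 1] <- blobs[k, 1] - 1L
    }
    while (blobs[k, 2] < n && s[blobs[k, 2] + 1] > base_return) {
      blobs[k, 2] <- blobs[k, 2] + 1L
    }
  }
  # merge overlapping/adjacent extended blobs
  merged <- blobs[1, , drop = FALSE]
  for (k in seq_len(nrow(blobs))[-1]) {
    last <- nrow(merged)
    if (blobs[k, 1] <= merged[last, 2] + 1L) {
      merged[last, 2] <- max(merged[last, 2], blobs[k, 2])
    } else {
      merged <- rbind(merged, blobs[k, ])
    }
  }
  regions <- list()
  for (k in seq_len(nrow(merged))) {
    lo <- merged[k, 1]; hi <- merged[k, 2]
    if (hi - lo + 1L < 3L) { lo <- max(1L, lo - 1L); hi <- min(n, hi + 1L) }
    # split at deep valleys between well-separated apexes
    for (rg in .split_blob(s, lo, hi, thr, level, valley_frac)) {
      regions[[length(regions) + 1L]] <- rg
    }
  }
  regions
}

# split one above-baseline blob at the valleys between genuinely separated
# apexes. Candidate local maxima are accepted in descending height order; a
# candidate only counts as a separate apex when the deepest valley between
# it and its nearest accepted neighbour drops below valley_frac of the
# smaller of the two apex heights (measured above baseline) -- noise
# micro-maxima are absorbed by their taller neighbours.
.split_blob <- function(s, lo, hi, thr, level, valley_frac) {
  idx <- lo:hi
  seg <- s[idx]
  m <- length(seg)
  one <- function() list(peak_region(lo, idx[which.max(seg)], hi))
  if (m < 7) return(one())
  is_max <- c(FALSE, seg[2:(m - 1)] >= seg[1:(m - 2)] &
                seg[2:(m - 1)] > seg[3:m], FALSE) & seg > thr
  cand <- which(is_max)
  if (length(cand) <= 1) return(one())
  cand <- cand[order(-seg[cand])]
  acc <- cand[1]
  for (p in cand[-1]) {
    separated <- TRUE
    for (nb in c(suppressWarnings(max(acc[acc < p])),
                 suppressWarnings(min(acc[acc > p])))) {
      if (!is.finite(nb)) next
      v <- min(seg[min(p, nb):max(p, nb)])
      if (v - level >= valley_frac * (min(seg[p], seg[nb]) - level)) {
        separated <- FALSE
        break
      }
    }
    if (separated) acc <- sort(c(acc, p))
  }
  if (length(acc) <= 1) return(one())
  cuts <- vapply(seq_len(length(acc) - 1L), function(j) {
    between <- acc[j]:acc[j + 1L]
    between[which.min(seg[between])]
  }, integer(1))
  bounds <- c(1L, cuts, m)
  out <- list()
  for (j in seq_len(length(bounds) - 1L)) {
    a <- bounds[j]; b <- bounds[j + 1L]
    if (b - a + 1L < 3L) next
    sub <- a:b
    out[[length(out) + 1L]] <-
      peak_region(idx[a], idx[sub[which.max(seg[sub])]], idx[b])
  }
  if (!length(out)) one() else out
}

#' Select invariant scans within a region
#'
#' Finds the contiguous window of `n_min`--`n_max` scans whose spectra are
#' most mutually constant (smallest mean pairwise cosine distance), subject
#' to every pairwise distance being within `tol`. A window of constant
#' spectra indicates a single dominating component; on the flank of a
#' coelution the window settles where one compound dominates.
#'
#' @param run a `chrom_run`.
#' @param region a `peak_region`.
#' @param n_min,n_max window size bounds (defaults 3 and 5).
#' @param tol maximum allowed pairwise cosine distance (default 0.05).
#' @return Integer vector of scan indices, or `NULL` when no window
#'   satisfies `tol`.
#' @export
select_invariant_scans <- function(run, region, n_min = 3L, n_max = 5L,
                                   tol = 0.05) {
  stopifnot(inherits(region, "peak_region"))
  idx <- region$start_scan:region$end_scan
  m <- run$intensities[idx, , drop = FALSE]
  norms <- sqrt(rowSums(m^2))
  nz <- norms > 0
  # pairwise cosine distance matrix across the region
  d <- matrix(1, nrow = length(idx), ncol = length(idx))
  if (any(nz)) {
    mn <- m[nz, , drop = FALSE] / norms[nz]
    cosm <- tcrossprod(mn)
    cosm[cosm > 1] <- 1
    d[nz, nz] <- 1 - cosm
  }
  diag(d) <- 0
  best <- NULL; best_mean <- Inf; best_n <- 0L
  for (n in seq(min(n_max, length(idx)), n_min)) {
    if (n > length(idx)) next
    for (s in seq_len(length(idx) - n + 1L)) {
      sub <- d[s:(s + n - 1L), s:(s + n - 1L)]
      pw <- sub[upper.tri(sub)]
      if (max(pw) > tol) next
      mp <- mean(pw)
      if (mp < best_mean - 1e-12 ||
          (abs(mp - best_mean) <= 1e-12 && n > best_n)) {
        best_mean <- mp; best <- idx[s:(s + n - 1L)]; best_n <- n
      }
    }
  }
  best
}

#' Average spectrum over selected scans
#'
#' @param run a `chrom_run`.
#' @param scans integer vector of scan indices (at least one).
#' @return A `mass_spectrum`, the per-m/z arithmetic mean.
#' @export
average_spectrum <- function(run, scans) {
  if (!length(scans)) stop("average_spectrum needs at least one scan index")
  v <- colMeans(run$intensities[scans, , drop = FALSE])
  .grid_to_spec(v, run$mz, attr(run, "mz_range"))
}

#' Subtract a component spectrum from a peak region
#'
#' For every scan in the region the component spectrum is scaled so that its
#' intensity at `anchor_ion` equals the scan's intensity there, then
#' subtracted; negative residuals are clipped to zero. Scans outside the
#' region are untouched. Before clipping, mass balance holds exactly:
#' subtracted + residual = original.
#'
#' @param run a `chrom_run`.
#' @param region a `peak_region`.
#' @param component a `mass_spectrum` with nonzero intensity at `anchor_ion`.
#' @param anchor_ion m/z used to scale the component per scan (typically the
#'   component's main ion).
#' @return A list with `residual` (the modified `chrom_run`), `scale`
#'   (per-scan scale factors), `subtracted_tic` (per-scan TIC removed,
#'   pre-clipping), `subtracted_total` (its sum), and `clipped` (total
#'   intensity lost to clipping).
#' @export
subtract_component <- function(run, region, component, anchor_ion) {
  stopifnot(inherits(run, "chrom_run"), inherits(region, "peak_region"),
            inherits(component, "mass_spectrum"))
  comp_anchor <- spectrum_intensity_at(component, anchor_ion)
  if (comp_anchor <= 0) {
    stop("component has no intensity at the anchor ion m/z ", anchor_ion)
  }
  idx <- region$start_scan:region$end_scan
  anchor_col <- match(as.integer(anchor_ion), run$mz)
  comp_vec <- .spec_on_grid(component, run$mz)
  scale <- run$intensities[idx, anchor_col] / comp_anchor
  sub_mat <- outer(scale, comp_vec)
  raw_resid <- run$intensities[idx, , drop = FALSE] - sub_mat
  clipped <- -sum(raw_resid[raw_resid < 0])
  out <- run
  out$intensities[idx, ] <- pmax(raw_resid, 0)
  list(residual = out, scale = scale, subtracted_tic = rowSums(sub_mat),
       subtracted_total = sum(sub_mat), clipped = clipped)
}

#' Is a region's residual signal indistinguishable from background?
#'
#' True when the maximum of the smoothed residual TIC over the region is at
#' or below `baseline_level + 3 * baseline_mad`.
#'
#' @param run a `chrom_run` (typically a residual after subtraction).
#' @param region a `peak_region`.
#' @param noise a `noise_model`.
#' @return Logical scalar.
#' @export
residual_is_background <- function(run, region, noise) {
  idx <- region$start_scan:region$end_scan
  s <- .smooth_tic(tic(run)[idx])
  max(s) <= noise$baseline_level + 3 * noise$baseline_mad
}

#' Deconvolve one peak region by iterative identification and subtraction
#'
#' Each iteration (a) evaluates every library target whose retention time
#' falls inside the region and subtracts the passing ones in descending
#' Q-value order (ties broken by larger integrated main-ion area, then
#' lexical id); then (b) if nothing passed, selects invariant scans on the
#' residual, averages them, attempts a library match for the averaged
#' spectrum and otherwise emits an unknown with a fresh numeric identifier,
#' then subtracts it. Iteration stops when the residual approximates
#' background, when an iteration extracts nothing, or after `max_iter`
#' rounds.
#'
#' Each reported component carries a data-derived spectrum estimate: the
#' average, over the component's qualifying window, of the original signal
#' minus the estimated contributions of every other extracted component.
#'
#' @param run a `chrom_run`.
#' @param region a `peak_region` (from [detect_peaks()]).
#' @param library a `target_library` (may be empty).
#' @param criteria a [match_criteria()].
#' @param noise a `noise_model`.
#' @param match_score_min minimum weighted-cosine score for identifying a
#'   residual spectrum against the library (default 0.80).
#' @param next_unknown_id first numeric id to assign to unknowns
#'   (default 1).
#' @param max_iter iteration cap (default 20).
#' @param invariant_tol tolerance for [select_invariant_scans()].
#' @return A list with `components` (each a list with `target`, `result`,
#'   `abundance` = pre-clipping subtracted total ion counts, `spectrum_est`,
#'   and `origin` = `"target"`, `"library_match"` or `"unknown"`),
#'   `residual` (final residual `chrom_run`), `background_reached` (logical)
#'   and `next_unknown_id`.
#' @export
deconvolve_peak <- function(run, region, library = target_library(),
                            criteria = match_criteria(), noise = NULL,
                            match_score_min = 0.80, next_unknown_id = 1L,
                            max_iter = 20L, invariant_tol = 0.05) {
  stopifnot(inherits(run, "chrom_run"), inherits(region, "peak_region"))
  if (is.null(noise)) noise <- estimate_noise(run)
  t_lo <- run$times[region$start_scan]; t_hi <- run$times[region$end_scan]
  in_region <- Filter(function(e) !is.na(e$rt) && e$rt >= t_lo && e$rt <= t_hi,
                      library$entries)
  residual <- run
  components <- list()
  extracted_ids <- character(0)
  for (iter in seq_len(max_iter)) {
    if (residual_is_background(residual, region, noise)) break
    extracted_this_iter <- FALSE
    # (a) evaluate remaining library targets on the current residual
    remaining <- in_region[!names(in_region) %in% extracted_ids]
    if (length(remaining)) {
      results <- lapply(remaining, function(tg)
        evaluate_target(residual, tg, criteria, noise = noise,
                        scans = region$start_scan:region$end_scan))
      passed <- vapply(results, function(r) isTRUE(r$passed), logical(1))
      if (any(passed)) {
        ord <- order(-vapply(results[passed], `[[`, numeric(1), "q_value"),
                     -vapply(results[passed], `[[`, numeric(1), "abundance"),
                     names(results)[passed])
        for (nm in names(results)[passed][ord]) {
          tg <- remaining[[nm]]
          res <- evaluate_target(residual, tg, criteria, noise = noise,
                                 scans = region$start_scan:region$end_scan)
          if (!isTRUE(res$passed)) next  # earlier subtraction removed it
          sub <- subtract_component(residual, region, tg$ref_spectrum,
                                    tg$main_ion)
          residual <- sub$residual
          components[[length(components) + 1L]] <-
            list(target = tg, result = res,
                 abundance = .component_abundance(sub$scale, tg, noise, run),
                 scale = sub$scale, origin = "target")
          extracted_ids <- c(extracted_ids, nm)
          extracted_this_iter <- TRUE
        }
      }
    }
    if (extracted_this_iter) next
    # (b) invariant-scan path on the residual; relax the constancy
    # tolerance stepwise before falling back to the apex scans
    inv <- NULL
    for (tol in invariant_tol * c(1, 2, 4)) {
      inv <- select_invariant_scans(residual, region, tol = tol)
      if (!is.null(inv)) break
    }
    if (is.null(inv)) {
      # no spectrally constant window (heavy coelution): average the scans
      # at the residual TIC apex and rely on the library match to resolve it
      idx <- region$start_scan:region$end_scan
      apex <- idx[which.max(tic(residual)[idx])]
      inv <- intersect((apex - 2L):(apex + 2L), idx)
      if (length(inv) < 2) break
    }
    avg <- .denoise_spectrum(average_spectrum(residual, inv), residual, noise,
                             n_avg = length(inv))
    if (length(avg$mz) < 3 || max(avg$intensity) <= 0) break
    avg <- .filter_correlated_ions(avg, residual, region)
    if (length(avg$mz) < 3) break
    matches <- match_library(avg, library)
    matches <- matches[!matches$id %in% extracted_ids, , drop = FALSE]
    if (nrow(matches) && matches$score[1] >= match_score_min) {
      # recognized: subtract the clean library spectrum, not the average
      tg <- library$entries[[matches$id[1]]]
      origin <- "library_match"
    } else {
      rt_here <- mean(residual$times[inv])
      tg <- target_compound(id = as.character(next_unknown_id),
                            ref_spectrum = normalize_spectrum(avg),
                            rt = rt_here)
      next_unknown_id <- next_unknown_id + 1L
      origin <- "unknown"
    }
    res <- evaluate_target(residual, tg, criteria, noise = noise,
                           scans = region$start_scan:region$end_scan)
    sub <- subtract_component(residual, region, tg$ref_spectrum, tg$main_ion)
    if (sub$subtracted_total <= 0) break
    residual <- sub$residual
    components[[length(components) + 1L]] <-
      list(target = tg, result = res,
           abundance = .component_abundance(sub$scale, tg, noise, run),
           scale = sub$scale, origin = origin)
    if (origin == "library_match") extracted_ids <- c(extracted_ids, tg$id)
  }
  components <- .refine_components(run, region, components, noise)
  components <- .attach_spectrum_estimates(run, region, components, noise)
  list(components = components, residual = residual,
       background_reached = residual_is_background(residual, region, noise),
       next_unknown_id = next_unknown_id)
}

# internal: drop ions of an averaged spectrum that are consistent with the
# per-cell baseline floor (TIC-level noise model spread across the m/z
# grid); n_avg scans were averaged, so the noise floor shrinks as sqrt(n).
.denoise_spectrum <- function(spec, run, noise, n_avg = 1L) {
  n_mz <- length(run$mz)
  cell_level <- noise$baseline_level / n_mz
  cell_sd <- noise$baseline_mad / sqrt(n_mz)
  floor_i <- cell_level + 2 * cell_sd / sqrt(n_avg)
  keep <- spec$intensity > floor_i
  if (!any(keep)) {
    return(new_spectrum(integer(0), numeric(0), attr(spec, "mz_range")))
  }
  new_spectrum(spec$mz[keep], spec$intensity[keep] - cell_level,
               mz_range = attr(spec, "mz_range"))
}

# internal: baseline-corrected integrated abundance of a subtracted
# component. The per-scan anchor-channel signal (scale x anchor intensity)
# is corrected by the expected per-cell baseline level before rescaling to
# the full spectrum, so small components are not inflated by the noise
# floor under the peak.
.component_abundance <- function(scale, target, noise, run) {
  comp <- target$ref_spectrum
  anchor_int <- spectrum_intensity_at(comp, target$main_ion)
  cell_level <- noise$baseline_level / length(run$mz)
  anchor_signal <- pmax(scale * anchor_int - cell_level, 0)
  sum(anchor_signal) * sum(comp$intensity) / anchor_int
}

# internal: restrict an averaged spectrum to ions that co-elute with its
# base-peak ion. When the averaging window straddles two coeluting
# components, the second component's ions peak several scans away from the
# base-peak ion's apex and their profiles decorrelate; such ions are
# excluded, so the emitted spectrum belongs to the component that owns the
# base peak and the other component survives in the residual for the next
# iteration.
.filter_correlated_ions <- function(spec, run, region, apex_tol = 3L,
                                    cor_min = 0.95) {
  idx <- region$start_scan:region$end_scan
  if (length(idx) < 7 || length(spec$mz) < 4) return(spec)
  cols <- match(spec$mz, run$mz)
  prof <- apply(run$intensities[idx, cols, drop = FALSE], 2, .smooth_tic, n = 5L)
  apexes <- apply(prof, 2, which.max)
  anchor <- which(spec$mz == base_peak(spec))
  r <- suppressWarnings(as.numeric(stats::cor(prof, prof[, anchor])))
  r[is.na(r)] <- 0
  keep <- abs(apexes - apexes[anchor]) <= apex_tol | r >= cor_min
  keep[anchor] <- TRUE
  if (sum(keep) < 3) return(spec)
  new_spectrum(spec$mz[keep], spec$intensity[keep],
               mz_range = attr(spec, "mz_range"))
}

# internal: joint refinement of the per-scan component contributions.
# Sequential anchor-ion subtraction is biased when components share ions;
# with every component spectrum in hand, the baseline-corrected region
# signal is decomposed per scan onto all spectra at once by linear least
# squares (negative profile values clipped to zero), and abundances are
# recomputed from the refined elution profiles.
.refine_components <- function(run, region, components, noise) {
  k <- length(components)
  if (k == 0) return(components)
  idx <- region$start_scan:region$end_scan
  cell_level <- noise$baseline_level / length(run$mz)
  X <- pmax(run$intensities[idx, , drop = FALSE] - cell_level, 0)
  A <- vapply(components, function(cp)
    .spec_on_grid(cp$target$ref_spectrum, run$mz), numeric(length(run$mz)))
  ata <- crossprod(A)
  S <- tryCatch({
    sol <- solve(ata + diag(1e-9 * max(diag(ata)), k), t(A) %*% t(X))
    pmax(t(sol), 0)
  }, error = function(e) NULL)
  if (is.null(S)) return(components)  # degenerate spectra: keep sequential fit
  for (c in seq_len(k)) {
    components[[c]]$scale <- S[, c]
    components[[c]]$abundance <- sum(S[, c]) * sum(A[, c])
  }
  components
}

# internal: per-component cleaned spectrum = original minus the estimated
# contributions of every OTHER component, averaged over the component's
# qualifying window (clipped at zero), with the baseline floor removed.
.attach_spectrum_estimates <- function(run, region, components, noise) {
  if (!length(components)) return(components)
  idx <- region$start_scan:region$end_scan
  contrib <- lapply(components, function(cp) {
    outer(cp$scale, .spec_on_grid(cp$target$ref_spectrum, run$mz))
  })
  for (k in seq_along(components)) {
    other <- Reduce(`+`, contrib[-k],
                    accumulate = FALSE,
                    right = FALSE)
    if (is.null(other)) other <- 0
    cleaned <- pmax(run$intensities[idx, , drop = FALSE] - other, 0)
    res <- components[[k]]$result
    win <- if (!is.null(res$region)) {
      intersect(res$region$start_scan:res$region$end_scan, idx)
    } else idx
    rows <- match(win, idx)
    v <- colMeans(cleaned[rows, , drop = FALSE])
    est <- .grid_to_spec(v, run$mz, attr(run, "mz_range"))
    components[[k]]$spectrum_est <- .denoise_spectrum(est, run, noise,
                                                      n_avg = length(rows))
    components[[k]]$scale <- NULL
  }
  components
}

#' Cross-scan spectral distance matrix (diagnostic)
#'
#' Pairwise cosine distances between the spectra of the scans of a region:
#' the first scan compared with scans 2, 3, ..., n; the second with 3, 4,
#' ..., n; and so on. Exposed as a diagnostic view of scan-to-scan spectral
#' constancy alongside the abundance-weighted SSV statistic.
#'
#' @param run a `chrom_run`.
#' @param region a `peak_region`.
#' @return A symmetric matrix of cosine distances.
#' @export
scan_distance_matrix <- function(run, region) {
  idx <- region$start_scan:region$end_scan
  m <- run$intensities[idx, , drop = FALSE]
  norms <- sqrt(rowSums(m^2))
  d <- matrix(1, length(idx), length(idx),
              dimnames = list(idx, idx))
  nz <- norms > 0
  if (any(nz)) {
    mn <- m[nz, , drop = FALSE] / norms[nz]
    cs <- tcrossprod(mn); cs[cs > 1] <- 1
    d[nz, nz] <- 1 - cs
  }
  diag(d) <- 0
  d
}
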