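# run code under a fixed RNG state without disturbing the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Instrument-like defaults: 12 scans/s over a unit-mass 50--350 m/z grid,
#' an additive constant baseline with Gaussian cell noise clipped at zero.
#'
#' @param duration run length in minutes.
#' @param scan_rate scans per second (default 12).
#' @param mz_range nominal m/z window (default 50--350).
#' @param baseline constant baseline level per (scan, m/z) cell, counts.
#' @param noise_sd standard deviation of the additive Gaussian cell noise.
#' @param seed integer seed; mandatory, every simulation is a pure function
#'   of its seed and configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration, scan_rate = 12, mz_range = c(50L, 350L),
                       baseline = 2, noise_sd = 1, seed) {
  stopifnot(duration > 0, scan_rate > 0, baseline >= 0, noise_sd >= 0)
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(duration = duration, scan_rate = scan_rate,
                 mz_range = as.integer(mz_range), baseline = baseline,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted compound (simulation ground truth)
#'
#' @param truth_id identifier used to link recovered components back to the
#'   ground truth.
#' @param spectrum a `mass_spectrum` (5--25 ions is typical).
#' @param rt apex retention time, minutes.
#' @param sigma Gaussian peak width (standard deviation), minutes.
#' @param total_abundance integrated TIC contribution, counts.
#' @return An object of class `planted_compound`.
#' @export
planted_compound <- function(truth_id, spectrum, rt, sigma, total_abundance) {
  stopifnot(inherits(spectrum, "mass_spectrum"), sigma > 0,
            total_abundance > 0, rt >= 0)
  structure(list(truth_id = as.character(truth_id), spectrum = spectrum,
                 rt = rt, sigma = sigma, total_abundance = total_abundance),
            class = "planted_compound")
}

#' Random unit-mass spectrum
#'
#' `n_ions` distinct m/z values drawn uniformly over the range, intensities
#' from a long-tailed lognormal draw, base peak normalized to 999. A pure
#' function of the seed.
#'
#' @param seed integer seed.
#' @param n_ions number of ions (>= 2).
#' @param mz_range m/z window.
#' @return A `mass_spectrum`.
#' @export
random_spectrum <- function(seed, n_ions, mz_range = c(50L, 350L)) {
  if (n_ions < 2) stop("a spectrum needs at least 2 ions")
  .with_seed(seed, {
    mz <- sample(seq.int(mz_range[1], mz_range[2]), n_ions)
    int <- stats::rlnorm(n_ions, meanlog = 0, sdlog = 1.2)
    normalize_spectrum(new_spectrum(mz, int, mz_range = mz_range))
  })
}

#' Internal-standard target: deuterated naphthalene
#'
#' A synthetic stand-in reference spectrum for perdeuterated naphthalene
#' (naphthalene-d8), the spiked internal standard of the profiling workflow:
#' molecular ion m/z 136 as main ion with minor isotope and fragment ions.
#' The spectrum is constructed, not measured.
#'
#' @param rt retention time to assign, minutes.
#' @return A `target_compound` with id `"d8-naphthalene"`.
#' @export
d8_naphthalene_target <- function(rt = NA_real_) {
  spec <- new_spectrum(c(136, 137, 134, 108, 84, 68),
                       c(999, 110, 95, 130, 60, 45))
  target_compound(id = "d8-naphthalene", name = "naphthalene-d8",
                  cas = "1146-65-2", rt = rt, ref_spectrum = spec,
                  annotations = list(role = "internal_standard",
                                     synthetic_spectrum = TRUE))
}

#' Simulate a chromatographic run with known ground truth
#'
#' Each planted compound contributes a Gaussian elution profile times its
#' (sum-normalized) spectrum, so its integrated TIC contribution equals
#' `total_abundance` up to truncation at the run boundaries. A constant
#' baseline plus seeded Gaussian noise (clipped at zero) is added on top.
#'
#' @param compounds list of [planted_compound()] objects.
#' @param cfg a [sim_config()].
#' @param internal_standard optional `target_compound` (e.g.
#'   [d8_naphthalene_target()]); when given (with a finite `rt`), it is
#'   planted with `is_abundance` total counts.
#' @param is_abundance internal-standard total abundance (default `2e5`).
#' @param sample_id sample identifier for the run.
#' @return A list with `run` (a `chrom_run`) and `truth` (per-compound
#'   per-scan TIC contributions, the noiseless matrix, and the inputs).
#' @export
simulate_run <- function(compounds, cfg, internal_standard = NULL,
                         is_abundance = 2e5, sample_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(internal_standard)) {
    is_spec <- internal_standard$ref_spectrum
    compounds <- c(compounds, list(planted_compound(
      internal_standard$id, is_spec, internal_standard$rt,
      sigma = 0.02, total_abundance = is_abundance)))
  }
  for (cp in compounds) {
    if (cp$rt <= 0 || cp$rt >= cfg$duration) {
      stop("compound '", cp$truth_id, "' rt ", cp$rt,
           " outside the run duration (0, ", cfg$duration, ")")
    }
  }
  n <- round(cfg$duration * 60 * cfg$scan_rate)
  dt <- 1 / (cfg$scan_rate * 60)
  times <- seq_len(n) * dt
  grid <- seq.int(cfg$mz_range[1], cfg$mz_range[2])
  clean <- matrix(0, nrow = n, ncol = length(grid))
  contributions <- matrix(0, nrow = n, ncol = length(compounds))
  for (k in seq_along(compounds)) {
    cp <- compounds[[k]]
    amp <- cp$total_abundance * stats::dnorm(times, cp$rt, cp$sigma) * dt
    frac <- .spec_on_grid(cp$spectrum, grid)
    frac <- frac / sum(frac)
    clean <- clean + outer(amp, frac)
    contributions[, k] <- amp
  }
  noisy <- .with_seed(cfg$seed, {
    pmax(clean + cfg$baseline +
           matrix(stats::rnorm(length(clean), 0, cfg$noise_sd),
                  nrow = n), 0)
  })
  run <- new_chrom_run(times, noisy, mz = grid, scan_rate = cfg$scan_rate,
                       sample_id = sample_id, mz_range = cfg$mz_range,
                       metadata = list(seed = cfg$seed))
  colnames(contributions) <- vapply(compounds, `[[`, character(1), "truth_id")
  list(run = run,
       truth = list(compounds = compounds, contributions = contributions,
                    clean = clean, baseline = cfg$baseline, cfg = cfg))
}

#' Library of targets from planted compounds
#'
#' Convenience: turns the ground-truth compounds of a simulation into a
#' `target_library` (reference spectrum = planted spectrum).
#'
#' @param compounds list of `planted_compound` objects.
#' @return A `target_library`.
#' @export
truth_library <- function(compounds) {
  target_library(lapply(compounds, function(cp)
    target_compound(id = cp$truth_id, ref_spectrum = cp$spectrum,
                    rt = cp$rt)))
}

#' Simulate a heartcut campaign
#'
#' Compounds are assigned to contiguous 1-min half-open first-column windows
#' `[i-1, i)` by their first-column retention time (`rt1`); each compound
#' elutes on the second column at a seeded position within the cut's run. A
#' seeded fraction of compounds also appears in the next adjacent cut at
#' `carryover_fraction` of its abundance, emulating transference of sample
#' components between consecutive cuts.
#'
#' @param compounds list of `planted_compound` objects; each may carry an
#'   `rt1` attribute (first-column retention time in minutes); otherwise
#'   `rt1` values are drawn seeded and uniformly over the campaign span.
#' @param n_cuts number of 1-min heartcut windows (>= 1).
#' @param cfg a [sim_config()] describing each cut's second-column run.
#' @param carryover_fraction relative abundance of the carried-over
#'   occurrence (default 0.1).
#' @param carryover_prob probability that a compound transfers into the next
#'   cut (default 0.1).
#' @return A list with `heartcuts` (list of `heartcut_run`) and `truth`
#'   (assignment data.frame and the per-cut planted compounds).
#' @export
simulate_heartcut_campaign <- function(compounds, n_cuts, cfg,
                                       carryover_fraction = 0.1,
                                       carryover_prob = 0.1) {
  if (n_cuts < 1) stop("n_cuts must be >= 1")
  stopifnot(inherits(cfg, "sim_config"))
  ids <- vapply(compounds, `[[`, character(1), "truth_id")
  draws <- .with_seed(cfg$seed, {
    rt1 <- vapply(compounds, function(cp) {
      a <- attr(cp, "rt1")
      if (is.null(a)) stats::runif(1, 0, n_cuts) else a
    }, numeric(1))
    list(rt1 = rt1,
         rt2 = stats::runif(length(compounds), 0.15 * cfg$duration,
                            0.85 * cfg$duration),
         carry = stats::runif(length(compounds)) < carryover_prob)
  })
  cut_of <- pmin(pmax(floor(draws$rt1), 0), n_cuts - 1) + 1L
  assignment <- data.frame(truth_id = ids, rt1 = draws$rt1, cut = cut_of,
                           rt2 = draws$rt2,
                           carried = draws$carry & cut_of < n_cuts)
  heartcuts <- vector("list", n_cuts)
  per_cut_truth <- vector("list", n_cuts)
  for (ci in seq_len(n_cuts)) {
    members <- which(assignment$cut == ci)
    carried_in <- which(assignment$carried & assignment$cut == ci - 1L)
    planted <- c(
      lapply(members, function(k) {
        cp <- compounds[[k]]
        planted_compound(cp$truth_id, cp$spectrum, assignment$rt2[k],
                         cp$sigma, cp$total_abundance)
      }),
      lapply(carried_in, function(k) {
        cp <- compounds[[k]]
        planted_compound(cp$truth_id, cp$spectrum, assignment$rt2[k],
                         cp$sigma, cp$total_abundance * carryover_fraction)
      }))
    cut_cfg <- cfg
    cut_cfg$seed <- cfg$seed + ci  # per-cut noise stream, still seed-pure
    sim <- simulate_run(planted, cut_cfg,
                        sample_id = sprintf("heartcut_%02d", ci))
    heartcuts[[ci]] <- heartcut_run(c(ci - 1, ci), sim$run)
  per_cut_truth[[ci]] <- planted
  }
  list(heartcuts = heartcuts,
       truth = list(assignment = assignment, per_cut = per_cut_truth))
}
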