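#' Kovats retention index under a temperature program
#'
#' Linear (van den Dool--Kratz) interpolation between the bracketing
#' n-alkanes: `RI = 100 * (n + (rt - rt_n) / (rt_{n+1} - rt_n))` where `n`
#' and `n+1` are the alkane carbon numbers bracketing `rt`. No
#' extrapolation: retention times outside the calibrated alkane span are an
#' error.
#'
#' @param rt retention time(s) in minutes.
#' @param cal an [ri_calibration()].
#' @return Retention index (numeric, vectorized over `rt`).
#' @examples
#' cal <- ri_calibration(7:12, c(2, 4, 6, 8, 10, 12))
#' kovats_ri(8, cal)   # anchor: C10 -> 1000
#' @export
kovats_ri <- function(rt, cal) {
  stopifnot(inherits(cal, "ri_calibration"))
  if (any(rt < cal$rt_min[1] | rt > cal$rt_min[length(cal$rt_min)])) {
    stop(sprintf("retention time outside the alkane calibration span [%.3f, %.3f] min",
                 cal$rt_min[1], cal$rt_min[length(cal$rt_min)]))
  }
  i <- findInterval(rt, cal$rt_min, rightmost.closed = TRUE)
  100 * (cal$carbon[i] +
           (cal$carbon[i + 1] - cal$carbon[i]) *
           (rt - cal$rt_min[i]) / (cal$rt_min[i + 1] - cal$rt_min[i]))
}

#' Match a query spectrum against a target library
#'
#' NIST-style weighted cosine: intensities are weighted by
#' `m/z^1 * intensity^0.5` on the unit-mass grid before the cosine is taken,
#' emphasizing the heavier, more structurally diagnostic fragments. When
#' both the query and a candidate carry retention indices, candidates
#' farther than `ri_window` index units are excluded.
#'
#' @param query a `mass_spectrum` (non-empty).
#' @param library a `target_library`.
#' @param ri optional retention index of the query.
#' @param ri_window retention-index exclusion window (default 30 units).
#' @return A data.frame with columns `id`, `score` (in `[0, 1]`) and
#'   `ri_delta` (`NA` when either RI is unknown), ranked by descending
#'   score, ties broken by smaller `ri_delta` then lexical id.
#' @export
match_library <- function(query, library, ri = NULL, ri_window = 30) {
  stopifnot(inherits(query, "mass_spectrum"))
  if (!length(query$mz)) stop("query spectrum is empty")
  empty <- data.frame(id = character(0), score = numeric(0),
                      ri_delta = numeric(0))
  if (!length(library$entries)) return(empty)
  ids <- names(library$entries)
  ri_lib <- vapply(library$entries,
                   function(e) if (is.null(e$ri)) NA_real_ else e$ri,
                   numeric(1))
  ri_delta <- if (is.null(ri)) rep(NA_real_, length(ids)) else abs(ri - ri_lib)
  keep <- is.na(ri_delta) | ri_delta <= ri_window
  if (!any(keep)) return(empty)
  score <- vapply(library$entries[keep], function(e)
    .weighted_cosine(query, e$ref_spectrum), numeric(1))
  out <- data.frame(id = ids[keep], score = score,
                    ri_delta = ri_delta[keep], row.names = NULL)
  out[order(-out$score, out$ri_delta, out$id), , drop = FALSE]
}

# internal: weighted cosine with w = mz * sqrt(intensity)
.weighted_cosine <- function(a, b) {
  mz <- union(a$mz, b$mz)
  wa <- mz * sqrt(spectrum_intensity_at(a, mz))
  wb <- mz * sqrt(spectrum_intensity_at(b, mz))
  na <- sqrt(sum(wa^2)); nb <- sqrt(sum(wb^2))
  if (na == 0 || nb == 0) return(0)
  min(1, sum(wa * wb) / (na * nb))
}

#' Classify an identification as positive, tentative or unknown
#'
#' Tentative identification requires a library-match score of at least
#' `score_min` and (when known) a retention-index agreement within
#' `ri_window`; a tentative identification backed by an authentic reference
#' standard is positive; anything else remains unknown and receives a
#' numerical identifier downstream.
#'
#' @param match one row of a [match_library()] result (fields `score` and
#'   `ri_delta`), or a list with those fields.
#' @param has_reference_standard logical: is an authentic standard available
#'   for the candidate compound?
#' @param score_min minimum score for a tentative call (default 0.80).
#' @param ri_window maximum `ri_delta` for a tentative call (default 30).
#' @return One of `"positive"`, `"tentative"`, `"unknown"`.
#' @export
classify_identification <- function(match, has_reference_standard = FALSE,
                                    score_min = 0.80, ri_window = 30) {
  score <- match$score[1]
  rid <- match$ri_delta[1]
  tentative <- !is.na(score) && score >= score_min &&
    (is.na(rid) || rid <= ri_window)
  if (tentative && isTRUE(has_reference_standard)) return("positive")
  if (tentative) return("tentative")
  "unknown"
}

#' Construct a heartcut run
#'
#' One timed window of first-column effluent re-chromatographed on the
#' second column.
#'
#' @param window `c(start_min, end_min)` on the first column (1-min wide by
#'   convention).
#' @param run a `chrom_run` acquired on the second column.
#' @return An object of class `heartcut_run`.
#' @export
heartcut_run <- function(window, run) {
  stopifnot(length(window) == 2, window[2] > window[1],
            inherits(run, "chrom_run"))
  structure(list(window = as.numeric(window), run = run),
            class = "heartcut_run")
}

#' Build a cumulative target library from heartcut runs
#'
#' Processes the heartcuts in window order. For each cut, every peak region
#' is deconvolved against the current cumulative library, so components
#' already registered (including those transferred from an adjacent cut by
#' carryover) are recognized first and only residual novelty spawns new
#' entries. A new component is merged into an existing entry (duplicate
#' suppression) when its spectrum cosine is at least `dedup_cosine` and its
#' retention agrees within `dedup_ri` index units (or `dedup_rt` minutes
#' when no calibration is given); the spectrum of the higher-abundance
#' occurrence is kept. Unknown numeric ids are issued monotonically across
#' the whole campaign.
#'
#' @param heartcuts list of `heartcut_run` objects, ordered by window start,
#'   with non-overlapping windows.
#' @param ref_libraries optional `target_library` of reference spectra used
#'   to name new components (tentative identification).
#' @param criteria a [match_criteria()].
#' @param noise optional `noise_model`; estimated per cut when `NULL`.
#' @param start_library optional starting `target_library` (e.g. for
#'   idempotence checks or cross-campaign accumulation).
#' @param cal optional [ri_calibration()] used to stamp retention indices on
#'   new entries.
#' @param dedup_cosine,dedup_ri,dedup_rt duplicate-suppression thresholds
#'   (defaults 0.95, 10 index units, 0.05 min).
#' @param match_score_min score threshold passed to [deconvolve_peak()].
#' @param invariant_tol tolerance for invariant-scan selection.
#' @param min_unknown_frac minimum share of its region's largest component
#'   abundance an unknown must carry to be registered (default 0.05);
#'   smaller residuals are treated as subtraction shards.
#' @return A `target_library` of all distinct components found, entries
#'   annotated with their source heartcut and integrated abundance.
#' @export
build_library <- function(heartcuts, ref_libraries = NULL,
                          criteria = match_criteria(), noise = NULL,
                          start_library = NULL, cal = NULL,
                          dedup_cosine = 0.95, dedup_ri = 10,
                          dedup_rt = 0.05, match_score_min = 0.80,
                          invariant_tol = 0.05, min_unknown_frac = 0.05) {
  stopifnot(all(vapply(heartcuts, inherits, logical(1), "heartcut_run")))
  if (length(heartcuts) > 1) {
    starts <- vapply(heartcuts, function(h) h$window[1], numeric(1))
    ends <- vapply(heartcuts, function(h) h$window[2], numeric(1))
    o <- order(starts)
    heartcuts <- heartcuts[o]; starts <- starts[o]; ends <- ends[o]
    if (any(starts[-1] < ends[-length(ends)])) {
      stop("heartcut windows overlap")
    }
  }
  entries <- if (is.null(start_library)) list() else start_library$entries
  abundances <- vapply(entries, function(e) {
    a <- e$annotations$abundance
    if (is.null(a)) 0 else a
  }, numeric(1))
  next_id <- .next_numeric_id(names(entries))
  for (h in heartcuts) {
    run <- h$run
    nz <- if (is.null(noise)) estimate_noise(run) else noise
    lib_now <- target_library(unname(entries))
    regions <- detect_peaks(run, nz)
    for (rg in regions) {
      dec <- deconvolve_peak(run, rg, lib_now, criteria, nz,
                             match_score_min = match_score_min,
                             next_unknown_id = next_id,
                             invariant_tol = invariant_tol)
      next_id <- dec$next_unknown_id
      max_ab <- if (length(dec$components)) {
        max(vapply(dec$components, `[[`, numeric(1), "abundance"))
      } else 0
      for (cp in dec$components) {
        if (cp$origin %in% c("target", "library_match")) {
          # already registered; keep the higher-abundance occurrence's spectrum
          id <- cp$target$id
          if (!is.null(entries[[id]]) && cp$abundance > abundances[[id]] &&
              !is.null(cp$spectrum_est) && length(cp$spectrum_est$mz) >= 3) {
            e <- entries[[id]]
            entries[[id]] <- target_compound(
              id = e$id, name = e$name, cas = e$cas, rt = e$rt, ri = e$ri,
              ref_spectrum = normalize_spectrum(cp$spectrum_est),
              source_heartcut = h$window,
              annotations = utils::modifyList(e$annotations,
                                              list(abundance = cp$abundance)))
            abundances[[id]] <- cp$abundance
          }
          next
        }
        # residual shards left behind by subtracting much larger
        # components are within the scaling error of those subtractions;
        # an unknown is only registered when it carries a non-negligible
        # share of its region's signal
        if (cp$abundance < min_unknown_frac * max_ab) next
        spec <- cp$target$ref_spectrum
        rt_here <- cp$target$rt
        ri_here <- if (!is.null(cal)) tryCatch(kovats_ri(rt_here, cal),
                                               error = function(e) NULL) else NULL
        dup <- .find_duplicate(entries, spec, rt_here, ri_here,
                               dedup_cosine, dedup_ri, dedup_rt)
        if (!is.null(dup)) {
          if (cp$abundance > abundances[[dup]]) {
            e <- entries[[dup]]
            entries[[dup]] <- target_compound(
              id = e$id, name = e$name, cas = e$cas, rt = rt_here,
              ri = ri_here, ref_spectrum = spec,
              source_heartcut = h$window,
              annotations = utils::modifyList(e$annotations,
                                              list(abundance = cp$abundance)))
            abundances[[dup]] <- cp$abundance
          }
          next
        }
        # name it against the reference libraries when possible
        nm <- NULL
        if (!is.null(ref_libraries) && length(ref_libraries$entries)) {
          mm <- match_library(spec, ref_libraries, ri = ri_here)
          if (nrow(mm) && mm$score[1] >= match_score_min) nm <- mm$id[1]
        }
        id <- if (!is.null(nm) && is.null(entries[[nm]])) nm else cp$target$id
        entries[[id]] <- target_compound(
          id = id, name = nm, rt = rt_here, ri = ri_here,
          ref_spectrum = spec, source_heartcut = h$window,
          annotations = list(abundance = cp$abundance))
        abundances[[id]] <- cp$abundance
      }
    }
  }
  target_library(unname(entries),
                 provenance = list(n_heartcuts = length(heartcuts)))
}

# internal: next free numeric unknown id given existing ids
.next_numeric_id <- function(ids) {
  nums <- suppressWarnings(as.integer(ids))
  if (all(is.na(nums))) 1L else max(nums, na.rm = TRUE) + 1L
}

# internal: id of an existing entry that duplicates (spec, rt/ri), or NULL
.find_duplicate <- function(entries, spec, rt, ri, dedup_cosine, dedup_ri,
                            dedup_rt) {
  for (id in names(entries)) {
    e <- entries[[id]]
    close_ret <- if (!is.null(ri) && !is.null(e$ri)) {
      abs(ri - e$ri) <= dedup_ri
    } else {
      !is.na(e$rt) && abs(rt - e$rt) <= dedup_rt
    }
    if (close_ret && spectrum_cosine(spec, e$ref_spectrum) >= dedup_cosine) {
      return(id)
    }
  }
  NULL
}
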