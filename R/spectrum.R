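#' Construct a unit-mass mass spectrum
#'
#' A spectrum is a sparse map from nominal (integer) m/z to non-negative
#' intensity in arbitrary counts. All subtraction and matching in the package
#' operates on this representation; the instrument premise is a scanning
#' quadrupole acquiring nominal-mass spectra over a fixed scan range.
#'
#' @param mz integer vector of nominal m/z values (distinct).
#' @param intensity numeric vector of non-negative intensities, same length.
#' @param mz_range length-2 numeric, allowed m/z window (default 50--350).
#' @return An object of class `mass_spectrum`: a list with sorted `mz` and
#'   `intensity` vectors.
#' @examples
#' s <- new_spectrum(c(93, 136), c(999, 350))
#' base_peak(s)
#' @export
new_spectrum <- function(mz, intensity, mz_range = c(50L, 350L)) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  mz <- as.integer(round(mz))
  intensity <- as.numeric(intensity)
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  if (any(intensity < 0)) stop("spectrum intensities must be non-negative")
  if (length(mz) && (min(mz) < mz_range[1] || max(mz) > mz_range[2])) {
    stop(sprintf("m/z outside configured scan range [%d, %d]",
                 mz_range[1], mz_range[2]))
  }
  o <- order(mz)
  structure(list(mz = mz[o], intensity = intensity[o]),
            mz_range = as.integer(mz_range), class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum: %d ions", length(x$mz)))
  if (length(x$mz)) {
    cat(sprintf(", base peak m/z %d (%.4g)", base_peak(x), max(x$intensity)))
  }
  cat(">\n")
  invisible(x)
}

#' Base peak of a spectrum
#'
#' @param spec a `mass_spectrum`.
#' @return The m/z of maximum intensity (ties broken by smaller m/z).
#' @export
base_peak <- function(spec) {
  stopifnot(inherits(spec, "mass_spectrum"))
  if (!length(spec$mz)) stop("empty spectrum has no base peak")
  spec$mz[which.max(spec$intensity)]
}

#' Normalize a spectrum to base peak = 999
#'
#' The MSP convention for interchange of unit-mass library spectra. The
#' operation is a pure view: applying it twice gives the same result.
#'
#' @param spec a `mass_spectrum`.
#' @return A `mass_spectrum` with maximum intensity 999.
#' @export
normalize_spectrum <- function(spec) {
  stopifnot(inherits(spec, "mass_spectrum"))
  if (!length(spec$mz) || max(spec$intensity) == 0) return(spec)
  spec$intensity <- spec$intensity / max(spec$intensity) * 999
  spec
}

#' Intensity at given m/z values
#'
#' @param spec a `mass_spectrum`.
#' @param mz integer vector of m/z values to look up.
#' @return Numeric vector of intensities (0 where the ion is absent).
#' @export
spectrum_intensity_at <- function(spec, mz) {
  idx <- match(as.integer(round(mz)), spec$mz)
  out <- spec$intensity[idx]
  out[is.na(idx)] <- 0
  out
}

#' Cosine similarity between two unit-mass spectra
#'
#' Plain (unweighted) cosine on the union m/z support; used for invariant-scan
#' selection and duplicate suppression. See [match_library()] for the
#' mass-weighted score used in library search.
#'
#' @param a,b `mass_spectrum` objects.
#' @return Similarity in `[0, 1]`; 0 if either spectrum is empty or all-zero.
#' @export
spectrum_cosine <- function(a, b) {
  mz <- union(a$mz, b$mz)
  va <- spectrum_intensity_at(a, mz)
  vb <- spectrum_intensity_at(b, mz)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

# internal: spectrum as a dense vector over a given integer m/z grid
.spec_on_grid <- function(spec, grid) {
  v <- numeric(length(grid))
  idx <- match(spec$mz, grid)
  keep <- !is.na(idx)
  v[idx[keep]] <- spec$intensity[keep]
  v
}

# internal: dense grid vector back to a sparse spectrum (drops zeros)
.grid_to_spec <- function(values, grid, mz_range = c(50L, 350L)) {
  keep <- values > 0
  new_spectrum(grid[keep], values[keep], mz_range = mz_range)
}
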