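#' Construct a chromatographic run
#'
#' A `chrom_run` holds a time-ordered sequence of unit-mass scans as a dense
#' scan-by-m/z intensity matrix over a fixed nominal-mass grid. The total ion
#' current is always recomputed from the matrix, never stored.
#'
#' @param times numeric vector of scan times in minutes, strictly increasing.
#' @param intensities numeric matrix, `length(times)` rows by `length(mz)`
#'   columns, non-negative.
#' @param mz integer vector of column m/z values (defaults to the full
#'   50--350 grid when `intensities` has 301 columns).
#' @param scan_rate scans per second (default 12).
#' @param sample_id,column_id free-text identifiers.
#' @param metadata named list of additional metadata.
#' @param mz_range allowed m/z window.
#' @return An object of class `chrom_run`.
#' @export
new_chrom_run <- function(times, intensities, mz = NULL, scan_rate = 12,
                          sample_id = "", column_id = "",
                          metadata = list(), mz_range = c(50L, 350L)) {
  times <- as.numeric(times)
  intensities <- as.matrix(intensities)
  if (is.null(mz)) mz <- seq.int(mz_range[1], mz_range[2])
  mz <- as.integer(mz)
  if (length(times) != nrow(intensities)) {
    stop("times and intensity rows disagree")
  }
  if (length(mz) != ncol(intensities)) stop("mz and intensity columns disagree")
  if (length(times) && any(times < 0)) stop("scan times must be >= 0")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("scan times must be strictly increasing")
  }
  if (length(mz) && (min(mz) < mz_range[1] || max(mz) > mz_range[2])) {
    stop(sprintf("m/z outside configured scan range [%d, %d]",
                 mz_range[1], mz_range[2]))
  }
  if (length(intensities) && any(intensities < 0)) {
    stop("intensities must be non-negative")
  }
  dimnames(intensities) <- NULL
  structure(list(times = times, mz = mz, intensities = intensities,
                 scan_rate = scan_rate, sample_id = sample_id,
                 column_id = column_id, metadata = metadata),
            mz_range = as.integer(mz_range), class = "chrom_run")
}

#' @export
print.chrom_run <- function(x, ...) {
  cat(sprintf("<chrom_run '%s': %d scans, %.3f-%.3f min, m/z %d-%d>\n",
              x$sample_id, n_scans(x),
              if (n_scans(x)) min(x$times) else NA,
              if (n_scans(x)) max(x$times) else NA,
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' Number of scans in a run
#' @param run a `chrom_run`.
#' @export
n_scans <- function(run) length(run$times)

#' Total ion current trace
#'
#' Recomputed per call as the row sums of the intensity matrix, so it can
#' never go stale relative to the scans.
#'
#' @param run a `chrom_run`.
#' @return Numeric vector, one TIC value per scan.
#' @export
tic <- function(run) {
  stopifnot(inherits(run, "chrom_run"))
  if (!n_scans(run)) return(numeric(0))
  rowSums(run$intensities)
}

#' Extract one scan as a spectrum
#'
#' @param run a `chrom_run`.
#' @param i scan index.
#' @return A list with `time` (minutes) and `spectrum` (`mass_spectrum`).
#' @export
run_scan <- function(run, i) {
  stopifnot(i >= 1, i <= n_scans(run))
  list(time = run$times[i],
       spectrum = .grid_to_spec(run$intensities[i, ], run$mz,
                                attr(run, "mz_range")))
}

# internal: scan interval in minutes
.dt_min <- function(run) 1 / (run$scan_rate * 60)

#' Read a chromatographic run
#'
#' Two on-disk forms are supported: a CSV scan matrix whose first column is
#' `time_min` and whose remaining column headers are integer m/z values, and
#' mzML (read through the `mzR` package; profile spectra are binned to the
#' nearest integer m/z).
#'
#' @param path file path.
#' @param format `"csv"` or `"mzml"`; default guessed from the file extension.
#' @param scan_rate scans per second recorded on the returned run; for mzML
#'   input the default is inferred from the median scan spacing.
#' @param mz_range allowed m/z window; values outside it are rejected for CSV
#'   and dropped (with a warning) for mzML.
#' @param ... passed to [new_chrom_run()] (`sample_id`, `column_id`, ...).
#' @return A `chrom_run`.
#' @export
read_run <- function(path, format = c("guess", "csv", "mzml"),
                     scan_rate = NULL, mz_range = c(50L, 350L), ...) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mzml = "mzml",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format = \"csv\" or \"mzml\""))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = .read_run_csv(path, scan_rate, mz_range, ...),
         mzml = .read_run_mzml(path, scan_rate, mz_range, ...))
}

.read_run_csv <- function(path, scan_rate, mz_range, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!ncol(df) || names(df)[1] != "time_min") {
    stop("CSV scan matrix must have 'time_min' as its first column (", path, ")")
  }
  mz_chr <- names(df)[-1]
  mz <- suppressWarnings(as.integer(mz_chr))
  if (anyNA(mz)) {
    stop("non-integer m/z column header(s) in ", path, ": ",
         paste(mz_chr[is.na(mz)], collapse = ", "))
  }
  times <- as.numeric(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  mat[mat < 0] <- 0
  if (is.null(scan_rate)) {
    scan_rate <- if (length(times) > 1) 1 / (stats::median(diff(times)) * 60) else 12
  }
  new_chrom_run(times, mat, mz = mz, scan_rate = scan_rate,
                mz_range = mz_range, ...)
}

.read_run_mzml <- function(path, scan_rate, mz_range, ...) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  times <- hd$retentionTime / 60  # mzR reports seconds
  grid <- seq.int(mz_range[1], mz_range[2])
  mat <- matrix(0, nrow = length(pk), ncol = length(grid))
  dropped <- 0L
  for (i in seq_along(pk)) {
    p <- pk[[i]]
    if (!nrow(p)) next
    m <- as.integer(round(p[, 1]))
    keep <- m >= mz_range[1] & m <= mz_range[2]
    dropped <- dropped + sum(!keep)
    if (any(keep)) {
      idx <- m[keep] - mz_range[1] + 1L
      v <- pmax(p[keep, 2], 0)
      for (k in seq_along(idx)) mat[i, idx[k]] <- mat[i, idx[k]] + v[k]
    }
  }
  if (dropped > 0) {
    warning(sprintf("%d centroid(s) outside m/z [%d, %d] dropped", dropped,
                    mz_range[1], mz_range[2]))
  }
  if (is.null(scan_rate)) {
    scan_rate <- if (length(times) > 1) 1 / (stats::median(diff(times)) * 60) else 12
  }
  new_chrom_run(times, mat, mz = grid, scan_rate = scan_rate,
                mz_range = mz_range, ...)
}

#' Write a chromatographic run
#'
#' Inverse of [read_run()]; `read_run(write_run(run))` reproduces the run to
#' within 1e-6 relative intensity tolerance.
#'
#' @param run a `chrom_run`.
#' @param path output file path.
#' @param format `"csv"` or `"mzml"` (default guessed from the extension).
#' @return Invisibly, `path`.
#' @export
write_run <- function(run, path, format = c("guess", "csv", "mzml")) {
  stopifnot(inherits(run, "chrom_run"))
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mzml = "mzml",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "csv") {
    df <- data.frame(time_min = run$times, check.names = FALSE)
    mat <- as.data.frame(run$intensities)
    names(mat) <- as.character(run$mz)
    utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  } else {
    .write_run_mzml(run, path)
  }
  invisible(path)
}

.write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package")
  }
  n <- n_scans(run)
  if (n == 0) stop("cannot write an mzML file with zero scans; use CSV")
  pk <- vector("list", n)
  bp_mz <- numeric(n); bp_i <- numeric(n); npk <- integer(n)
  lo <- numeric(n); hi <- numeric(n)
  for (i in seq_len(n)) {
    v <- run$intensities[i, ]
    keep <- v > 0
    if (!any(keep)) {  # placeholder centroid so the scan survives round-trip
      pk[[i]] <- cbind(mz = as.numeric(run$mz[1]), intensity = 0)
    } else {
      pk[[i]] <- cbind(mz = as.numeric(run$mz[keep]), intensity = v[keep])
    }
    npk[i] <- nrow(pk[[i]])
    j <- which.max(pk[[i]][, 2])
    bp_mz[i] <- pk[[i]][j, 1]; bp_i[i] <- pk[[i]][j, 2]
    lo[i] <- min(pk[[i]][, 1]); hi[i] <- max(pk[[i]][, 1])
  }
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk, totIonCurrent = tic(run),
    retentionTime = run$times * 60, basePeakMZ = bp_mz,
    basePeakIntensity = bp_i, collisionEnergy = NA_real_,
    ionisationEnergy = 0, lowMZ = lo, highMZ = hi,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = attr(run, "mz_range")[1],
    scanWindowUpperLimit = attr(run, "mz_range")[2])
  mzR::writeMSData(pk, path, header = hdr)
  invisible(path)
}

#' Quick-look TIC plot (debug helper)
#'
#' @param x a `chrom_run`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.chrom_run <- function(x, ...) {
  graphics::plot(x$times, tic(x), type = "l", xlab = "time (min)",
                 ylab = "TIC", main = x$sample_id, ...)
  invisible(x)
}
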