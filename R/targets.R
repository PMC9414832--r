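#' Construct a target compound
#'
#' A target pairs a reference spectrum with the ions used for qualification:
#' the main (100%) ion and 2--5 qualifier ions with their expected relative
#' abundances `Ri` (qualifier intensity divided by main-ion intensity in the
#' reference spectrum). When `qualifiers` is not supplied, the most intense
#' ions after the base peak are taken (see `n_qualifiers`).
#'
#' @param id compound identifier (name or numeric unknown identifier), unique
#'   within a library.
#' @param ref_spectrum a `mass_spectrum`, the stored reference spectrum.
#' @param rt retention time in minutes.
#' @param name,cas optional compound name and CAS registry number.
#' @param ri optional retention index (n-alkane scale).
#' @param main_ion m/z of the quantification ion; defaults to the base peak of
#'   `ref_spectrum` and must be its 100% ion.
#' @param qualifiers optional data.frame with columns `mz` and `ri_expected`;
#'   derived from the reference spectrum when absent.
#' @param n_qualifiers how many qualifier ions to derive when `qualifiers` is
#'   absent (default 3, capped at 5 and at the number of available ions).
#' @param source_heartcut optional `c(start_min, end_min)` of the heartcut the
#'   spectrum was collected from.
#' @param annotations named list (sample type, odor descriptors, ...).
#' @return An object of class `target_compound`.
#' @export
target_compound <- function(id, ref_spectrum, rt, name = NULL, cas = NULL,
                            ri = NULL, main_ion = NULL, qualifiers = NULL,
                            n_qualifiers = 3L, source_heartcut = NULL,
                            annotations = list()) {
  stopifnot(inherits(ref_spectrum, "mass_spectrum"), length(ref_spectrum$mz) >= 3)
  if (is.null(main_ion)) main_ion <- base_peak(ref_spectrum)
  main_ion <- as.integer(main_ion)
  main_int <- spectrum_intensity_at(ref_spectrum, main_ion)
  if (main_int <= 0 || main_int < max(ref_spectrum$intensity)) {
    stop("main_ion must be the 100% (base peak) ion of the reference spectrum")
  }
  if (is.null(qualifiers)) {
    o <- order(ref_spectrum$intensity, decreasing = TRUE)
    cand <- ref_spectrum$mz[o]
    cand <- cand[cand != main_ion]
    n_take <- min(max(n_qualifiers, 2L), 5L, length(cand))
    qmz <- cand[seq_len(n_take)]
    qualifiers <- data.frame(mz = as.integer(qmz),
                             ri_expected = spectrum_intensity_at(ref_spectrum, qmz) / main_int)
  } else {
    qualifiers <- as.data.frame(qualifiers)
    stopifnot(all(c("mz", "ri_expected") %in% names(qualifiers)))
    qualifiers$mz <- as.integer(qualifiers$mz)
  }
  if (nrow(qualifiers) < 2 || nrow(qualifiers) > 5) {
    stop("a target needs 2-5 qualifier ions (main ion plus 2-5 qualifiers)")
  }
  if (any(qualifiers$ri_expected <= 0) || any(qualifiers$ri_expected > 1)) {
    stop("expected relative abundances Ri must lie in (0, 1]")
  }
  structure(list(id = as.character(id), name = name, cas = cas,
                 rt = as.numeric(rt), ri = if (is.null(ri)) NULL else as.numeric(ri),
                 ref_spectrum = ref_spectrum, main_ion = main_ion,
                 qualifiers = qualifiers, source_heartcut = source_heartcut,
                 annotations = annotations),
            class = "target_compound")
}

#' @export
print.target_compound <- function(x, ...) {
  cat(sprintf("<target '%s'%s rt=%.3f min, main ion m/z %d, %d qualifiers>\n",
              x$id, if (!is.null(x$ri)) sprintf(" RI=%.0f", x$ri) else "",
              x$rt, x$main_ion, nrow(x$qualifiers)))
  invisible(x)
}

#' Construct a target library
#'
#' @param entries list of `target_compound` objects with unique ids.
#' @param provenance named list describing where the entries came from.
#' @return An object of class `target_library`; entries are sorted by
#'   retention time.
#' @export
target_library <- function(entries = list(), provenance = list()) {
  ids <- vapply(entries, function(e) e$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate target ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rts <- vapply(entries, function(e) e$rt, numeric(1))
  entries <- entries[order(rts)]
  names(entries) <- vapply(entries, function(e) e$id, character(1))
  structure(list(entries = entries, provenance = provenance),
            class = "target_library")
}

#' @export
print.target_library <- function(x, ...) {
  cat(sprintf("<target_library: %d entries>\n", length(x$entries)))
  invisible(x)
}

#' @export
length.target_library <- function(x) length(x$entries)

#' Read an MSP spectral library
#'
#' Parses the NIST-style MSP text format: records with `Name:`, optional
#' `CAS#:`, optional `RI:`/`RT:` (also recognized inside `Comment:`),
#' `Num Peaks:` and a peak list. Qualifier ions absent from the record are
#' derived from the most intense reference-spectrum ions. Records that cannot
#' be parsed are skipped with a warning; the skip count is attached as
#' attribute `n_skipped`.
#'
#' @param path MSP file path.
#' @param mz_range allowed m/z window; ions outside it are dropped.
#' @return A `target_library`.
#' @export
read_msp <- function(path, mz_range = c(50L, 350L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # split into records at Name: lines
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  entries <- list()
  n_skipped <- 0L
  for (k in seq_along(starts)) {
    lo <- starts[k]
    hi <- if (k < length(starts)) starts[k + 1] - 1L else length(lines)
    rec <- lines[lo:hi]
    ent <- tryCatch(.parse_msp_record(rec, mz_range), error = function(e) e)
    if (inherits(ent, "error")) {
      n_skipped <- n_skipped + 1L
      warning(sprintf("skipping malformed MSP record starting at line %d: %s",
                      lo, conditionMessage(ent)), call. = FALSE)
    } else {
      entries[[length(entries) + 1L]] <- ent
    }
  }
  lib <- target_library(entries, provenance = list(source = path,
                                                   n_skipped = n_skipped))
  attr(lib, "n_skipped") <- n_skipped
  lib
}

.msp_field <- function(rec, field) {
  hit <- grep(paste0("^", field, ":"), rec, ignore.case = TRUE, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub(paste0("^", field, ":"), "", hit[1], ignore.case = TRUE))
}

.parse_msp_record <- function(rec, mz_range) {
  nm <- .msp_field(rec, "Name")
  if (is.null(nm) || !nzchar(nm)) stop("missing Name")
  cas <- .msp_field(rec, "CAS#")
  if (is.null(cas)) cas <- .msp_field(rec, "CAS")
  np_line <- grep("^Num ?Peaks:", rec, ignore.case = TRUE)
  if (!length(np_line)) stop("missing Num Peaks")
  np <- as.integer(trimws(sub("^Num ?Peaks:", "", rec[np_line[1]],
                              ignore.case = TRUE)))
  if (is.na(np) || np < 1) stop("bad Num Peaks")
  num_or_na <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (!length(v)) NA_real_ else v[1]
  }
  ri <- num_or_na(.msp_field(rec, "RI"))
  rt <- num_or_na(.msp_field(rec, "RT"))
  cm <- .msp_field(rec, "Comment")
  if (is.na(ri) && !is.null(cm)) {
    m <- regmatches(cm, regexec("RI[= ]([0-9.]+)", cm))[[1]]
    if (length(m) == 2) ri <- as.numeric(m[2])
  }
  if (is.na(rt) && !is.null(cm)) {
    m <- regmatches(cm, regexec("RT[= ]([0-9.]+)", cm))[[1]]
    if (length(m) == 2) rt <- as.numeric(m[2])
  }
  peak_lines <- rec[(np_line[1] + 1L):length(rec)]
  peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
  toks <- unlist(strsplit(paste(peak_lines, collapse = " "), "[;,[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals) || length(vals) < 2 * np) stop("unparseable peak list")
  vals <- vals[seq_len(2 * np)]
  mz <- vals[seq(1, 2 * np, by = 2)]
  int <- vals[seq(2, 2 * np, by = 2)]
  keep <- mz >= mz_range[1] & mz <= mz_range[2]
  if (sum(keep) < 3) stop("fewer than 3 ions inside the scan range")
  spec <- new_spectrum(mz[keep], int[keep], mz_range = mz_range)
  target_compound(id = nm, name = nm, cas = cas,
                  rt = rt,
                  ri = if (is.na(ri)) NULL else ri,
                  ref_spectrum = spec)
}

#' Write a target library in MSP format
#'
#' @param library a `target_library`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_msp <- function(library, path) {
  stopifnot(inherits(library, "target_library"))
  con <- file(path, "w")
  on.exit(close(con))
  for (e in library$entries) {
    cat(sprintf("Name: %s\n", e$id), file = con)
    if (!is.null(e$cas) && !is.na(e$cas)) cat(sprintf("CAS#: %s\n", e$cas), file = con)
    if (!is.null(e$ri)) cat(sprintf("RI: %g\n", e$ri), file = con)
    if (!is.na(e$rt)) cat(sprintf("RT: %g\n", e$rt), file = con)
    s <- e$ref_spectrum
    cat(sprintf("Num Peaks: %d\n", length(s$mz)), file = con)
    cat(paste(sprintf("%d %g;", s$mz, s$intensity), collapse = " "),
        "\n\n", file = con)
  }
  invisible(path)
}

#' Serialize / restore a target library as JSON
#'
#' Versioned JSON schema carrying ids, names, CAS numbers, retention data,
#' reference spectra, main/qualifier ions and annotations.
#'
#' @param library a `target_library`.
#' @param path output (input) JSON path.
#' @return `write_library_json()` returns `path` invisibly;
#'   `read_library_json()` returns a `target_library`.
#' @export
write_library_json <- function(library, path) {
  stopifnot(inherits(library, "target_library"))
  entries <- lapply(library$entries, function(e) {
    list(id = e$id, name = e$name, cas = e$cas,
         rt = if (is.na(e$rt)) NULL else e$rt, ri = e$ri,
         main_ion = e$main_ion,
         spectrum = list(mz = e$ref_spectrum$mz,
                         intensity = e$ref_spectrum$intensity),
         qualifiers = e$qualifiers,
         source_heartcut = e$source_heartcut,
         annotations = e$annotations)
  })
  obj <- list(schema = "iondecon-target-library", schema_version = 1L,
              provenance = library$provenance, entries = unname(entries))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_library_json
#' @export
read_library_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema) || obj$schema != "iondecon-target-library") {
    stop("not an iondecon target-library JSON file: ", path)
  }
  entries <- lapply(obj$entries, function(e) {
    spec <- new_spectrum(unlist(e$spectrum$mz), unlist(e$spectrum$intensity))
    q <- do.call(rbind, lapply(e$qualifiers, function(r)
      data.frame(mz = r$mz, ri_expected = r$ri_expected)))
    target_compound(id = e$id, name = e$name, cas = e$cas,
                    rt = if (is.null(e$rt)) NA_real_ else e$rt,
                    ri = e$ri, ref_spectrum = spec, main_ion = e$main_ion,
                    qualifiers = q,
                    source_heartcut = if (is.null(e$source_heartcut)) NULL else unlist(e$source_heartcut),
                    annotations = if (is.null(e$annotations)) list() else e$annotations)
  })
  target_library(entries, provenance = if (is.null(obj$provenance)) list() else obj$provenance)
}

#' Retention-index calibration from an n-alkane series
#'
#' @param carbon integer vector of alkane carbon numbers (e.g. 7--30).
#' @param rt_min numeric vector of their retention times in minutes, strictly
#'   increasing with carbon number.
#' @return An object of class `ri_calibration`.
#' @export
ri_calibration <- function(carbon, rt_min) {
  stopifnot(length(carbon) == length(rt_min), length(carbon) >= 2)
  o <- order(carbon)
  carbon <- as.integer(carbon[o]); rt_min <- as.numeric(rt_min[o])
  if (anyDuplicated(carbon)) stop("duplicate carbon numbers")
  if (any(diff(rt_min) <= 0)) {
    stop("alkane retention times must increase strictly with carbon number")
  }
  structure(list(carbon = carbon, rt_min = rt_min), class = "ri_calibration")
}

#' Read an alkane calibration table
#'
#' CSV with columns `carbon` and `rt_min`.
#' @param path CSV path.
#' @return An `ri_calibration`.
#' @export
read_alkane_calibration <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("carbon", "rt_min") %in% names(df)))
  ri_calibration(df$carbon, df$rt_min)
}
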