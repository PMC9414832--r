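#' Profile a set of runs against a growing target library
#'
#' The composite GC/MS profiling workflow: each run is peak-detected and
#' deconvolved against the current library; newly discovered unknowns are
#' appended to the library (annotation growth), so later runs are searched
#' with an enlarged target set; every run is then quantified against the
#' final library, and, when sample roles are supplied, the multi-sample
#' comparison report is produced.
#'
#' @param runs list of `chrom_run` objects (sample ids taken from the runs).
#' @param library starting `target_library`.
#' @param criteria a [match_criteria()].
#' @param internal_standard optional `target_compound` for ratio
#'   quantification (see [quantify()]).
#' @param roles optional named list (`green_high`, `green_low`,
#'   `roast_high`, `roast_low`) mapping roles to run sample ids; when given
#'   and at least two runs are present, a [comparison_report()] is computed.
#' @param scale internal-standard response scale (default `1e6`).
#' @param detect_threshold detection threshold for the comparison layer.
#' @return A list with `table` (an `abundance_table`, compounds x runs),
#'   `library` (the grown `target_library`) and `report` (a comparison
#'   report or `NULL`).
#' @export
run_profile_pipeline <- function(runs, library = target_library(),
                                 criteria = match_criteria(),
                                 internal_standard = NULL, roles = NULL,
                                 scale = 1e6, detect_threshold = 0) {
  stopifnot(all(vapply(runs, inherits, logical(1), "chrom_run")))
  sample_ids <- vapply(runs, `[[`, character(1), "sample_id")
  if (anyDuplicated(sample_ids)) stop("runs must carry distinct sample_ids")
  # pass 1: grow the library with unknowns discovered run by run
  next_id <- .next_numeric_id(names(library$entries))
  for (run in runs) {
    noise <- estimate_noise(run)
    for (rg in detect_peaks(run, noise)) {
      dec <- deconvolve_peak(run, rg, library, criteria, noise,
                             next_unknown_id = next_id)
      next_id <- dec$next_unknown_id
      for (cp in dec$components) {
        if (cp$origin != "unknown") next
        if (length(cp$target$ref_spectrum$mz) < 3) next
        entries <- library$entries
        entries[[cp$target$id]] <- cp$target
        library <- target_library(unname(entries), library$provenance)
      }
    }
  }
  # pass 2: quantify every run against the final library
  cols <- lapply(runs, function(run)
    quantify(run, library, criteria, internal_standard, scale = scale))
  values <- do.call(cbind, cols)
  colnames(values) <- sample_ids
  table <- abundance_table(values)
  report <- NULL
  if (!is.null(roles) && length(runs) >= 2) {
    report <- comparison_report(table, roles, threshold = detect_threshold)
  }
  list(table = table, library = library, report = report)
}
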