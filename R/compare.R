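#' Quantify library targets in a run relative to an internal standard
#'
#' Each detected peak region is deconvolved against the library; a target's
#' abundance is its deconvolved main-ion area over the matched region,
#' divided by the internal standard's main-ion area, times the nominal
#' response scale. Targets failing the identification criterion score 0.
#'
#' @param run a `chrom_run`.
#' @param library a `target_library`.
#' @param criteria a [match_criteria()].
#' @param internal_standard a `target_compound` for the spiked internal
#'   standard (e.g. [d8_naphthalene_target()]); it must pass
#'   [evaluate_target()] in the run. `NULL` skips the ratio (raw main-ion
#'   areas are returned with `scale = 1`).
#' @param noise optional `noise_model`.
#' @param scale nominal internal-standard response scale (default `1e6`).
#' @param rt_window search half-window for the internal standard, minutes.
#' @return A named numeric vector of relative abundances, one per library
#'   entry (0 = not detected).
#' @export
quantify <- function(run, library, criteria = match_criteria(),
                     internal_standard = NULL, noise = NULL, scale = 1e6,
                     rt_window = 0.2) {
  stopifnot(inherits(run, "chrom_run"), inherits(library, "target_library"))
  if (is.null(noise)) noise <- estimate_noise(run)
  is_area <- 1
  if (!is.null(internal_standard)) {
    is_res <- evaluate_target(run, internal_standard, criteria,
                              rt_window = rt_window, noise = noise)
    if (!isTRUE(is_res$passed)) {
      stop("internal standard '", internal_standard$id,
           "' not detected in run '", run$sample_id, "'")
    }
    is_area <- is_res$abundance
  } else {
    scale <- 1
  }
  out <- stats::setNames(numeric(length(library$entries)),
                         names(library$entries))
  regions <- detect_peaks(run, noise)
  for (rg in regions) {
    dec <- deconvolve_peak(run, rg, library, criteria, noise)
    for (cp in dec$components) {
      id <- cp$target$id
      if (!id %in% names(out) || cp$origin == "unknown") next
      # main-ion share of the subtracted component signal
      spec <- cp$target$ref_spectrum
      main_frac <- spectrum_intensity_at(spec, cp$target$main_ion) /
        sum(spec$intensity)
      main_area <- cp$abundance * main_frac * .dt_min(run)
      out[id] <- out[id] + main_area / is_area * scale
    }
  }
  out
}

#' Presence matrix from an abundance table
#'
#' @param table an `abundance_table`.
#' @param threshold detection threshold; a compound is present in a sample
#'   when its value strictly exceeds it (default 0, i.e. any nonzero value).
#' @return A logical matrix with the table's dimnames.
#' @export
detect <- function(table, threshold = 0) {
  stopifnot(inherits(table, "abundance_table"))
  table$values > threshold
}

#' Venn partition of a presence matrix
#'
#' Assigns every compound detected in at least one sample to exactly one
#' region: the subset of samples in which it is present. Region names join
#' the member sample ids with `" & "` in column order.
#'
#' @param presence logical compound-by-sample matrix (>= 2 samples).
#' @return An object of class `venn_partition`: a list with `regions`
#'   (named list of compound-id character vectors) and `samples`.
#' @export
venn_partition <- function(presence) {
  stopifnot(is.matrix(presence), ncol(presence) >= 2)
  detected <- rowSums(presence) > 0
  keys <- apply(presence[detected, , drop = FALSE], 1, function(p)
    paste(colnames(presence)[p], collapse = " & "))
  regions <- split(rownames(presence)[detected], keys)
  structure(list(regions = regions, samples = colnames(presence)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition: %d samples, %d non-empty regions, %d compounds>\n",
              length(x$samples), length(x$regions),
              sum(lengths(x$regions))))
  invisible(x)
}

#' Compounds in the region of exactly the given samples
#'
#' @param partition a `venn_partition`.
#' @param samples character vector of sample ids defining the region.
#' @return Character vector of compound ids (possibly empty).
#' @export
venn_region <- function(partition, samples) {
  ordered <- partition$samples[partition$samples %in% samples]
  if (length(ordered) != length(samples)) stop("unknown sample id(s)")
  key <- paste(ordered, collapse = " & ")
  ids <- partition$regions[[key]]
  if (is.null(ids)) character(0) else ids
}

#' Pairwise commonality count
#'
#' Number of compounds present in both samples: the sum of the sizes of all
#' regions containing both.
#'
#' @param partition a `venn_partition`.
#' @param s1,s2 sample ids.
#' @return Integer count.
#' @export
venn_pair_count <- function(partition, s1, s2) {
  sum(vapply(names(partition$regions), function(key) {
    members <- strsplit(key, " & ", fixed = TRUE)[[1]]
    if (all(c(s1, s2) %in% members)) length(partition$regions[[key]]) else 0L
  }, integer(1)))
}

#' Fold change of one compound between two samples
#'
#' @param table an `abundance_table`.
#' @param compound compound id.
#' @param numerator,denominator sample ids.
#' @return A one-row data.frame with `compound`, `numerator`, `denominator`,
#'   `ratio` (`Inf` when the denominator is 0 and the numerator positive),
#'   `infinite` (logical) and `rounded_fold` (nearest integer, half away
#'   from zero; `NA` when infinite). Both values zero: `NULL` is returned
#'   with a warning (the row is omitted).
#' @export
fold_change <- function(table, compound, numerator, denominator) {
  stopifnot(inherits(table, "abundance_table"))
  if (!compound %in% rownames(table$values)) {
    stop("compound not in table: ", compound)
  }
  num <- table$values[compound, numerator]
  den <- table$values[compound, denominator]
  if (num == 0 && den == 0) {
    warning("compound '", compound, "' undetected in both samples; row omitted")
    return(NULL)
  }
  if (den == 0) {
    return(data.frame(compound = compound, numerator = numerator,
                      denominator = denominator, ratio = Inf,
                      infinite = TRUE, rounded_fold = NA_integer_))
  }
  r <- num / den
  data.frame(compound = compound, numerator = numerator,
             denominator = denominator, ratio = r, infinite = FALSE,
             rounded_fold = .round_half_away(r))
}

# nearest integer, halves away from zero (so 178.5 -> 179, -2.5 -> -3)
.round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Count compounds at or above a fold-change threshold
#'
#' Strict arithmetic on the unrounded ratio: compounds with a positive
#' denominator value and `numerator / denominator >= k`.
#'
#' @param table an `abundance_table`.
#' @param numerator,denominator sample ids.
#' @param k fold threshold (default 2).
#' @param restrict_to optional character vector of compound ids to count
#'   within (default: all compounds).
#' @return Integer count.
#' @export
count_fold_threshold <- function(table, numerator, denominator, k = 2,
                                 restrict_to = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  ids <- rownames(table$values)
  if (!is.null(restrict_to)) ids <- intersect(ids, restrict_to)
  if (!length(ids)) return(0L)
  num <- table$values[ids, numerator]
  den <- table$values[ids, denominator]
  sum(den > 0 & num / den >= k)
}

#' Fold-change list between two samples
#'
#' All compounds detected in either sample, with ratios in the
#' numerator/denominator direction; zero-denominator compounds are flagged
#' infinite (they belong in "unique" listings, not fold lists).
#'
#' @inheritParams count_fold_threshold
#' @param restrict_to optional compound ids.
#' @return A data.frame as in [fold_change()], one row per reportable
#'   compound, sorted by descending ratio.
#' @export
fold_change_list <- function(table, numerator, denominator,
                             restrict_to = NULL) {
  ids <- rownames(table$values)
  if (!is.null(restrict_to)) ids <- intersect(ids, restrict_to)
  rows <- lapply(ids, function(id) {
    if (all(table$values[id, c(numerator, denominator)] == 0)) return(NULL)
    suppressWarnings(fold_change(table, id, numerator, denominator))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(-out$ratio), , drop = FALSE]
}

#' Four-sample comparison report
#'
#' The full comparison layer over a green/roasted pair of sample qualities:
#' Venn partitioning of detected compounds, per-region unique-compound
#' tables, fold-change lists between the two green samples (thresholds 2 and
#' 10) and between the two roasted samples, and the survivor table (the
#' region common to all four samples) with green-to-roast fold changes.
#'
#' @param table an `abundance_table`.
#' @param roles named list mapping `green_high`, `green_low`, `roast_high`,
#'   `roast_low` to sample column names.
#' @param threshold detection threshold (default 0).
#' @param out_dir optional directory; when given, writes `venn.json`,
#'   `unique_<sample>.csv`, `folds_<pair>.csv` and `survivors.csv`.
#' @return A list with `venn` (`venn_partition`), `unique` (named list of
#'   data.frames), `green_folds`, `green_folds_2`, `green_folds_10`,
#'   `roast_folds`, `survivors` (data.frame with both green-to-roast fold
#'   columns) and `counts` (named integer summary).
#' @export
comparison_report <- function(table, roles, threshold = 0, out_dir = NULL) {
  need <- c("green_high", "green_low", "roast_high", "roast_low")
  if (!all(need %in% names(roles))) {
    stop("roles must name all of: ", paste(need, collapse = ", "))
  }
  roles <- lapply(roles, as.character)
  if (!all(unlist(roles) %in% colnames(table$values))) {
    stop("role sample(s) missing from the table: ",
         paste(setdiff(unlist(roles), colnames(table$values)), collapse = ", "))
  }
  pres <- detect(table, threshold)
  vp <- venn_partition(pres)
  uniq <- lapply(stats::setNames(unlist(roles), unlist(roles)), function(s) {
    ids <- venn_region(vp, s)
    data.frame(compound = ids,
               value = table$values[ids, s],
               row.names = NULL)
  })
  survivors_ids <- venn_region(vp, unlist(roles))
  gh <- roles$green_high; gl <- roles$green_low
  rh <- roles$roast_high; rl <- roles$roast_low
  green_folds <- fold_change_list(table, gh, gl)
  roast_folds <- fold_change_list(table, rh, rl)
  finite2 <- function(df, k) df[!df$infinite & df$ratio >= k, , drop = FALSE]
  surv <- data.frame(compound = survivors_ids,
                     green_high = table$values[survivors_ids, gh],
                     green_low = table$values[survivors_ids, gl],
                     roast_high = table$values[survivors_ids, rh],
                     roast_low = table$values[survivors_ids, rl],
                     row.names = NULL)
  surv$fold_roast_high_vs_green_high <- ifelse(surv$green_high > 0,
                                               surv$roast_high / surv$green_high, Inf)
  surv$fold_roast_high_vs_green_low <- ifelse(surv$green_low > 0,
                                              surv$roast_high / surv$green_low, Inf)
  counts <- c(
    n_detected = sum(rowSums(pres) > 0),
    n_unique_green_high = length(venn_region(vp, gh)),
    n_unique_green_low = length(venn_region(vp, gl)),
    n_unique_roast_high = length(venn_region(vp, rh)),
    n_unique_roast_low = length(venn_region(vp, rl)),
    n_survivors = length(survivors_ids),
    n_green_pair_common = venn_pair_count(vp, gh, gl),
    n_survivor_fold2_roast_high_vs_green_high =
      count_fold_threshold(table, rh, gh, 2, survivors_ids),
    n_survivor_fold2_roast_high_vs_green_low =
      count_fold_threshold(table, rh, gl, 2, survivors_ids))
  rep <- list(venn = vp, unique = uniq,
              green_folds = green_folds,
              green_folds_2 = finite2(green_folds, 2),
              green_folds_10 = finite2(green_folds, 10),
              roast_folds = roast_folds,
              survivors = surv, counts = counts, roles = roles)
  if (!is.null(out_dir)) .write_report(rep, table, out_dir)
  rep
}

.write_report <- function(rep, table, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(samples = rep$venn$samples,
         regions = lapply(rep$venn$regions, as.list),
         counts = as.list(rep$counts)),
    file.path(out_dir, "venn.json"), auto_unbox = TRUE, digits = NA)
  for (s in names(rep$unique)) {
    utils::write.csv(rep$unique[[s]],
                     file.path(out_dir, paste0("unique_", gsub("[^A-Za-z0-9]+", "_", s), ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(rep$green_folds, file.path(out_dir, "folds_green.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$roast_folds, file.path(out_dir, "folds_roast.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$survivors, file.path(out_dir, "survivors.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
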