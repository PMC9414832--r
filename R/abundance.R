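#' Construct an abundance table
#'
#' A compound-by-sample matrix of relative abundances (analyte to internal
#' standard response, arbitrary units; 0 means not detected), with optional
#' per-compound annotation columns (retention time, odor descriptors, ...).
#'
#' @param values numeric matrix, compounds in rows (unique rownames), samples
#'   in columns (colnames), all values >= 0.
#' @param annotations optional data.frame with one row per compound.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, annotations = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have compound rownames")
  if (is.null(colnames(values))) stop("values must have sample colnames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate compound ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("abundance values must not be missing")
  if (any(values < 0)) stop("abundance values must be non-negative")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    stopifnot(nrow(annotations) == nrow(values))
    rownames(annotations) <- rownames(values)
  }
  structure(list(values = values, annotations = annotations),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table: %d compounds x %d samples>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Compounds absent from every sample
#'
#' @param table an `abundance_table`.
#' @return Character vector of compound ids with all-zero rows.
#' @export
all_absent_compounds <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  rownames(table$values)[rowSums(table$values) == 0]
}

#' Read / write an abundance table as CSV
#'
#' The first column holds compound ids; columns named in `annotation_cols`
#' are carried as annotations; all remaining columns are sample abundances.
#'
#' @param path CSV file path.
#' @param annotation_cols column names treated as annotations rather than
#'   samples (default `rt_min`, `lit_odor`, `group`).
#' @return An `abundance_table` (for the reader); the writer returns `path`
#'   invisibly.
#' @export
read_abundance_table <- function(path,
                                 annotation_cols = c("rt_min", "lit_odor", "group")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("abundance CSV needs a compound column plus samples")
  compounds <- df[[1]]
  if (anyDuplicated(compounds)) {
    stop("duplicate compound ids in ", path, ": ",
         paste(unique(compounds[duplicated(compounds)]), collapse = ", "))
  }
  rest <- df[, -1, drop = FALSE]
  is_ann <- names(rest) %in% annotation_cols
  samples <- rest[, !is_ann, drop = FALSE]
  vals <- vapply(samples, function(col) {
    v <- suppressWarnings(as.numeric(gsub(",", "", col)))
    if (anyNA(v)) stop("non-numeric abundance value in ", path)
    v
  }, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(compounds, names(samples)))
  if (any(vals < 0)) stop("negative abundance value in ", path)
  ann <- if (any(is_ann)) rest[, is_ann, drop = FALSE] else NULL
  abundance_table(vals, ann)
}

#' @rdname read_abundance_table
#' @param table an `abundance_table` to write.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(compound = rownames(table$values), check.names = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  if (!is.null(table$annotations)) {
    df <- cbind(df, table$annotations)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Packaged green/roasted coffee abundance fixture
#'
#' The relative-abundance table of 227 volatile compounds across four coffee
#' samples (Green AAA, Green AA, Roast AAA, Roast AA): compounds unique to
#' each green sample, compounds unique to each roasted sample, and the 72
#' compounds detected in all four ("survivors" of roasting). Values are
#' analyte:internal-standard response in arbitrary units; annotations carry
#' retention time, literature odor descriptors and the table grouping.
#'
#' @return An `abundance_table` with 227 compounds and 4 samples.
#' @examples
#' tab <- tables_fixture()
#' dim(tab)
#' @export
tables_fixture <- function() {
  path <- system.file("extdata", "coffee_abundance_tables.csv",
                      package = "iondecon", mustWork = TRUE)
  read_abundance_table(path)
}
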