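#' Construct a multilevel mixed-type dataset
#'
#' Bundles an N x p response matrix of ordered variables (continuous, ordinal
#' or binary), a per-row cluster label and an optional cluster-to-cohort map
#' into a validated container used by [mgcgm()] and the synthetic generators.
#' Missing responses are `NA` cells in `values`.
#'
#' @param values numeric matrix or data frame, N rows by p columns; ordinal
#'   and binary variables coded as integers (binary as 0/1).
#' @param types character vector of length p with entries `"continuous"`,
#'   `"ordinal"` or `"binary"`.
#' @param cluster per-row cluster labels (factor, character or integer).
#' @param cohort_of_cluster optional named vector mapping cluster labels to
#'   cohort labels (used by [cohort_contrast()]).
#' @return an object of class `mixed_data` with elements `values` (numeric
#'   matrix), `types`, `cluster` (integer codes 1..m), `cluster_labels`,
#'   `missing` (logical mask) and `cohort_of_cluster`.
#' @export
mixed_data <- function(values, types, cluster, cohort_of_cluster = NULL) {
  if (is.data.frame(values)) values <- data.matrix(values)
  if (!is.matrix(values)) stop("values must be a matrix or data frame")
  storage.mode(values) <- "double"
  p <- ncol(values)
  if (p < 1L) stop("at least one variable is required")
  if (is.null(colnames(values))) colnames(values) <- paste0("V", seq_len(p))
  types <- match.arg(types, c("continuous", "ordinal", "binary"),
                     several.ok = TRUE)
  if (length(types) == 1L) types <- rep(types, p)
  if (length(types) != p) stop("types must have one entry per column")
  names(types) <- colnames(values)
  if (length(cluster) != nrow(values)) stop("cluster must have one label per row")
  cl <- factor(cluster)
  if (nlevels(cl) < 1L) stop("at least one cluster is required")
  for (j in which(types == "binary")) {
    v <- values[, j]
    v <- v[!is.na(v)]
    if (length(v) && !all(v %in% c(0, 1)))
      stop(sprintf("binary column '%s' has values outside {0,1}", colnames(values)[j]))
  }
  if (!is.null(cohort_of_cluster)) {
    cohort_of_cluster <- setNames(as.character(cohort_of_cluster),
                                  names(cohort_of_cluster))
    if (!all(levels(cl) %in% names(cohort_of_cluster)))
      stop("cohort_of_cluster must map every cluster label")
  }
  structure(list(values = values, types = types,
                 cluster = as.integer(cl), cluster_labels = levels(cl),
                 missing = is.na(values),
                 cohort_of_cluster = cohort_of_cluster),
            class = "mixed_data")
}

#' @export
print.mixed_data <- function(x, ...) {
  cat(sprintf("mixed_data: %d rows, %d variables, %d clusters\n",
              nrow(x$values), ncol(x$values), length(x$cluster_labels)))
  tb <- table(factor(x$types, c("continuous", "ordinal", "binary")))
  cat(sprintf("  types: %d continuous, %d ordinal, %d binary\n",
              tb[1], tb[2], tb[3]))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(x$missing),
              100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.mixed_data <- function(x) dim(x$values)

#' Read a mixed-type dataset from CSV plus a metadata sidecar
#'
#' The sidecar (YAML or JSON, by file extension) declares the cluster column,
#' each variable's type, missing-value codes and optional validity ranges;
#' nothing is inferred from the data.  Declared codes (for example `"NA"` or
#' `"do not know"`) and out-of-range values become missing cells.
#'
#' Sidecar fields: `cluster` (column name), `columns` (named list with `type`
#' and optional `range = c(lo, hi)` per variable), optional `missing_codes`
#' (character vector applied to every variable) and optional
#' `cohort_of_cluster` (named map).
#'
#' @param data_path CSV file with a header row.
#' @param meta_path metadata sidecar (`.yaml`/`.yml` or `.json`).
#' @return a [mixed_data] object.
#' @export
read_mixed_data <- function(data_path, meta_path) {
  meta <- .read_meta(meta_path)
  if (is.null(meta$cluster)) stop("metadata must name the cluster column")
  raw <- read.csv(data_path, colClasses = "character", check.names = FALSE)
  if (!meta$cluster %in% names(raw))
    stop(sprintf("cluster column '%s' not found in data", meta$cluster))
  cols <- meta$columns
  if (is.null(cols)) stop("metadata must declare column types")
  miss_codes <- c(meta$missing_codes, "")
  vars <- names(cols)
  missing_vars <- setdiff(vars, names(raw))
  if (length(missing_vars))
    stop(sprintf("declared columns absent from data: %s",
                 paste(missing_vars, collapse = ", ")))
  vals <- matrix(NA_real_, nrow(raw), length(vars),
                 dimnames = list(NULL, vars))
  types <- character(length(vars))
  for (k in seq_along(vars)) {
    nm <- vars[k]
    spec <- cols[[nm]]
    if (is.null(spec$type) ||
        !spec$type %in% c("continuous", "ordinal", "binary"))
      stop(sprintf("unknown or missing type for column '%s'", nm))
    types[k] <- spec$type
    v <- trimws(raw[[nm]])
    v[v %in% trimws(miss_codes)] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad))
      stop(sprintf("column '%s' has non-numeric entries not declared as missing codes", nm))
    if (!is.null(spec$range)) {
      rng <- as.numeric(spec$range)
      num[!is.na(num) & (num < rng[1] | num > rng[2])] <- NA
    }
    if (spec$type == "binary") {
      lev <- unique(num[!is.na(num)])
      if (length(lev) > 2 || !all(lev %in% c(0, 1)))
        stop(sprintf("binary column '%s' has levels other than {0,1}", nm))
    }
    vals[, k] <- num
  }
  mixed_data(vals, types, cluster = raw[[meta$cluster]],
             cohort_of_cluster = .as_named_chr(meta$cohort_of_cluster))
}

#' Write a mixed-type dataset to CSV plus a metadata sidecar
#'
#' Inverse of [read_mixed_data()]: `read_mixed_data()` on the written pair
#' reproduces the values, missing mask, types and cluster assignment exactly.
#'
#' @param data a [mixed_data] object.
#' @param data_path output CSV path.
#' @param meta_path output sidecar path (`.yaml`/`.yml` or `.json`).
#' @param truth optional list (e.g. true precision and random-effect
#'   covariance matrices for a simulated dataset) stored in the sidecar for
#'   benchmarking.
#' @return invisibly, the paths written.
#' @export
write_mixed_data <- function(data, data_path, meta_path, truth = NULL) {
  stopifnot(inherits(data, "mixed_data"))
  df <- as.data.frame(data$values)
  # 17 significant digits so numeric values round-trip exactly
  df[] <- lapply(df, function(x)
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
  df$.cluster <- data$cluster_labels[data$cluster]
  write.csv(df, data_path, row.names = FALSE, na = "", quote = FALSE)
  meta <- list(
    cluster = ".cluster",
    columns = lapply(setNames(nm = colnames(data$values)), function(nm)
      list(type = unname(data$types[nm]))),
    missing_codes = "NA"
  )
  if (!is.null(data$cohort_of_cluster))
    meta$cohort_of_cluster <- as.list(data$cohort_of_cluster)
  if (!is.null(truth)) meta$truth <- lapply(truth, .mat_to_list)
  .write_meta(meta, meta_path)
  invisible(c(data_path, meta_path))
}

.read_meta <- function(path) {
  if (grepl("\\.(yaml|yml)$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("metadata must be .yaml/.yml or .json")
}

.write_meta <- function(meta, path) {
  if (grepl("\\.(yaml|yml)$", path)) yaml::write_yaml(meta, path)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  else stop("metadata must be .yaml/.yml or .json")
}

.mat_to_list <- function(M) if (is.matrix(M)) apply(M, 1, c, simplify = FALSE) else M

.as_named_chr <- function(x) {
  if (is.null(x)) return(NULL)
  setNames(as.character(unlist(x)), names(x))
}
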