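#' AQoL-6D item metadata
#'
#' Builds the metadata table for the 20 AQoL-6D items: item identifiers
#' `Q1`..`Q20`, the six dimensions (independent living, 4 items; social and
#' family relationships, 3; mental health, 4; coping, 3; pain, 3; senses, 3)
#' and the response-category range of each item. Response codes run from
#' `min_code` (1, best) to `max_code` (poorest quality of life on that item).
#'
#' @param n_categories Integer scalar or length-20 vector of response-category
#'   counts per item. The instrument uses variable scales; five categories per
#'   item is the default used throughout the package.
#' @return A `data.frame` with columns `item_id`, `dimension`, `n_categories`,
#'   `min_code`, `max_code`.
#' @examples
#' head(aqol_metadata())
#' @export
aqol_metadata <- function(n_categories = 5L) {
  dims <- c(
    independent_living = 4L, relationships = 3L, mental_health = 4L,
    coping = 3L, pain = 3L, senses = 3L
  )
  n_items <- sum(dims)
  n_categories <- as.integer(n_categories)
  if (length(n_categories) == 1L) n_categories <- rep(n_categories, n_items)
  if (length(n_categories) != n_items || any(n_categories < 2L)) {
    stop("'n_categories' must be a scalar or length-20 vector of counts >= 2")
  }
  data.frame(
    item_id = paste0("Q", seq_len(n_items)),
    dimension = rep(names(dims), dims),
    n_categories = n_categories,
    min_code = 1L,
    max_code = n_categories,
    stringsAsFactors = FALSE
  )
}

#' Validate a raw person-by-item response table
#'
#' Checks a raw table of ordinal questionnaire responses against item
#' metadata, builds the missingness mask and returns an item-response matrix
#' object. Empty/`NA` cells are masked as missing; values outside an item's
#' `[min_code, max_code]` range raise an error naming the offending row and
#' item, and unknown or absent item columns raise a schema error.
#'
#' @param raw A `data.frame` or matrix whose columns include all `item_id`s in
#'   `metadata`. Extra columns are an error.
#' @param metadata Item metadata, as from [aqol_metadata()].
#' @return An object of class `item_matrix`: a list with `values` (integer
#'   matrix, `NA` = missing) and `metadata`.
#' @examples
#' md <- aqol_metadata()
#' raw <- as.data.frame(matrix(1L, nrow = 2, ncol = 20,
#'                             dimnames = list(NULL, md$item_id)))
#' items <- validate_responses(raw, md)
#' @export
validate_responses <- function(raw, metadata = aqol_metadata()) {
  raw <- as.data.frame(raw)
  missing_cols <- setdiff(metadata$item_id, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing item columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), metadata$item_id)
  if (length(extra)) {
    stop("schema error: unknown item columns: ", paste(extra, collapse = ", "))
  }
  raw <- raw[, metadata$item_id, drop = FALSE]
  values <- vapply(raw, function(col) {
    if (is.character(col)) col[!nzchar(trimws(col))] <- NA
    suppressWarnings(as.integer(col))
  }, integer(nrow(raw)))
  values <- matrix(values, nrow = nrow(raw),
                   dimnames = list(NULL, metadata$item_id))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    bad <- which(!is.na(v) & (v < metadata$min_code[j] | v > metadata$max_code[j]))
    if (length(bad)) {
      stop(sprintf(
        "range error: item %s row %d has value %d outside [%d, %d]",
        metadata$item_id[j], bad[1], v[bad[1]],
        metadata$min_code[j], metadata$max_code[j]
      ))
    }
  }
  new_item_matrix(values, metadata)
}

new_item_matrix <- function(values, metadata) {
  storage.mode(values) <- "integer"
  colnames(values) <- metadata$item_id
  structure(list(values = values, metadata = metadata), class = "item_matrix")
}

#' @export
print.item_matrix <- function(x, ...) {
  n_inc <- sum(!stats::complete.cases(x$values))
  cat(sprintf(
    "<item_matrix> %d persons x %d items (%d rows with missing items)\n",
    nrow(x$values), ncol(x$values), n_inc
  ))
  invisible(x)
}

#' @export
dim.item_matrix <- function(x) dim(x$values)

#' Restrict an item-response matrix to complete cases
#'
#' Removes every row with at least one missing item, mirroring the analysis
#' cohort definition in which only persons with complete AQoL-6D responses are
#' scored and modelled. The identities of the dropped rows are attached as the
#' `"dropped"` attribute.
#'
#' @param items An `item_matrix`.
#' @return An `item_matrix` of the complete rows; `attr(, "dropped")` holds
#'   the integer indices of removed rows. Dropping every row is an error.
#' @export
complete_case_filter <- function(items) {
  stopifnot(inherits(items, "item_matrix"))
  keep <- stats::complete.cases(items$values)
  if (!any(keep)) stop("empty-data error: all rows have missing items")
  out <- new_item_matrix(items$values[keep, , drop = FALSE], items$metadata)
  attr(out, "dropped") <- which(!keep)
  out
}

# Internal: complete integer matrix or error (used by LCA and descriptives).
complete_values <- function(items, context = "this operation") {
  if (anyNA(items$values)) {
    stop(sprintf(
      "%s requires complete cases; apply complete_case_filter() first", context
    ))
  }
  items$values
}
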