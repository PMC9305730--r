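#' Standardised dimension score
#'
#' Computes, for every person, the reverse min-max scaled unweighted total of
#' one AQoL-6D dimension: `100 * (max_total - total) / (max_total - min_total)`
#' where `min_total`/`max_total` are the sums of the dimension items'
#' `min_code`/`max_code`. 100 is the best health state on the dimension
#' (every item at its minimum code) and 0 the worst. The theoretical scale
#' anchors, not the observed minima/maxima, define the scaling.
#'
#' @param items An `item_matrix`.
#' @param dimension Dimension name, e.g. `"pain"`.
#' @return Numeric vector in `[0, 100]`; `NA` for persons missing any item of
#'   the dimension (dimension scores are not pro-rated).
#' @export
standardise_dimension <- function(items, dimension) {
  stopifnot(inherits(items, "item_matrix"))
  md <- items$metadata
  sel <- md$dimension == dimension
  if (!any(sel)) stop("unknown dimension: ", dimension)
  vals <- items$values[, md$item_id[sel], drop = FALSE]
  total <- rowSums(vals)                       # NA when any item missing
  min_total <- sum(md$min_code[sel])
  max_total <- sum(md$max_code[sel])
  100 * (max_total - total) / (max_total - min_total)
}

#' Dimension scores and utility for a cohort
#'
#' Computes the unweighted total and standardised score per dimension, plus
#' (when a utility specification is supplied) the 0-1 utility index.
#'
#' @param items An `item_matrix`.
#' @param utility_spec Optional utility specification (see [compute_utility()]).
#' @return A `data.frame` with columns `total_<dimension>`,
#'   `std_<dimension>` and, if requested, `utility`; one row per person.
#' @export
dimension_scores <- function(items, utility_spec = NULL) {
  stopifnot(inherits(items, "item_matrix"))
  md <- items$metadata
  dims <- unique(md$dimension)
  out <- data.frame(row.names = seq_len(nrow(items$values)))
  for (d in dims) {
    sel <- md$dimension == d
    out[[paste0("total_", d)]] <-
      rowSums(items$values[, md$item_id[sel], drop = FALSE])
    out[[paste0("std_", d)]] <- standardise_dimension(items, d)
  }
  if (!is.null(utility_spec)) {
    out$utility <- compute_utility(items, utility_spec)
  }
  out
}

#' Cronbach's alpha for one dimension
#'
#' Internal consistency of a dimension's items,
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`,
#' computed on rows with complete responses for that dimension (listwise).
#'
#' @param items An `item_matrix`.
#' @param dimension Dimension name.
#' @return Numeric scalar.
#' @export
cronbach_alpha <- function(items, dimension) {
  stopifnot(inherits(items, "item_matrix"))
  md <- items$metadata
  sel <- md$dimension == dimension
  if (!any(sel)) stop("unknown dimension: ", dimension)
  k <- sum(sel)
  if (k < 2) stop("cronbach_alpha needs at least two items in the dimension")
  vals <- items$values[, md$item_id[sel], drop = FALSE]
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 2) stop("cronbach_alpha needs at least two complete rows")
  total_var <- stats::var(rowSums(vals))
  if (total_var <= 0) stop("undefined alpha: total score has zero variance")
  item_var <- sum(apply(vals, 2, stats::var))
  (k / (k - 1)) * (1 - item_var / total_var)
}
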