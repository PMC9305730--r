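#' Utility specifications
#'
#' A utility specification maps a complete AQoL-6D response pattern to a
#' single preference-weighted index on a 0 (worst health state) to 1 (best
#' health state) scale. The instrument's adolescent weighting algorithm is
#' proprietary, so the package treats the utility function as pluggable: any
#' spec satisfying the endpoint invariants (all items at `min_code` -> 1, all
#' at `max_code` -> 0, each to 1e-9) can be supplied, and a calibrated
#' surrogate with dimension-level weights ships with the package.
#'
#' The packaged surrogate is a multiplicative-disvalue model. Writing
#' `D_d = 1 - S_d/100` for the disvalue of dimension `d` (with `S_d` the
#' standardised dimension score), the raw index `prod_d (1 - w_d * D_d)` is
#' rescaled linearly so the best and worst health states map exactly to 1 and
#' 0: `u = (prod_d (1 - w_d * D_d) - u0) / (1 - u0)` with
#' `u0 = prod_d (1 - w_d)`. Utility is monotone non-increasing in every item
#' code because each factor is decreasing in each item's disvalue.
#'
#' @param name Identifier for the spec.
#' @param weights Named numeric vector of dimension weights in `(0, 1]`, one
#'   per AQoL-6D dimension.
#' @return An object of class `utility_spec`.
#' @seealso [compute_utility()], [load_utility_spec()]
#' @export
utility_spec <- function(name, weights) {
  dims <- c("independent_living", "relationships", "mental_health",
            "coping", "pain", "senses")
  if (!all(dims %in% names(weights))) {
    stop("utility spec validation error: weights must name all six dimensions")
  }
  weights <- unlist(weights)[dims]
  if (any(!is.finite(weights)) || any(weights <= 0) || any(weights > 1)) {
    stop("utility spec validation error: weights must lie in (0, 1]")
  }
  structure(list(name = as.character(name), weights = weights,
                 rule = "multiplicative"),
            class = "utility_spec")
}

#' Read a utility specification from YAML/JSON
#'
#' @param path File with fields `name` and `weights` (named by dimension).
#' @return A validated `utility_spec`.
#' @export
load_utility_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$weights)) {
    stop("utility spec validation error: file must define 'name' and 'weights'")
  }
  utility_spec(cfg$name, cfg$weights)
}

#' The packaged surrogate utility specification
#'
#' Dimension weights calibrated jointly with the packaged cohort profile (see
#' [aqol_reference_profile()]); the calibration script ships under `scripts/`.
#'
#' @return A `utility_spec`.
#' @export
aqol_surrogate_utility <- function() {
  load_utility_spec(system.file("extdata", "aqol_surrogate_utility.yaml",
                                package = "qolclasses", mustWork = TRUE))
}

#' Compute per-person utility scores
#'
#' Applies a utility specification to an item-response matrix. Endpoint
#' invariants of the spec are re-checked against the item metadata before
#' scoring (a spec violating them is rejected).
#'
#' @param items An `item_matrix`.
#' @param spec A `utility_spec`.
#' @return Numeric vector in `[0, 1]`; `NA` for persons with any missing item.
#' @export
compute_utility <- function(items, spec) {
  stopifnot(inherits(items, "item_matrix"), inherits(spec, "utility_spec"))
  md <- items$metadata
  dims <- names(spec$weights)
  u0 <- prod(1 - spec$weights)
  if (!is.finite(u0) || u0 >= 1) {
    stop("utility spec validation error: degenerate weights")
  }
  # endpoint invariant: best health state -> 1, worst -> 0 (tolerance 1e-9)
  best <- eval_utility_rule(spec, setNames(rep(100, length(dims)), dims))
  worst <- eval_utility_rule(spec, setNames(rep(0, length(dims)), dims))
  if (abs(best - 1) > 1e-9 || abs(worst) > 1e-9) {
    stop("utility spec validation error: endpoint invariant violated")
  }
  s_mat <- vapply(dims, function(d) standardise_dimension(items, d),
                  numeric(nrow(items$values)))
  s_mat <- matrix(s_mat, nrow = nrow(items$values),
                  dimnames = list(NULL, dims))
  apply(s_mat, 1, function(s) eval_utility_rule(spec, s))
}

# Direct evaluation of a spec's combination rule on one vector of
# standardised dimension scores (named, 0-100 scale).
eval_utility_rule <- function(spec, s) {
  w <- spec$weights
  u0 <- prod(1 - w)
  raw <- prod(1 - w * (1 - s[names(w)] / 100))
  unname((raw - u0) / (1 - u0))
}
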