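#' Thresholds for an ordinal variable
#'
#' First step of two-step polychoric estimation: thresholds are standard
#' normal quantiles of the cumulative category proportions of the observed
#' margin. A category with zero observed margin collapses two adjacent
#' thresholds (allowed); a variable with a single observed category is
#' degenerate and raises an error.
#'
#' @param x Integer vector of ordinal codes (1-based).
#' @param n_categories Number of categories; defaults to `max(x)`.
#' @return Numeric vector of `n_categories - 1` thresholds.
#' @export
estimate_thresholds <- function(x, n_categories = max(x, na.rm = TRUE)) {
  x <- x[!is.na(x)]
  tab <- tabulate(x, nbins = n_categories)
  if (sum(tab > 0) < 2) {
    stop("degenerate-variable error: fewer than two observed categories")
  }
  cum <- cumsum(tab) / sum(tab)
  stats::qnorm(cum[-n_categories])
}

# Gauss-Legendre nodes/weights on [0, 1] via Golub-Welsch; cached.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre_01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- (rev(e$values) + 1) / 2
  weights <- rev(2 * e$vectors[1, ]^2) / 2
  res <- list(nodes = nodes, weights = weights)
  .gl_cache[[key]] <- res
  res
}

#' Standard bivariate normal CDF
#'
#' `P(X <= h, Y <= k)` for standard normal `X`, `Y` with correlation `rho`,
#' computed from the tetrachoric integral representation
#' `Phi2(h, k, rho) = Phi(h) Phi(k) +
#'   (1/2pi) int_0^{asin(rho)} exp(-(h^2 + k^2 - 2 h k sin t)/(2 cos^2 t)) dt`
#' by 64-point Gauss-Legendre quadrature. The sine substitution keeps the
#' integrand smooth even as `|rho| -> 1`; absolute accuracy is well inside
#' 1e-7 over `|rho| <= 0.999`. Vectorised over `h` and `k`; infinite limits
#' are handled exactly.
#'
#' @param h,k Numeric vectors of upper limits (recycled to common length).
#' @param rho Scalar correlation in `(-1, 1)`.
#' @return Numeric vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1, abs(rho) < 1)
  nn <- max(length(h), length(k))
  h <- rep_len(h, nn)
  k <- rep_len(k, nn)
  out <- numeric(nn)
  lo <- h == -Inf | k == -Inf
  out[lo] <- 0
  hi_h <- !lo & h == Inf
  out[hi_h] <- stats::pnorm(k[hi_h])
  hi_k <- !lo & !hi_h & k == Inf
  out[hi_k] <- stats::pnorm(h[hi_k])
  fin <- !(lo | hi_h | hi_k)
  if (any(fin)) {
    hf <- h[fin]; kf <- k[fin]
    base <- stats::pnorm(hf) * stats::pnorm(kf)
    if (rho == 0) {
      out[fin] <- base
    } else {
      gl <- gauss_legendre_01(64)
      theta <- asin(rho) * gl$nodes             # integrate over [0, asin(rho)]
      ct2 <- cos(theta)^2
      st <- sin(theta)
      acc <- 0
      for (q in seq_along(theta)) {
        acc <- acc + gl$weights[q] *
          exp(-(hf^2 + kf^2 - 2 * hf * kf * st[q]) / (2 * ct2[q]))
      }
      out[fin] <- base + asin(rho) / (2 * pi) * acc
    }
  }
  pmin(pmax(out, 0), 1)
}

# Cell probabilities of a discretised bivariate normal given threshold
# vectors (without the +/-Inf padding) and correlation rho.
bvn_cell_probs <- function(ta, tb, rho) {
  a <- c(-Inf, ta, Inf)
  b <- c(-Inf, tb, Inf)
  grid <- pbvnorm(rep(a, times = length(b)), rep(b, each = length(a)), rho)
  grid <- matrix(grid, nrow = length(a))
  nr <- length(a) - 1
  nc <- length(b) - 1
  grid[-1, -1, drop = FALSE] - grid[-(nr + 1), -1, drop = FALSE] -
    grid[-1, -(nc + 1), drop = FALSE] + grid[-(nr + 1), -(nc + 1), drop = FALSE]
}

#' Polychoric correlation of a pair of ordinal variables
#'
#' Two-step estimator: thresholds are fixed from the univariate margins
#' ([estimate_thresholds()]), then the latent correlation maximises the
#' bivariate-normal contingency-table likelihood over `rho` in
#' `(-0.999, 0.999)` by one-dimensional golden-section/parabolic search.
#'
#' @param x,y Integer vectors of ordinal codes; pairwise complete
#'   observations are used.
#' @param n_cat_x,n_cat_y Category counts (default: observed maxima).
#' @return List with `rho`, `thresholds` (list of two vectors) and `loglik`,
#'   of class `polychoric_pair`.
#' @export
polychoric_pair <- function(x, y,
                            n_cat_x = max(x, na.rm = TRUE),
                            n_cat_y = max(y, na.rm = TRUE)) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  ta <- estimate_thresholds(x, n_cat_x)
  tb <- estimate_thresholds(y, n_cat_y)
  counts <- table(factor(x, levels = seq_len(n_cat_x)),
                  factor(y, levels = seq_len(n_cat_y)))
  counts <- matrix(as.numeric(counts), n_cat_x, n_cat_y)
  nll <- function(rho) {
    p <- bvn_cell_probs(ta, tb, rho)
    -sum(counts * log(pmax(p, 1e-12)))
  }
  opt <- tryCatch(
    stats::optimise(nll, interval = c(-0.999, 0.999), tol = 1e-6),
    error = function(e) stop("estimation error in polychoric_pair: ",
                             conditionMessage(e), call. = FALSE)
  )
  rho <- min(max(opt$minimum, -0.999), 0.999)
  structure(list(rho = rho, thresholds = list(ta, tb), loglik = -opt$objective),
            class = "polychoric_pair")
}

#' Polychoric correlation matrix of an item-response matrix
#'
#' Estimates the latent inter-item correlation matrix by applying
#' [polychoric_pair()] to every item pair; the result is symmetric with unit
#' diagonal by construction. Requires complete cases.
#'
#' @param items An `item_matrix` without missing values.
#' @return Object of class `polychoric_matrix`: list with `r_pc` (JxJ matrix)
#'   and `thresholds` (per item).
#' @export
polychoric_matrix <- function(items) {
  x <- complete_values(items, "polychoric_matrix")
  md <- items$metadata
  j <- ncol(x)
  r <- diag(1, j)
  dimnames(r) <- list(md$item_id, md$item_id)
  thresholds <- lapply(seq_len(j), function(jj) {
    estimate_thresholds(x[, jj], md$n_categories[jj])
  })
  names(thresholds) <- md$item_id
  for (a in seq_len(j - 1)) {
    for (b in seq((a + 1), j)) {
      est <- tryCatch(
        polychoric_pair(x[, a], x[, b], md$n_categories[a], md$n_categories[b]),
        error = function(e) {
          stop(sprintf("polychoric estimation failed for items %s/%s: %s",
                       md$item_id[a], md$item_id[b], conditionMessage(e)),
               call. = FALSE)
        }
      )
      r[a, b] <- r[b, a] <- est$rho
    }
  }
  structure(list(r_pc = r, thresholds = thresholds),
            class = "polychoric_matrix")
}

#' @export
print.polychoric_matrix <- function(x, ...) {
  off <- x$r_pc[upper.tri(x$r_pc)]
  cat(sprintf("<polychoric_matrix> %d items; off-diagonal range [%.2f, %.2f]\n",
              nrow(x$r_pc), min(off), max(off)))
  invisible(x)
}
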