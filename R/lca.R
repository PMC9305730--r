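#' Construct and validate latent class parameters
#'
#' The multinomial latent class model assumes each person belongs to one of
#' `K` unobserved classes with prevalences `pi`, and that item responses are
#' independent given class, each item following a class-specific multinomial
#' distribution over its categories (`item_probs`).
#'
#' @param prevalences Probability vector of length `K` (sums to 1, tol 1e-10).
#' @param item_probs List of `J` matrices, each `K x C_j` with rows summing
#'   to 1 (tol 1e-10).
#' @return Object of class `lca_parameters`.
#' @export
lca_parameters <- function(prevalences, item_probs) {
  prevalences <- as.numeric(prevalences)
  k <- length(prevalences)
  if (any(prevalences < 0) || abs(sum(prevalences) - 1) > 1e-10) {
    stop("prevalences must be a probability vector summing to 1")
  }
  item_probs <- lapply(item_probs, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != k || any(m < 0) || any(abs(rowSums(m) - 1) > 1e-10)) {
      stop("each item_probs matrix must be K x C with probability rows")
    }
    m
  })
  structure(list(K = k, prevalences = prevalences, item_probs = item_probs),
            class = "lca_parameters")
}

# K x N matrix of per-class complete-data log-densities log pi_k + sum_j log rho.
lca_class_logdens <- function(x, params) {
  k <- params$K
  n <- nrow(x)
  a <- matrix(log(params$prevalences), k, n)
  for (j in seq_len(ncol(x))) {
    lp <- log(params$item_probs[[j]])
    a <- a + lp[, x[, j], drop = FALSE]
  }
  a
}

#' Log-likelihood of the multinomial latent class model
#'
#' `sum_i log sum_k pi_k prod_j rho_{k, j, x_ij}`, computed in log space.
#' A zero class-conditional probability at an observed cell yields `-Inf`
#' with a structured warning identifying the first offending
#' (class, item, category) triple.
#'
#' @param items An `item_matrix` without missing values (or an integer
#'   matrix of 1-based codes).
#' @param params An `lca_parameters`.
#' @return Numeric scalar.
#' @export
loglikelihood <- function(items, params) {
  x <- if (inherits(items, "item_matrix")) {
    complete_values(items, "loglikelihood")
  } else {
    items
  }
  stopifnot(inherits(params, "lca_parameters"))
  for (j in seq_along(params$item_probs)) {
    zero <- params$item_probs[[j]][, sort(unique(x[, j])), drop = FALSE] == 0
    if (any(zero)) {
      idx <- which(zero, arr.ind = TRUE)[1, ]
      warning(sprintf(
        "zero-probability observed cell at class %d, item %d, category %d",
        idx[1], j, sort(unique(x[, j]))[idx[2]]
      ))
    }
  }
  a <- lca_class_logdens(x, params)
  sum(col_log_sum_exp(a))
}

#' One EM step for the latent class model
#'
#' E-step: responsibilities `gamma_{ik}` proportional to
#' `pi_k prod_j rho_{k,j,x_ij}`, row-normalised. M-step: `pi_k` is the mean
#' responsibility, `rho_{k,j,c}` the responsibility-weighted category
#' frequency. A smoothing floor (default 1e-6) is applied to the updated
#' item-category probabilities with renormalisation, preventing degenerate
#' zero cells; classes whose total responsibility falls below 1e-8 trigger a
#' class-collapse warning.
#'
#' @param items An `item_matrix` (complete) or integer matrix.
#' @param params Current `lca_parameters`.
#' @param floor Smoothing floor for item-category probabilities.
#' @return List with updated `params`, `posteriors` (N x K) and `loglik`
#'   (the log-likelihood of the *input* parameters).
#' @export
em_step <- function(items, params, floor = 1e-6) {
  x <- if (inherits(items, "item_matrix")) {
    complete_values(items, "em_step")
  } else {
    items
  }
  a <- lca_class_logdens(x, params)
  lse <- col_log_sum_exp(a)
  gamma <- t(exp(sweep(a, 2, lse, "-")))       # N x K
  gsum <- colSums(gamma)
  if (any(gsum < 1e-8)) {
    warning(sprintf("class collapse: class %s has vanishing responsibility",
                    paste(which(gsum < 1e-8), collapse = ", ")))
  }
  new_pi <- gsum / nrow(x)
  new_rho <- lapply(seq_len(ncol(x)), function(j) {
    cj <- ncol(params$item_probs[[j]])
    ind <- matrix(0, nrow(x), cj)
    ind[cbind(seq_len(nrow(x)), x[, j])] <- 1
    num <- t(crossprod(ind, gamma))            # K x C
    r <- num / pmax(gsum, 1e-300)
    r <- pmax(r, floor)
    r / rowSums(r)
  })
  list(
    params = lca_parameters(new_pi, new_rho),
    posteriors = gamma,
    loglik = sum(lse)
  )
}

#' Fit the latent class model by multi-start EM
#'
#' Runs EM from `n_restarts` random starts (responsibilities drawn from a
#' flat Dirichlet per person) and keeps the fit with the highest final
#' log-likelihood. Convergence is declared when the relative change in
#' log-likelihood between successive iterations falls below `tol`.
#' Deterministic given `seed`. If no restart converges within `max_iter`
#' iterations, an error of class `qol_nonconvergence` is raised carrying the
#' best trace.
#'
#' @param items An `item_matrix` (complete cases) or integer matrix of codes.
#' @param K Number of classes (>= 1).
#' @param n_restarts Number of random restarts (default 20).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap per restart (default 1000).
#' @param seed Integer seed.
#' @param floor Smoothing floor for item-category probabilities.
#' @param metadata Item metadata when `items` is a bare matrix.
#' @return Object of class `lca_fit` with elements `params`, `posteriors`,
#'   `loglik`, `loglik_trace`, `converged`, `n_params`, `aic`, `bic`, `n`,
#'   and `provenance` (seed, chosen restart).
#' @export
fit_em <- function(items, K, n_restarts = 20, tol = 1e-6, max_iter = 1000,
                   seed = 1, floor = 1e-6, metadata = NULL) {
  if (inherits(items, "item_matrix")) {
    metadata <- items$metadata
    x <- complete_values(items, "fit_em")
  } else {
    x <- items
    if (is.null(metadata)) {
      metadata <- data.frame(
        item_id = colnames(x) %||% paste0("item_", seq_len(ncol(x))),
        n_categories = apply(x, 2, max)
      )
    }
  }
  stopifnot(K >= 1)
  storage.mode(x) <- "integer"
  ncat <- as.integer(metadata$n_categories)
  n <- nrow(x)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    gamma0 <- with_seed(derive_seed(seed, K, r), {
      g <- matrix(stats::rgamma(n * K, 1), n, K)
      g / rowSums(g)
    })
    res <- .em_fit_cpp(x, ncat, gamma0, tol, as.integer(max_iter), floor)
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$restart <- r
    }
  }
  if (!isTRUE(best$converged) && K > 1) {
    cond <- structure(
      class = c("qol_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "no EM restart converged within %d iterations (best loglik %.4f)",
        max_iter, best$loglik
      ), call = sys.call(), trace = best$trace)
    )
    stop(cond)
  }
  params <- lca_parameters(best$pi, best$rho)
  p <- lca_n_params(K, ncat)
  structure(list(
    params = params,
    posteriors = best$posteriors,
    loglik = best$loglik,
    loglik_trace = as.numeric(best$trace),
    converged = isTRUE(best$converged),
    n_params = p,
    aic = -2 * best$loglik + 2 * p,
    bic = -2 * best$loglik + p * log(n),
    n = n,
    class_labels = paste0("class_", seq_len(K)),
    provenance = list(seed = seed, n_restarts = n_restarts,
                      best_restart = best$restart, tol = tol,
                      max_iter = max_iter, floor = floor,
                      empty_class = isTRUE(best$empty_class))
  ), class = "lca_fit")
}

#' Number of free parameters of a K-class model
#'
#' `p = (K - 1) + K * sum_j (C_j - 1)`.
#' @param K Number of classes.
#' @param n_categories Vector of category counts per item.
#' @return Integer count.
#' @export
lca_n_params <- function(K, n_categories) {
  as.integer((K - 1) + K * sum(n_categories - 1))
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf(
    "<lca_fit> K = %d, N = %d, loglik = %.2f, AIC = %.1f, BIC = %.1f (%s)\n",
    x$params$K, x$n, x$loglik, x$aic, x$bic,
    if (x$converged) "converged" else "not converged"
  ))
  cat("prevalences:", sprintf("%.3f", x$params$prevalences), "\n")
  invisible(x)
}

#' Modal class assignment
#'
#' Assigns each person to the class with the largest posterior probability;
#' ties are broken in favour of the lowest class index.
#'
#' @param posteriors N x K matrix of responsibilities, or an `lca_fit`.
#' @return Integer vector of class labels.
#' @export
classify_modal <- function(posteriors) {
  if (inherits(posteriors, "lca_fit")) posteriors <- posteriors$posteriors
  max.col(posteriors, ties.method = "first")
}

#' Canonical class ordering by quality-of-life utility
#'
#' Reorders the classes of a fitted model so that class 1 has the highest
#' mean utility among its modal members and class `K` the lowest, resolving
#' the label-switching indeterminacy of the mixture likelihood. For
#' four-class solutions the two middle ("Moderate") classes are ordered by
#' their mean standardised pain score: the class with the *higher* pain
#' score (less pain impairment) is placed second and labelled
#' `"Moderate-Psy"`, the other third as `"Moderate-Phy"`; classes 1 and 4
#' are labelled `"No/Mild"` and `"Severe"`.
#'
#' @param fit An `lca_fit`.
#' @param scores A `data.frame` from [dimension_scores()] (same persons as
#'   the fit), containing `utility` and `std_pain`.
#' @return The fit with classes permuted into canonical order; the applied
#'   permutation is stored in `fit$provenance$utility_order` and display
#'   labels in `fit$class_labels`.
#' @export
rank_classes_by_utility <- function(fit, scores) {
  stopifnot(inherits(fit, "lca_fit"))
  k <- fit$params$K
  if (k < 2) return(fit)
  if (is.null(scores$utility)) stop("scores must contain a 'utility' column")
  modal <- classify_modal(fit)
  mean_u <- vapply(seq_len(k), function(kk) {
    mean(scores$utility[modal == kk])
  }, numeric(1))
  ord <- order(mean_u, decreasing = TRUE, na.last = TRUE)
  if (k == 4 && !is.null(scores$std_pain)) {
    mean_pain <- vapply(seq_len(k), function(kk) {
      mean(scores$std_pain[modal == kk])
    }, numeric(1))
    mid <- ord[2:3]
    ord[2:3] <- mid[order(mean_pain[mid], decreasing = TRUE)]
  }
  fit$params <- lca_parameters(
    fit$params$prevalences[ord],
    lapply(fit$params$item_probs, function(m) m[ord, , drop = FALSE])
  )
  fit$posteriors <- fit$posteriors[, ord, drop = FALSE]
  fit$class_labels <- if (k == 4) {
    c("No/Mild", "Moderate-Psy", "Moderate-Phy", "Severe")
  } else {
    paste0("class_", seq_len(k))
  }
  fit$provenance$utility_order <- ord
  fit$provenance$class_mean_utility <- mean_u[ord]
  fit
}
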