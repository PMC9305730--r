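#' Build cross-validation folds
#'
#' Three schemes are supported: `"kfold"` (seeded random partition into
#' near-equal folds), `"loso"` (leave-one-site-out: one fold per distinct
#' recruitment site) and `"splithalf"` (a seeded random 50/50 split; each
#' half serves as the held-out set once, so both directions are evaluated).
#' Folds always partition the persons: disjoint and exhaustive.
#'
#' @param n Number of persons.
#' @param scheme One of `"kfold"`, `"loso"`, `"splithalf"`.
#' @param sites Site label per person (required for `"loso"`).
#' @param n_folds Number of folds for `"kfold"` (default 10).
#' @param seed Integer seed.
#' @return Object of class `fold_spec`: list with `scheme`, `assignments`
#'   (fold index per person), `n_folds`, `fold_labels`, `seed`.
#' @export
make_folds <- function(n, scheme = c("kfold", "loso", "splithalf"),
                       sites = NULL, n_folds = 10, seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold") {
    if (n_folds > n) stop("n_folds must not exceed n")
    assignments <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
    fold_labels <- paste0("fold_", seq_len(n_folds))
  } else if (scheme == "loso") {
    if (is.null(sites) || length(sites) != n) {
      stop("loso requires a site label per person")
    }
    f <- factor(sites)
    if (nlevels(f) < 2) stop("loso requires at least two distinct sites")
    assignments <- as.integer(f)
    n_folds <- nlevels(f)
    fold_labels <- levels(f)
  } else {
    if (n < 2) stop("splithalf requires at least two persons")
    n_folds <- 2
    assignments <- with_seed(seed, sample(rep_len(1:2, n)))
    fold_labels <- c("half_1", "half_2")
  }
  structure(list(scheme = scheme, assignments = assignments,
                 n_folds = as.integer(n_folds), fold_labels = fold_labels,
                 seed = seed),
            class = "fold_spec")
}

#' Held-out fit indices for one train/test split
#'
#' Fits the `K`-class model on the training rows and evaluates the
#' log-likelihood on the held-out rows. The held-out BIC is
#' `-2 * loglik_test + p * ln(N_test)` (the `"test"` penalty; set
#' `penalty_n = "train"` for the alternative) and the held-out AIC
#' `-2 * loglik_test + 2p`. Categories present only in the test set keep a
#' finite likelihood through the smoothing floor of [fit_em()].
#'
#' @param train,test `item_matrix` objects (or integer matrices) with
#'   identical item metadata; normally disjoint row sets.
#' @param K Number of classes.
#' @param penalty_n Which sample size enters the BIC penalty.
#' @param ... Passed to [fit_em()] (`n_restarts`, `tol`, `max_iter`, `seed`,
#'   `floor`).
#' @return One-row `data.frame` with the train/holdout indices.
#' @export
holdout_indices <- function(train, test, K, penalty_n = c("test", "train"),
                            ...) {
  penalty_n <- match.arg(penalty_n)
  x_test <- if (inherits(test, "item_matrix")) {
    complete_values(test, "holdout_indices")
  } else {
    test
  }
  if (inherits(train, "item_matrix")) {
    fit <- fit_em(train, K, ...)
  } else {
    # shared category ranges: a category seen only in the held-out rows must
    # still have a (floored) probability under the training fit
    md <- data.frame(
      item_id = colnames(train) %||% paste0("item_", seq_len(ncol(train))),
      n_categories = pmax(apply(train, 2, max), apply(x_test, 2, max))
    )
    fit <- fit_em(train, K, metadata = md, ...)
  }
  ll_test <- loglikelihood(x_test, fit$params)
  n_test <- nrow(x_test)
  n_pen <- if (penalty_n == "test") n_test else fit$n
  data.frame(
    K = K,
    n_train = fit$n,
    n_test = n_test,
    n_params = fit$n_params,
    loglik_train = fit$loglik,
    loglik_test = ll_test,
    bic_test = -2 * ll_test + fit$n_params * log(n_pen),
    aic_test = -2 * ll_test + 2 * fit$n_params,
    converged = fit$converged
  )
}

#' Cross-validated fit indices over a range of class numbers
#'
#' Runs [holdout_indices()] for every `(K, fold)` combination. Failed cells
#' (EM non-convergence) are retained with their failure reason rather than
#' silently dropped.
#'
#' @param items An `item_matrix` of complete cases.
#' @param k_range Candidate class numbers (default 1..6).
#' @param folds A `fold_spec` from [make_folds()].
#' @param n_restarts,tol,max_iter,floor EM settings per training fit.
#' @param seed Master seed; each `(K, fold)` fit derives its own stream.
#' @param penalty_n BIC penalty sample size, see [holdout_indices()].
#' @return Object of class `cv_table`: a `data.frame` with one row per
#'   `(K, fold)`.
#' @export
run_cv <- function(items, k_range = 1:6, folds, n_restarts = 20, tol = 1e-6,
                   max_iter = 1000, floor = 1e-6, seed = 1,
                   penalty_n = c("test", "train")) {
  penalty_n <- match.arg(penalty_n)
  stopifnot(inherits(folds, "fold_spec"))
  x <- complete_values(items, "run_cv")
  md <- items$metadata
  rows <- list()
  for (K in k_range) {
    for (f in seq_len(folds$n_folds)) {
      test_idx <- folds$assignments == f
      train <- new_item_matrix(x[!test_idx, , drop = FALSE], md)
      test <- new_item_matrix(x[test_idx, , drop = FALSE], md)
      cell <- tryCatch(
        cbind(
          data.frame(scheme = folds$scheme, fold = folds$fold_labels[f]),
          holdout_indices(train, test, K, penalty_n = penalty_n,
                          n_restarts = n_restarts, tol = tol,
                          max_iter = max_iter, floor = floor,
                          seed = derive_seed(seed, K, f)),
          data.frame(failed = FALSE, reason = NA_character_)
        ),
        error = function(e) {
          data.frame(
            scheme = folds$scheme, fold = folds$fold_labels[f], K = K,
            n_train = sum(!test_idx), n_test = sum(test_idx),
            n_params = lca_n_params(K, md$n_categories),
            loglik_train = NA_real_, loglik_test = NA_real_,
            bic_test = NA_real_, aic_test = NA_real_, converged = FALSE,
            failed = TRUE, reason = conditionMessage(e)
          )
        }
      )
      rows[[length(rows) + 1]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_table", "data.frame")
  attr(out, "penalty_n") <- penalty_n
  out
}

#' Select the number of classes from a cross-validation table
#'
#' Because folds partition the cohort, the out-of-fold log-likelihoods
#' concatenate into an honest predictive log-likelihood of the whole sample,
#' and the default selection index is the *pooled* held-out BIC,
#' `-2 * sum_f loglik_test_f + p * ln(sum_f N_test_f)`. The selected `K`
#' minimises this index (`criterion = "mean"` switches to the per-fold mean
#' of the held-out BIC instead, whose `p * ln(N_test)` penalty is markedly
#' more conservative for small folds). An elbow diagnostic is also reported:
#' the first `K` at which the successive improvement in the selection index
#' drops below `elbow_frac` (default 10%) of the largest single improvement.
#' A `K` whose cells all failed is excluded with a warning; an index
#' decreasing monotonically over the whole range selects the largest `K`
#' with a boundary warning.
#'
#' @param cv A `cv_table` from [run_cv()].
#' @param elbow_frac Fraction of the largest improvement defining the elbow.
#' @param criterion `"pooled"` (default) or `"mean"`; see Details.
#' @return List with `selected_k`, `summary` (per-K pooled indices, means
#'   and dispersions), `elbow_k` and `boundary` flag.
#' @export
select_k <- function(cv, elbow_frac = 0.10, criterion = c("pooled", "mean")) {
  stopifnot(inherits(cv, "cv_table") || is.data.frame(cv))
  criterion <- match.arg(criterion)
  ks <- sort(unique(cv$K))
  summ <- do.call(rbind, lapply(ks, function(K) {
    sub <- cv[cv$K == K & !cv$failed, , drop = FALSE]
    n_fail <- sum(cv$K == K & cv$failed)
    pooled_n <- sum(sub$n_test)
    pooled_ll <- sum(sub$loglik_test)
    p <- if (nrow(sub)) sub$n_params[1] else NA_real_
    data.frame(
      K = K, n_folds = nrow(sub), n_failed = n_fail,
      pooled_bic = if (nrow(sub)) -2 * pooled_ll + p * log(pooled_n) else NA_real_,
      pooled_aic = if (nrow(sub)) -2 * pooled_ll + 2 * p else NA_real_,
      pooled_loglik = if (nrow(sub)) pooled_ll else NA_real_,
      mean_bic = if (nrow(sub)) mean(sub$bic_test) else NA_real_,
      sd_bic = if (nrow(sub) > 1) stats::sd(sub$bic_test) else NA_real_,
      mean_aic = if (nrow(sub)) mean(sub$aic_test) else NA_real_,
      mean_loglik = if (nrow(sub)) mean(sub$loglik_test) else NA_real_
    )
  }))
  index <- if (criterion == "pooled") summ$pooled_bic else summ$mean_bic
  usable <- !is.na(index)
  if (any(!usable)) {
    warning("excluding K with all folds failed: ",
            paste(summ$K[!usable], collapse = ", "))
  }
  if (!any(usable)) stop("no usable K in cv table")
  cand_k <- summ$K[usable]
  cand_idx <- index[usable]
  selected <- cand_k[which.min(cand_idx)]
  boundary <- FALSE
  if (selected == max(cand_k) && length(cand_k) > 1 &&
      all(diff(cand_idx) < 0)) {
    boundary <- TRUE
    warning("held-out BIC decreases monotonically over k_range; ",
            "selected K is at the boundary")
  }
  elbow_k <- NA_integer_
  if (length(cand_k) > 1) {
    imp <- -diff(cand_idx)             # improvement going to the next K
    max_imp <- max(imp)
    if (max_imp > 0) {
      below <- which(imp < elbow_frac * max_imp)
      if (length(below)) elbow_k <- cand_k[below[1]]
    }
  }
  list(selected_k = selected, summary = summ, elbow_k = elbow_k,
       boundary = boundary, criterion = criterion)
}

#' K-means-on-principal-components sensitivity analysis
#'
#' Treats the ordinal item codes as numeric, centres and scales each item,
#' retains principal components up to a cumulative explained-variance target
#' (default 80%), and clusters the component scores with k-means (25 seeded
#' restarts). When a reference labelling is supplied (e.g. modal LCA
#' classes), agreement is reported as the adjusted Rand index.
#'
#' @param items An `item_matrix` of complete cases.
#' @param K Number of clusters.
#' @param seed Integer seed for the k-means restarts.
#' @param var_explained Cumulative variance target in `(0, 1]`.
#' @param reference_labels Optional labelling to compare against.
#' @param nstart k-means restarts (default 25).
#' @return List with `labels`, `n_components`, and `ari` (NA when no
#'   reference labelling given).
#' @export
kmeans_pca_sensitivity <- function(items, K, seed = 1, var_explained = 0.8,
                                   reference_labels = NULL, nstart = 25) {
  x <- complete_values(items, "kmeans_pca_sensitivity")
  if (K > nrow(x)) stop("K must not exceed the number of persons")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_comp <- which(cum >= var_explained)[1]
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  km <- with_seed(seed, stats::kmeans(scores, centers = K, nstart = nstart,
                                      iter.max = 100))
  ari <- if (!is.null(reference_labels)) {
    mclust::adjustedRandIndex(km$cluster, reference_labels)
  } else {
    NA_real_
  }
  list(labels = km$cluster, n_components = n_comp, ari = ari)
}
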