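#' Per-class covariate and score profile
#'
#' Summarises covariates by assigned class: median and interquartile range
#' for continuous variables, counts and percentages for categorical ones
#' (available cases per variable), plus mean and standard deviation of the
#' utility score when a score set is supplied. Empty classes yield zero-count
#' rows rather than errors.
#'
#' @param labels Class label per person (integer or factor).
#' @param covariates A `data.frame` of covariates, rows aligned with
#'   `labels`.
#' @param scores Optional `data.frame` from [dimension_scores()] with a
#'   `utility` column.
#' @return A long `data.frame` with columns `class`, `variable`, `level`,
#'   `n`, `pct`, `median`, `q1`, `q3`, `mean`, `sd`.
#' @export
profile_classes <- function(labels, covariates, scores = NULL) {
  stopifnot(nrow(covariates) == length(labels))
  classes <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  vars <- names(covariates)
  if (!is.null(scores) && !is.null(scores$utility)) {
    covariates <- cbind(covariates, utility = scores$utility)
    vars <- c(vars, "utility")
  }
  for (cl in classes) {
    sel <- labels == cl
    for (v in vars) {
      col <- covariates[[v]][sel]
      col <- col[!is.na(col)]
      if (is.numeric(col)) {
        if (length(col)) {
          q <- stats::quantile(col, c(0.25, 0.5, 0.75), names = FALSE)
          add(class = cl, variable = v, level = NA_character_,
              n = length(col), pct = NA_real_,
              median = q[2], q1 = q[1], q3 = q[3],
              mean = mean(col), sd = stats::sd(col))
        } else {
          add(class = cl, variable = v, level = NA_character_, n = 0,
              pct = NA_real_, median = NA_real_, q1 = NA_real_,
              q3 = NA_real_, mean = NA_real_, sd = NA_real_)
        }
      } else {
        col <- factor(col)
        lev <- levels(factor(covariates[[v]]))
        tab <- table(factor(col, levels = lev))
        for (lv in lev) {
          add(class = cl, variable = v, level = lv,
              n = as.integer(tab[[lv]]),
              pct = if (length(col)) 100 * tab[[lv]] / length(col) else 0,
              median = NA_real_, q1 = NA_real_, q3 = NA_real_,
              mean = NA_real_, sd = NA_real_)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Standardise clinical covariates
#'
#' Centres the named clinical variables and divides by their standard
#' deviation, so regression coefficients correspond to a one-s.d. change.
#' Age and dummy variables are left untouched by convention. Externally
#' supplied (e.g. reference-cohort) standard deviations may be fixed via
#' `sds`; otherwise the observed s.d. of each variable is used. The applied
#' means and s.d.s are recorded in the `"standardisation"` attribute.
#'
#' @param covariates A `data.frame`.
#' @param vars Variables to standardise (default the four clinical totals).
#' @param sds Optional named numeric vector of fixed s.d.s.
#' @param center Centre before scaling (default TRUE).
#' @return The `data.frame` with standardised columns and a
#'   `"standardisation"` attribute.
#' @export
standardise_covariates <- function(covariates,
                                   vars = c("phq9", "gad7", "siqjr", "psqi"),
                                   sds = NULL, center = TRUE) {
  vars <- intersect(vars, names(covariates))
  rec <- data.frame(variable = character(), mean = numeric(), sd = numeric())
  for (v in vars) {
    x <- covariates[[v]]
    if (!is.numeric(x)) stop("cannot standardise non-numeric variable: ", v)
    m <- if (center) mean(x, na.rm = TRUE) else 0
    s <- if (!is.null(sds) && !is.na(sds[v])) unname(sds[v]) else {
      stats::sd(x, na.rm = TRUE)
    }
    if (!is.finite(s) || s == 0) {
      stop("zero standard deviation: cannot standardise variable '", v, "'")
    }
    covariates[[v]] <- (x - m) / s
    rec <- rbind(rec, data.frame(variable = v, mean = m, sd = s))
  }
  attr(covariates, "standardisation") <- rec
  covariates
}

#' Multiple imputation of covariates by chained equations
#'
#' Fills covariate missingness with `m` completed copies using
#' fully-conditional specification: type-1 predictive-mean matching (with a
#' Bayesian draw of the regression coefficients and a 5-donor pool) for
#' continuous variables, logistic regression with a coefficient draw for
#' binary factors, and multinomial regression (category probabilities, no
#' coefficient draw) for factors with more than two levels. Variables are
#' visited in order of increasing missingness for a fixed number of cycles.
#' Non-missing cells are identical across copies, and the whole set is
#' deterministic given `seed`.
#'
#' @param covariates A `data.frame`; factors and numeric columns supported.
#' @param m Number of imputations (>= 2; default 20).
#' @param seed Integer seed.
#' @param n_iter Chained-equation cycles per imputation (default 10).
#' @param extra Optional `data.frame` of fully observed extra predictors
#'   (e.g. the modal class label) used in every imputation model but not
#'   themselves imputed.
#' @return Object of class `imputation_set`: list with `imputations` (list
#'   of `m` data.frames), `method` record and `seed`.
#' @export
impute_covariates <- function(covariates, m = 20, seed = 1, n_iter = 10,
                              extra = NULL) {
  if (m < 2) stop("m must be at least 2")
  miss_frac <- vapply(covariates, function(x) mean(is.na(x)), numeric(1))
  if (any(miss_frac == 1)) {
    stop("all-missing variable: ", names(covariates)[which(miss_frac == 1)[1]])
  }
  if (any(miss_frac > 0.5)) {
    warning("variable(s) with >50% missing: ",
            paste(names(covariates)[miss_frac > 0.5], collapse = ", "))
  }
  targets <- names(covariates)[miss_frac > 0]
  targets <- targets[order(miss_frac[targets])]
  methods <- vapply(targets, function(v) {
    x <- covariates[[v]]
    if (is.numeric(x)) "pmm" else if (nlevels(factor(x)) <= 2) "logreg" else "polyreg"
  }, character(1))

  imputations <- with_seed(seed, {
    lapply(seq_len(m), function(im) {
      dat <- covariates
      # initial fill: random draws from the observed margin
      for (v in targets) {
        nas <- is.na(dat[[v]])
        obs <- dat[[v]][!nas]
        dat[[v]][nas] <- sample(obs, sum(nas), replace = TRUE)
      }
      if (length(targets)) {
        for (iter in seq_len(n_iter)) {
          for (v in targets) {
            dat[[v]] <- impute_one(dat, v, is.na(covariates[[v]]),
                                   methods[[v]], extra)
          }
        }
      }
      dat
    })
  })
  structure(list(imputations = imputations,
                 method = data.frame(variable = targets, method = methods,
                                     row.names = NULL),
                 m = m, n_iter = n_iter, seed = seed),
            class = "imputation_set")
}

# One Gibbs update of variable `v` given currently completed data.
impute_one <- function(dat, v, nas, method, extra) {
  if (!any(nas)) return(dat[[v]])
  preds <- setdiff(names(dat), v)
  rhs <- dat[, preds, drop = FALSE]
  if (!is.null(extra)) rhs <- cbind(rhs, extra)
  # drop constant predictors to keep designs full rank
  keep <- vapply(rhs, function(x) length(unique(x)) > 1, logical(1))
  rhs <- rhs[, keep, drop = FALSE]
  X <- stats::model.matrix(~ ., data = rhs)
  y <- dat[[v]]

  if (method == "pmm") {
    Xo <- X[!nas, , drop = FALSE]
    yo <- y[!nas]
    qr_fit <- stats::lm.fit(Xo, yo)
    ok <- !is.na(qr_fit$coefficients)
    beta <- qr_fit$coefficients[ok]
    Xok <- Xo[, ok, drop = FALSE]
    res <- qr_fit$residuals
    df <- max(length(yo) - sum(ok), 1)
    sigma2 <- sum(res^2) / stats::rchisq(1, df)
    xtx_inv <- chol2inv(chol(crossprod(Xok) + diag(1e-8, sum(ok))))
    beta_star <- beta + drop(chol(xtx_inv) %*% stats::rnorm(sum(ok))) *
      sqrt(sigma2)
    yhat_obs <- drop(Xok %*% beta)
    yhat_mis <- drop(X[nas, ok, drop = FALSE] %*% beta_star)
    donors <- vapply(yhat_mis, function(z) {
      pool <- order(abs(yhat_obs - z))[seq_len(min(5, length(yhat_obs)))]
      yo[sample(pool, 1)]
    }, numeric(1))
    y[nas] <- donors
  } else if (method == "logreg") {
    yf <- factor(y)
    fit <- suppressWarnings(stats::glm.fit(X[!nas, , drop = FALSE],
                                           yf[!nas] == levels(yf)[2],
                                           family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    eta <- drop(X[nas, , drop = FALSE] %*% beta)
    p <- stats::plogis(eta)
    y[nas] <- levels(yf)[1 + stats::rbinom(sum(nas), 1, p)]
    y <- factor(y, levels = levels(yf))
  } else {
    yf <- factor(y)
    dat_fit <- data.frame(.y = yf, rhs)
    fit <- nnet::multinom(.y ~ ., data = dat_fit[!nas, , drop = FALSE],
                          trace = FALSE, maxit = 200)
    p <- predict(fit, newdata = dat_fit[nas, , drop = FALSE], type = "probs")
    if (is.null(dim(p))) p <- matrix(p, nrow = sum(nas))
    lev <- fit$lev
    draws <- apply(p, 1, function(pr) sample(lev, 1, prob = pr))
    y[nas] <- draws
    y <- factor(y, levels = levels(yf))
  }
  y
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d copies, %d imputed variable(s)\n",
              x$m, nrow(x$method)))
  invisible(x)
}
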