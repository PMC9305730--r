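#' Multinomial logistic regression by Newton-Raphson
#'
#' Maximum-likelihood fit of the multinomial logit
#' `log P(class = k | x) / P(class = ref | x) = x' beta_k` for each
#' non-reference class, by full Newton iterations with step halving. The
#' Wald covariance is the inverse of the observed information at the
#' optimum. If separation is detected (a coefficient diverging beyond 15 in
#' magnitude or a numerically singular information matrix) the fit falls
#' back, with a warning, to a ridge-penalised likelihood (penalty 1e-4).
#'
#' @param labels Outcome class per person (factor or coercible); the
#'   reference class must be non-empty.
#' @param design Numeric design matrix including an intercept column, or a
#'   `data.frame` passed through [stats::model.matrix()].
#' @param reference Reference class label (default: first factor level).
#' @return Object of class `multinom_fit`: `coefficients` ((K-1) x P matrix,
#'   rows named by non-reference class), `vcov` (of `vec(t(coefficients))`),
#'   `se` (matching `coefficients`), `loglik`, `fitted` (N x K
#'   probabilities), `accuracy` (share of persons whose highest fitted
#'   probability matches their label), `converged`, `ridged`.
#' @export
fit_multinomial <- function(labels, design, reference = NULL) {
  y <- factor(labels)
  if (!is.null(reference)) y <- stats::relevel(y, ref = as.character(reference))
  if (!sum(y == levels(y)[1])) stop("reference class is empty")
  if (is.data.frame(design)) design <- stats::model.matrix(~ ., data = design)
  X <- as.matrix(design)
  # rank check, naming aliased columns
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  k <- nlevels(y)
  p <- ncol(X)
  n <- nrow(X)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  newton <- function(lambda) {
    beta <- matrix(0, p, k - 1)
    ll_of <- function(b) {
      eta <- cbind(0, X %*% b)
      lse <- col_log_sum_exp(t(eta))
      sum(eta[cbind(seq_len(n), as.integer(y))]) - sum(lse) -
        (lambda / 2) * sum(b^2)
    }
    ll <- ll_of(beta)
    converged <- FALSE
    for (it in seq_len(200)) {
      eta <- cbind(0, X %*% beta)
      eta <- eta - apply(eta, 1, max)
      P_mat <- exp(eta)
      P_mat <- P_mat / rowSums(P_mat)
      G <- crossprod(X, Y[, -1, drop = FALSE] - P_mat[, -1, drop = FALSE]) -
        lambda * beta
      H <- matrix(0, p * (k - 1), p * (k - 1))
      for (a in seq_len(k - 1)) {
        for (b2 in seq_len(a)) {
          w <- if (a == b2) {
            P_mat[, a + 1] * (1 - P_mat[, a + 1])
          } else {
            -P_mat[, a + 1] * P_mat[, b2 + 1]
          }
          blk <- crossprod(X, X * w)
          ia <- (a - 1) * p + seq_len(p)
          ib <- (b2 - 1) * p + seq_len(p)
          H[ia, ib] <- blk
          if (a != b2) H[ib, ia] <- blk
        }
      }
      H <- H + diag(lambda, p * (k - 1))
      step <- tryCatch(solve(H, as.vector(G)),
                       error = function(e) NULL)
      if (is.null(step)) return(NULL)
      step_m <- matrix(step, p, k - 1)
      # step halving
      alpha <- 1
      repeat {
        beta_new <- beta + alpha * step_m
        ll_new <- ll_of(beta_new)
        if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
        alpha <- alpha / 2
        if (alpha < 1e-8) break
      }
      moved <- max(abs(beta_new - beta))
      beta <- beta_new
      # separation: diverging coefficients or a saturated linear predictor
      if (lambda == 0 &&
          (max(abs(beta)) > 15 || max(abs(X %*% beta)) > 30)) {
        return(NULL)
      }
      grad_norm <- max(abs(G))
      ll <- ll_new
      if (grad_norm < 1e-8 || moved < 1e-10) { converged <- TRUE; break }
    }
    list(beta = beta, H = H, ll = ll, converged = converged)
  }

  res <- newton(0)
  ridged <- FALSE
  if (is.null(res)) {
    warning("separation or singular information detected; ",
            "refitting with ridge penalty 1e-4")
    ridged <- TRUE
    res <- newton(1e-4)
    if (is.null(res)) stop("multinomial fit failed even with ridge penalty")
  }
  beta <- t(res$beta)                       # (K-1) x P
  dimnames(beta) <- list(levels(y)[-1], colnames(X))
  vc <- solve(res$H)
  se <- matrix(sqrt(diag(vc)), nrow = p)    # p x (k-1)
  se <- t(se)
  dimnames(se) <- dimnames(beta)
  eta <- cbind(0, X %*% res$beta)
  eta <- eta - apply(eta, 1, max)
  fitted <- exp(eta) / rowSums(exp(eta))
  colnames(fitted) <- levels(y)
  pred <- levels(y)[max.col(fitted, ties.method = "first")]
  structure(list(
    coefficients = beta, vcov = vc, se = se, loglik = res$ll,
    fitted = fitted, accuracy = mean(pred == as.character(y)),
    converged = res$converged, ridged = ridged,
    reference = levels(y)[1], levels = levels(y)
  ), class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf(
    "<multinom_fit> %d outcome classes (ref '%s'), %d coefficients, loglik %.2f\n",
    length(x$levels), x$reference, length(x$coefficients), x$loglik
  ))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance
#' `T = Wbar + (1 + 1/m) B` with `Wbar` the mean within-imputation variance
#' and `B` the between-imputation variance. Degrees of freedom follow the
#' classical `(m - 1) (1 + Wbar / ((1 + 1/m) B))^2` formula (infinite when
#' `B = 0`, so identical fits reduce exactly to single-fit inference).
#'
#' @param estimates m x p matrix (or list) of per-imputation estimates.
#' @param variances m x p matrix (or list) of their squared standard errors.
#' @param conf_level Confidence level for the returned intervals.
#' @return A `data.frame` with `estimate`, `within`, `between`, `total_var`,
#'   `se`, `df`, `ci_low`, `ci_high` per parameter.
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  if (is.list(estimates) && !is.matrix(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, as.vector))
  }
  if (is.list(variances) && !is.matrix(variances)) {
    variances <- do.call(rbind, lapply(variances, as.vector))
  }
  estimates <- as.matrix(estimates)
  variances <- as.matrix(variances)
  if (!all(dim(estimates) == dim(variances)) || nrow(estimates) < 2) {
    stop("estimates and variances must be conformable with m >= 2 rows")
  }
  m <- nrow(estimates)
  qbar <- colMeans(estimates)
  wbar <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  total <- wbar + (1 + 1 / m) * b
  df <- ifelse(b > 0, (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2, Inf)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  tq[!is.finite(df)] <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    parameter = colnames(estimates) %||% paste0("b", seq_along(qbar)),
    estimate = qbar, within = wbar, between = b, total_var = total,
    se = sqrt(total), df = df,
    ci_low = qbar - tq * sqrt(total), ci_high = qbar + tq * sqrt(total),
    row.names = NULL
  )
}

# Build the analysis design data.frame for the two validation models.
# Model 1: demographics + diagnosis + clinical staging (stages 0/1a collapsed
# to the reference band). Model 2 adds the standardised symptom totals.
validation_design <- function(covariates, model = 1) {
  dat <- data.frame(age = covariates$age)
  for (v in c("sex", "lgbtiq", "neet", "region")) {
    if (!is.null(covariates[[v]])) dat[[v]] <- factor(covariates[[v]])
  }
  if (!is.null(covariates$diagnosis)) {
    dat$diagnosis <- factor(covariates$diagnosis)
  }
  if (!is.null(covariates$clinical_stage)) {
    st <- as.character(covariates$clinical_stage)
    st[st %in% c("0", "1a")] <- "0-1a"
    dat$stage <- factor(st, levels = c("0-1a", "1b", "2-4"))
  }
  if (model == 2) {
    for (v in c("phq9", "gad7", "siqjr", "psqi")) {
      dat[[v]] <- covariates[[v]]
    }
  }
  dat
}

#' 3-step validation: pooled relative risk ratios for class membership
#'
#' Third step of the 3-step latent class workflow: persons are assigned to
#' their modal class, and class membership is regressed on covariates with
#' multivariate multinomial logistic regression. Two models are fitted:
#' model 1 uses demographics (age, sex, LGBTIQ, NEET, region), primary
#' diagnosis and clinical staging (reference band stages 0-1a); model 2 adds
#' the standardised clinical symptom totals (PHQ-9, GAD-7, SIQ-JR, PSQI).
#' Covariate missingness is handled by multiple imputation; coefficients and
#' Wald variances are pooled by Rubin's rules on the log scale and
#' exponentiated into relative risk ratios with confidence intervals.
#' Prediction accuracy (share of persons whose highest fitted probability
#' matches their assigned class) is averaged over imputations.
#'
#' @param labels Assigned class per person (factor; its first level — or
#'   `reference` — is the reference outcome, conventionally the
#'   highest-utility class).
#' @param covariates Covariate `data.frame` (raw scale; clinical totals are
#'   standardised internally using observed cohort s.d.s unless `sds` gives
#'   fixed values).
#' @param m Number of imputations (default 20).
#' @param seed Integer seed for the imputation draws.
#' @param models Which models to fit (subset of `c(1, 2)`).
#' @param reference Reference outcome class label.
#' @param sds Optional fixed s.d.s passed to [standardise_covariates()].
#' @param n_iter Chained-equation cycles (default 10).
#' @return Object of class `rrr_report`: list with `rrr` (a `data.frame`
#'   with `model`, `class`, `predictor`, `rrr`, `ci_low`, `ci_high`),
#'   `accuracy` (named per model) and `pooled` (full pooling tables).
#' @export
rrr_report <- function(labels, covariates, m = 20, seed = 1, models = c(1, 2),
                       reference = NULL, sds = NULL, n_iter = 10) {
  y <- factor(labels)
  if (!is.null(reference)) y <- stats::relevel(y, ref = as.character(reference))
  covariates <- standardise_covariates(covariates, sds = sds)
  imp <- impute_covariates(covariates, m = m, seed = seed, n_iter = n_iter,
                           extra = data.frame(.class = y))
  out_rrr <- list()
  pooled <- list()
  accuracy <- c()
  for (mod in models) {
    ests <- list(); vars <- list(); accs <- numeric(0)
    for (im in seq_len(m)) {
      design <- validation_design(imp$imputations[[im]], model = mod)
      fit <- fit_multinomial(y, design)
      ests[[im]] <- as.vector(t(fit$coefficients))
      vars[[im]] <- as.vector(t(fit$se))^2
      accs <- c(accs, fit$accuracy)
    }
    cf <- fit_multinomial(y, validation_design(imp$imputations[[1]],
                                               model = mod))
    par_names <- as.vector(t(outer(rownames(cf$coefficients),
                                   colnames(cf$coefficients), paste,
                                   sep = " ~ ")))
    est_mat <- do.call(rbind, ests)
    colnames(est_mat) <- par_names
    pl <- pool_rubin(est_mat, do.call(rbind, vars))
    cls <- sub(" ~ .*$", "", pl$parameter)
    prd <- sub("^.* ~ ", "", pl$parameter)
    tag <- paste0("model-", mod)
    out_rrr[[tag]] <- data.frame(
      model = tag, class = cls, predictor = prd,
      rrr = exp(pl$estimate),
      ci_low = exp(pl$ci_low), ci_high = exp(pl$ci_high),
      stringsAsFactors = FALSE
    )
    pooled[[tag]] <- pl
    accuracy[tag] <- mean(accs)
  }
  structure(list(
    rrr = do.call(rbind, c(out_rrr, list(make.row.names = FALSE))),
    accuracy = accuracy,
    pooled = pooled,
    reference = levels(y)[1],
    m = m
  ), class = "rrr_report")
}

#' @export
print.rrr_report <- function(x, ...) {
  cat(sprintf("<rrr_report> reference class '%s', m = %d imputations\n",
              x$reference, x$m))
  cat("prediction accuracy:",
      paste(names(x$accuracy), sprintf("%.3f", x$accuracy), collapse = "; "),
      "\n")
  invisible(x)
}
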