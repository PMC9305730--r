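# Brute-force mixture log-likelihood by direct enumeration over classes.
enum_loglik <- function(x, pi, rho) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    li <- 0
    for (k in seq_along(pi)) {
      term <- pi[k]
      for (j in seq_len(ncol(x))) term <- term * rho[[j]][k, x[i, j]]
      li <- li + term
    }
    total <- total + log(li)
  }
  total
}

random_params <- function(K, J, C, seed) {
  withr::with_seed(seed, {
    pi <- rgamma(K, 1); pi <- pi / sum(pi)
    rho <- lapply(seq_len(J), function(j) {
      m <- matrix(rgamma(K * C, 1), K, C)
      m / rowSums(m)
    })
    lca_parameters(pi, rho)
  })
}

test_that("log-likelihood matches closed forms and the enumeration oracle", {
  # K = 1: mixture collapses to a product
  withr::with_seed(61, x <- matrix(sample(1:4, 8 * 3, replace = TRUE), 8, 3))
  p1 <- random_params(1, 3, 4, seed = 62)
  direct <- sum(vapply(seq_len(8), function(i) {
    sum(log(vapply(1:3, function(j) p1$item_probs[[j]][1, x[i, j]],
                   numeric(1))))
  }, numeric(1)))
  expect_equal(loglikelihood(x, p1), direct, tolerance = 1e-12)

  # uniform item probabilities: N * J * log(1/C)
  md <- aqol_metadata()
  unif <- lca_parameters(c(0.5, 0.5),
                         lapply(1:20, function(j) matrix(0.2, 2, 5)))
  withr::with_seed(63, {
    xm <- matrix(sample(1:5, 7 * 20, replace = TRUE), 7, 20)
  })
  expect_equal(loglikelihood(xm, unif), 7 * 20 * log(1 / 5), tolerance = 1e-10)

  # random small instances against direct enumeration
  for (rep in 1:5) {
    K <- sample(1:3, 1); J <- sample(2:4, 1); C <- sample(2:4, 1)
    withr::with_seed(100 + rep, {
      x <- matrix(sample(seq_len(C), 10 * J, replace = TRUE), 10, J)
    })
    params <- random_params(K, J, C, seed = 200 + rep)
    expect_equal(loglikelihood(x, params),
                 enum_loglik(x, params$prevalences, params$item_probs),
                 tolerance = 1e-9)
  }

  # zero-probability observed cell warns and returns -Inf
  pz <- lca_parameters(1, list(matrix(c(1, 0), 1, 2)))
  expect_warning(ll <- loglikelihood(matrix(2L, 1, 1), pz),
                 "zero-probability")
  expect_identical(ll, -Inf)
})

test_that("EM steps are monotone, fix K = 1, and match hand-computed posteriors", {
  # K = 1 fixed point: parameters reproduce themselves
  withr::with_seed(70, x <- matrix(sample(1:3, 60 * 4, replace = TRUE), 60, 4))
  marg <- lapply(1:4, function(j) matrix(tabulate(x[, j], 3) / 60, 1, 3))
  p1 <- lca_parameters(1, marg)
  step <- em_step(x, p1)
  expect_equal(step$params$item_probs, marg, tolerance = 1e-12)
  expect_equal(step$params$prevalences, 1, tolerance = 1e-12)

  # monotone log-likelihood from arbitrary valid starts
  for (rep in 1:5) {
    params <- random_params(2, 4, 3, seed = 300 + rep)
    ll_prev <- -Inf
    for (it in 1:20) {
      step <- em_step(x, params)
      expect_gte(step$loglik, ll_prev - 1e-9)
      ll_prev <- step$loglik
      params <- step$params
    }
  }

  # two-person, one-item, two-class toy with hand-computable E and M steps
  toy_x <- matrix(c(1L, 2L), 2, 1)
  toy <- lca_parameters(c(0.5, 0.5),
                        list(matrix(c(0.8, 0.3, 0.2, 0.7), 2, 2)))
  st <- em_step(toy_x, toy, floor = 0)
  expect_equal(st$posteriors[1, ], c(8 / 11, 3 / 11), tolerance = 1e-12)
  expect_equal(st$posteriors[2, ], c(2 / 9, 7 / 9), tolerance = 1e-12)
  expect_equal(st$params$prevalences[1], (8 / 11 + 2 / 9) / 2,
               tolerance = 1e-12)
  expect_equal(st$params$item_probs[[1]][1, 1],
               (8 / 11) / (8 / 11 + 2 / 9), tolerance = 1e-12)
})

test_that("fit_em: closed-form K = 1, determinism, monotone trace, and a stationary end point", {
  withr::with_seed(80, x <- matrix(sample(1:5, 200 * 6, replace = TRUE), 200, 6))
  fit1 <- fit_em(x, K = 1, n_restarts = 2, seed = 4)
  expect_equal(fit1$params$prevalences, 1)
  for (j in 1:6) {
    expect_equal(fit1$params$item_probs[[j]][1, ],
                 tabulate(x[, j], 5) / 200, tolerance = 1e-4)
  }

  dat <- gen_lca_data(600, c(0.5, 0.5), lapply(1:5, function(j) {
    rbind(c(0.8, 0.15, 0.05), c(0.05, 0.15, 0.8))
  }), seed = 81)
  fit <- fit_em(dat$x, K = 2, n_restarts = 5, seed = 9)
  fit_again <- fit_em(dat$x, K = 2, n_restarts = 5, seed = 9)
  expect_identical(fit$loglik, fit_again$loglik)
  expect_identical(fit$params$prevalences, fit_again$params$prevalences)
  expect_identical(fit$provenance$best_restart,
                   fit_again$provenance$best_restart)

  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # the EM end point is (numerically) a fixed point of a full EM step
  step <- em_step(dat$x, fit$params)
  expect_lt(abs(step$loglik - fit$loglik), 0.02)

  # information criteria closed forms
  expect_equal(fit$n_params, 1 + 2 * (3 - 1) * 5)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(600))
  expect_equal(lca_n_params(4, rep(5, 20)), 323)
})

test_that("parameters of a separated two-class model are recovered", {
  rho <- lapply(1:8, function(j) rbind(c(0.80, 0.15, 0.05),
                                       c(0.05, 0.15, 0.80)))
  dat <- gen_lca_data(2000, c(0.6, 0.4), rho, seed = 90)
  fit <- fit_em(dat$x, K = 2, n_restarts = 10, seed = 13)
  modal <- classify_modal(fit)
  al <- best_permutation(modal, dat$class, 2)
  expect_gt(al$accuracy, 0.95)
  perm <- order(al$perm)        # map true class -> estimated class
  expect_lt(max(abs(fit$params$prevalences[perm[c(1, 2)]] - c(0.6, 0.4))),
            0.03)
  dev <- unlist(lapply(1:8, function(j) {
    abs(fit$params$item_probs[[j]][perm, ] - rho[[j]])
  }))
  expect_lt(mean(dev), 0.05)
})

test_that("label permutations leave fit indices invariant and canonical ranking restores order", {
  rho <- lapply(1:6, function(j) rbind(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7)))
  dat <- gen_lca_data(400, c(0.5, 0.5), rho, seed = 95)
  fit <- fit_em(dat$x, K = 2, n_restarts = 4, seed = 2)
  swapped <- lca_parameters(rev(fit$params$prevalences),
                            lapply(fit$params$item_probs,
                                   function(m) m[2:1, , drop = FALSE]))
  expect_equal(loglikelihood(dat$x, swapped),
               loglikelihood(dat$x, fit$params), tolerance = 1e-9)

  # modal assignment: argmax rows, ties to the lowest index
  post <- rbind(c(0.1, 0.7, 0.1, 0.1), c(0.5, 0.5, 0, 0),
                c(0.25, 0.25, 0.25, 0.25))
  expect_identical(classify_modal(post), c(2L, 1L, 1L))
})

test_that("utility ranking canonicalises any label permutation identically", {
  fx <- reference_cohort_fixture()
  fit <- fit_em(fx$complete, K = 4, n_restarts = 6, seed = 3)
  ranked <- rank_classes_by_utility(fit, fx$scores)

  # permute the fitted classes and rank again: same canonical result
  perm <- c(3, 1, 4, 2)
  fit_p <- fit
  fit_p$params <- lca_parameters(
    fit$params$prevalences[perm],
    lapply(fit$params$item_probs, function(m) m[perm, , drop = FALSE])
  )
  fit_p$posteriors <- fit$posteriors[, perm, drop = FALSE]
  ranked_p <- rank_classes_by_utility(fit_p, fx$scores)
  expect_equal(ranked_p$params$prevalences, ranked$params$prevalences,
               tolerance = 1e-12)
  expect_equal(ranked_p$params$item_probs, ranked$params$item_probs,
               tolerance = 1e-12)

  # mean utilities decrease from class 1 to class K, and the Moderate pair
  # is ordered by pain: class 2 (Psy) has the higher pain score (less pain)
  modal <- classify_modal(ranked)
  mu <- tapply(fx$scores$utility, modal, mean)
  expect_true(all(diff(mu) < 0))
  pain <- tapply(fx$scores$std_pain, modal, mean)
  expect_gt(pain[["2"]], pain[["3"]])
  expect_identical(ranked$class_labels,
                   c("No/Mild", "Moderate-Psy", "Moderate-Phy", "Severe"))
})
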