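# Shared fixtures: all synthetic inputs are built in code.

# Direct sampler for small latent class instances (independent of the
# package's generator): pi over classes, rho = list of J matrices K x C.
gen_lca_data <- function(n, pi, rho, seed = 1) {
  withr::with_seed(seed, {
    k <- length(pi)
    cls <- sample.int(k, n, replace = TRUE, prob = pi)
    x <- matrix(0L, n, length(rho))
    for (j in seq_along(rho)) {
      for (kk in seq_len(k)) {
        idx <- which(cls == kk)
        if (length(idx)) {
          x[idx, j] <- sample.int(ncol(rho[[j]]), length(idx),
                                  replace = TRUE, prob = rho[[j]][kk, ])
        }
      }
    }
    list(x = x, class = cls)
  })
}

# 20-item, 5-category class-conditional profiles from per-dimension
# disvalue levels (binomial(4, p) + 1 discretisation), matching the
# structure of the packaged profile.
binom_item_profiles <- function(p_by_class_dim) {
  dims <- c(4, 3, 4, 3, 3, 3)
  lapply(seq_len(nrow(p_by_class_dim)), function(k) {
    probs <- list()
    for (d in seq_along(dims)) {
      for (i in seq_len(dims[d])) {
        probs[[length(probs) + 1]] <- dbinom(0:4, 4, p_by_class_dim[k, d])
      }
    }
    probs
  })
}

# A well-separated K-class 20-item config (no covariates) for selection and
# recovery experiments.
separated_config <- function(K, n = 1500) {
  p_grid <- c(0.08, 0.34, 0.60, 0.86)
  profiles <- binom_item_profiles(
    matrix(rep(p_grid[seq_len(K)], each = 6), nrow = K, byrow = TRUE)
  )
  validate_generator_config(list(
    name = paste0("separated_", K),
    n_subjects = n, n_classes = K,
    prevalences = rep(1 / K, K),
    items = list(n_categories = rep(5L, 20)),
    item_profiles = profiles,
    covariates = list(),
    sites = list(labels = c("s1", "s2"), metro = c(TRUE, FALSE),
                 probs = c(0.5, 0.5)),
    missingness = list(n_rows = 0),
    seed = 1
  ))
}

# Best label alignment of an estimated K-class fit to a reference labelling
# (exhaustive over permutations; K <= 4 here).
best_permutation <- function(est, truth, K) {
  perms <- do.call(rbind, combinat_perms(seq_len(K)))
  best <- NULL; best_acc <- -1
  for (i in seq_len(nrow(perms))) {
    acc <- mean(perms[i, est] == truth)
    if (acc > best_acc) { best_acc <- acc; best <- perms[i, ] }
  }
  list(perm = best, accuracy = best_acc)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Paper-profile cohort pieces shared across acceptance checks, computed once.
reference_cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      profile <- aqol_reference_profile()
      cohort <- generate_cohort(profile, seed = 1)
      complete <- complete_case_filter(cohort$items)
      keep <- setdiff(seq_len(profile$n_subjects), attr(complete, "dropped"))
      scores <- dimension_scores(complete, aqol_surrogate_utility())
      cache <<- list(profile = profile, cohort = cohort, complete = complete,
                     keep = keep, scores = scores,
                     true_class = cohort$true_class[keep],
                     sites = cohort$site[keep])
    }
    cache
  }
})
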