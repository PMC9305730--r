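test_that("thresholds are normal quantiles of cumulative margins", {
  x <- rep(1:2, each = 500)
  expect_equal(estimate_thresholds(x), 0)

  # cumulative proportions 0.5 and 0.8413 -> thresholds ~ (0, 1)
  y <- rep(1:3, times = c(5000, 3413, 1587))
  th <- estimate_thresholds(y)
  expect_equal(th[1], 0, tolerance = 1e-12)
  expect_equal(th[2], 1, tolerance = 1e-3)

  expect_error(estimate_thresholds(rep(2L, 100), n_categories = 5),
               "degenerate")
})

test_that("bivariate normal CDF matches one-dimensional quadrature to 1e-7", {
  grid_h <- c(-2.1, -0.7, 0, 0.9, 2.4)
  for (rho in c(-0.95, -0.5, 0, 0.3, 0.8, 0.995)) {
    oracle <- outer(grid_h, grid_h, Vectorize(function(h, k) {
      stats::integrate(function(x) {
        stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2))
      }, -Inf, h, rel.tol = 1e-12)$value
    }))
    got <- matrix(pbvnorm(rep(grid_h, 5), rep(grid_h, each = 5), rho), 5)
    expect_lt(max(abs(got - oracle)), 1e-7)
  }
  # infinite limits are exact margins
  expect_equal(pbvnorm(Inf, 0.3, 0.5), pnorm(0.3))
  expect_equal(pbvnorm(-Inf, 0.3, 0.5), 0)
  expect_equal(pbvnorm(Inf, Inf, -0.4), 1)
})

test_that("polychoric pair estimates: concordance, independence and consistency", {
  cut3 <- function(z) {
    as.integer(cut(z, c(-Inf, qnorm(1 / 3), qnorm(2 / 3), Inf)))
  }
  # same discretisation of the same variable -> near-perfect correlation
  withr::with_seed(31, z <- rnorm(2000))
  expect_gte(polychoric_pair(cut3(z), cut3(z))$rho, 0.99)

  # independent ordinals at n = 50,000
  withr::with_seed(32, {
    a <- sample(1:4, 50000, replace = TRUE)
    b <- sample(1:5, 50000, replace = TRUE)
  })
  expect_lt(abs(polychoric_pair(a, b)$rho), 0.03)

  # consistency across true latent correlations at n = 50,000
  for (rho in c(-0.8, -0.3, 0, 0.3, 0.8)) {
    withr::with_seed(33 + round(10 * rho), {
      z1 <- rnorm(50000)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(50000)
    })
    est <- polychoric_pair(cut3(z1), cut3(z2))$rho
    expect_lt(abs(est - rho), 0.02)
  }
})

test_that("two-step estimate agrees with a brute-force likelihood grid search", {
  cut4 <- function(z) {
    as.integer(cut(z, c(-Inf, qnorm(c(0.2, 0.55, 0.85)), Inf)))
  }
  for (rho_true in c(-0.4, 0.5)) {
    withr::with_seed(40 + round(10 * rho_true), {
      z1 <- rnorm(4000)
      z2 <- rho_true * z1 + sqrt(1 - rho_true^2) * rnorm(4000)
    })
    x <- cut4(z1); y <- cut4(z2)
    est <- polychoric_pair(x, y)$rho

    # oracle: same two-step likelihood, maximised by exhaustive grid search
    # with cell probabilities from an independent bivariate-normal CDF
    ta <- qnorm(cumsum(tabulate(x, 4) / length(x)))[1:3]
    tb <- qnorm(cumsum(tabulate(y, 4) / length(y)))[1:3]
    counts <- table(factor(x, levels = 1:4), factor(y, levels = 1:4))
    a <- c(-Inf, ta, Inf); b <- c(-Inf, tb, Inf)
    grid_ll <- function(r) {
      s <- matrix(diag(c(1, 1)), 2); s[1, 2] <- s[2, 1] <- r
      p <- matrix(0, 4, 4)
      for (i in 1:4) for (jj in 1:4) {
        p[i, jj] <- mvtnorm::pmvnorm(
          lower = c(a[i], b[jj]), upper = c(a[i + 1], b[jj + 1]), sigma = s
        )
      }
      sum(counts * log(pmax(p, 1e-12)))
    }
    rhos <- seq(-0.99, 0.99, by = 0.001)
    lls <- vapply(rhos, grid_ll, numeric(1))
    oracle <- rhos[which.max(lls)]
    expect_lt(abs(est - oracle), 0.002)
  }
})

test_that("polychoric matrix is symmetric, flags duplicates and stays near zero under independence", {
  md <- aqol_metadata()
  withr::with_seed(50, {
    vals <- matrix(sample(1:5, 20000 * 20, replace = TRUE), 20000, 20)
  })
  vals[, 2] <- vals[, 1]                     # duplicated item column
  items <- validate_responses(as.data.frame(`colnames<-`(vals, md$item_id)), md)
  pm <- polychoric_matrix(items)
  expect_identical(pm$r_pc, t(pm$r_pc))
  expect_equal(diag(pm$r_pc), stats::setNames(rep(1, 20), md$item_id))
  expect_gte(pm$r_pc[1, 2], 0.99)
  off <- pm$r_pc[upper.tri(pm$r_pc)]
  off <- off[-1]                             # all but the duplicated pair
  expect_lt(max(abs(off)), 0.05)

  # missing values must be filtered first
  vals[1, 1] <- NA
  items_na <- validate_responses(
    as.data.frame(`colnames<-`(vals, md$item_id)), md
  )
  expect_error(polychoric_matrix(items_na), "complete")
})

test_that("MDS layout reflects the correlation structure", {
  # two blocks: internal r = 0.9, cross r = 0 -> within-block distances smaller
  r <- diag(1, 6)
  r[1:3, 1:3] <- 0.9; r[4:6, 4:6] <- 0.9; diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("i", 1:6)
  ly <- mds_layout(r)
  d <- as.matrix(dist(ly$coordinates))
  within <- c(d[1, 2], d[1, 3], d[2, 3], d[4, 5], d[4, 6], d[5, 6])
  between <- as.vector(d[1:3, 4:6])
  expect_lt(mean(within), mean(between))
  expect_equal(nrow(ly$edge_list), 6)        # the six r = 0.9 pairs

  # all correlations 1 -> all points coincide
  ones <- matrix(1, 4, 4)
  rownames(ones) <- colnames(ones) <- paste0("i", 1:4)
  ly1 <- mds_layout(ones)
  expect_lt(max(dist(ly1$coordinates)), 1e-8)

  # three points always embed exactly: distance ordering preserved
  r3 <- diag(1, 3)
  r3[1, 2] <- r3[2, 1] <- 0.8
  r3[1, 3] <- r3[3, 1] <- 0.5
  r3[2, 3] <- r3[3, 2] <- 0.1
  rownames(r3) <- colnames(r3) <- paste0("i", 1:3)
  ly3 <- mds_layout(r3)
  d3 <- as.matrix(dist(ly3$coordinates))
  expect_true(d3[1, 2] < d3[1, 3] && d3[1, 3] < d3[2, 3])
  expect_equal(d3[1, 2], sqrt(2 * (1 - 0.8)), tolerance = 1e-6)
})
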