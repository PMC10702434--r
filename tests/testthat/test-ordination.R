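test_that("arcsine-square-root transform has the closed-form landmarks", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.5), pi / 4)
  expect_error(arcsine_sqrt(1.1), "0, 1")
  expect_error(arcsine_sqrt(-0.1), "0, 1")
})

test_that("PCA matches an independent eigen decomposition and reconstructs", {
  # brute-force oracle: eigenvalues of the covariance of the scaled matrix
  x <- matrix(c(1, 2, 4, 1, 3, 8), nrow = 3)
  ord <- pfw_pca(x, scale = TRUE)
  ev <- eigen(cov(scale(x)))$values
  expect_equal(ord$sdev^2, ev[ev > 1e-12], tolerance = 1e-10)
  expect_equal(ord$explained_variance, ev[ev > 1e-12] / sum(ev),
               tolerance = 1e-10)

  set.seed(21)
  y <- matrix(rnorm(60), 12, 5)
  ordy <- pfw_pca(y, scale = TRUE)
  # scores x loadings' reconstructs the standardized data at full rank
  expect_equal(ordy$scores %*% t(ordy$loadings),
               scale(y), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(colMeans(ordy$scores)), rep(0, 5), tolerance = 1e-10)
  expect_equal(sum(ordy$explained_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(ordy$explained_variance) <= 1e-12))
  # fixed sign convention: dominant loading positive per axis
  expect_true(all(apply(ordy$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))

  # collinear data are rank one
  z <- cbind(1:6, 2 * (1:6))
  expect_equal(pfw_pca(z, scale = TRUE)$explained_variance, 1)

  # isotropic Gaussian splits variance evenly
  set.seed(8)
  iso <- matrix(rnorm(4000), 2000, 2)
  expect_equal(pfw_pca(iso)$explained_variance, c(0.5, 0.5),
               tolerance = 0.05)

  const <- cbind(a = rep(1, 5), b = rnorm(5))
  expect_error(pfw_pca(const, scale = TRUE), "a")
})

test_that("group ellipses use the 95% normal-theory radius", {
  set.seed(3)
  ord <- pfw_pca(matrix(rnorm(80), 20, 4))
  ell <- ordination_ellipses(ord, rep(c("p", "q"), each = 10))
  expect_equal(nrow(ell), 2L)
  expect_equal(ell$radius, rep(sqrt(qchisq(0.95, 2)), 2))
  expect_equal(ell$radius[1], 2.4477, tolerance = 1e-4)
})

test_that("Pillai's trace matches closed forms and stats::manova", {
  # one response: Pillai reduces to SSB/(SSB+SSW); hand value for the
  # 6-point example {1,2 | 4,6 | 9,11} is 73/77.5 = 0.94193548
  x1 <- matrix(c(1, 2, 4, 6, 9, 11), ncol = 1)
  g1 <- rep(c("A", "B", "C"), each = 2)
  expect_equal(manova_pillai(x1, g1)$pillai_trace, 0.94193548,
               tolerance = 1e-8)

  # identical group means leave (almost) no between-group trace
  base <- matrix(rnorm(20), 10, 2)
  same <- rbind(base, base)
  mv0 <- manova_pillai(same, rep(c("g1", "g2"), each = 10))
  expect_lt(mv0$pillai_trace, 1e-20)

  # full agreement with the independent stats::manova route
  set.seed(14)
  x <- matrix(rnorm(34 * 4), 34, 4)
  g <- rep(c("ai", "ti", "liver", "carcass"), c(5, 5, 15, 9))
  mine <- manova_pillai(x, g)
  ref <- summary(stats::manova(x ~ factor(g)), test = "Pillai")$stats
  expect_equal(mine$pillai_trace, ref[1, "Pillai"], tolerance = 1e-10)
  expect_equal(mine$f_approx, ref[1, "approx F"], tolerance = 1e-10)
  expect_equal(mine$df_num, ref[1, "num Df"])
  expect_equal(mine$df_den, ref[1, "den Df"])
  expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)

  # the trace never exceeds min(p, g - 1)
  for (s in 1:25) {
    set.seed(s)
    xs <- matrix(rnorm(18 * 3), 18, 3)
    gs <- rep(c("a", "b", "c"), each = 6)
    expect_lte(manova_pillai(xs, gs)$pillai_trace, min(3, 2) + 1e-12)
  }

  # invariance under affine rescaling of a response
  x2 <- x
  x2[, 2] <- 100 * x2[, 2] - 7
  expect_equal(manova_pillai(x2, g)$pillai_trace, mine$pillai_trace,
               tolerance = 1e-10)

  expect_error(manova_pillai(x[1:3, ], c("a", "a", "b")), ">= 2 samples")
})

test_that("Tukey-Kramer matches the hand oracle and collapses to HSD", {
  # frozen hand arithmetic: groups {4,5,6}, {7,9}, {10,11,12,13}
  v <- c(4, 5, 6, 7, 9, 10, 11, 12, 13)
  g <- rep(c("a", "b", "c"), c(3, 2, 4))
  res <- anova_tukey_kramer(v, g)
  pr <- res$pairs
  expect_equal(res$mse, 1.5, tolerance = 1e-12)
  expect_equal(pr$q[pr$group_i == "a" & pr$group_j == "b"],
               3.79473319, tolerance = 1e-7)
  expect_equal(pr$q[pr$group_i == "a" & pr$group_j == "c"],
               9.82707630, tolerance = 1e-7)
  expect_equal(pr$p_adjusted[pr$group_i == "a" & pr$group_j == "b"],
               0.08088279, tolerance = 1e-7)

  # unequal-n adjusted p equals stats::TukeyHSD everywhere
  hsd <- stats::TukeyHSD(stats::aov(v ~ factor(g)))$`factor(g)`
  expect_equal(unname(pr$p_adjusted),
               unname(hsd[c("b-a", "c-a", "c-b"), "p adj"]),
               tolerance = 1e-8)

  # equal group sizes: identical to Tukey HSD by construction
  set.seed(31)
  ve <- rnorm(12)
  ge <- rep(c("a", "b", "c"), each = 4)
  pe <- anova_tukey_kramer(ve, ge)$pairs
  he <- stats::TukeyHSD(stats::aov(ve ~ factor(ge)))$`factor(ge)`
  expect_equal(unname(pe$p_adjusted), unname(he[, "p adj"]),
               tolerance = 1e-10)

  # identical constant groups: F = 0, nothing significant
  rc <- anova_tukey_kramer(rep(5, 9), g)
  expect_equal(rc$f, 0)
  expect_true(all(rc$pairs$p_adjusted > 0.99))

  expect_error(anova_tukey_kramer(1:4, c("a", "a", "a", "b")),
               ">= 2 samples")
})

test_that("MFA balances variable groups by first-eigenvalue weighting", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))

  # one group: global axes equal that group's standardized PCA axes
  m1 <- mfa(list(only = x))
  p1 <- pfw_pca(x, scale = TRUE)
  expect_equal(abs(cor(m1$scores[, 1], p1$scores[, 1])), 1,
               tolerance = 1e-10)
  expect_equal(m1$explained_variance, p1$explained_variance,
               tolerance = 1e-10)
  expect_equal(unname(m1$group_weights),
               1 / (p1$sdev[1]^2), tolerance = 1e-10)

  # duplicating a group gives both copies equal weight, axes unchanged
  m2 <- mfa(list(a = x, b = x))
  expect_equal(unname(m2$group_weights[1]), unname(m2$group_weights[2]))
  expect_equal(abs(cor(m2$scores[, 1], m1$scores[, 1])), 1,
               tolerance = 1e-10)

  # two orthogonal one-variable groups contribute equally after weighting
  set.seed(6)
  u <- rnorm(200)
  w <- rnorm(200) * 50       # much larger raw variance
  u <- u - mean(u); w <- w - mean(w)
  w <- w - u * sum(w * u) / sum(u * u)   # exactly orthogonal
  m3 <- mfa(list(g1 = cbind(p = u), g2 = cbind(q = w)))
  expect_equal(m3$explained_variance, c(0.5, 0.5), tolerance = 1e-10)

  expect_error(mfa(list(a = cbind(x, const = 1))), "zero-variance")
  expect_error(mfa(list(a = x, b = x[1:5, ])), "same samples")
  expect_error(mfa(list(x)), "name")

  # dimension correlations carry a significance call
  expect_true(all(c("correlation", "p_value", "significant") %in%
                    names(m1$dimension_correlations)))
})

test_that("MANOVA separates planted centroids at the study sample sizes", {
  # power with distinct centroids separated by 2 within-group SDs
  reps <- 120
  p <- 7
  sizes <- c(5, 5, 15, 15)
  shift <- c(0, 2, 4, 6)   # group means in within-group SD units
  reject <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(2000 + r)
    x <- do.call(rbind, lapply(seq_along(sizes), function(i) {
      m <- matrix(rnorm(sizes[i] * p), sizes[i], p)
      m[, 1] <- m[, 1] + shift[i]
      m
    }))
    g <- rep(paste0("g", seq_along(sizes)), sizes)
    reject[r] <- manova_pillai(x, g)$p_value < 0.05
  }
  expect_gt(mean(reject), 0.95)
})
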