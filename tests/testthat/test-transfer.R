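test_that("balanced resampling is reproducible and draws input elements", {
  spec <- bootstrap_spec(n_draws = 500, seed = 99)
  expect_true(all(bootstrap_balance(c(2, 2, 2), spec) == 2))
  d1 <- bootstrap_balance(1:10, spec)
  d2 <- bootstrap_balance(1:10, spec)
  expect_identical(d1, d2)
  expect_true(all(d1 %in% 1:10))
  d3 <- bootstrap_balance(1:10, bootstrap_spec(500, seed = 100))
  expect_false(identical(d1, d3))
  expect_error(bootstrap_balance(numeric(0), spec), "empty")
  expect_error(bootstrap_spec(n_draws = 0), "n_draws")

  # law of large numbers: resample mean tracks the sample mean
  v <- rlnorm(15, 0, 0.5)
  means <- vapply(1:50, function(s)
    mean(bootstrap_balance(v, bootstrap_spec(1000, seed = s))), 0)
  expect_lt(abs(mean(means) - mean(v)),
            3 * sd(v) / sqrt(50 * 1000))
})

test_that("transfer factors behave like ratio-of-mean estimators", {
  spec <- bootstrap_spec(n_draws = 1000, seed = 3, n_boot = 100)
  v <- rlnorm(15, 1, 0.4)

  self <- transfer_factor(v, v, spec = spec)
  expect_equal(self$point_estimate, 1, tolerance = 0.05)
  expect_true(self$interval_2_5 <= self$bootstrap_mean + 1e-9)
  expect_true(self$bootstrap_mean <= self$interval_97_5 + 1e-9)

  # scale equivariance: numerator scaled by k scales the estimate by k
  a <- transfer_factor(v, v, spec = spec)
  b <- transfer_factor(3 * v, v, spec = spec)
  expect_equal(b$point_estimate, 3 * a$point_estimate, tolerance = 1e-12)

  # reciprocity within Monte-Carlo noise
  w <- rlnorm(10, 0, 0.4)
  ab <- transfer_factor(v, w, spec = spec)$point_estimate
  ba <- transfer_factor(w, v, spec = spec)$point_estimate
  expect_equal(ab * ba, 1, tolerance = 0.05)

  # degenerate constant inputs reproduce published ratio spot checks
  pfos <- transfer_factor(rep(29.18, 15), rep(0.006, 6), spec = spec)
  expect_equal(pfos$point_estimate, 29.18 / 0.006, tolerance = 1e-12)
  gi_ai <- transfer_factor(rep(9.6, 15), rep(1.46, 5), spec = spec)
  expect_equal(gi_ai$point_estimate, 6.575, tolerance = 1e-3)

  # not-computable contracts
  empty <- transfer_factor(numeric(0), v, spec = spec)
  expect_equal(empty$status, "not_computable")
  expect_match(empty$reason, "numerator")
  zero <- transfer_factor(v, rep(0, 5), spec = spec)
  expect_equal(zero$reason, "zero denominator")
})

test_that("the transfer matrix is seed-stable and order-independent", {
  ds <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      mk_meas(paste0("a", i), "aquatic_invertebrates", "PFOS", 1 + i / 10))),
    do.call(rbind, lapply(1:5, function(i)
      mk_meas(paste0("a", i), "aquatic_invertebrates", "PFDA", 0.1))),
    do.call(rbind, lapply(1:6, function(i)
      mk_meas(paste0("w", i), "surface_water", "PFOS", 0.006))),
    do.call(rbind, lapply(1:6, function(i)
      mk_meas(paste0("w", i), "surface_water", "PFDA", 0.001))))
  pairs <- data.frame(factor_kind = "BAF",
                      numerator = "aquatic_invertebrates",
                      denominator = "surface_water")
  spec <- bootstrap_spec(500, seed = 5, n_boot = 50)
  m1 <- transfer_matrix(ds, pairs, c("PFOS", "PFDA"), spec)
  m2 <- transfer_matrix(ds, pairs, c("PFDA", "PFOS"), spec)
  for (cg in c("PFOS", "PFDA"))
    expect_equal(m1[m1$congener == cg, ], m2[m2$congener == cg, ],
                 ignore_attr = TRUE)
  expect_identical(m1, transfer_matrix(ds, pairs, c("PFOS", "PFDA"), spec))
  expect_equal(nrow(transfer_matrix(ds, pairs, "PFOS", spec)), 1L)
  # a congener absent from one side is not computable with a named reason
  m3 <- transfer_matrix(ds, pairs, c("PFOS", "PFNA"), spec)
  expect_equal(m3$status[m3$congener == "PFNA"], "not_computable")
  expect_error(transfer_matrix(ds, data.frame(factor_kind = "BAF",
                                              numerator = "liver",
                                              denominator = "soil"),
                               "PFOS", spec), "unknown compartment")
})

test_that("bootstrap intervals cover the true ratio at ~95%", {
  # parameter-recovery property at the study's n = 15 vs 15
  reps <- 200
  true_ratio <- 5
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    den <- rlnorm(15, 0, log(1.6))
    num <- rlnorm(15, log(true_ratio), log(1.6))
    tf <- transfer_factor(num, den,
                          spec = bootstrap_spec(1000, seed = r,
                                                n_boot = 200))
    covered[r] <- tf$interval_2_5 <= true_ratio &&
      true_ratio <= tf$interval_97_5
  }
  expect_gt(mean(covered), 0.85)
  expect_lt(mean(covered), 0.999)
})

test_that("classification is strict at 1 and needs a computed factor", {
  tf <- transfer_factor(rep(6.58, 5), rep(1, 5),
                        spec = bootstrap_spec(100, 1, n_boot = 10))
  expect_true(classify_transfer(tf))
  tf$point_estimate <- 1
  expect_false(classify_transfer(tf))
  tf$point_estimate <- 0.73
  expect_false(classify_transfer(tf))
  nc <- transfer_factor(numeric(0), 1:3,
                        spec = bootstrap_spec(100, 1, n_boot = 10))
  expect_error(classify_transfer(nc), "not_computable")
})

test_that("rendered tables use the dash sentinel only", {
  ds <- rbind(mk_meas("a1", "liver", "PFOS", 29),
              mk_meas("a2", "liver", "PFOS", 30),
              mk_meas("w1", "surface_water", "PFOS", 0.006),
              mk_meas("w2", "surface_water", "PFOS", 0.006))
  pairs <- data.frame(factor_kind = "BAF", numerator = "liver",
                      denominator = "surface_water")
  tfm <- transfer_matrix(ds, pairs, c("PFOS", "PFNA"),
                         bootstrap_spec(200, 2, n_boot = 20))
  tab <- format_transfer_table(tfm)
  expect_equal(tab$PFNA, "-")
  expect_false(tab$PFOS == "-")
})
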