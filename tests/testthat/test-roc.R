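test_that("ROC curve handles separation, mixing and pure ties", {
  r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  r2 <- roc_curve(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r2$auc, 0.75)  # 3 concordant of 4 pairs
  r3 <- roc_curve(rep(2, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(r3$auc, 0.5)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both outcome classes")
  # rates are non-increasing in threshold, within [0, 1]
  set.seed(30)
  v <- rnorm(60); l <- runif(60) < 0.3
  r4 <- roc_curve(v, l)
  expect_true(all(diff(r4$tpr) <= 0) && all(diff(r4$fpr) <= 0))
  expect_true(all(r4$tpr >= 0 & r4$tpr <= 1 & r4$fpr >= 0 & r4$fpr <= 1))
})

test_that("trapezoidal AUC equals Mann-Whitney concordance", {
  set.seed(31)
  for (rep in 1:50) {
    n1 <- sample(3:20, 1); n0 <- sample(3:40, 1)
    v <- c(rnorm(n1, 0.5), rnorm(n0))
    if (rep %% 2 == 0) v <- round(v)  # force ties half the time
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    curve <- roc_curve(v, labels)
    u <- mann_whitney_u(v[labels], v[!labels])$statistic
    expect_equal(curve$auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("optimal operating point: examples and exhaustive minimality", {
  # perfect separation attains the ideal corner
  r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  o <- optimal_operating_point(r)
  expect_equal(o$critical_value, 3)
  expect_equal(c(o$tpr, o$fpr, o$distance), c(1, 0, 0))

  # distance tie resolved toward smaller FPR (more specific constraint)
  r2 <- roc_curve(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  o2 <- optimal_operating_point(r2)
  expect_equal(o2$critical_value, 4)
  expect_equal(o2$tpr, 0.5)
  expect_equal(o2$fpr, 0)

  set.seed(32)
  for (rep in 1:20) {
    v <- rnorm(40); l <- runif(40) < 0.35
    if (sum(l) == 0 || all(l)) next
    curve <- roc_curve(v, l)
    o3 <- optimal_operating_point(curve)
    d <- sqrt((1 - curve$tpr)^2 + curve$fpr^2)
    expect_lte(o3$distance, min(d) + 1e-12)
  }
})

test_that("critical_volume is deterministic and respects degenerate reps", {
  set.seed(33)
  v <- c(rnorm(8, 2), rnorm(40)); l <- rep(c(TRUE, FALSE), c(8, 40))
  a <- critical_volume(v, l, bootstrap_spec(50, seed = 4), "v40")
  b <- critical_volume(v, l, bootstrap_spec(50, seed = 4), "v40")
  expect_identical(a, b)
  expect_lte(a$ci_low, a$ci_high)
  # tpr/fpr consistent with the curve at the critical value
  expect_equal(a$tpr_at, mean(v[l] >= a$critical_value))
  expect_equal(a$fpr_at, mean(v[!l] >= a$critical_value))
})

test_that("bootstrap n_reps = 1 with identity strata returns the point", {
  d <- data.frame(x = rnorm(20))
  bt <- bootstrap_ci(function(d) mean(d$x), d,
                     bootstrap_spec(n_reps = 1, seed = 2),
                     strata = seq_len(20))
  expect_equal(unname(bt$ci_low), unname(bt$point))
  expect_equal(unname(bt$ci_high), unname(bt$point))
})

test_that("bootstrap is seeded, stratified and rejects starved resamples", {
  set.seed(34)
  d <- data.frame(x = rnorm(60),
                  modality = rep(c("photon", "proton"), each = 30),
                  orn = rep(c(TRUE, FALSE, TRUE, FALSE), c(6, 24, 4, 26)))
  spec <- bootstrap_spec(100, seed = 11)
  b1 <- bootstrap_ci(function(d) mean(d$x), d, spec)
  b2 <- bootstrap_ci(function(d) mean(d$x), d, spec)
  expect_identical(b1, b2)
  # constant statistic -> zero-width CI
  bc <- bootstrap_ci(function(d) 3.5, d, spec)
  expect_equal(unname(c(bc$ci_low, bc$ci_high)), c(3.5, 3.5))
  # modality x outcome stratification preserves group and event counts
  bt <- bootstrap_ci(function(d)
    c(ev_ph = sum(d$orn[d$modality == "photon"]),
      ev_pr = sum(d$orn[d$modality == "proton"]),
      n = nrow(d)), d, spec)
  expect_equal(unname(bt$ci_low), unname(bt$ci_high))
  expect_equal(unname(bt$point), c(6, 4, 60))
  # plain modality stratification with an unreachable event floor must
  # abort via the rejection rule
  spec2 <- bootstrap_spec(20, seed = 12, stratification = "modality",
                          min_cases = 20)
  expect_error(bootstrap_ci(function(d) mean(d$x), d, spec2),
               "rejection rate")
})

test_that("bootstrap percentile CI attains nominal-range coverage", {
  # mean of n = 100 known-normal draws; scaled-down replication count
  # (300 reps x 120 outer; see ledger), coverage within [90%, 99%]
  n_outer <- 120L
  covered <- 0L
  for (k in seq_len(n_outer)) {
    set.seed(6000 + k)
    d <- data.frame(x = rnorm(100, mean = 1.5, sd = 2))
    bt <- bootstrap_ci(function(d) mean(d$x), d,
                       bootstrap_spec(300, seed = k))
    covered <- covered + (bt$ci_low <= 1.5 && 1.5 <= bt$ci_high)
  }
  expect_gte(covered / n_outer, 0.90)
  expect_lte(covered / n_outer, 0.99)
})
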