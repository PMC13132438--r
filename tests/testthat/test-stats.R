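test_that("bh_fdr matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "pb_input_error")
})

test_that("bh_fdr equals brute-force step-up (property)", {
  brute <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(1, min(vapply(i:m, function(j) p[o[j]] * m / j, 0)))
    }
    q
  }
  set.seed(13)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute(p), tolerance = 1e-12)
  }
})

test_that("logistic OR: contingency identity, null and planted recovery", {
  # binary 2x2 a=10,b=40 / c=5,d=45: OR = (10*45)/(40*5) = 2.25
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 10), rep(0, 40), rep(1, 5), rep(0, 45))
  row <- logistic_or_per_sd(x, y)
  expect_equal(row$or, 2.25, tolerance = 1e-6)
  expect_equal(row$scaling, "binary")
  # null
  nulld <- gen_cohort(cohort_sim_params(n = 2000, or_per_sd = c(f = 1),
                                        seed = 8))
  expect_true(logistic_or_per_sd(nulld$f, nulld$death)$or > 0.9 &&
                logistic_or_per_sd(nulld$f, nulld$death)$or < 1.1)
  # planted per-SD effect
  eff <- gen_cohort(cohort_sim_params(n = 2000, or_per_sd = c(f = 2),
                                      seed = 9))
  r <- logistic_or_per_sd(eff$f, eff$death)
  expect_true(r$or > 1.8 && r$or < 2.2)
  expect_equal(r$scaling, "per-SD")
  # separation flags the caller towards Firth
  xs <- c(rep(0, 20), rep(1, 20)); ys <- c(rep(0, 20), rep(1, 20))
  expect_equal(logistic_or_per_sd(xs, ys)$status,
               "non_convergence_consider_firth")
})

test_that("firth_logistic: Haldane 2x2 identity and finiteness", {
  # cells a=0,b=10 (exposed), c=5,d=5: Firth = +0.5-corrected cross-product
  x <- c(rep(1, 10), rep(0, 10))
  y <- c(rep(1, 0), rep(0, 10), rep(1, 5), rep(0, 5))
  f <- firth_logistic(cbind(x = x), y)
  expect_true(f$converged)
  expect_equal(unname(f$or["x"]), (0.5 * 5.5) / (10.5 * 5.5),
               tolerance = 1e-4)
  # balanced null
  xb <- rep(c(0, 1), 50); yb <- rep(c(0, 1, 1, 0), 25)
  fb <- firth_logistic(cbind(x = xb), yb)
  expect_lt(abs(fb$coef["x"]), 0.1)
  # complete separation still yields a finite estimate
  xs <- c(rep(0, 15), rep(1, 15)); ys <- c(rep(0, 15), rep(1, 15))
  fs <- firth_logistic(cbind(x = xs), ys)
  expect_true(all(is.finite(fs$coef)))
  expect_error(firth_logistic(cbind(x = xs, x2 = xs), ys),
               class = "pb_input_error")
})

test_that("firth matches grid maximisation of the penalised likelihood", {
  pen_ll <- function(b0, b1, x, y) {
    eta <- b0 + b1 * x
    p <- plogis(eta)
    w <- p * (1 - p)
    X <- cbind(1, x)
    info <- t(X * w) %*% X
    sum(y * eta - log1p(exp(eta))) + 0.5 * log(det(info))
  }
  set.seed(17)
  for (rep in 1:5) {
    a <- sample(0:8, 1); b <- sample(1:10, 1)
    cc <- sample(1:10, 1); d <- sample(1:10, 1)
    x <- c(rep(1, a + b), rep(0, cc + d))
    y <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
    f <- firth_logistic(cbind(x = x), y)
    # profile the slope on a grid, maximising over the intercept
    grid <- seq(f$coef["x"] - 1, f$coef["x"] + 1, by = 0.001)
    prof <- vapply(grid, function(b1) {
      stats::optimize(function(b0) pen_ll(b0, b1, x, y),
                      c(-10, 10), maximum = TRUE)$objective
    }, 0)
    expect_lt(abs(grid[which.max(prof)] - f$coef["x"]), 1e-3 + 1e-4)
  }
})

test_that("random-intercept LMM: balanced identity and degenerate cases", {
  # balanced design, zero random variance: beta equals the difference of
  # group means of patient means (on the standardised response)
  set.seed(19)
  pat <- rep(1:8, each = 10)
  out <- rep(rep(c(0, 1), each = 4), each = 10)
  y <- rnorm(80)
  res <- lmm_random_intercept(data.frame(f = y), out, pat)
  ys <- as.numeric(scale(y))
  pm <- tapply(ys, pat, mean)
  po <- tapply(out, pat, unique)
  expected <- mean(pm[po == 1]) - mean(pm[po == 0])
  expect_equal(res$table$beta, expected, tolerance = 1e-6)
  expect_equal(res$n_patients, 8)
  expect_equal(res$n_beats, 80)
  # constant response collapses to zero
  resc <- lmm_random_intercept(data.frame(f = rep(1, 80)), out, pat)
  expect_equal(resc$table$beta, 0)
  expect_equal(resc$table$var_intercept, 0)
  # single patient in a group is degenerate
  expect_error(
    lmm_random_intercept(data.frame(f = y), rep(c(0, 1), c(70, 10)), pat),
    class = "pb_degenerate_design")
})

test_that("pointwise permutation: exactness, trivia and reproducibility", {
  set.seed(23)
  tm <- matrix(rnorm(8 * 5), 8, 5)
  lab <- rep(c(0, 1), each = 4)
  # identical group means at a timepoint give p = 1
  tm[, 3] <- rep(c(1, 2, 3, 4), 2)   # same values per group -> delta = 0
  pr <- pointwise_permutation(tm, lab, n_perm = 1000, seed = 1)
  expect_true(pr$exhaustive)      # choose(8,4) = 70 <= 1000
  expect_equal(pr$delta_obs[3], 0)
  expect_equal(pr$p[3], 1)
  expect_true(all(pr$p >= 1 / 70 & pr$p <= 1))
  expect_true(all(pr$q >= pr$p - 1e-12))
  # a planted extreme difference attains the minimum achievable p
  tm2 <- matrix(rnorm(30 * 4, sd = 0.01), 30, 4)
  lab2 <- rep(c(0, 1), each = 15)
  tm2[lab2 == 1, 2] <- tm2[lab2 == 1, 2] + 0.2
  pr2 <- pointwise_permutation(tm2, lab2, n_perm = 999, seed = 2)
  expect_false(pr2$exhaustive)
  expect_equal(pr2$p[2], 1 / 1000)
  # label flip only flips the sign of delta
  pr3 <- pointwise_permutation(tm2, 1 - lab2, n_perm = 999, seed = 2)
  expect_equal(pr3$delta_obs, -pr2$delta_obs)
  expect_equal(pr3$p, pr2$p)
  # seeded reproducibility
  expect_identical(pointwise_permutation(tm2, lab2, n_perm = 99, seed = 7),
                   pointwise_permutation(tm2, lab2, n_perm = 99, seed = 7))
  expect_error(pointwise_permutation(tm, rep(1, 8)), class = "pb_input_error")
})

test_that("rank_compare: U, p and rank-biserial conventions", {
  rc <- rank_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rc$u, 0)
  expect_equal(rc$r, 1)
  expect_equal(rc$method, "exact")
  rc2 <- rank_compare(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rc2$r, -1)
  x <- rnorm(30)
  expect_equal(rank_compare(x, x)$r, 0)
})

test_that("table_one picks tests by distribution and sparsity", {
  set.seed(29)
  df <- data.frame(
    death = rep(c(0, 1), c(102, 19)),
    age = c(rnorm(102, 66, 12), rnorm(19, 66, 12)),
    skewed = rexp(121),
    rare = rep(c(0, 1), c(118, 3)),
    konst = rep(2.5, 121)
  )
  t1 <- table_one(df, "death")
  expect_equal(t1$p[t1$variable == "konst"], 1)
  expect_equal(t1$test[t1$variable == "rare"], "Fisher")  # zero/low cells
  expect_equal(t1$test[t1$variable == "skewed"], "Mann-Whitney")
  expect_error(table_one(df, "konst"), class = "pb_input_error")
})
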