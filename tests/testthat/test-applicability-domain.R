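test_that("leverage matches the explicit 1x1 Gram arithmetic", {
  ad <- suppressWarnings(fit_ad(matrix(c(1, 2), ncol = 1)))
  expect_equal(leverage(1, ad), 0.2)     # 1 * (1/5) * 1
  expect_equal(leverage(2, ad), 0.8)
  expect_equal(leverage(3, ad), 1.8)
  expect_equal(leverage(0, ad), 0)
  expect_error(leverage(c(1, 2), ad), "features")
})

test_that("orthonormal training rows have leverage one (hat matrix = identity)", {
  ad <- fit_ad(diag(2))
  expect_equal(unname(leverage(c(1, 0), ad)), 1)
  expect_equal(unname(leverage(c(0, 1), ad)), 1)
})

test_that("leverage agrees with brute-force Gram inversion and trace(H) = rank(X)", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:50, 1); p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    ad <- fit_ad(X)
    h_brute <- diag(X %*% solve(crossprod(X)) %*% t(X))
    expect_equal(unname(ad$training_leverages), h_brute, tolerance = 1e-10)
    expect_true(all(ad$training_leverages >= -1e-12 & ad$training_leverages <= 1 + 1e-12))
    expect_equal(sum(ad$training_leverages), p, tolerance = 1e-8)
  }
  # rank-deficient: a duplicated column, pseudo-inverse path
  X <- matrix(rnorm(40), 20, 2); X <- cbind(X, X[, 1])
  ad <- suppressWarnings(fit_ad(X))
  expect_equal(sum(ad$training_leverages), 2, tolerance = 1e-8)
})

test_that("rescaling a feature and the query together leaves leverage unchanged", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  x <- rnorm(3)
  ad <- fit_ad(X)
  for (c_ in c(0.1, 7, -3)) {
    Xs <- X; Xs[, 2] <- Xs[, 2] * c_
    xs <- x; xs[2] <- xs[2] * c_
    expect_equal(unname(leverage(xs, fit_ad(Xs))), unname(leverage(x, ad)),
                 tolerance = 1e-8)
  }
})

test_that("leave-one-out leverages match closed forms", {
  # identical unit rows: every LOO leverage is 1/(n-1)
  lt <- loo_threshold(matrix(1, 4, 1))
  expect_equal(lt$loo_leverages, rep(1 / 3, 4))
  expect_equal(lt$h_star, 1 / 3)
  # two points: each evaluated against only the other
  lt2 <- loo_threshold(matrix(c(1, 2), ncol = 1))
  expect_equal(lt2$loo_leverages, c(1 / 4, 4))   # 1/2^2 and 4/1^2
  # Sherman-Morrison path equals direct removal on a general design
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3)
  lt3 <- loo_threshold(X)
  direct <- vapply(1:20, function(i) {
    drop(X[i, ] %*% solve(crossprod(X[-i, ])) %*% X[i, ])
  }, 0)
  expect_equal(lt3$loo_leverages, direct, tolerance = 1e-8)
})

test_that("about 5% of training rows exceed the 95th LOO percentile", {
  set.seed(31)
  X <- matrix(rnorm(500 * 5), 500, 5)
  ad <- fit_ad(X)
  frac_loo <- mean(ad$loo_leverages > ad$h_star)
  expect_gte(frac_loo, 0.03)
  expect_lte(frac_loo, 0.07)
})

test_that("the in-domain boundary is inclusive", {
  ad <- fit_ad(matrix(1, 4, 1))          # h* = 1/3, Gram inverse = 1/4
  # a query sitting exactly at the threshold is inside
  q0 <- in_domain(1.2, ad)
  ad_tied <- ad
  ad_tied$h_star <- q0$leverage
  expect_true(in_domain(1.2, ad_tied)$in_domain)
  expect_false(in_domain(1.2 + 1e-9, ad_tied)$in_domain)
  expect_false(in_domain(10, ad)$in_domain)
  # a central point of a centered design is deep inside
  set.seed(2)
  X <- scale(matrix(rnorm(200), 50, 4), scale = FALSE)
  adc <- fit_ad(X)
  expect_true(in_domain(rep(0, 4), adc)$in_domain)
})

test_that("tidy and glance expose the leverage distribution and threshold", {
  X <- matrix(rnorm(100), 25, 4)
  ad <- fit_ad(X)
  expect_equal(nrow(tidy(ad)), 25)
  g <- glance(ad)
  expect_equal(g$n, 25)
  expect_equal(g$p, 4)
  expect_equal(g$h_star, ad$h_star)
})
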