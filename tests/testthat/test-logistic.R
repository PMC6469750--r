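test_that("logistic evaluation matches closed-form landmarks", {
  p <- ref_params()
  # symmetric curve passes through the mean of the asymptotes at xmid
  expect_equal(logistic(p$xmid, p), (p$a + p$d) / 2, tolerance = 1e-12)
  expect_equal(logistic(log(1300), p), 1.595, tolerance = 1e-12)
  # asymptote reached far from the midpoint
  expect_lt(abs(logistic(p$xmid + 50 * p$scal, p) - p$d), 1e-12)
  expect_lt(abs(logistic(p$xmid - 50 * p$scal, p) - p$a), 1e-12)
})

test_that("5PL with g = 1 coincides with the 4PL pointwise", {
  p4 <- curve_params(0.1, 2.9, 5, 0.8, g = 1)
  x <- seq(p4$xmid - 10, p4$xmid + 10, length.out = 500)
  y5 <- p4$a + (p4$d - p4$a) / (1 + exp((p4$xmid - x) / p4$scal))^1
  expect_lt(max(abs(logistic(x, p4) - y5)), 1e-12)
})

test_that("forward/inverse roundtrip is exact to 1e-9 across the range", {
  for (p in list(ref_params(), curve_params(0.2, 2.5, 6, -0.9, g = 2.5))) {
    x <- seq(p$xmid - 6 * abs(p$scal), p$xmid + 6 * abs(p$scal),
             length.out = 1000)
    y <- logistic(x, p)
    expect_lt(max(abs(inverse_logistic(y, p) - x)), 1e-9)
  }
})

test_that("inverse at half-height returns xmid and OD 0.686 inverts to ~484 pg/mL", {
  p <- ref_params()
  expect_equal(inverse_logistic((p$a + p$d) / 2, p), p$xmid,
               tolerance = 1e-12)
  # independent oracle: bisection on the forward curve over (1, 1e6) pg/mL
  lo <- 1; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (logistic(log(mid), p) < 0.686) lo <- mid else hi <- mid
  }
  conc <- exp(inverse_logistic(0.686, p))
  expect_equal(conc, lo, tolerance = 1e-9)
  expect_equal(conc, 484.0611736, tolerance = 1e-6)
})

test_that("ODs at or beyond the asymptotes are rejected with a tagged side", {
  p <- ref_params()
  err <- expect_error(inverse_logistic(p$d, p),
                      class = "elisashift_range_error")
  expect_identical(err$side, "above_range")
  err <- expect_error(inverse_logistic(p$a - 0.5, p),
                      class = "elisashift_range_error")
  expect_identical(err$side, "below_range")
})

test_that("the curve is strictly monotone for random parameter draws", {
  set.seed(101)
  for (i in 1:25) {
    p <- curve_params(a = runif(1, -0.2, 0.5),
                      d = runif(1, 1.5, 3.5),
                      xmid = runif(1, 4, 9),
                      scal = runif(1, 0.3, 1.5),
                      g = exp(runif(1, log(0.3), log(3))))
    x <- sort(runif(200, p$xmid - 5, p$xmid + 5))
    expect_true(all(diff(logistic(x, p)) > 0))
  }
})

test_that("self-start heuristic follows the stated rules and flags degenerate input", {
  std <- noiseless_standards(ref_params())
  p0 <- initial_params(std)
  rng <- max(std$od) - min(std$od)
  expect_equal(p0$a, min(std$od) - 0.05 * rng)
  expect_equal(p0$d, max(std$od) + 0.05 * rng)
  expect_gt(p0$scal, 0)
  expect_equal(p0$g, 1)
  # decreasing data flips the slope sign
  dec <- data.frame(x = std$x, od = logistic(std$x,
    curve_params(3.2, -0.01, log(1300), 1 / 1.3)))
  expect_lt(initial_params(dec)$scal, 0)
  expect_error(initial_params(std[std$x %in% unique(std$x)[1:3], ]),
               class = "elisashift_precondition_error")
  flat <- data.frame(x = log(c(10, 20, 40, 80)), od = rep(1, 4))
  expect_error(initial_params(flat), class = "elisashift_degenerate_error")
})

test_that("noiseless 4PL data are recovered to 1e-6 relative", {
  truth <- curve_params(0, 3.2, 7.17, 0.77, g = 1)
  std <- noiseless_standards(truth)
  fit <- fit_curve(std, "4pl")
  rel <- abs(unlist(fit$params) - unlist(truth)) /
    pmax(abs(unlist(truth)), 0.1)
  expect_lt(max(rel), 1e-6)
  expect_lt(fit$rss, 1e-16)
  expect_true(fit$converged)
})

test_that("a 5PL fit of symmetric data finds g near 1", {
  truth <- curve_params(0, 3.2, 7.17, 0.77, g = 1)
  fit <- fit_curve(noiseless_standards(truth), "5pl")
  expect_lt(abs(fit$params$g - 1), 1e-3)
})

test_that("noiseless parameter recovery holds across random parameter draws", {
  set.seed(2024)
  for (i in 1:100) {
    a <- runif(1, 0, 0.6)
    truth <- curve_params(a = a, d = a + runif(1, 0.5, 3),
                          xmid = runif(1, 4, 9),
                          scal = sample(c(-1, 1), 1) * runif(1, 0.4, 1.4),
                          g = 1)
    x <- truth$xmid + truth$scal * seq(-4, 4, length.out = 8)
    std <- data.frame(x = rep(x, each = 3))
    std$od <- logistic(std$x, truth)
    fit <- fit_curve(std, "4pl")
    rel <- abs(unlist(fit$params) - unlist(truth)) /
      pmax(abs(unlist(truth)), 0.1)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("fit_curve validates its inputs", {
  std <- noiseless_standards(ref_params())
  std$well <- paste0(rep(LETTERS[1:8], each = 3), rep(1:3, 8))
  bad <- std; bad$od[5] <- NaN
  err <- expect_error(fit_curve(bad, "4pl"), class = "elisashift_value_error")
  expect_match(conditionMessage(err), bad$well[5], fixed = TRUE)
  few <- std[std$x %in% unique(std$x)[1:4], ]
  expect_error(fit_curve(few, "5pl"), class = "elisashift_precondition_error")
  expect_s3_class(fit_curve(few, "4pl"), "curve_fit")
})

test_that("exponential-form mapping matches the plate-reader convention", {
  p <- ref_params()
  ep <- to_exp_form(p)
  expect_equal(ep$C, 1300, tolerance = 1e-12)
  expect_equal(ep$B, -1.30, tolerance = 1e-12)
  expect_equal(ep$A, p$a)
  expect_equal(ep$D, p$d)
  expect_error(from_exp_form(structure(list(A = 0, D = 3, C = -5, B = -1,
                                            g = 1),
                                       class = "exp_form_params")),
               class = "elisashift_value_error")
  set.seed(5)
  for (i in 1:20) {
    q <- curve_params(runif(1, -1, 1), runif(1, 2, 4), runif(1, 3, 9),
                      sample(c(-1, 1), 1) * runif(1, 0.2, 2),
                      exp(runif(1, -1, 1)))
    back <- from_exp_form(to_exp_form(q))
    expect_lt(max(abs(unlist(back) - unlist(q))), 1e-12)
  }
})
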