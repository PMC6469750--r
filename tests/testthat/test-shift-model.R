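test_that("the pooled reference fit recovers truth from many noiseless curves", {
  truth <- ref_params()
  spec <- sim_spec(true_params = truth, batch_shifts = c(lot1 = 0),
                   plates_per_batch = 28, od_noise_sd = 0, controls = NULL,
                   seed = 3)
  plates <- simulate_plates(spec)
  reference <- fit_reference(plates, "4pl")
  rel <- abs(unlist(unclass(reference)) - unlist(unclass(truth))) /
    pmax(abs(unlist(unclass(truth))), 0.1)
  expect_lt(max(rel), 1e-6)
  expect_identical(attr(reference, "n_curves"), 28L)
})

test_that("pooling over one plate equals a plain curve fit", {
  plates <- simulate_plates(small_spec(shifts = c(lot1 = 0), plates = 1,
                                       noise = 0.02, seed = 21))
  reference <- fit_reference(plates, "4pl")
  direct <- fit_curve(elisashift:::standard_wells(plates)[, c("x", "od")],
                      "4pl")
  expect_equal(unlist(unclass(reference)), unlist(direct$params),
               tolerance = 1e-10)
})

test_that("a batch drawn from the reference itself has S = 0", {
  truth <- ref_params()
  plates <- simulate_plates(sim_spec(true_params = truth,
                                     batch_shifts = c(b = 0),
                                     plates_per_batch = 1, od_noise_sd = 0,
                                     controls = NULL, seed = 4))
  s <- estimate_shift(plates, truth)
  expect_lt(abs(s$S), 1e-8)
})

test_that("relabelled standards shift S by exactly the log fold change, matching a grid oracle", {
  truth <- ref_params()
  plates <- simulate_plates(sim_spec(true_params = truth,
                                     batch_shifts = c(b = 0),
                                     plates_per_batch = 1, od_noise_sd = 0,
                                     controls = NULL, seed = 4))
  for (N in c(0.5, 2, 10)) {
    relab <- plates
    relab[[1]]$wells$conc <- relab[[1]]$wells$conc * N
    s <- estimate_shift(relab, truth)
    expect_lt(abs(s$S - log(N)), 1e-6)
    # independent oracle: brute-force grid refinement of the 1-D RSS
    std <- elisashift:::standard_wells(relab)
    lo <- -4; hi <- 4
    for (pass in 1:6) {
      grid <- seq(lo, hi, length.out = 101)
      rss <- vapply(grid, elisashift:::shift_rss, numeric(1), std = std,
                    reference = truth)
      i <- which.min(rss)
      lo <- grid[max(1, i - 1)]; hi <- grid[min(101, i + 1)]
    }
    expect_lt(abs(s$S - (lo + hi) / 2), 1e-5)
  }
})

test_that("noisy shift estimates land within 3 se of truth and 2 se covers ~95%", {
  truth <- ref_params()
  n_rep <- 500
  hits3 <- 0; hits2 <- 0
  set.seed(1)
  seeds <- sample.int(1e6, n_rep)
  for (r in seq_len(n_rep)) {
    plates <- simulate_plates(sim_spec(true_params = truth,
                                       batch_shifts = c(ref = 0, b = 0.70),
                                       plates_per_batch = 1,
                                       od_noise_sd = 0.02, controls = NULL,
                                       seed = seeds[r]))
    s <- estimate_shift(group_by_batch(plates)$b, truth)
    hits3 <- hits3 + (abs(s$S - 0.70) <= 3 * s$se_S)
    hits2 <- hits2 + (abs(s$S - 0.70) <= 2 * s$se_S)
  }
  expect_gte(hits3 / n_rep, 0.99)
  expect_gte(hits2 / n_rep, 0.90)
})

test_that("a batch entirely outside the reference asymptotes is rejected", {
  truth <- ref_params()
  plates <- simulate_plates(sim_spec(true_params = truth,
                                     batch_shifts = c(b = 0),
                                     plates_per_batch = 1, od_noise_sd = 0,
                                     controls = NULL, seed = 5))
  plates[[1]]$wells$od <- plates[[1]]$wells$od * 0 + 3.5  # above d
  expect_error(estimate_shift(plates, truth),
               class = "elisashift_estimation_error")
})

test_that("identical noiseless batches give all-zero shifts and exact shared parameters", {
  spec <- sim_spec(batch_shifts = c(lot1 = 0, lot2 = 0, lot3 = 0),
                   plates_per_batch = 2, od_noise_sd = 0, controls = NULL,
                   seed = 6)
  plates <- simulate_plates(spec)
  for (mode in c("fixed_reference", "joint")) {
    fit <- fit_shift_model(plates, "lot1", mode = mode)
    expect_lt(max(abs(fit$shifts$S)), 1e-8)
    rel <- abs(unlist(unclass(fit$reference)) -
                 unlist(unclass(spec$true_params))) /
      pmax(abs(unlist(unclass(spec$true_params))), 0.1)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("joint estimation recovers the lot structure within 0.05", {
  spec <- sim_spec(plates_per_batch = 4, od_noise_sd = 0.02,
                   controls = NULL, seed = 7)
  tab <- recovery_experiment(spec, mode = "joint")
  expect_lt(max(abs(tab$est_S - tab$true_S)), 0.05)
  expect_identical(tab$est_S[1], 0)
})

test_that("joint and fixed-reference modes agree in the noiseless limit", {
  spec <- sim_spec(batch_shifts = c(lot1 = 0, lot2 = 0.3, lot3 = -0.4),
                   plates_per_batch = 2, od_noise_sd = 0, controls = NULL,
                   seed = 8)
  plates <- simulate_plates(spec)
  f1 <- fit_shift_model(plates, "lot1", mode = "fixed_reference")
  f2 <- fit_shift_model(plates, "lot1", mode = "joint")
  expect_lt(max(abs(f1$shifts$S - f2$shifts$S)), 1e-6)
})

test_that("the reference batch is pinned at exactly zero in every fit", {
  spec <- small_spec(noise = 0.02, seed = 12)
  plates <- simulate_plates(spec)
  for (mode in c("fixed_reference", "joint")) {
    fit <- fit_shift_model(plates, "lot1", mode = mode)
    expect_identical(fit$shifts$S[fit$shifts$batch == "lot1"], 0)
    expect_equal(fit$shifts$adjusted_xmid - fit$reference$xmid,
                 fit$shifts$S)
  }
})

test_that("shifting the gauge leaves fitted ODs unchanged", {
  spec <- small_spec(noise = 0.02, seed = 13)
  fit <- fit_shift_model(simulate_plates(spec), "lot1")
  delta <- 0.37
  moved <- fit
  moved$reference$xmid <- fit$reference$xmid + delta
  moved$shifts$S <- fit$shifts$S - delta
  expect_equal(fitted(moved), fitted(fit), tolerance = 1e-12)
})

test_that("the joint fit cannot beat unconstrained per-batch curves", {
  spec <- small_spec(noise = 0.03, seed = 14)
  plates <- simulate_plates(spec)
  fit <- fit_shift_model(plates, "lot1", mode = "joint")
  free_rss <- sum(vapply(group_by_batch(plates), function(pl)
    fit_curve(elisashift:::standard_wells(pl)[, c("x", "od")], "4pl")$rss, numeric(1)))
  expect_gte(fit$rss, free_rss - 1e-10)
})

test_that("batches with too few standard levels are named in the error", {
  spec <- small_spec(noise = 0, seed = 15)
  plates <- simulate_plates(spec)
  batches <- group_by_batch(plates)
  # cripple lot2: keep only 3 standard levels
  batches$lot2 <- structure(lapply(batches$lot2, function(p) {
    p$wells <- p$wells[p$wells$role != "standard" |
                         p$wells$conc > 1500, , drop = FALSE]
    p
  }), class = "elisa_plates")
  err <- expect_error(fit_joint(batches, "lot1"),
                      class = "elisashift_data_error")
  expect_match(conditionMessage(err), "lot2")
})

test_that("model persistence round-trips bit-exactly", {
  spec <- small_spec(noise = 0.02, seed = 16)
  fit <- fit_shift_model(simulate_plates(spec), "lot1")
  path <- withr::local_tempfile(fileext = ".txt")
  write_shift_model(fit, path)
  back <- read_shift_model(path)
  expect_identical(unlist(unclass(back$reference)),
                   unlist(unclass(fit$reference)))
  expect_identical(back$shifts$S, fit$shifts$S)
  expect_identical(back$shifts$se_S, fit$shifts$se_S)
  expect_identical(back$shifts$x_lo, fit$shifts$x_lo)
  expect_identical(back$rss, fit$rss)
  expect_identical(back$model, fit$model)
  expect_identical(back$mode, fit$mode)
  expect_identical(back$reference_batch, fit$reference_batch)
})

test_that("model methods expose coefficients, residuals and predictions coherently", {
  spec <- small_spec(noise = 0.02, seed = 17)
  fit <- fit_shift_model(simulate_plates(spec), "lot1")
  cf <- coef(fit)
  expect_true(all(c("a", "d", "xmid", "scal", "g", "S_lot2", "S_lot3") %in%
                    names(cf)))
  expect_equal(sum(residuals(fit)^2),
               sum((fit$data$od - fitted(fit))^2), tolerance = 1e-12)
  pr <- predict(fit, data.frame(od = 1.0, batch = "lot3"))
  expect_equal(pr$adjusted_conc, pr$raw_conc / exp(cf[["S_lot3"]]),
               tolerance = 1e-9)
  expect_error(predict(fit, data.frame(od = 1, batch = "nope")),
               class = "elisashift_lookup_error")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sims), c(nrow(fit$data), 2L))
  expect_output(print(summary(fit)), "Shift-factor model")
})
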