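test_that("beta-binomial estimation follows conjugate arithmetic", {
  # 30 January days, 15 above threshold, uniform prior: mean 16/32
  s <- data.frame(date = seq(as.Date("2020-01-01"), by = "day",
                             length.out = 30),
                  above = rep(c(1, 0), 15))
  est <- estimate_light_saturation_probability(s)
  expect_equal(est$mean[1], 16 / 32)
  expect_equal(est$n_days[1], 30L)
  expect_true(est$estimated[1])
  expect_false(any(est$estimated[2:12]))
  expect_true(all(is.na(est$mean[2:12])))
  expect_true(est$lower[1] <= est$mean[1] && est$mean[1] <= est$upper[1])

  s0 <- s
  s0$above <- 0
  est0 <- estimate_light_saturation_probability(s0)
  expect_equal(est0$mean[1], 1 / 32)
})

test_that("irradiance input requires a threshold and honours it", {
  s <- data.frame(date = seq(as.Date("2020-06-01"), by = "day",
                             length.out = 10),
                  irradiance = c(rep(8, 6), rep(2, 4)))
  expect_error(estimate_light_saturation_probability(s), "threshold")
  est <- estimate_light_saturation_probability(s, threshold = 5)
  expect_equal(est$n_above[6], 6L)
  expect_error(estimate_light_saturation_probability(rbind(s, s[1, ]),
                                                     threshold = 5),
               "unique")
})

test_that("monthly estimates recover generating probabilities and tighten with data", {
  p <- synth_light_climatology(0.6, 0.25, 1)
  d10 <- synth_daily_light(p, years = 10, seed = 1)
  e10 <- estimate_light_saturation_probability(d10)
  expect_true(all(abs(e10$mean - p) < 0.05))
  d1 <- synth_daily_light(p, years = 1, seed = 1)
  e1 <- estimate_light_saturation_probability(d1)
  expect_lt(mean(abs(e10$mean - p)), mean(abs(e1$mean - p)))
})

pop <- discretization_scheme("population")

test_that("observation conversion applies the Dirichlet-multinomial posterior mean", {
  obs <- data.frame(date = as.Date("2020-03-15"), value = c(90, 95, 85))
  oss <- observations_to_state_probabilities(obs, 100, pop)
  expect_equal(oss$high, 4 / 7)
  expect_equal(oss$zero, 1 / 7)
  expect_equal(oss$low + oss$moderate, 2 / 7)
  expect_equal(rowSums(oss[, c("zero", "low", "moderate", "high")]), 1)

  one <- observations_to_state_probabilities(
    data.frame(date = as.Date("2020-03-15"), value = 0), 100, pop)
  expect_equal(one$zero, 2 / 5)

  mixed <- data.frame(date = as.Date(c("2020-01-01", "2020-02-01")),
                      value = c(50, NA))
  oss2 <- observations_to_state_probabilities(mixed, 100, pop)
  expect_equal(nrow(oss2), 1L)
  expect_equal(attr(oss2, "excluded_dates"), as.Date("2020-02-01"))
  expect_error(observations_to_state_probabilities(obs, -5, pop), "positive")
})

mk_pred <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- c("zero", "low", "moderate", "high")
  structure(list(slice_index = seq_len(nrow(m)) - 1L,
                 month = rep(1:12, length.out = nrow(m)),
                 marginals = list(realised_shoot_density = m)),
            class = "dbn_trajectory")
}

test_that("validation MSE is zero at identity and matches hand arithmetic", {
  pred <- mk_pred(list(c(0.25, 0.25, 0.25, 0.25), c(1, 0, 0, 0)))
  obs_eq <- data.frame(slice = 0:1, zero = c(0.25, 1), low = c(0.25, 0),
                       moderate = c(0.25, 0), high = c(0.25, 0))
  r0 <- validation_mse(pred, obs_eq)
  expect_equal(r0$mse_all_states, 0)
  expect_equal(r0$mse_zero_state, 0)

  obs1 <- data.frame(slice = 1, zero = 0.5, low = 0.5, moderate = 0, high = 0)
  r1 <- validation_mse(pred, obs1)
  expect_equal(r1$mse_all_states, (0.25 + 0.25) / 4)
  expect_equal(r1$mse_zero_state, 0.25)

  expect_error(validation_mse(pred, obs1[, -2]), "zero")
  expect_error(validation_mse(pred, data.frame(slice = 99, zero = 1, low = 0,
                                               moderate = 0, high = 0)),
               "aligns")
})

test_that("validation MSE is symmetric in predicted and observed", {
  set.seed(8)
  a <- matrix(rgamma(8, 1), 2)
  a <- a / rowSums(a)
  b <- matrix(rgamma(8, 1), 2)
  b <- b / rowSums(b)
  pred_a <- mk_pred(list(a[1, ], a[2, ]))
  pred_b <- mk_pred(list(b[1, ], b[2, ]))
  obs_b <- data.frame(slice = 0:1, zero = b[, 1], low = b[, 2],
                      moderate = b[, 3], high = b[, 4])
  obs_a <- data.frame(slice = 0:1, zero = a[, 1], low = a[, 2],
                      moderate = a[, 3], high = a[, 4])
  expect_equal(validation_mse(pred_a, obs_b)$mse_all_states,
               validation_mse(pred_b, obs_a)$mse_all_states)
})

sens_results <- function() {
  if (is.null(.fx$sens)) {
    .fx$sens <- lapply(c(1, 4, 7, 10), function(m)
      fx_run("opportunistic", 6, month = m, windows = run_windows(12, 24)))
  }
  .fx$sens
}

test_that("influence weights normalize and reports are seed-deterministic", {
  rep1 <- sensitivity_influence(sens_results(), seed = 2)
  rep2 <- sensitivity_influence(sens_results(), seed = 2)
  expect_identical(rep1$responses, rep2$responses)
  for (r in rep1$responses) {
    if (isTRUE(r$skipped)) next
    expect_equal(sum(r$influence$weight), 1, tolerance = 1e-6)
    expect_true(all(r$influence$weight >= 0))
    expect_true(any(r$influence$top))
  }
  expect_error(sensitivity_influence(sens_results()[1]), "at least 2")
})

test_that("a pure-noise predictor ranks below the structural predictors", {
  res <- sens_results()
  set.seed(5)
  spiked <- lapply(res, function(r) {
    tr <- r$response_traj
    n <- length(tr$slice_index)
    noise <- matrix(runif(2 * n), n)
    noise <- noise / rowSums(noise)
    colnames(noise) <- c("off", "on")
    tr$marginals$spikein_noise <- noise
    tr
  })
  rep <- sensitivity_influence(spiked, seed = 2)
  inf <- rep$responses$realised_shoot_density.high$influence
  noise_w <- max(inf$weight[grepl("spikein_noise", inf$variable)])
  top_struct <- inf$weight[!grepl("spikein_noise", inf$variable)][1:5]
  expect_true(all(top_struct > noise_w))
})

test_that("the lagged response dominates in a persistence-dominated system", {
  # near-static fixture: a sticky autoregressive state node plus pure-noise
  # companions; the signal lives in the one-step lag
  set.seed(11)
  mk <- function() {
    n <- 60
    x <- numeric(n)
    x[1] <- 0.7
    for (t in 2:n) x[t] <- min(max(0.95 * x[t - 1] +
                                     rnorm(1, 0, 0.01), 0.02), 0.98)
    w <- runif(n)  # complement states split randomly so only the lagged
    resp <- cbind(low = (1 - x) * w, mid = (1 - x) * (1 - w), high = x)
    noise <- matrix(runif(2 * n), n)
    noise <- noise / rowSums(noise)
    colnames(noise) <- c("a", "b")
    structure(list(slice_index = seq_len(n) - 1L,
                   month = rep(1:12, length.out = n),
                   marginals = list(stock = resp, ambient = noise)),
              class = "dbn_trajectory")
  }
  trajs <- list(mk(), mk(), mk())
  rep <- sensitivity_influence(trajs, response_nodes = "stock", seed = 2)
  inf <- rep$responses$stock.high$influence
  expect_true("stock.high.lag1" %in% inf$variable[inf$top])
  expect_equal(inf$variable[1], "stock.high.lag1")
})

test_that("constant responses are flagged and skipped", {
  res <- sens_results()
  flat <- lapply(res, function(r) {
    tr <- r$response_traj
    n <- length(tr$slice_index)
    m <- matrix(rep(c(0.4, 0.6), each = n), n)
    colnames(m) <- c("a", "b")
    tr$marginals$flatnode <- m
    tr
  })
  rep <- sensitivity_influence(flat, response_nodes = "flatnode", seed = 2)
  expect_true(rep$responses$flatnode.a$skipped)
})

test_that("reference-value calibration selects the best-fitting scale", {
  res <- fx_run("opportunistic", 0, windows = run_windows(6, 6))
  tr <- res$baseline_traj
  # fabricate replicate observations consistent with a reference of 600
  set.seed(3)
  obs <- do.call(rbind, lapply(c(3, 6, 9), function(sl) {
    data.frame(date = as.Date("2021-01-01") + 31 * sl, slice = sl,
               value = runif(3, 350, 550))
  }))
  cal <- calibrate_reference_value(tr, obs, reference_value = 600,
                                   scales = c(0.5, 1, 2))
  expect_true(cal$scale %in% c(0.5, 1, 2))
  expect_s3_class(cal$report, "validation_report")
})
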