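test_that("the standard grid counts 108 scenarios per site", {
  site <- fx_site("colonising")
  scns <- enumerate_scenarios(site, paper_designs(), light_levels = 0,
                              include_control = TRUE)
  expect_length(scns, 108L)
})

test_that("grid counts follow the enumeration contract", {
  site <- fx_site("colonising")
  one <- enumerate_scenarios(site, list(dredge_design(3)), 0,
                             include_control = FALSE)
  expect_length(one, 12L)
  multi <- enumerate_scenarios(site, paper_designs(),
                               c(0, 0.25, 0.5, 0.75), TRUE)
  expect_length(multi, 8L * 12L * 4L + 12L)
  # deterministic (design, month, level) ordering
  expect_equal(multi[[1]]$design$label, "1-0")
  expect_equal(multi[[2]]$light_level, 0.25)
  expect_equal(multi[[5]]$start_month, 2L)
})

test_that("dredge designs enforce the admitted alternating patterns", {
  expect_error(dredge_design(6, 4), "6-3 and 6-2")
  expect_error(dredge_design(9, 3), "6-3 and 6-2")
  expect_error(dredge_design(5), "\\{1,2,3,6,9,12\\}")
  ctrl <- dredge_design(0)
  expect_true(ctrl$is_control)
  expect_equal(ctrl$total_dredge_months, 0L)
  labels <- vapply(paper_designs(), function(d) d$label, character(1))
  expect_equal(labels, c("1-0", "2-0", "3-0", "6-0", "6-3", "6-2",
                         "9-0", "12-0"))
})

test_that("alternating designs span rest months but dredge exactly 6", {
  p63 <- ecowindows:::stress_pattern(dredge_design(6, 3))
  expect_length(p63, 9L)
  expect_equal(sum(p63), 6L)
  expect_true(p63[1] && p63[9])  # starts and ends dredging
  p62 <- ecowindows:::stress_pattern(dredge_design(6, 2))
  expect_length(p62, 10L)
  expect_equal(sum(p62), 6L)
  p30 <- ecowindows:::stress_pattern(dredge_design(3))
  expect_equal(p30, rep(TRUE, 3))
})

test_that("the light stressor takes the minimum of baseline and level", {
  site <- fx_site("colonising")
  site$light_p <- c(0.8, 0.4, rep(0.6, 10))
  wins <- run_windows(2, 6)
  # dredging Jan-Feb at full deprivation
  s0 <- apply_stressor_to_light(site$light_p,
                                scenario(site, dredge_design(2), 1, 0), wins)
  expect_equal(s0$p_above[s0$stress_first + 1], 0)
  expect_equal(s0$p_above[s0$stress_last + 1], 0)
  # level 0.5 against baseline 0.4 keeps the baseline
  s5 <- apply_stressor_to_light(site$light_p,
                                scenario(site, dredge_design(1), 2, 0.5), wins)
  expect_equal(s5$p_above[s5$stress_first + 1], 0.4)
  # level 0.25 against baseline 0.8 caps at 0.25
  s25 <- apply_stressor_to_light(site$light_p,
                                 scenario(site, dredge_design(1), 1, 0.25),
                                 wins)
  expect_equal(s25$p_above[s25$stress_first + 1], 0.25)
  # initialisation slices always baseline
  expect_equal(s0$p_above[1:2], site$light_p[c(11, 12)])
})

test_that("stressed light is pointwise non-decreasing in the permitted level", {
  site <- fx_site("opportunistic")
  wins <- run_windows()
  prev <- NULL
  for (l in c(0, 0.25, 0.5, 0.75)) {
    s <- apply_stressor_to_light(site$light_p,
                                 scenario(site, dredge_design(6, 3), 4, l),
                                 wins)
    if (!is.null(prev)) expect_true(all(s$p_above >= prev - 1e-12))
    prev <- s$p_above
  }
})

test_that("shifting the start month shifts the stressed sequence seasonally", {
  site <- fx_site("opportunistic")
  wins <- run_windows(12, 12)
  s1 <- apply_stressor_to_light(site$light_p,
                                scenario(site, dredge_design(3), 2, 0), wins)
  s2 <- apply_stressor_to_light(site$light_p,
                                scenario(site, dredge_design(3), 5, 0), wins)
  expect_equal(s2$months, (s1$months + 3 - 1) %% 12 + 1)
  expect_equal(s2$stress_first, s1$stress_first)
})

test_that("control scenarios are light-invariant and identical to baseline", {
  res <- fx_run("persistent", 0)
  expect_identical(res$baseline_traj$marginals, res$response_traj$marginals)
  scn <- scenario(fx_site("persistent"), dredge_design(0), 3, 0.75)
  expect_true(is.na(scn$light_level))
})

test_that("baseline and stressed trajectories agree on initialisation slices", {
  res <- fx_run("colonising", 3, month = 5)
  init <- res$windows$initialisation_months
  for (nd in c("realised_shoot_density", "physiological_status")) {
    expect_equal(res$baseline_traj$marginals[[nd]][1:init, ],
                 res$response_traj$marginals[[nd]][1:init, ],
                 tolerance = 1e-12)
  }
})

test_that("full deprivation raises the zero-state probability during stress", {
  res <- fx_run("colonising", 3, month = 2)
  i <- res$stress_span["first"]:res$stress_span["last"] + 1L
  zb <- res$baseline_traj$marginals$realised_shoot_density[i, "zero"]
  zr <- res$response_traj$marginals$realised_shoot_density[i, "zero"]
  expect_true(all(zr > zb))
})

test_that("all marginals stay normalized at every slice of a stressed run", {
  res <- fx_run("opportunistic", 6, rest = 2, month = 9)
  for (tr in list(res$baseline_traj, res$response_traj))
    for (nd in names(tr$marginals))
      expect_true(all(abs(rowSums(tr$marginals[[nd]]) - 1) < 1e-9))
})

test_that("run_study streams resumable records and counts runs correctly", {
  site <- fx_site("persistent")
  bundles <- list(persistent = fx_bundle("persistent"))
  wins <- run_windows(6, 6)
  res <- run_study(list(site), bundles, list(dredge_design(1)),
                   light_levels = 0, windows = wins, include_control = FALSE)
  expect_length(res, 12L)

  out <- withr::local_tempdir()
  idx1 <- run_study(list(site), bundles, list(dredge_design(1)),
                    light_levels = 0, windows = wins,
                    include_control = FALSE, out_dir = out)
  expect_equal(sum(idx1$status == "done"), 12L)
  files1 <- lapply(idx1$file, readLines)
  idx2 <- run_study(list(site), bundles, list(dredge_design(1)),
                    light_levels = 0, windows = wins,
                    include_control = FALSE, out_dir = out)
  expect_equal(sum(idx2$status == "cached"), 12L)
  expect_identical(lapply(idx2$file, readLines), files1)
})
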