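test_that("the linguistic scale is strictly decreasing with 50/50 at 0.5", {
  s <- linguistic_scale()
  expect_length(s, 9L)
  expect_true(all(diff(s) < 0))
  expect_equal(s[["certainty"]], 1.0)
  expect_equal(s[["impossible"]], 0.0)
  expect_equal(s[["50/50"]], 0.5)
  bad <- unclass(linguistic_scale())
  bad["50/50"] <- 0.55
  expect_error(linguistic_scale(bad), "exactly 0.5")
  bad2 <- unclass(linguistic_scale())
  bad2["unlikely"] <- 0.9
  expect_error(linguistic_scale(bad2), "decreasing")
})

test_that("archetype ordering violations raise named errors", {
  p <- archetype_params("persistent", growth_rate = "certainty")
  expect_error(synth_site_archetype_cpts(p, seed = 1), "growth_rate")
  p2 <- archetype_params("colonising", resistance_strength = "certainty")
  expect_error(synth_site_archetype_cpts(p2, seed = 1), "resistance_strength")
})

test_that("light climatologies are sinusoidal, rotatable and reproducible", {
  flat <- synth_light_climatology(0.6, 0, 1)
  expect_equal(flat, rep(0.6, 12))
  p1 <- synth_light_climatology(0.6, 0.3, 1)
  p7 <- synth_light_climatology(0.6, 0.3, 7)
  expect_equal(p7, p1[c(7:12, 1:6)], tolerance = 1e-12)
  n1 <- synth_light_climatology(0.6, 0.3, 1, concentration = 40, seed = 9)
  n2 <- synth_light_climatology(0.6, 0.3, 1, concentration = 40, seed = 9)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
})

test_that("emitted daily series match their monthly probabilities at 10 years", {
  p <- synth_light_climatology(0.6, 0.25, 1)
  daily <- synth_daily_light(p, years = 10, seed = 1)
  month <- as.integer(format(daily$date, "%m"))
  freq <- tapply(daily$above, month, mean)
  expect_true(all(abs(freq - p) < 0.05))
  # irradiance column is consistent with the binary flag
  thr <- attr(daily, "threshold")
  expect_equal(as.integer(daily$irradiance > thr), daily$above)
})

test_that("bundles are deterministic given the seed", {
  b1 <- synth_site_archetype_cpts(archetype_params("opportunistic"), seed = 3)
  b2 <- synth_site_archetype_cpts(archetype_params("opportunistic"), seed = 3)
  expect_identical(b1, b2)
  b3 <- synth_site_archetype_cpts(archetype_params("opportunistic"), seed = 4)
  expect_false(identical(b1, b3))
})

test_that("a 50/50 elicitation yields an even split in a binary rule", {
  b <- synth_site_archetype_cpts(archetype_params("opportunistic"),
                                 seed = 1, jitter = 0)
  # opportunistic resistance is 50/50; at neutral physiology (middle state)
  # the resist rule carries no information
  tab <- b$ability_to_resist
  expect_equal(unname(tab$prob[2, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("stochastic dominance holds in every emitted ordinal table", {
  st <- ecowindows:::reference_states()
  checks <- list(
    list("physiological_status", "light", 1),
    list("physiological_status", "physiological_status@prev", 1),
    list("growth.growing", "light", 1),
    list("growth.growing", "physiological_status", 1),
    list("growth.senescent", "light", 1),
    list("growth.senescent", "physiological_status", 1),
    list("seed_density.seedset", "physiological_status", 1),
    list("seed_density.seedset", "seed_density@prev", 1),
    list("recruitment_from_seeds.germination", "seed_density", 1),
    list("recruitment_from_seeds.germination", "light", 1),
    list("ability_to_resist", "physiological_status", 1),
    list("ability_to_recover", "growth", 1),
    list("ability_to_recover", "recruitment_from_seeds", 1),
    list("loss", "ability_to_resist", -1),
    list("loss", "light", -1),
    list("loss", "physiological_status", -1),
    list("recovery", "ability_to_recover", 1),
    list("net_change", "recovery", 1),
    list("net_change", "loss", -1),
    list("realised_shoot_density", "net_change", 1),
    list("realised_shoot_density", "realised_shoot_density@prev", 1),
    list("realised_shoot_density", "baseline_population", 1),
    list("realised_biomass", "realised_shoot_density", 1),
    list("baseline_population.growing", "baseline_population@prev", 1),
    list("baseline_population.senescent", "baseline_population@prev", 1))
  for (lh in c("colonising", "opportunistic", "persistent")) {
    b <- fx_bundle(lh)
    for (chk in checks) {
      tab <- b[[chk[[1]]]]
      labs <- lapply(tab$parent_order, function(p)
        st[[ecowindows:::strip_prev(p)]])
      names(labs) <- tab$parent_order
      expect_true(
        ecowindows:::cpt_monotone_in(tab, chk[[2]], labs, chk[[3]]),
        label = sprintf("%s: %s monotone in %s", lh, chk[[1]], chk[[2]]))
    }
  }
})

test_that("colonising seed production stochastically dominates persistent's", {
  bc <- fx_bundle("colonising")$seed_density.seedset
  bp <- fx_bundle("persistent")$seed_density.seedset
  for (r in seq_len(nrow(bc$prob)))
    expect_true(ecowindows:::fosd_geq(bc$prob[r, ], bp$prob[r, ]))
})

test_that("study fixtures span the design space and are reproducible", {
  fx <- make_study_fixture(28, seed = 7)
  expect_length(fx$sites, 28L)
  lh <- vapply(fx$sites, function(s) s$life_history, character(1))
  expect_setequal(unique(lh), c("colonising", "opportunistic", "persistent"))
  hemi <- vapply(fx$sites, function(s) s$hemisphere, character(1))
  expect_setequal(unique(hemi), c("north", "south"))
  mt <- vapply(fx$sites, function(s) s$meadow_type, character(1))
  expect_setequal(unique(mt), c("enduring", "transitory"))
  expect_named(fx$bundles, c("colonising", "opportunistic", "persistent"))

  one <- make_study_fixture(1, seed = 3)
  expect_length(one$sites, 1L)
  expect_s3_class(one$sites[[1]], "site_config")

  # byte-identical YAML under a fixed seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    f <- make_study_fixture(4, seed = 11)
    for (s in f$sites)
      write_site_yaml(s, file.path(d, paste0(s$site_name, ".yaml")))
  }
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
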