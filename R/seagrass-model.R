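#' Discretization scheme for population and loss/recovery factors
#'
#' Population-type factors (shoot density, biomass, baseline population) use
#' ordinal categories defined as a percentage of a reference value: zero = 0,
#' low = (0, 20], moderate = (20, 80], high = (80, 100]. Loss and recovery
#' factors use zero = 0, low = (0, 10], moderate = (10, 30], high = (30, 100].
#' Intervals are half-open (lower, upper] on the continuous percent scale;
#' printed integer thresholds (e.g. "21-80") are the integer-labelled
#' endpoints of these intervals.
#'
#' @param kind `"population"` or `"loss_recovery"`.
#' @return an object of class `discretization_scheme` with a `states` data
#'   frame (state, lower, upper) ordered worst to best, and `zero_label`.
#' @export
discretization_scheme <- function(kind = c("population", "loss_recovery")) {
  kind <- match.arg(kind)
  states <- if (kind == "population") {
    data.frame(state = c("zero", "low", "moderate", "high"),
               lower = c(NA, 0, 20, 80), upper = c(NA, 20, 80, 100))
  } else {
    data.frame(state = c("zero", "low", "moderate", "high"),
               lower = c(NA, 0, 10, 30), upper = c(NA, 10, 30, 100))
  }
  structure(list(kind = kind, states = states, zero_label = "zero"),
            class = "discretization_scheme")
}

#' Classify a measurement into an ordinal state
#'
#' Computes `100 * value / reference`, clamps to 100, and maps through the
#' scheme's half-open intervals; exactly 0 maps to the zero state.
#'
#' @param value non-negative measurement.
#' @param reference positive reference value in the same units.
#' @param scheme a [discretization_scheme].
#' @return the state label.
#' @export
discretize_measurement <- function(value, reference, scheme) {
  if (any(value < 0)) stop("measurement must be non-negative")
  if (reference <= 0) stop("reference value must be positive")
  pct <- pmin(100 * value / reference, 100)
  vapply(pct, function(p) {
    if (p == 0) return(scheme$zero_label)
    s <- scheme$states[-1L, ]
    s$state[p > s$lower & p <= s$upper]
  }, character(1))
}

#' Five-point state value grid
#'
#' For each non-zero state with integer-labelled interval `lo..hi`
#' (`lo = lower + 1`), the five points are `lo + ceiling(w * k / 4)` for
#' `k = 0..4` with `w = hi - lo` (ceiling-rounded quartiles of a uniform
#' distribution on the interval); the state value is the median (third)
#' point. The zero state has value 0. For the high population interval
#' 81..100 this yields {81, 86, 91, 96, 100} with median 91.
#'
#' @param scheme a [discretization_scheme].
#' @return an object of class `state_value_grid` with `points` (named list of
#'   5-vectors) and `medians` (named numeric).
#' @export
state_value_grid <- function(scheme) {
  points <- list()
  medians <- numeric(0)
  for (i in seq_len(nrow(scheme$states))) {
    st <- scheme$states$state[i]
    if (st == scheme$zero_label) {
      points[[st]] <- rep(0, 5)
      medians[st] <- 0
      next
    }
    lo <- scheme$states$lower[i] + 1
    hi <- scheme$states$upper[i]
    w <- hi - lo
    pts <- lo + ceiling(w * 0:4 / 4)
    points[[st]] <- pts
    medians[st] <- pts[3]
  }
  structure(list(kind = scheme$kind, points = points, medians = medians,
                 zero_label = scheme$zero_label),
            class = "state_value_grid")
}

#' @export
print.state_value_grid <- function(x, ...) {
  cat(sprintf("State value grid (%s scheme):\n", x$kind))
  for (st in names(x$points))
    cat(sprintf("  %-9s {%s}  median %g\n", st,
                paste(x$points[[st]], collapse = ","), x$medians[st]))
  invisible(x)
}

#' Site configuration
#'
#' Captures the site-level inputs of the analysis: life history of the
#' dominant genus, climate, tidal regime, meadow type, and the monthly
#' probability of above-saturation benthic light that drives the network.
#'
#' @param site_name label.
#' @param latitude degrees, negative = south.
#' @param climate `"tropical"` or `"temperate"`.
#' @param tidal `"subtidal"` or `"intertidal"`.
#' @param meadow_type `"enduring"` or `"transitory"`.
#' @param life_history `"colonising"`, `"opportunistic"` or `"persistent"`.
#' @param light_p numeric vector of 12 monthly probabilities of
#'   above-saturation light, January..December, each in [0, 1].
#' @param genus_label free-text genus (metadata).
#' @param reference_value population reference (e.g. shoots per m^2;
#'   metadata used when discretizing observations).
#' @return an object of class `site_config`.
#' @export
site_config <- function(site_name, latitude,
                        climate = c("temperate", "tropical"),
                        tidal = c("subtidal", "intertidal"),
                        meadow_type = c("enduring", "transitory"),
                        life_history = c("colonising", "opportunistic",
                                         "persistent"),
                        light_p, genus_label = "", reference_value = NA_real_) {
  climate <- match.arg(climate)
  tidal <- match.arg(tidal)
  meadow_type <- match.arg(meadow_type)
  life_history <- match.arg(life_history)
  light_p <- as.numeric(light_p)
  if (length(light_p) != 12L) stop("light_p must have 12 monthly values")
  if (any(light_p < 0 | light_p > 1)) stop("light_p values must lie in [0,1]")
  structure(list(site_name = site_name, latitude = latitude,
                 hemisphere = if (latitude < 0) "south" else "north",
                 climate = climate, tidal = tidal, meadow_type = meadow_type,
                 life_history = life_history, genus_label = genus_label,
                 light_p = light_p, reference_value = reference_value),
            class = "site_config")
}

#' @export
print.site_config <- function(x, ...) {
  cat(sprintf("Site '%s' (%.1f deg %s)\n", x$site_name, abs(x$latitude),
              ifelse(x$hemisphere == "south", "S", "N")))
  cat(sprintf("  %s %s %s meadow, %s life history (%s)\n", x$climate,
              x$tidal, x$meadow_type, x$life_history, x$genus_label))
  cat("  monthly P(above-saturation light):\n   ",
      paste(sprintf("%.2f", x$light_p), collapse = " "), "\n")
  invisible(x)
}

# Seasonal month sets by hemisphere: the growing season is the summer
# half-year; seed set occupies its last third, germination its first third.
season_months <- function(hemisphere) {
  growing <- if (hemisphere == "south") c(10:12, 1:3) else 4:9
  list(growing = growing,
       senescent = setdiff(1:12, growing),
       germination = growing[1:3],
       seedset = growing[4:6])
}

# Names of the conditional tables a reference-network CPT bundle must supply.
reference_table_ids <- function() {
  c("physiological_status", "growth.growing", "growth.senescent",
    "seed_density.seedset", "seed_density.offseason",
    "recruitment_from_seeds.germination", "recruitment_from_seeds.offseason",
    "ability_to_resist", "ability_to_recover", "loss", "recovery",
    "net_change", "baseline_population.growing",
    "baseline_population.senescent", "realised_shoot_density",
    "realised_biomass")
}

# State spaces of the reference topology (ordered worst to best; for the loss
# node "high" means high loss).
reference_states <- function() {
  list(light = c("below", "above"),
       climate = c("tropical", "temperate"),
       tidal = c("subtidal", "intertidal"),
       meadow_type = c("enduring", "transitory"),
       life_history = c("colonising", "opportunistic", "persistent"),
       physiological_status = c("critical", "poor", "good"),
       growth = c("none", "slow", "fast"),
       seed_density = c("none", "low", "high"),
       recruitment_from_seeds = c("none", "low", "high"),
       ability_to_resist = c("low", "high"),
       ability_to_recover = c("low", "high"),
       loss = c("zero", "low", "moderate", "high"),
       recovery = c("zero", "low", "moderate", "high"),
       net_change = c("decline", "stable", "increase"),
       baseline_population = c("zero", "low", "moderate", "high"),
       realised_shoot_density = c("zero", "low", "moderate", "high"),
       realised_biomass = c("zero", "low", "moderate", "high"))
}

point_mass_cpt <- function(child, labels, at) {
  v <- numeric(length(labels))
  v[match(at, labels)] <- 1
  cpt(child, character(0), matrix(v, 1))
}

#' Build the seagrass reference network for a site
#'
#' Assembles the ~17-node reference topology (light driver, site descriptors,
#' physiological status, growth, seed bank, recruitment, resist/recover
#' abilities, loss, recovery, net change, baseline and realised population
#' nodes) around a site configuration and an archetype CPT bundle. Regime
#' selectors encode calendar-month seasonality (growing/senescent season,
#' seed set, germination) oriented by the site's hemisphere. Population nodes
#' use the population discretization scheme, loss/recovery nodes the
#' loss/recovery scheme, and the light node has the two states below/above
#' saturation.
#'
#' @param site a [site_config].
#' @param archetype_tables named list of [cpt] objects covering
#'   `reference_table_ids()`, e.g. from [synth_site_archetype_cpts()].
#' @return a validated [network_schema]; its interface contains at most 5
#'   nodes so exact filtering stays tractable.
#' @export
build_reference_network <- function(site, archetype_tables) {
  need <- reference_table_ids()
  missing <- setdiff(need, names(archetype_tables))
  if (length(missing))
    stop("archetype CPT bundle is missing table(s): ",
         paste(missing, collapse = ", "))
  st <- reference_states()
  sm <- season_months(site$hemisphere)
  zero4 <- function(labels) state_space(labels, zero_label = "zero")

  nodes <- list(
    node_spec("light", st$light, role = "environment"),
    node_spec("climate", st$climate, role = "site"),
    node_spec("tidal", st$tidal, role = "site"),
    node_spec("meadow_type", st$meadow_type, role = "site"),
    node_spec("life_history", st$life_history, role = "site"),
    node_spec("physiological_status", st$physiological_status,
              intra_parents = "light",
              inter_parents = "physiological_status"),
    node_spec("growth", st$growth,
              intra_parents = c("light", "physiological_status", "climate")),
    node_spec("seed_density", st$seed_density,
              intra_parents = "physiological_status",
              inter_parents = "seed_density"),
    node_spec("recruitment_from_seeds", st$recruitment_from_seeds,
              intra_parents = c("seed_density", "light")),
    node_spec("ability_to_resist", st$ability_to_resist,
              intra_parents = "physiological_status"),
    node_spec("ability_to_recover", st$ability_to_recover,
              intra_parents = c("growth", "recruitment_from_seeds")),
    node_spec("loss", zero4(st$loss),
              intra_parents = c("ability_to_resist", "light", "tidal",
                                "physiological_status")),
    node_spec("recovery", zero4(st$recovery),
              intra_parents = "ability_to_recover"),
    node_spec("net_change", st$net_change,
              intra_parents = c("loss", "recovery")),
    node_spec("baseline_population", zero4(st$baseline_population),
              intra_parents = "meadow_type",
              inter_parents = "baseline_population", role = "population"),
    node_spec("realised_shoot_density", zero4(st$realised_shoot_density),
              intra_parents = c("net_change", "baseline_population"),
              inter_parents = "realised_shoot_density", role = "population"),
    node_spec("realised_biomass", zero4(st$realised_biomass),
              intra_parents = c("realised_shoot_density", "net_change"),
              role = "output")
  )

  tables <- archetype_tables[need]
  tables$site.climate <- point_mass_cpt("climate", st$climate, site$climate)
  tables$site.tidal <- point_mass_cpt("tidal", st$tidal, site$tidal)
  tables$site.meadow_type <-
    point_mass_cpt("meadow_type", st$meadow_type, site$meadow_type)
  tables$site.life_history <-
    point_mass_cpt("life_history", st$life_history, site$life_history)

  selectors <- list(
    climate = "site.climate", tidal = "site.tidal",
    meadow_type = "site.meadow_type", life_history = "site.life_history",
    physiological_status = "physiological_status",
    growth = regime_selector("growth.senescent",
      list(list(months = sm$growing, table = "growth.growing"))),
    seed_density = regime_selector("seed_density.offseason",
      list(list(months = sm$seedset, table = "seed_density.seedset"))),
    recruitment_from_seeds = regime_selector(
      "recruitment_from_seeds.offseason",
      list(list(months = sm$germination,
                table = "recruitment_from_seeds.germination"))),
    ability_to_resist = "ability_to_resist",
    ability_to_recover = "ability_to_recover",
    loss = "loss", recovery = "recovery", net_change = "net_change",
    baseline_population = regime_selector("baseline_population.senescent",
      list(list(months = sm$growing, table = "baseline_population.growing"))),
    realised_shoot_density = "realised_shoot_density",
    realised_biomass = "realised_biomass")

  schema <- network_schema(nodes, tables, selectors)
  diags <- validate_schema(schema)
  if (length(diags))
    stop("reference network failed validation:\n  ",
         paste(diags, collapse = "\n  "))
  schema
}

#' Shipped synthetic example sites
#'
#' Three synthetic site configurations, one per life-history archetype, with
#' identical weakly seasonal light climatologies (southern hemisphere,
#' temperate, subtidal, enduring). These are the fixtures behind the
#' archetype behavioural-signature and monotonicity checks.
#'
#' @return named list of [site_config] objects keyed by life history.
#' @export
example_sites <- function() {
  dir <- system.file("extdata", "sites", package = "ecowindows")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  sites <- lapply(files, read_site_yaml)
  names(sites) <- vapply(sites, function(s) s$life_history, character(1))
  sites[c("colonising", "opportunistic", "persistent")]
}
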