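# Synthetic stand-ins for the expert-elicited inputs of the original study:
# a linguistic probability scale, life-history archetype parameters, monotone
# CPT bundles built from ordered logistic kernels, seasonal light
# climatologies, and a whole study fixture. These target the qualitative
# behavioural signatures of the three life histories, not any numeric
# reproduction of elicited probabilities (which are not published).

#' Linguistic probability scale
#'
#' The nine elicitation labels mapped to probabilities, strictly decreasing
#' from certainty (1.0) to impossible (0.0) and symmetric around 50/50 = 0.5.
#'
#' @param values optional named numeric vector overriding the defaults.
#' @return named numeric vector of class `linguistic_scale`.
#' @export
linguistic_scale <- function(values = NULL) {
  default <- c(certainty = 1.0, extremely_likely = 0.95, very_likely = 0.85,
               likely = 0.70, `50/50` = 0.5, unlikely = 0.30,
               very_unlikely = 0.15, extremely_unlikely = 0.05,
               impossible = 0.0)
  v <- if (is.null(values)) default else values
  if (length(v) != 9L || is.null(names(v)))
    stop("a linguistic scale needs 9 named values")
  if (any(diff(v) >= 0)) stop("scale must be strictly decreasing")
  if (v[["50/50"]] != 0.5) stop("the 50/50 label must map to exactly 0.5")
  structure(v, class = c("linguistic_scale", "numeric"))
}

#' Life-history archetype parameters
#'
#' Each behavioural axis is expressed as a linguistic label (see
#' [linguistic_scale()]). The three defaults encode the field's life-history
#' contrast: colonising genera invest heavily in seeds and rapid growth but
#' have low physiological resistance; persistent genera are the reverse;
#' opportunistic genera are intermediate on every axis.
#'
#' @param life_history one of the three archetypes.
#' @param resistance_strength,growth_rate,seed_production,seed_recruitment,seasonal_amplitude,mortality_under_low_light
#'   linguistic labels; defaults depend on `life_history`.
#' @return an object of class `archetype_params`.
#' @export
archetype_params <- function(life_history = c("colonising", "opportunistic",
                                              "persistent"),
                             resistance_strength = NULL, growth_rate = NULL,
                             seed_production = NULL, seed_recruitment = NULL,
                             seasonal_amplitude = NULL,
                             mortality_under_low_light = NULL) {
  life_history <- match.arg(life_history)
  def <- list(
    colonising = list(resistance_strength = "unlikely",
                      growth_rate = "extremely_likely",
                      seed_production = "extremely_likely",
                      seed_recruitment = "extremely_likely",
                      seasonal_amplitude = "very_likely",
                      mortality_under_low_light = "very_likely"),
    opportunistic = list(resistance_strength = "50/50",
                         growth_rate = "likely",
                         seed_production = "likely",
                         seed_recruitment = "likely",
                         seasonal_amplitude = "likely",
                         mortality_under_low_light = "50/50"),
    persistent = list(resistance_strength = "extremely_likely",
                      growth_rate = "unlikely",
                      seed_production = "very_unlikely",
                      seed_recruitment = "unlikely",
                      seasonal_amplitude = "unlikely",
                      mortality_under_low_light = "very_unlikely"))[[life_history]]
  p <- list(life_history = life_history,
            resistance_strength = resistance_strength %||% def$resistance_strength,
            growth_rate = growth_rate %||% def$growth_rate,
            seed_production = seed_production %||% def$seed_production,
            seed_recruitment = seed_recruitment %||% def$seed_recruitment,
            seasonal_amplitude = seasonal_amplitude %||% def$seasonal_amplitude,
            mortality_under_low_light =
              mortality_under_low_light %||% def$mortality_under_low_light)
  structure(p, class = "archetype_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- ordered logistic kernel -------------------------------------------------

# One CPT row over K ordered states (column 1 = worst): cumulative logits at
# evenly spaced cutpoints shifted by a location. Higher loc puts more mass on
# higher (better) states; rows are first-order stochastically monotone in loc.
ord_logit_row <- function(K, loc, spread = 2.2) {
  theta <- spread * stats::qlogis(seq_len(K - 1) / K)
  cum <- stats::plogis(theta - loc)
  diff(c(0, cum, 1))
}

# Evenly spaced ordinal score in [-1, 1] for state index i of L.
ord_score <- function(i, L) if (L == 1L) 0 else 2 * (i - 1) / (L - 1) - 1

# Normalized effect of a linguistic label: logit of its probability clipped
# to +/-3, scaled to [-1, 1].
label_effect <- function(label, scale) {
  q <- min(max(scale[[label]], 0.001), 0.999)
  max(min(stats::qlogis(q), 3), -3) / 3
}

# Build a dense CPT over the given parents where the row location is
# loc_fun(scores), scores being the named list of parent ordinal scores in
# [-1, 1]. `jitter` adds a small seeded elicitation-noise term per row.
build_ordinal_cpt <- function(child, parent_order, parent_labels, K, loc_fun,
                              jitter = 0) {
  if (length(parent_order) == 0L) {
    prob <- matrix(ord_logit_row(K, loc_fun(list())), 1)
    return(cpt(child, character(0), prob))
  }
  cards <- vapply(parent_labels, length, integer(1))
  grid <- expand.grid(lapply(cards, seq_len))
  colnames(grid) <- parent_order
  prob <- matrix(NA_real_, nrow(grid), K)
  for (r in seq_len(nrow(grid))) {
    scores <- lapply(seq_along(parent_order), function(k)
      ord_score(grid[r, k], cards[k]))
    names(scores) <- parent_order
    eps <- if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
    prob[r, ] <- ord_logit_row(K, loc_fun(scores) + eps)
  }
  cpt(child, parent_order, prob)
}

# First-order stochastic dominance: does distribution a (over ordered states,
# worst first) dominate b?
fosd_geq <- function(a, b, tol = 1e-9) all(cumsum(a) <= cumsum(b) + tol)

# Check that a CPT is stochastically monotone in one parent, in the given
# direction (+1: higher parent state => stochastically higher child).
cpt_monotone_in <- function(tab, parent, parent_labels, direction = 1) {
  cards <- vapply(parent_labels, length, integer(1))
  grid <- as.matrix(expand.grid(lapply(cards, seq_len)))
  colnames(grid) <- tab$parent_order
  k <- match(parent, tab$parent_order)
  ok <- TRUE
  for (r in seq_len(nrow(grid))) {
    if (grid[r, k] >= cards[k]) next
    r2 <- which(apply(grid, 1, function(g)
      all(g[-k] == grid[r, -k]) && g[k] == grid[r, k] + 1L))
    hi <- tab$prob[r2, ]; lo <- tab$prob[r, ]
    ok <- ok && if (direction > 0) fosd_geq(hi, lo) else fosd_geq(lo, hi)
  }
  ok
}

#' Generate a monotone archetype CPT bundle
#'
#' Emits every conditional table the reference topology names
#' ([reference_table_ids()]), built from ordered logistic kernels whose
#' locations are linear in the parents' ordinal scores with coefficients set
#' by the archetype's linguistic labels. By construction every table is
#' normalized and first-order stochastically monotone: better light gives
#' stochastically higher growth, higher growth gives higher net change (via
#' recovery), longer deprivation gives lower physiological status, stronger
#' resistance gives lower loss.
#'
#' @param params an [archetype_params].
#' @param scale a [linguistic_scale].
#' @param seed integer seed for the small per-row elicitation jitter.
#' @param jitter half-width of the uniform per-row location jitter (kept well
#'   below the parent effect sizes so monotonicity is never broken).
#' @param check if `TRUE`, verify stochastic dominance on every table and the
#'   archetype ordering invariants; violations raise a named error.
#' @return named list of [cpt] objects.
#' @export
synth_site_archetype_cpts <- function(params, scale = linguistic_scale(),
                                      seed = 1L, jitter = 0.05,
                                      check = TRUE) {
  if (check) {
    # archetype ordering invariant: the supplied parameters must keep their
    # life history in its place relative to the default other archetypes
    trio <- list(colonising = archetype_params("colonising"),
                 opportunistic = archetype_params("opportunistic"),
                 persistent = archetype_params("persistent"))
    trio[[params$life_history]] <- params
    q <- function(a, f) scale[[trio[[a]][[f]]]]
    if (!(q("persistent", "resistance_strength") >
            q("opportunistic", "resistance_strength") &&
          q("opportunistic", "resistance_strength") >
            q("colonising", "resistance_strength")))
      stop("archetype ordering violated for parameter 'resistance_strength'")
    for (f in c("growth_rate", "seed_production", "seed_recruitment",
                "seasonal_amplitude", "mortality_under_low_light"))
      if (!(q("colonising", f) > q("opportunistic", f) &&
            q("opportunistic", f) > q("persistent", f)))
        stop("archetype ordering violated for parameter '", f, "'")
  }
  st <- reference_states()
  eff <- function(f) label_effect(params[[f]], scale)
  pr <- function(f) scale[[params[[f]]]]
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old())

  tabs <- list()
  # physiological status: sticky in its own past; light below saturation
  # erodes it at a rate set by mortality_under_low_light
  # piecewise status carry-over: robust while good; once degraded, the
  # collapse rate scales with the archetype's mortality under low light
  m01 <- pr("mortality_under_low_light")
  phys_carry <- function(prev)
    if (prev > 0.5) 3.2
    else if (prev > -0.5) -0.8 - 1.2 * (2 * m01 - 1)
    else -4.2 + 2.0 * (1 - m01)
  tabs$physiological_status <- build_ordinal_cpt(
    "physiological_status", c("light", "physiological_status@prev"),
    list(st$light, st$physiological_status), 3,
    function(s) phys_carry(s$`physiological_status@prev`) +
      ifelse(s$light > 0, 1.6 + 2.2 * eff("growth_rate"),
             -(0.4 + 2.6 * pr("mortality_under_low_light"))),
    jitter)
  # growth: dominated by the archetype's growth rate, modulated by light,
  # physiology and climate, strongly seasonal
  growth_loc <- function(season_shift) function(s)
    3.5 * eff("growth_rate") + 1.0 * s$light + 1.2 * s$physiological_status +
      0.2 * s$climate + season_shift
  tabs$growth.growing <- build_ordinal_cpt(
    "growth", c("light", "physiological_status", "climate"),
    list(st$light, st$physiological_status, st$climate), 3,
    growth_loc(0.6), jitter)
  tabs$growth.senescent <- build_ordinal_cpt(
    "growth", c("light", "physiological_status", "climate"),
    list(st$light, st$physiological_status, st$climate), 3,
    growth_loc(-0.6), jitter)
  # seed bank: replenished during seed set in proportion to seed_production,
  # decays slowly off season
  tabs$seed_density.seedset <- build_ordinal_cpt(
    "seed_density", c("physiological_status", "seed_density@prev"),
    list(st$physiological_status, st$seed_density), 3,
    function(s) 1.2 * s$`seed_density@prev` + 1.0 * s$physiological_status +
      2.0 * eff("seed_production") + 0.6, jitter)
  tabs$seed_density.offseason <- build_ordinal_cpt(
    "seed_density", c("physiological_status", "seed_density@prev"),
    list(st$physiological_status, st$seed_density), 3,
    function(s) 2.8 * s$`seed_density@prev` - 0.6 +
      0.2 * s$physiological_status, jitter)
  # recruitment: germination season only, needs a seed bank and light
  tabs$recruitment_from_seeds.germination <- build_ordinal_cpt(
    "recruitment_from_seeds", c("seed_density", "light"),
    list(st$seed_density, st$light), 3,
    function(s) 2.0 * s$seed_density + 0.8 * s$light +
      1.4 * eff("seed_recruitment") - 0.4, jitter)
  tabs$recruitment_from_seeds.offseason <- build_ordinal_cpt(
    "recruitment_from_seeds", c("seed_density", "light"),
    list(st$seed_density, st$light), 3,
    function(s) 0.5 * s$seed_density + 0.2 * s$light - 3.2, jitter)
  # resistance/recovery abilities
  tabs$ability_to_resist <- build_ordinal_cpt(
    "ability_to_resist", "physiological_status",
    list(st$physiological_status), 2,
    function(s) 3.0 * eff("resistance_strength") +
      1.9 * s$physiological_status, jitter)
  tabs$ability_to_recover <- build_ordinal_cpt(
    "ability_to_recover", c("growth", "recruitment_from_seeds"),
    list(st$growth, st$recruitment_from_seeds), 2,
    function(s) 2.2 * s$growth + 0.9 * s$recruitment_from_seeds +
      1.8 * (eff("growth_rate") + eff("seed_recruitment")) / 2, jitter)
  # loss: higher states mean greater loss; driven by deprivation, damped by
  # resistance (note negative coefficient: dominance direction reversed)
  tabs$loss <- build_ordinal_cpt(
    "loss", c("ability_to_resist", "light", "tidal", "physiological_status"),
    list(st$ability_to_resist, st$light, st$tidal, st$physiological_status), 4,
    function(s) ifelse(s$light > 0, -3.0,
                       1.4 + 1.2 * pr("mortality_under_low_light")) -
      2.0 * s$ability_to_resist + 0.3 * s$tidal -
      3.4 * s$physiological_status, jitter)
  tabs$recovery <- build_ordinal_cpt(
    "recovery", "ability_to_recover", list(st$ability_to_recover), 4,
    function(s) -1.8 + 3.2 * s$ability_to_recover, jitter)
  tabs$net_change <- build_ordinal_cpt(
    "net_change", c("loss", "recovery"), list(st$loss, st$recovery), 3,
    function(s) 1.8 * (s$recovery - s$loss), jitter)
  # baseline population: seasonal attractor; transitory meadows crash to zero
  # off season, with amplitude set by seasonal_amplitude
  tabs$baseline_population.growing <- build_ordinal_cpt(
    "baseline_population", c("meadow_type", "baseline_population@prev"),
    list(st$meadow_type, st$baseline_population), 4,
    function(s) 1.7 * s$`baseline_population@prev` + 2.6, jitter)
  tabs$baseline_population.senescent <- build_ordinal_cpt(
    "baseline_population", c("meadow_type", "baseline_population@prev"),
    list(st$meadow_type, st$baseline_population), 4,
    function(s) 1.7 * s$`baseline_population@prev` -
      ifelse(s$meadow_type > 0, 7.0, 0.2 + 1.6 * pr("seasonal_amplitude")),
    jitter)
  # realised population: a sticky chain moved by net change, with
  # archetype-dependent step sizes: regrowth steps scale with the genus's
  # growth rate, decline steps are damped by its resistance
  up_step <- 1.5 + 2.2 * eff("growth_rate")
  down_step <- 2.4 - 0.85 * eff("resistance_strength")
  tabs$realised_shoot_density <- build_ordinal_cpt(
    "realised_shoot_density",
    c("net_change", "baseline_population", "realised_shoot_density@prev"),
    list(st$net_change, st$baseline_population, st$realised_shoot_density), 4,
    function(s) 3.6 * s$`realised_shoot_density@prev` +
      (if (s$net_change > 0) up_step else down_step) * s$net_change +
      0.1 * s$baseline_population, jitter)
  tabs$realised_biomass <- build_ordinal_cpt(
    "realised_biomass", c("realised_shoot_density", "net_change"),
    list(st$realised_shoot_density, st$net_change), 4,
    function(s) 2.8 * s$realised_shoot_density + 0.5 * s$net_change, jitter)

  if (check) {
    checks <- list(
      list("physiological_status", "light", 1),
      list("physiological_status", "physiological_status@prev", 1),
      list("growth.growing", "light", 1),
      list("growth.growing", "physiological_status", 1),
      list("growth.senescent", "light", 1),
      list("seed_density.seedset", "physiological_status", 1),
      list("recruitment_from_seeds.germination", "seed_density", 1),
      list("ability_to_resist", "physiological_status", 1),
      list("ability_to_recover", "growth", 1),
      list("loss", "ability_to_resist", -1),
      list("loss", "light", -1),
      list("loss", "physiological_status", -1),
      list("recovery", "ability_to_recover", 1),
      list("net_change", "recovery", 1),
      list("net_change", "loss", -1),
      list("realised_shoot_density", "net_change", 1),
      list("realised_shoot_density", "realised_shoot_density@prev", 1),
      list("realised_biomass", "realised_shoot_density", 1))
    for (chk in checks) {
      tab <- tabs[[chk[[1]]]]
      labs <- lapply(tab$parent_order, function(p) st[[strip_prev(p)]])
      names(labs) <- tab$parent_order
      if (!cpt_monotone_in(tab, chk[[2]], labs, chk[[3]]))
        stop("monotonicity violated in table '", chk[[1]],
             "' with respect to parent '", chk[[2]], "'")
    }
  }
  tabs
}

# Save/restore RNG state so generators are self-seeding but polite.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    function() assign(".Random.seed", old, globalenv())
  } else function() {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Synthetic monthly light climatology
#'
#' Sinusoidal seasonal mean with optional beta-distributed monthly noise:
#' `p_m = mean + amplitude * cos(2 pi (m - peak_month) / 12)`, clipped to
#' [0, 1].
#'
#' @param mean annual mean probability of above-saturation light.
#' @param amplitude seasonal amplitude.
#' @param peak_month calendar month (1--12) of the light maximum.
#' @param concentration beta concentration of monthly observation noise;
#'   `Inf` (default) disables noise.
#' @param seed integer seed (used only when noise is enabled).
#' @return numeric vector of 12 monthly probabilities (January..December).
#' @export
synth_light_climatology <- function(mean = 0.6, amplitude = 0.25,
                                    peak_month = 1, concentration = Inf,
                                    seed = 1L) {
  m <- 1:12
  p <- mean + amplitude * cospi(2 * (m - peak_month) / 12)
  p <- pmin(pmax(p, 0), 1)
  if (is.finite(concentration)) {
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(old())
    pc <- pmin(pmax(p, 0.01), 0.99)
    p <- stats::rbeta(12, pc * concentration, (1 - pc) * concentration)
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

#' Synthetic daily above-saturation light series
#'
#' Emits a daily series consistent with a monthly climatology: each day is an
#' independent Bernoulli draw with that calendar month's probability. A
#' pseudo-irradiance column is included so both input modes of
#' [estimate_light_saturation_probability()] can be exercised
#' (above-threshold days draw irradiance above `threshold`, below-threshold
#' days below it).
#'
#' @param monthly_p 12 monthly probabilities.
#' @param years number of years of days.
#' @param seed integer seed.
#' @param start_year first calendar year of the series.
#' @param threshold saturation threshold for the pseudo-irradiance column
#'   (mol photons m^-2 d^-1).
#' @return data frame with columns `date`, `above` (0/1), `irradiance`;
#'   `threshold` is attached as an attribute.
#' @export
synth_daily_light <- function(monthly_p, years = 10, seed = 1L,
                              start_year = 2000, threshold = 5) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old())
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1)), by = "day")
  month <- as.integer(format(dates, "%m"))
  above <- stats::rbinom(length(dates), 1, monthly_p[month])
  irr <- ifelse(above == 1,
                threshold * (1 + stats::rexp(length(dates), 2)),
                threshold * stats::runif(length(dates)))
  out <- data.frame(date = dates, above = above, irradiance = irr)
  attr(out, "threshold") <- threshold
  out
}

#' Generate a synthetic study fixture
#'
#' Produces `n_sites` site configurations spanning both hemispheres, all
#' three life histories and both meadow types (mirroring the scale of a
#' 28-site global study), together with the three archetype CPT bundles.
#'
#' @param n_sites number of sites (default 28).
#' @param seed integer seed.
#' @return list with `sites` (list of [site_config]) and `bundles` (named
#'   list of CPT bundles keyed by life history).
#' @export
make_study_fixture <- function(n_sites = 28, seed = 1L) {
  stopifnot(n_sites >= 1)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old())
  lhs <- c("colonising", "opportunistic", "persistent")
  genus <- c(colonising = "Halophila", opportunistic = "Zostera",
             persistent = "Amphibolis")
  sites <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    lh <- lhs[(i - 1L) %% 3L + 1L]
    south <- i %% 2L == 0L
    lat <- stats::runif(1, 8, 64) * ifelse(south, -1, 1)
    climate <- if (abs(lat) < 23.5) "tropical" else "temperate"
    tidal <- if (i %% 4L == 0L) "intertidal" else "subtidal"
    # transitory meadows occur among colonising (and some opportunistic) sites
    meadow <- if (lh == "colonising" && i %% 6L %in% c(1L, 4L))
      "transitory" else "enduring"
    amp <- 0.10 + 0.35 * min(abs(lat), 60) / 60
    peak <- (if (south) 1L else 7L) + sample(-1:1, 1)
    peak <- ((peak - 1L) %% 12L) + 1L
    light <- synth_light_climatology(
      mean = stats::runif(1, 0.5, 0.7), amplitude = amp, peak_month = peak,
      concentration = 60, seed = sample.int(1e6, 1))
    sites[[i]] <- site_config(
      site_name = sprintf("synthetic-%02d-%s", i, lh), latitude = lat,
      climate = climate, tidal = tidal, meadow_type = meadow,
      life_history = lh, light_p = light, genus_label = genus[[lh]],
      reference_value = round(stats::runif(1, 200, 1200)))
  }
  bundles <- lapply(lhs, function(lh)
    synth_site_archetype_cpts(archetype_params(lh), seed = seed))
  names(bundles) <- lhs
  list(sites = sites, bundles = bundles)
}
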