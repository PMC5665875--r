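#' Parameters of the weighted-mean trajectory
#'
#' @param grid a [state_value_grid] supplying the per-state median values.
#' @param alpha threshold on the weighted-mean scale below which the
#'   trajectory is considered to be in the zero state (default 1.0, the
#'   lower edge of the "low" interval).
#' @return an object of class `weighted_mean_params`.
#' @export
weighted_mean_params <- function(grid = state_value_grid(
                                   discretization_scheme("population")),
                                 alpha = 1.0) {
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(grid = grid, alpha = alpha), class = "weighted_mean_params")
}

#' Weighted-mean trajectory of a state-probability time series
#'
#' Aggregates per-slice state probabilities into a single trajectory:
#' `mu'(t) = sum_j p_j(t) * xbar_j` with the per-state median values, and
#' `mu(t) = p_0(t)` when `mu'(t) < alpha`, else `(1 - p_0(t)) * mu'(t)`,
#' where `p_0` is the zero-state probability. Note the deliberate scale mix
#' of the published form: near extinction (`mu' < alpha`) the trajectory
#' reports the zero-state *probability*, so near-extinct meadows sit near 0-1
#' on the percent scale.
#'
#' @param state_probs matrix of per-slice probability vectors (rows = slices,
#'   columns named by state) or a `dbn_trajectory` marginal matrix.
#' @param params a [weighted_mean_params].
#' @return numeric vector of per-slice mu values.
#' @export
weighted_mean_trajectory <- function(state_probs, params =
                                       weighted_mean_params()) {
  m <- as.matrix(state_probs)
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stop("state probability rows must be normalized")
  med <- params$grid$medians
  if (is.null(colnames(m))) {
    if (ncol(m) != length(med)) stop("cannot align states without column names")
    colnames(m) <- names(med)
  }
  if (!all(colnames(m) %in% names(med)))
    stop("state columns do not match the value grid")
  xbar <- med[colnames(m)]
  mu_prime <- as.vector(m %*% xbar)
  zl <- params$grid$zero_label
  p0 <- if (!is.null(zl) && zl %in% colnames(m)) m[, zl] else
    rep(0, nrow(m))
  ifelse(mu_prime < params$alpha, p0, (1 - p0) * mu_prime)
}

#' Resilience criteria configuration
#'
#' The three criteria: resistance (< 20% change in the weighted mean relative
#' to the month-matched baseline immediately after the stress), recovery
#' (within 20% of the baseline within 6 months of stress removal; a loss is
#' permanent if not recovered within 60 months), and persistence (ratio of
#' mean response to baseline zero-state probability over the 5-year response
#' window below 1.025).
#'
#' @param resistance_threshold,recovery_threshold relative-change thresholds.
#' @param recovery_window_months months allowed for recovery.
#' @param persistence_ratio zero-state probability ratio threshold.
#' @param permanence_horizon_months censoring horizon for recovery time.
#' @param persistence_aggregate `"mean"` (default) or `"max"` aggregation of
#'   the zero-state probabilities over the response window.
#' @param alpha zero-state threshold on the weighted-mean scale.
#' @return an object of class `resilience_criteria_config`.
#' @export
resilience_criteria_config <- function(resistance_threshold = 0.20,
                                       recovery_threshold = 0.20,
                                       recovery_window_months = 6L,
                                       persistence_ratio = 1.025,
                                       permanence_horizon_months = 60L,
                                       persistence_aggregate = c("mean", "max"),
                                       alpha = 1.0) {
  stopifnot(resistance_threshold > 0, resistance_threshold < 1,
            recovery_threshold > 0, recovery_threshold < 1,
            recovery_window_months > 0, permanence_horizon_months > 0)
  structure(list(resistance_threshold = resistance_threshold,
                 recovery_threshold = recovery_threshold,
                 recovery_window_months = as.integer(recovery_window_months),
                 persistence_ratio = persistence_ratio,
                 permanence_horizon_months =
                   as.integer(permanence_horizon_months),
                 persistence_aggregate = match.arg(persistence_aggregate),
                 alpha = alpha),
            class = "resilience_criteria_config")
}

# Relative change with the zero-baseline convention: when the baseline
# weighted mean is zero (annual meadow off-season), a response below alpha is
# no change (0) and a response above an absent baseline is not a loss
# (also satisfied); both register 0.
rel_change <- function(baseline, response, alpha) {
  if (baseline == 0) {
    attr_val <- 0
    attr(attr_val, "zero_baseline") <- TRUE
    return(attr_val)
  }
  abs(response - baseline) / baseline
}

#' Resistance criterion
#'
#' Satisfied when the relative change of the weighted-mean response against
#' the month-matched baseline at the first slice after the last dredging
#' month is below the threshold.
#'
#' @param baseline_mu,response_mu weighted-mean trajectories (month-aligned).
#' @param stress_end_slice 0-based slice index of the last dredging month.
#' @param cfg a [resilience_criteria_config].
#' @return logical; attribute `rel_change` carries the observed change.
#' @export
assess_resistance <- function(baseline_mu, response_mu, stress_end_slice,
                              cfg = resilience_criteria_config()) {
  i <- stress_end_slice + 2L  # first slice after stress, 1-based
  if (i > length(baseline_mu) || i > length(response_mu))
    stop("slice out of range")
  rc <- rel_change(baseline_mu[i], response_mu[i], cfg$alpha)
  out <- as.vector(rc) < cfg$resistance_threshold
  attr(out, "rel_change") <- as.vector(rc)
  out
}

#' Recovery criterion and recovery time
#'
#' Recovery time is the smallest number of months m >= 0 after the end of the
#' stress at which the response is within the threshold of the month-matched
#' baseline (m = 0 meaning already within it at the last dredging month). The
#' criterion is satisfied when recovery occurs within the recovery window;
#' losses not recovered within the permanence horizon are censored as
#' `"permanent"`.
#'
#' @inheritParams assess_resistance
#' @return `list(criterion = logical, recovery_time_months = integer or
#'   "permanent")`.
#' @export
assess_recovery <- function(baseline_mu, response_mu, stress_end_slice,
                            cfg = resilience_criteria_config()) {
  H <- cfg$permanence_horizon_months
  if (stress_end_slice + H + 1L > length(response_mu))
    stop("response horizon shorter than the permanence horizon")
  rt <- NULL
  for (m in 0:H) {
    i <- stress_end_slice + m + 1L  # 1-based
    rc <- rel_change(baseline_mu[i], response_mu[i], cfg$alpha)
    if (as.vector(rc) < cfg$recovery_threshold) { rt <- m; break }
  }
  if (is.null(rt))
    return(list(criterion = FALSE, recovery_time_months = "permanent"))
  list(criterion = rt <= cfg$recovery_window_months,
       recovery_time_months = rt)
}

#' Persistence criterion and extinction-risk ratio
#'
#' The extinction ratio is the mean (or maximum) zero-state probability of
#' the response over the permanence horizon after the stress, divided by the
#' same for the month-matched baseline (0/0 treated as 1). Satisfied when the
#' ratio is below the threshold.
#'
#' @param baseline_zero_p,response_zero_p per-slice zero-state probabilities.
#' @inheritParams assess_resistance
#' @return `list(criterion = logical, extinction_ratio = numeric)`.
#' @export
assess_persistence <- function(baseline_zero_p, response_zero_p,
                               stress_end_slice,
                               cfg = resilience_criteria_config()) {
  idx <- stress_end_slice + 1L + seq_len(cfg$permanence_horizon_months)
  idx <- idx[idx <= length(baseline_zero_p)]
  agg <- if (cfg$persistence_aggregate == "mean") mean else max
  b <- agg(baseline_zero_p[idx])
  r <- agg(response_zero_p[idx])
  ratio <- if (b == 0 && r == 0) 1 else r / b
  list(criterion = ratio < cfg$persistence_ratio, extinction_ratio = ratio)
}

#' Resilience score (0--4)
#'
#' 4 = all three criteria; 3 = resistance and recovery without persistence;
#' 2 = recovery and persistence without resistance; 1 = recovery only;
#' 0 = recovery not satisfied. Resistance as defined implies the recovery
#' criterion, so resistance without recovery is rejected as inconsistent.
#'
#' @param resistance,recovery_criterion,persistence logicals.
#' @return integer score.
#' @seealso [decode_resilience_score()]
#' @export
resilience_score <- function(resistance, recovery_criterion, persistence) {
  if (resistance && !recovery_criterion)
    stop("inconsistent input: resistance satisfied but recovery not")
  if (!recovery_criterion) return(0L)
  if (resistance && persistence) return(4L)
  if (resistance) return(3L)
  if (persistence) return(2L)
  1L
}

#' Decode a resilience score into its criteria
#'
#' Inverse of [resilience_score()] over the five admissible combinations.
#'
#' @param score integer 0--4.
#' @return `list(resistance =, recovery =, persistence =)`; for score 0 the
#'   resistance and persistence values are `FALSE` (the score carries no
#'   information beyond failed recovery, and failed recovery forces failed
#'   resistance).
#' @export
decode_resilience_score <- function(score) {
  switch(as.character(score),
         "4" = list(resistance = TRUE, recovery = TRUE, persistence = TRUE),
         "3" = list(resistance = TRUE, recovery = TRUE, persistence = FALSE),
         "2" = list(resistance = FALSE, recovery = TRUE, persistence = TRUE),
         "1" = list(resistance = FALSE, recovery = TRUE, persistence = FALSE),
         "0" = list(resistance = FALSE, recovery = FALSE, persistence = FALSE),
         stop("score must be an integer 0..4"))
}

#' Assess the three resilience criteria for one scenario run
#'
#' Computes the weighted-mean trajectories of the tracked population node for
#' the stressed and control runs, applies the three criteria month-matched
#' against the control, and combines them into the 0--4 score.
#'
#' @param res a `scenario_result` from [run_scenario()].
#' @param cfg a [resilience_criteria_config].
#' @param node tracked population node.
#' @param params a [weighted_mean_params].
#' @return an object of class `criteria_result`.
#' @export
assess_scenario <- function(res, cfg = resilience_criteria_config(),
                            node = "realised_shoot_density",
                            params = weighted_mean_params()) {
  bm <- res$baseline_traj$marginals[[node]]
  rm_ <- res$response_traj$marginals[[node]]
  mu_b <- weighted_mean_trajectory(bm, params)
  mu_r <- weighted_mean_trajectory(rm_, params)
  zl <- params$grid$zero_label
  end <- if (is.na(res$stress_span["last"]))
    res$windows$initialisation_months - 1L else
      unname(res$stress_span["last"])
  resist <- assess_resistance(mu_b, mu_r, end, cfg)
  recov <- assess_recovery(mu_b, mu_r, end, cfg)
  persist <- assess_persistence(bm[, zl], rm_[, zl], end, cfg)
  score <- resilience_score(as.vector(resist), recov$criterion,
                            persist$criterion)
  structure(list(scenario_id = res$scenario$id,
                 site = res$scenario$site$site_name,
                 design = res$scenario$design$label,
                 start_month = res$scenario$start_month,
                 light_level = res$scenario$light_level,
                 resistance = as.vector(resist),
                 recovery = recov$criterion,
                 persistence = persist$criterion,
                 recovery_time_months = recov$recovery_time_months,
                 extinction_ratio = persist$extinction_ratio,
                 resistance_change = attr(resist, "rel_change"),
                 score = score),
            class = "criteria_result")
}

#' @export
print.criteria_result <- function(x, ...) {
  cat(sprintf(
    "%s: score %d (R=%s C=%s P=%s), recovery time %s, extinction ratio %.3f\n",
    x$scenario_id, x$score, x$resistance, x$recovery, x$persistence,
    as.character(x$recovery_time_months), x$extinction_ratio))
  invisible(x)
}

#' Ecological window table for one site
#'
#' Tabulates the resilience score for every (design, start month) cell. A
#' cell with score >= 1 is an ecological window; score >= 3 marks minimal
#' impact (resistance and recovery both satisfied).
#'
#' @param results list of `scenario_result` or `criteria_result` objects
#'   covering the full (design x 12 start months) grid for one site.
#' @param cfg a [resilience_criteria_config].
#' @param ... passed to [assess_scenario()] for raw results.
#' @return a data frame of class `window_table`.
#' @export
build_window_table <- function(results, cfg = resilience_criteria_config(),
                               ...) {
  crit <- lapply(results, function(r)
    if (inherits(r, "criteria_result")) r else assess_scenario(r, cfg, ...))
  df <- do.call(rbind, lapply(crit, function(cr)
    data.frame(site = cr$site, design = cr$design,
               start_month = cr$start_month,
               light_level = cr$light_level,
               resistance = cr$resistance, recovery = cr$recovery,
               persistence = cr$persistence,
               recovery_time = as.character(cr$recovery_time_months),
               extinction_ratio = cr$extinction_ratio, score = cr$score)))
  df$window <- df$score >= 1L
  df$minimal_impact <- df$score >= 3L
  designs <- unique(df$design)
  missing <- character(0)
  for (d in designs) {
    have <- sort(unique(df$start_month[df$design == d]))
    lack <- setdiff(1:12, have)
    if (length(lack))
      missing <- c(missing, sprintf("(%s, %d)", d, lack))
  }
  if (length(missing))
    stop("incomplete scenario grid; missing cells: ",
         paste(missing, collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("window_table", "data.frame")
  df
}

#' @export
summary.window_table <- function(object, ...) {
  cat(sprintf("Ecological windows for site '%s':\n", object$site[1]))
  tab <- with(object, tapply(score, list(design, start_month), max))
  print(tab)
  cat(sprintf("windows (score >= 1): %d of %d cells; minimal impact: %d\n",
              sum(object$window), nrow(object), sum(object$minimal_impact)))
  invisible(tab)
}

#' @export
plot.window_table <- function(x, ...) {
  tab <- with(x, tapply(score, list(design, start_month), max))
  cols <- c("firebrick", "orange", "gold", "yellowgreen", "forestgreen")
  graphics::image(1:12, seq_len(nrow(tab)), t(tab), zlim = c(0, 4),
                  col = cols, xlab = "start month", ylab = "",
                  yaxt = "n", main = paste("Resilience scores:", x$site[1]),
                  ...)
  graphics::axis(2, seq_len(nrow(tab)), rownames(tab), las = 1)
  invisible(x)
}

#' Minimum light level yielding an ecological window
#'
#' Runs the scenario at increasing permitted light levels and returns the
#' first whose resilience score is at least 1 (the window satisfies at
#' minimum the recovery criterion), or `"none"` when even the highest level
#' fails (no light reduction allowed).
#'
#' @param site a [site_config].
#' @param design a [dredge_design].
#' @param start_month calendar month of dredging start.
#' @param schema the site's [network_schema] or compiled form.
#' @param levels ascending light levels to try.
#' @param cfg a [resilience_criteria_config].
#' @param windows a [run_windows].
#' @return numeric level, or the character `"none"`.
#' @export
min_light_for_window <- function(site, design, start_month, schema,
                                 levels = c(0, 0.25, 0.50, 0.75),
                                 cfg = resilience_criteria_config(),
                                 windows = run_windows()) {
  if (is.unsorted(levels)) stop("levels must be sorted ascending")
  for (l in levels) {
    scn <- scenario(site, design, start_month, l)
    res <- run_scenario(scn, schema, windows)
    if (assess_scenario(res, cfg)$score >= 1L) return(l)
  }
  "none"
}
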