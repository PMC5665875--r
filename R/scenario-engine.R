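#' Dredging design
#'
#' Continuous designs dredge `total` months in one block; the two alternating
#' designs, labelled "6-3" and "6-2", split 6 dredging months into cycles of
#' 3 on / 3 rest and 2 on / 2 rest, always starting and ending with a
#' dredging block.
#'
#' @param total total dredging months, one of 1, 2, 3, 6, 9, 12 (0 for the
#'   control).
#' @param rest rest-block months for alternating designs (0 = continuous;
#'   only 6-3 and 6-2 are admitted).
#' @return an object of class `dredge_design`.
#' @export
dredge_design <- function(total, rest = 0) {
  if (total == 0) {
    return(structure(list(label = "control", total_dredge_months = 0L,
                          on_block = 0L, rest_block = 0L, is_control = TRUE),
                     class = "dredge_design"))
  }
  if (!total %in% c(1, 2, 3, 6, 9, 12)) stop("total must be in {1,2,3,6,9,12}")
  if (rest == 0) {
    on <- total
  } else {
    if (!(total == 6 && rest %in% c(2, 3)))
      stop("alternating designs are exactly 6-3 and 6-2")
    on <- rest  # 6-3 = cycles of 3 on / 3 rest; 6-2 = 2 on / 2 rest
  }
  structure(list(label = sprintf("%d-%d", total, rest),
                 total_dredge_months = as.integer(total),
                 on_block = as.integer(on), rest_block = as.integer(rest),
                 is_control = FALSE),
            class = "dredge_design")
}

#' The eight dredging designs of the standard grid
#'
#' 1-0, 2-0, 3-0, 6-0, 6-3, 6-2, 9-0 and 12-0 months.
#' @return list of [dredge_design] objects.
#' @export
paper_designs <- function() {
  c(lapply(c(1, 2, 3, 6), dredge_design),
    list(dredge_design(6, 3), dredge_design(6, 2)),
    lapply(c(9, 12), dredge_design))
}

# Logical dredge/rest pattern over the stress span (TRUE = dredging month);
# starts and ends with a dredging block.
stress_pattern <- function(design) {
  if (design$is_control) return(logical(0))
  pat <- logical(0)
  done <- 0L
  while (done < design$total_dredge_months) {
    blk <- min(design$on_block, design$total_dredge_months - done)
    pat <- c(pat, rep(TRUE, blk))
    done <- done + blk
    if (done < design$total_dredge_months && design$rest_block > 0L)
      pat <- c(pat, rep(FALSE, design$rest_block))
  }
  pat
}

#' Scenario: site x design x start month x light level
#'
#' @param site a [site_config].
#' @param design a [dredge_design].
#' @param start_month calendar month (1--12) in which dredging starts.
#' @param light_level probability of above-saturation light permitted during
#'   dredging months: 0 (complete deprivation, the conservative default),
#'   0.25, 0.50 or 0.75. The realized probability is the smaller of this and
#'   the baseline. Ignored (NA) for the control.
#' @return an object of class `scenario`.
#' @export
scenario <- function(site, design, start_month, light_level = 0) {
  stopifnot(start_month %in% 1:12)
  if (design$is_control) {
    light_level <- NA_real_
  } else if (!light_level %in% c(0, 0.25, 0.50, 0.75)) {
    stop("light_level must be one of 0, 0.25, 0.50, 0.75")
  }
  structure(list(site = site, design = design,
                 start_month = as.integer(start_month),
                 light_level = light_level,
                 id = sprintf("%s_%s_m%02d_l%s", site$site_name, design$label,
                              start_month,
                              ifelse(is.na(light_level), "NA",
                                     format(light_level)))),
            class = "scenario")
}

#' Run windows: initialisation / stress / response periods
#'
#' @param initialisation_months slices before dredging starts, for settling
#'   into the baseline seasonal pattern (default 24: two full cycles).
#' @param response_months slices after the last dredging month (default 60;
#'   at least 60 is required when assessing permanence, since a loss is
#'   considered permanent if the meadow has not recovered within 5 years).
#' @return an object of class `run_windows`.
#' @export
run_windows <- function(initialisation_months = 24, response_months = 60) {
  stopifnot(initialisation_months >= 0, response_months >= 1)
  structure(list(initialisation_months = as.integer(initialisation_months),
                 response_months = as.integer(response_months)),
            class = "run_windows")
}

#' Enumerate the scenario grid for a site
#'
#' Cartesian product of designs, the 12 start months and the light levels, in
#' deterministic (design, month, level) order. The control is light-invariant
#' and emitted once per start month. With the 8 standard designs, the
#' control, and a single light level this yields the 108-scenario grid.
#'
#' @param site a [site_config].
#' @param designs list of [dredge_design] objects (without the control).
#' @param light_levels numeric vector of light levels for dredge designs.
#' @param include_control emit the control design (once per month)?
#' @return list of [scenario] objects.
#' @export
enumerate_scenarios <- function(site, designs = paper_designs(),
                                light_levels = 0, include_control = TRUE) {
  stopifnot(length(designs) > 0)
  out <- list()
  for (d in designs)
    for (m in 1:12)
      for (l in light_levels)
        out[[length(out) + 1L]] <- scenario(site, d, m, l)
  if (include_control) {
    ctrl <- dredge_design(0)
    for (m in 1:12)
      out[[length(out) + 1L]] <- scenario(site, ctrl, m)
  }
  out
}

#' Per-slice light driver under a dredging scenario
#'
#' During dredging months the probability of above-saturation light is the
#' smaller of the baseline climatology and the scenario's permitted level
#' (zero under complete deprivation); during rest blocks, the initialisation
#' period and the response period it follows the baseline. Slice 0 is the
#' start of initialisation, so dredging begins exactly at the scenario's
#' start month.
#'
#' @param baseline_p 12 monthly baseline probabilities (January..December).
#' @param scn a [scenario].
#' @param windows a [run_windows].
#' @return list with `p_above` (per-slice vector), `start_month` (calendar
#'   month of slice 0), `months`, `stress_first`/`stress_last` (0-based slice
#'   indices, NA for control), `dredge_slices` and `n_slices`.
#' @export
apply_stressor_to_light <- function(baseline_p, scn, windows) {
  stopifnot(length(baseline_p) == 12L)
  pat <- stress_pattern(scn$design)
  span <- length(pat)
  init <- windows$initialisation_months
  n <- init + span + windows$response_months
  start0 <- ((scn$start_month - 1L - init) %% 12L) + 1L
  months <- month_seq(start0, n)
  p <- baseline_p[months]
  dredge <- integer(0)
  if (span > 0) {
    idx <- init + which(pat)  # 1-based slice positions
    p[idx] <- pmin(p[idx], scn$light_level)
    dredge <- idx - 1L
  }
  list(p_above = p, start_month = start0, months = months,
       stress_first = if (span) init else NA_integer_,
       stress_last = if (span) init + span - 1L else NA_integer_,
       dredge_slices = dredge, n_slices = n)
}

# Uniform initial beliefs over the interface nodes.
uniform_initial <- function(schema) {
  init <- lapply(schema$interface, function(n) {
    k <- node_card(schema, n)
    rep(1 / k, k)
  })
  names(init) <- schema$interface
  init
}

light_driver <- function(p_above) cbind(below = 1 - p_above, above = p_above)

#' Run one scenario (stressed and control trajectories)
#'
#' Runs the stressed trajectory and a month-aligned control (baseline)
#' trajectory from identical initial beliefs through the same initialisation
#' period. Initialisation convergence to a seasonal limit cycle is checked
#' and recorded (a warning, never a failure: transitory meadows cycle through
#' zero by design).
#'
#' @param scn a [scenario].
#' @param schema the site's [network_schema] (or a [dbn_compile()] result).
#' @param windows a [run_windows].
#' @param baseline optional precomputed control `dbn_trajectory` with
#'   identical slice/month alignment (reused across scenarios of one site).
#' @param check_convergence verify the baseline settles into a 12-month limit
#'   cycle during initialisation (requires initialisation >= 24).
#' @return an object of class `scenario_result` with `baseline_traj`,
#'   `response_traj`, `stress_span` and metadata.
#' @export
run_scenario <- function(scn, schema, windows = run_windows(),
                         baseline = NULL, check_convergence = FALSE) {
  cmp <- NULL
  if (inherits(schema, "dbn_compiled")) {
    cmp <- schema
    schema <- cmp$schema
  } else if (compilable_schema(schema)) {
    cmp <- dbn_compile(schema)
  }
  stressed <- apply_stressor_to_light(scn$site$light_p, scn, windows)
  init <- uniform_initial(schema)
  run <- function(p_above) {
    drv <- list(light = light_driver(p_above))
    if (is.null(cmp))
      forward_infer(schema, init, stressed$start_month, stressed$n_slices, drv)
    else
      forward_infer_compiled(cmp, init, stressed$start_month,
                             stressed$n_slices, drv)
  }
  if (is.null(baseline)) {
    base_p <- scn$site$light_p[stressed$months]
    baseline <- run(base_p)
  }
  response <- if (scn$design$is_control) baseline else run(stressed$p_above)
  convergence <- NULL
  if (check_convergence) {
    if (windows$initialisation_months >= 24) {
      sub <- traj_window(baseline, 0L, windows$initialisation_months - 1L)
      convergence <- detect_limit_cycle(
        sub, 12L, 1e-3, nodes = c("realised_shoot_density",
                                  "realised_biomass"))
      if (!convergence$converged)
        warning("baseline not settled into a 12-month cycle at tolerance ",
                "1e-3 during initialisation (scenario ", scn$id, ")")
    }
  }
  structure(list(scenario = scn, baseline_traj = baseline,
                 response_traj = response,
                 stress_span = c(first = stressed$stress_first,
                                 last = stressed$stress_last),
                 windows = windows, convergence = convergence,
                 months = stressed$months,
                 dredge_slices = stressed$dredge_slices),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s: %d slices (init %d, stress span %s, response %d)\n",
              x$scenario$id, length(x$months),
              x$windows$initialisation_months,
              ifelse(is.na(x$stress_span[1]), "none",
                     sprintf("%d..%d", x$stress_span[1], x$stress_span[2])),
              x$windows$response_months))
  invisible(x)
}

# Restrict a trajectory to slices from..to (0-based, inclusive).
traj_window <- function(traj, from, to) {
  idx <- which(traj$slice_index >= from & traj$slice_index <= to)
  structure(list(slice_index = traj$slice_index[idx] - from,
                 month = traj$month[idx],
                 marginals = lapply(traj$marginals, function(m)
                   m[idx, , drop = FALSE]),
                 interface = traj$interface,
                 interface_card = traj$interface_card,
                 interface_joint = traj$interface_joint[idx, , drop = FALSE],
                 renorm = traj$renorm[idx], schema = traj$schema),
            class = "dbn_trajectory")
}

# Compact serializable record of one scenario run (tracked nodes only).
scenario_record <- function(res, tracked = c("realised_shoot_density",
                                             "realised_biomass")) {
  scn <- res$scenario
  list(id = scn$id, site = scn$site$site_name,
       life_history = scn$site$life_history, design = scn$design$label,
       start_month = scn$start_month, light_level = scn$light_level,
       months = res$months, stress_span = unname(res$stress_span),
       dredge_slices = res$dredge_slices,
       baseline = lapply(res$baseline_traj$marginals[tracked], unname),
       response = lapply(res$response_traj$marginals[tracked], unname),
       states = lapply(res$baseline_traj$marginals[tracked], colnames))
}

#' Run a full scenario study over many sites
#'
#' Runs the scenario grid for every site (28 sites x the 108-scenario grid
#' reproduces the 3024-run study scale). Control trajectories are computed
#' once per (site, start month, horizon) and shared. With `out_dir` set,
#' results stream to disk as one JSON record per scenario and completed
#' scenario ids are skipped on re-run (resumable); per-scenario failures are
#' recorded and the study continues.
#'
#' @param sites list of [site_config] objects.
#' @param bundles named list of CPT bundles keyed by life history (e.g. from
#'   [make_study_fixture()]).
#' @param designs,light_levels,include_control passed to
#'   [enumerate_scenarios()].
#' @param windows a [run_windows].
#' @param out_dir optional directory for streaming JSON records; when set,
#'   trajectories are not kept in memory.
#' @param tracked node marginals to keep in streamed records.
#' @param quiet suppress progress messages.
#' @return with `out_dir`: data frame indexing the written records; otherwise
#'   a list of `scenario_result` objects.
#' @export
run_study <- function(sites, bundles, designs = paper_designs(),
                      light_levels = 0, windows = run_windows(),
                      include_control = TRUE, out_dir = NULL,
                      tracked = c("realised_shoot_density",
                                  "realised_biomass"),
                      quiet = TRUE) {
  results <- list()
  index <- list()
  for (site in sites) {
    schema <- build_reference_network(site, bundles[[site$life_history]])
    cmp <- dbn_compile(schema)
    scns <- enumerate_scenarios(site, designs, light_levels, include_control)
    base_cache <- list()
    for (scn in scns) {
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(scn$id, ".json"))
        if (file.exists(path)) {
          index[[length(index) + 1L]] <-
            data.frame(id = scn$id, file = path, status = "cached")
          next
        }
      }
      stressed <- apply_stressor_to_light(site$light_p, scn, windows)
      key <- sprintf("m%d_n%d", stressed$start_month, stressed$n_slices)
      if (is.null(base_cache[[key]])) {
        base_p <- site$light_p[stressed$months]
        base_cache[[key]] <- forward_infer_compiled(
          cmp, uniform_initial(schema), stressed$start_month,
          stressed$n_slices, list(light = light_driver(base_p)))
      }
      res <- tryCatch(
        run_scenario(scn, cmp, windows, baseline = base_cache[[key]]),
        error = function(e) e)
      if (inherits(res, "error")) {
        index[[length(index) + 1L]] <-
          data.frame(id = scn$id, file = NA_character_,
                     status = paste("error:", conditionMessage(res)))
        next
      }
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        path <- file.path(out_dir, paste0(scn$id, ".json"))
        jsonlite::write_json(scenario_record(res, tracked), path,
                             auto_unbox = TRUE, digits = NA)
        index[[length(index) + 1L]] <-
          data.frame(id = scn$id, file = path, status = "done")
      } else {
        results[[scn$id]] <- res
      }
      if (!quiet) message("done: ", scn$id)
    }
  }
  if (!is.null(out_dir)) do.call(rbind, index) else results
}
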