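#' Estimate monthly light-saturation probabilities from daily data
#'
#' Conjugate beta-binomial estimation of the probability of an
#' above-saturation light day for each calendar month, pooling days across
#' years: with `n_above` of `n_days` above the threshold and a Beta(a, b)
#' prior, the posterior is Beta(a + n_above, b + n_days - n_above); the
#' estimate is its mean with an equal-tailed 95% credible interval. Months
#' with no data are flagged, never interpolated.
#'
#' @param series data frame with a `date` column and either an `above` column
#'   (0/1 flags) or an `irradiance` column (requires `threshold`).
#' @param threshold saturation threshold in the irradiance units (taken from
#'   `attr(series, "threshold")` when absent).
#' @param prior length-2 beta prior parameters (default uniform Beta(1, 1)).
#' @return data frame of class `light_estimate` with one row per calendar
#'   month: `n_days`, `n_above`, `mean`, `lower`, `upper`, `estimated`.
#' @export
estimate_light_saturation_probability <- function(series, threshold = NULL,
                                                  prior = c(1, 1)) {
  if (anyDuplicated(series$date)) stop("dates must be unique")
  if (!is.null(series$above)) {
    above <- series$above
  } else if (!is.null(series$irradiance)) {
    if (any(series$irradiance < 0)) stop("irradiance must be non-negative")
    threshold <- threshold %||% attr(series, "threshold")
    if (is.null(threshold))
      stop("a saturation threshold is required with raw irradiance input")
    above <- as.integer(series$irradiance > threshold)
  } else stop("series needs an 'above' or 'irradiance' column")
  month <- as.integer(format(as.Date(series$date), "%m"))
  out <- data.frame(month = 1:12, n_days = 0L, n_above = 0L,
                    mean = NA_real_, lower = NA_real_, upper = NA_real_,
                    estimated = FALSE)
  for (m in 1:12) {
    i <- month == m
    n <- sum(i)
    if (n == 0L) next
    k <- sum(above[i])
    a <- prior[1] + k
    b <- prior[2] + n - k
    out$n_days[m] <- n
    out$n_above[m] <- k
    out$mean[m] <- a / (a + b)
    out$lower[m] <- stats::qbeta(0.025, a, b)
    out$upper[m] <- stats::qbeta(0.975, a, b)
    out$estimated[m] <- TRUE
  }
  class(out) <- c("light_estimate", "data.frame")
  out
}

#' @export
print.light_estimate <- function(x, ...) {
  cat("Monthly P(above-saturation light), beta-binomial posterior:\n")
  print.data.frame(cbind(x[1:3],
                         round(x[c("mean", "lower", "upper")], 3),
                         x["estimated"]), row.names = FALSE)
  invisible(x)
}

#' Convert replicated measurements to observed state probabilities
#'
#' Each replicate at a time point is classified through the discretization
#' scheme; the observed state-probability vector is the
#' Dirichlet(1,...,1)-multinomial posterior mean `(n_j + 1) / (n + K)` over
#' the scheme's K states. Time points without replicates are excluded and
#' flagged.
#'
#' @param obs data frame with columns `date` and `value` (one row per
#'   replicate).
#' @param reference_value positive reference in the measurement units.
#' @param scheme a [discretization_scheme].
#' @return data frame of class `observation_state_series`: `date`, `month`,
#'   `n_replicates`, one probability column per state (scheme order).
#' @export
observations_to_state_probabilities <- function(obs, reference_value, scheme) {
  if (reference_value <= 0) stop("reference value must be positive")
  states <- scheme$states$state
  K <- length(states)
  dates <- sort(unique(obs$date))
  rows <- lapply(dates, function(d) {
    v <- obs$value[obs$date == d]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    lab <- discretize_measurement(v, reference_value, scheme)
    n <- table(factor(lab, levels = states))
    p <- (as.numeric(n) + 1) / (length(v) + K)
    cbind(data.frame(date = d, month = as.integer(format(as.Date(d), "%m")),
                     n_replicates = length(v)),
          stats::setNames(as.data.frame(t(p)), states))
  })
  dropped <- dates[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (length(dropped))
    attr(out, "excluded_dates") <- dropped
  class(out) <- c("observation_state_series", "data.frame")
  out
}

#' Validation mean-squared error
#'
#' MSE between predicted state probabilities of one node and observed state
#' probabilities, over all aligned (time point x state) cells, and separately
#' over the zero-state cells only.
#'
#' @param predicted a `dbn_trajectory`.
#' @param observed an `observation_state_series` with a `slice` column
#'   (0-based slice index of each time point), or a matrix of observed
#'   probabilities with rows named by slice.
#' @param node tracked node name.
#' @param zero_label name of the zero state column.
#' @return list of class `validation_report`: `mse_all_states`,
#'   `mse_zero_state`, `n_points`, `residuals` (time point x state matrix).
#' @export
validation_mse <- function(predicted, observed,
                           node = "realised_shoot_density",
                           zero_label = "zero") {
  pm <- predicted$marginals[[node]]
  if (is.null(pm)) stop("node '", node, "' not present in the trajectory")
  states <- colnames(pm)
  if (is.null(observed$slice))
    stop("observed series needs a 'slice' column for alignment")
  if (!all(states %in% colnames(observed)))
    stop("observed series lacks state column(s): ",
         paste(setdiff(states, colnames(observed)), collapse = ", "))
  keep <- observed$slice %in% predicted$slice_index
  if (!any(keep)) stop("no observation aligns with a predicted slice")
  obs <- observed[keep, , drop = FALSE]
  om <- as.matrix(obs[, states, drop = FALSE])
  idx <- match(obs$slice, predicted$slice_index)
  res <- om - pm[idx, , drop = FALSE]
  if (!zero_label %in% states)
    stop("observed missing the zero state column '", zero_label, "'")
  structure(list(mse_all_states = mean(res^2),
                 mse_zero_state = mean(res[, zero_label]^2),
                 n_points = nrow(om), residuals = res),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Validation MSE over %d time points: all states %.4g, zero state %.4g\n",
    x$n_points, x$mse_all_states, x$mse_zero_state))
  invisible(x)
}

# Logit with clipping (probabilities at 0/1 occur in near-deterministic
# regimes).
clipped_logit <- function(p, eps = 1e-6) stats::qlogis(pmin(pmax(p, eps),
                                                            1 - eps))

# Long predictor table from a list of trajectories: one column per
# (node, state) posterior probability, logit transformed, at t and t-1.
influence_design <- function(trajs, nodes = NULL, eps = 1e-6) {
  blocks <- lapply(trajs, function(tr) {
    nds <- nodes %||% names(tr$marginals)
    cols <- do.call(cbind, lapply(nds, function(n) {
      m <- tr$marginals[[n]]
      colnames(m) <- paste(n, colnames(m), sep = ".")
      m
    }))
    lg <- clipped_logit(cols, eps)
    t_now <- lg[-1, , drop = FALSE]
    t_lag <- lg[-nrow(lg), , drop = FALSE]
    colnames(t_lag) <- paste0(colnames(t_lag), ".lag1")
    cbind(t_now, t_lag)
  })
  do.call(rbind, blocks)
}

#' Boosted-regression-tree sensitivity analysis
#'
#' Ranks the influence of every (node, state) posterior-probability variable
#' on selected response variables. The design matrix holds logit-transformed
#' posterior probabilities at t plus a one-step lag (matching the DBN's
#' order); one gradient-boosted regression tree ensemble is fitted per
#' response (e.g. the four states of shoot density, and equivalently
#' biomass), and the normalized relative influence (total gain) is reported,
#' with the set of variables whose weight lies within two orders of magnitude
#' of the maximum flagged as most influential. Constant responses are flagged
#' and skipped.
#'
#' @param results list of `scenario_result` objects (or `dbn_trajectory`
#'   objects) from at least 2 scenarios.
#' @param response_nodes nodes whose states are used as responses.
#' @param predictor_nodes nodes contributing predictor variables (default:
#'   all).
#' @param seed integer seed (fitting is deterministic given it).
#' @param nrounds,max_depth,eta boosting parameters.
#' @param eps logit clipping.
#' @return object of class `influence_report`: per response a data frame of
#'   normalized weights with a `top` flag, plus training R-squared.
#' @export
sensitivity_influence <- function(results,
                                  response_nodes = c("realised_shoot_density",
                                                     "realised_biomass"),
                                  predictor_nodes = NULL, seed = 1L,
                                  nrounds = 60, max_depth = 3, eta = 0.3,
                                  eps = 1e-6) {
  if (length(results) < 2L) stop("need results from at least 2 scenarios")
  trajs <- lapply(results, function(r)
    if (inherits(r, "scenario_result")) r$response_traj else r)
  X <- influence_design(trajs, predictor_nodes, eps)
  reports <- list()
  for (rn in response_nodes) {
    states <- colnames(trajs[[1]]$marginals[[rn]])
    for (stt in states) {
      resp_col <- paste(rn, stt, sep = ".")
      y <- X[, resp_col]
      if (stats::sd(y) < 1e-12) {
        reports[[resp_col]] <- list(skipped = TRUE,
                                    reason = "constant response")
        next
      }
      # contemporaneous states of the response's own node are deterministic
      # complements of the response and are excluded; its lagged states
      # (including the lagged self) remain predictors
      own <- paste(rn, states, sep = ".")
      keep <- setdiff(colnames(X), own)
      set.seed(seed)
      dm <- xgboost::xgb.DMatrix(X[, keep, drop = FALSE], label = y,
                                 nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(max_depth = max_depth, eta = eta, nthread = 1,
                      objective = "reg:squarederror"),
        data = dm, nrounds = nrounds, verbose = 0)
      imp <- xgboost::xgb.importance(model = fit)
      w <- stats::setNames(rep(0, length(keep)), keep)
      w[imp$Feature] <- imp$Gain
      w <- w / sum(w)
      pred <- stats::predict(fit, dm)
      r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
      df <- data.frame(variable = names(w), weight = unname(w))
      df <- df[order(-df$weight), ]
      df$top <- df$weight >= max(df$weight) / 100
      rownames(df) <- NULL
      reports[[resp_col]] <- list(skipped = FALSE, influence = df, r2 = r2,
                                  mse = mean((y - pred)^2))
    }
  }
  structure(list(responses = reports, n_rows = nrow(X),
                 n_scenarios = length(results)),
            class = "influence_report")
}

#' @export
print.influence_report <- function(x, top_n = 5, ...) {
  cat(sprintf("Sensitivity analysis over %d scenarios (%d rows)\n",
              x$n_scenarios, x$n_rows))
  for (rn in names(x$responses)) {
    r <- x$responses[[rn]]
    if (isTRUE(r$skipped)) {
      cat(sprintf("  %s: skipped (%s)\n", rn, r$reason))
      next
    }
    lead <- utils::head(r$influence, top_n)
    cat(sprintf("  %s (R2 %.3f): %s\n", rn, r$r2,
                paste(sprintf("%s %.3f", lead$variable, lead$weight),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Deterministic reference-value calibration
#'
#' Replaces visual calibration of observations against predictions by a grid
#' search over a scaling of the reference value, minimizing the all-states
#' validation MSE.
#'
#' @param predicted a `dbn_trajectory`.
#' @param obs replicate-level observations (see
#'   [observations_to_state_probabilities()]) with a `slice` column.
#' @param reference_value initial reference.
#' @param scheme a [discretization_scheme].
#' @param node tracked node.
#' @param scales candidate multiplicative scalings.
#' @return list with the selected `scale`, `reference_value` and the
#'   corresponding `validation_report`.
#' @export
calibrate_reference_value <- function(predicted, obs, reference_value,
                                      scheme =
                                        discretization_scheme("population"),
                                      node = "realised_shoot_density",
                                      scales = seq(0.5, 2, by = 0.1)) {
  best <- NULL
  for (s in scales) {
    oss <- observations_to_state_probabilities(obs, reference_value * s,
                                               scheme)
    oss$slice <- obs$slice[match(oss$date, obs$date)]
    rep <- validation_mse(predicted, oss, node)
    if (is.null(best) || rep$mse_all_states < best$report$mse_all_states)
      best <- list(scale = s, reference_value = reference_value * s,
                   report = rep)
  }
  best
}
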