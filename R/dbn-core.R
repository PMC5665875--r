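#' Ordered state space of a discrete node
#'
#' Defines the ordered categories a node can take, optionally designating one
#' category as the absorbing-risk ("zero") state used by the extinction-risk
#' metrics.
#'
#' @param labels character vector of at least two unique state names, ordered
#'   from worst to best where the order is meaningful.
#' @param zero_label optional name of the zero (local extinction risk) state;
#'   must be one of `labels`.
#' @return an object of class `state_space`.
#' @export
state_space <- function(labels, zero_label = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a state space needs at least 2 labels")
  if (anyDuplicated(labels)) stop("state labels must be unique")
  if (!is.null(zero_label) && !zero_label %in% labels)
    stop("zero_label must be one of the labels")
  structure(list(labels = labels, zero_label = zero_label),
            class = "state_space")
}

#' Node specification for a dynamic Bayesian network
#'
#' @param name node identifier.
#' @param states a [state_space] or character vector of labels.
#' @param intra_parents names of parents in the same time slice.
#' @param inter_parents names of parents in the previous time slice.
#' @param role one of `"environment"`, `"site"`, `"population"`, `"process"`,
#'   `"output"`. Environment nodes receive per-slice soft evidence (drivers)
#'   instead of a conditional table.
#' @return an object of class `node_spec`.
#' @export
node_spec <- function(name, states, intra_parents = character(0),
                      inter_parents = character(0),
                      role = c("process", "environment", "site", "population",
                               "output")) {
  role <- match.arg(role)
  if (!inherits(states, "state_space")) states <- state_space(states)
  structure(list(name = name, states = states,
                 intra_parents = as.character(intra_parents),
                 inter_parents = as.character(inter_parents), role = role),
            class = "node_spec")
}

# Canonical reference to a previous-slice parent inside a parent_order.
prev_ref <- function(name) paste0(name, "@prev")
is_prev_ref <- function(x) grepl("@prev$", x)
strip_prev <- function(x) sub("@prev$", "", x)

#' Conditional probability table
#'
#' Dense table over the full parent-state grid. Rows are ordered so that the
#' first parent in `parent_order` cycles fastest; previous-slice parents are
#' referenced as `"<name>@prev"`.
#'
#' @param child child node name.
#' @param parent_order character vector of parent references.
#' @param prob numeric matrix, one row per parent-state combination (in grid
#'   order), one column per child state.
#' @return an object of class `dbn_cpt`.
#' @export
cpt <- function(child, parent_order, prob) {
  prob <- as.matrix(prob)
  structure(list(child = child, parent_order = as.character(parent_order),
                 prob = prob), class = "dbn_cpt")
}

#' Regime selector mapping time to a conditional table
#'
#' Encodes non-homogeneous dynamics: each rule maps calendar months (and
#' optionally slice-index ranges) to a named table; the first matching rule
#' wins, otherwise `default` applies.
#'
#' @param default table identifier used when no rule matches.
#' @param rules list of `list(months =, slices =, table =)` entries; `months`
#'   is an integer vector in 1..12, `slices` an inclusive `c(from, to)` range
#'   of 0-based slice indices; either may be omitted.
#' @return an object of class `regime_selector`.
#' @export
regime_selector <- function(default, rules = list()) {
  structure(list(default = default, rules = rules), class = "regime_selector")
}

resolve_table_id <- function(selector, slice_index, month) {
  if (is.character(selector)) return(selector)
  for (r in selector$rules) {
    ok <- TRUE
    if (!is.null(r$months) && !(month %in% r$months)) ok <- FALSE
    if (!is.null(r$slices) &&
        !(slice_index >= r$slices[1] && slice_index <= r$slices[2]))
      ok <- FALSE
    if (ok) return(r$table)
  }
  selector$default
}

#' Assemble a dynamic Bayesian network schema
#'
#' @param nodes list of [node_spec] objects.
#' @param tables named list of [cpt] objects.
#' @param selectors named list (by node name) of [regime_selector] objects or
#'   plain table-id strings; environment nodes need no selector.
#' @return an object of class `dbn_schema`. The `interface` field is derived:
#'   the set of nodes appearing in any node's `inter_parents` (the nodes whose
#'   joint distribution must be carried between slices for exact filtering).
#' @seealso [validate_schema()], [forward_infer()]
#' @export
network_schema <- function(nodes, tables, selectors) {
  names(nodes) <- vapply(nodes, function(n) n$name, character(1))
  interface <- unique(unlist(lapply(nodes, function(n) n$inter_parents)))
  interface <- intersect(names(nodes), interface)  # keep schema order
  structure(list(nodes = nodes, tables = tables, selectors = selectors,
                 interface = interface), class = "dbn_schema")
}

#' @export
print.dbn_schema <- function(x, ...) {
  cat("Dynamic Bayesian network schema\n")
  cat(sprintf("  nodes: %d (%s)\n", length(x$nodes),
              paste(names(x$nodes), collapse = ", ")))
  cat(sprintf("  interface (cross-slice): %s\n",
              paste(x$interface, collapse = ", ")))
  cat(sprintf("  tables: %d\n", length(x$tables)))
  invisible(x)
}

node_card <- function(schema, name) length(schema$nodes[[name]]$states$labels)

# Cardinalities for a parent_order (prev refs resolve to the same node's
# state space).
parent_cards <- function(schema, parent_order) {
  vapply(parent_order, function(p) node_card(schema, strip_prev(p)),
         integer(1))
}

# Canonical row labels for a CPT's parent grid, first parent fastest.
parent_grid_labels <- function(schema, parent_order) {
  if (length(parent_order) == 0L) return("(none)")
  states <- lapply(parent_order, function(p)
    schema$nodes[[strip_prev(p)]]$states$labels)
  g <- expand.grid(states, stringsAsFactors = FALSE)
  apply(g, 1L, function(r) paste(paste0(parent_order, "=", r), collapse = ","))
}

topo_order <- function(schema) {
  nm <- names(schema$nodes)
  deps <- lapply(schema$nodes, function(n) intersect(n$intra_parents, nm))
  out <- character(0)
  repeat {
    ready <- nm[!nm %in% out &
                  vapply(nm, function(x) all(deps[[x]] %in% out), logical(1))]
    ready <- setdiff(ready, out)
    if (!length(ready)) break
    out <- c(out, ready)
  }
  if (length(out) != length(nm)) return(NULL)  # cycle
  out
}

#' Validate a network schema
#'
#' Checks every structural invariant: state spaces, parent resolution,
#' acyclicity of the intra-slice graph, selector coverage, table existence and
#' shape, dense parent grids, row normalization, and the derived interface
#' set. Returns diagnostics rather than throwing.
#'
#' @param schema a [network_schema].
#' @param tol tolerance for CPT row sums.
#' @return character vector of human-readable diagnostics; `character(0)` iff
#'   the schema is well formed.
#' @export
validate_schema <- function(schema, tol = 1e-9) {
  d <- character(0)
  nm <- names(schema$nodes)
  if (anyDuplicated(nm)) d <- c(d, "duplicate node names")
  for (n in schema$nodes) {
    ss <- n$states
    if (length(ss$labels) < 2L)
      d <- c(d, sprintf("node '%s': fewer than 2 states", n$name))
    if (anyDuplicated(ss$labels))
      d <- c(d, sprintf("node '%s': duplicate state labels", n$name))
    if (!is.null(ss$zero_label) && !ss$zero_label %in% ss$labels)
      d <- c(d, sprintf("node '%s': zero_label not a state", n$name))
    if (n$name %in% n$intra_parents)
      d <- c(d, sprintf("node '%s': self-parent within slice", n$name))
    bad <- setdiff(c(n$intra_parents, n$inter_parents), nm)
    for (b in bad)
      d <- c(d, sprintf("node '%s': unresolved parent '%s'", n$name, b))
  }
  if (is.null(topo_order(schema)))
    d <- c(d, "intra-slice parent graph has a cycle")
  # interface derivation check
  expect_iface <- intersect(nm, unique(unlist(
    lapply(schema$nodes, function(n) n$inter_parents))))
  if (!setequal(schema$interface, expect_iface))
    d <- c(d, "interface set does not equal nodes with cross-slice children")
  # selectors and tables
  for (n in schema$nodes) {
    if (n$role == "environment") next
    sel <- schema$selectors[[n$name]]
    if (is.null(sel)) {
      d <- c(d, sprintf("node '%s': no selector/table assigned", n$name))
      next
    }
    ids <- unique(c(if (is.character(sel)) sel else sel$default,
                    if (!is.character(sel))
                      vapply(sel$rules, `[[`, character(1), "table")))
    for (m in 1:12) {
      id <- resolve_table_id(sel, 0L, m)
      if (is.null(id) || !id %in% names(schema$tables))
        d <- c(d, sprintf("node '%s': no table resolves for month %d", n$name, m))
    }
    for (id in ids) {
      tab <- schema$tables[[id]]
      if (is.null(tab)) {
        d <- c(d, sprintf("table '%s' (node '%s'): missing", id, n$name))
        next
      }
      if (tab$child != n$name)
        d <- c(d, sprintf("table '%s': child '%s' but assigned to node '%s'",
                          id, tab$child, n$name))
      want <- c(n$intra_parents, prev_ref(n$inter_parents))
      if (length(n$inter_parents) == 0L) want <- n$intra_parents
      if (!setequal(tab$parent_order, want))
        d <- c(d, sprintf(
          "table '%s': parent_order {%s} does not match node parents {%s}",
          id, paste(tab$parent_order, collapse = ","),
          paste(want, collapse = ",")))
      bad_ref <- setdiff(strip_prev(tab$parent_order), nm)
      if (length(bad_ref)) next
      nrow_want <- prod(parent_cards(schema, tab$parent_order))
      if (nrow(tab$prob) != nrow_want) {
        labels <- parent_grid_labels(schema, tab$parent_order)
        have <- rownames(tab$prob)
        missing <- if (!is.null(have)) setdiff(labels, have) else character(0)
        if (length(missing))
          d <- c(d, sprintf("table '%s': missing parent-combination row(s): %s",
                            id, paste(missing, collapse = "; ")))
        else
          d <- c(d, sprintf("table '%s': %d rows, expected %d (dense grid)",
                            id, nrow(tab$prob), nrow_want))
      }
      if (ncol(tab$prob) != node_card(schema, n$name))
        d <- c(d, sprintf("table '%s': %d columns, expected %d states",
                          id, ncol(tab$prob), node_card(schema, n$name)))
      if (any(tab$prob < 0 | tab$prob > 1))
        d <- c(d, sprintf("table '%s': entries outside [0,1]", id))
      rs <- rowSums(tab$prob)
      bad_rows <- which(abs(rs - 1) > tol)
      for (r in bad_rows)
        d <- c(d, sprintf("table '%s': row %d sums to %.10g, not 1", id, r, rs[r]))
    }
  }
  d
}

# --- drivers -----------------------------------------------------------------

# Normalize driver input to a list (per environment node) of
# n_slices x card matrices of per-slice soft-evidence distributions.
normalize_drivers <- function(schema, drivers, n_slices) {
  env_nodes <- names(schema$nodes)[vapply(schema$nodes, function(n)
    n$role == "environment", logical(1))]
  out <- list()
  for (e in env_nodes) {
    card <- node_card(schema, e)
    dr <- drivers[[e]]
    if (is.null(dr)) stop("driver missing for environment node '", e, "'")
    if (is.function(dr)) {
      m <- t(vapply(seq_len(n_slices) - 1L, function(s) dr(s), numeric(card)))
    } else if (is.matrix(dr)) {
      if (nrow(dr) < n_slices)
        stop("driver for '", e, "' covers ", nrow(dr), " slices, need ",
             n_slices)
      m <- dr[seq_len(n_slices), , drop = FALSE]
    } else {
      m <- matrix(dr, nrow = n_slices, ncol = card, byrow = TRUE)
    }
    if (ncol(m) != card) stop("driver for '", e, "' has wrong state count")
    if (any(abs(rowSums(m) - 1) > 1e-9))
      stop("driver for '", e, "' has unnormalized rows")
    out[[e]] <- m
  }
  out
}

# Initial joint over the interface nodes from independent marginals (named
# list) or an already-joint factor.
initial_joint_factor <- function(schema, initial, prefix = "prev.") {
  iface <- schema$interface
  if (length(iface) == 0L)
    return(fct(character(0), integer(0), 1))
  cards <- vapply(iface, function(n) node_card(schema, n), integer(1))
  if (is.list(initial) && !is.null(initial$vars)) {
    stopifnot(setequal(initial$vars, iface))
    f <- f_marginalize(initial, iface)  # reorder not guaranteed; remap below
    i <- f_index_map(iface, cards, f$vars, f$card)
    return(fct(paste0(prefix, iface), cards, f$val[i]))
  }
  f <- NULL
  for (n in iface) {
    p <- initial[[n]]
    if (is.null(p)) stop("initial marginal missing for interface node '", n, "'")
    if (abs(sum(p) - 1) > 1e-9) stop("initial marginal for '", n,
                                     "' not normalized")
    f <- f_product(f, fct(paste0(prefix, n), node_card(schema, n), p))
  }
  f
}

# Build the per-node factor for one slice. Environment nodes get the driver
# distribution; others their regime-resolved CPT.
slice_node_factor <- function(schema, node, slice_index, month, driver_row) {
  n <- schema$nodes[[node]]
  card <- node_card(schema, node)
  if (n$role == "environment") {
    return(fct(node, card, driver_row))
  }
  id <- resolve_table_id(schema$selectors[[node]], slice_index, month)
  tab <- schema$tables[[id]]
  pvars <- ifelse(is_prev_ref(tab$parent_order),
                  paste0("prev.", strip_prev(tab$parent_order)),
                  tab$parent_order)
  pcards <- parent_cards(schema, tab$parent_order)
  fct(c(pvars, node), c(pcards, card), as.vector(tab$prob))
}

month_seq <- function(start_month, n_slices) {
  ((start_month - 1L + seq_len(n_slices) - 1L) %% 12L) + 1L
}

#' Exact forward filtering of a non-homogeneous DBN
#'
#' Propagates the joint distribution over the interface nodes slice by slice
#' (sum-product over intra-slice factors with cross-slice conditioning) and
#' extracts per-node marginals. No sampling, no projection: inference is exact
#' over the interface joint.
#'
#' @param schema a validated [network_schema].
#' @param initial named list of marginals over the interface nodes (combined
#'   as independent), or a joint factor `list(vars, card, val)`.
#' @param start_month calendar month (1--12) of slice 0.
#' @param n_slices number of monthly slices to compute (>= 1).
#' @param drivers named list, one entry per environment node: an
#'   `n_slices x n_states` matrix of per-slice soft-evidence distributions, a
#'   single distribution recycled over slices, or a `function(slice_index)`.
#' @param interface_cap resource guard: maximum number of joint interface
#'   states; exceeding it raises an error rather than approximating.
#' @return an object of class `dbn_trajectory` with per-slice months,
#'   per-node marginal matrices, interface joints and a renormalization log.
#' @export
forward_infer <- function(schema, initial, start_month, n_slices, drivers,
                          interface_cap = 1e5) {
  stopifnot(n_slices >= 1, start_month %in% 1:12)
  iface <- schema$interface
  icards <- vapply(iface, function(n) node_card(schema, n), integer(1))
  if (length(iface) && prod(icards) > interface_cap)
    stop("interface joint has ", prod(icards), " states, exceeding the cap (",
         interface_cap, "); exact filtering refused")
  dr <- normalize_drivers(schema, drivers, n_slices)
  order_nodes <- topo_order(schema)
  if (is.null(order_nodes)) stop("intra-slice graph is cyclic")
  months <- month_seq(start_month, n_slices)
  prev <- initial_joint_factor(schema, initial)

  marg <- lapply(names(schema$nodes), function(n)
    matrix(NA_real_, n_slices, node_card(schema, n),
           dimnames = list(NULL, schema$nodes[[n]]$states$labels)))
  names(marg) <- names(schema$nodes)
  ijoint <- matrix(NA_real_, n_slices, max(1L, prod(icards)))
  renorm <- numeric(n_slices)

  for (t in seq_len(n_slices)) {
    m <- months[t]
    factors <- vector("list", length(order_nodes) + 1L)
    marginal_of <- c(NA_character_, order_nodes)
    factors[[1L]] <- prev
    for (k in seq_along(order_nodes)) {
      nd <- order_nodes[k]
      row <- if (!is.null(dr[[nd]])) dr[[nd]][t, ] else NULL
      factors[[k + 1L]] <- slice_node_factor(schema, nd, t - 1L, m, row)
    }
    res <- f_eliminate(factors, keep = iface, marginal_of = marginal_of)
    for (nd in order_nodes) {
      mf <- f_marginalize(res$marginals[[nd]], nd)
      s <- sum(mf$val)
      marg[[nd]][t, ] <- mf$val / s
    }
    fr <- res$frontier
    if (length(iface)) {
      i <- f_index_map(iface, icards, fr$vars, fr$card)
      v <- fr$val[i]
      s <- sum(v)
      renorm[t] <- abs(s - 1)
      v <- v / s
      ijoint[t, ] <- v
      prev <- fct(paste0("prev.", iface), icards, v)
    } else {
      renorm[t] <- abs(f_total(fr) - 1)
      ijoint[t, 1L] <- 1
      prev <- fct(character(0), integer(0), 1)
    }
  }
  if (any(renorm > 1e-6))
    warning(sprintf("renormalization exceeded 1e-6 at %d slice(s); max %.3g",
                    sum(renorm > 1e-6), max(renorm)))
  structure(list(slice_index = seq_len(n_slices) - 1L, month = months,
                 marginals = marg, interface = iface,
                 interface_card = icards, interface_joint = ijoint,
                 renorm = renorm, schema = schema),
            class = "dbn_trajectory")
}

#' @export
print.dbn_trajectory <- function(x, ...) {
  cat(sprintf("DBN trajectory: %d monthly slices (months %d..%d), %d nodes\n",
              length(x$slice_index), x$month[1],
              x$month[length(x$month)], length(x$marginals)))
  cat(sprintf("  interface: %s\n", paste(x$interface, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.dbn_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  out <- do.call(rbind, lapply(names(x$marginals), function(n) {
    m <- x$marginals[[n]]
    data.frame(slice = rep(x$slice_index, ncol(m)),
               month = rep(x$month, ncol(m)), node = n,
               state = rep(colnames(m), each = nrow(m)),
               probability = as.vector(m))
  }))
  rownames(out) <- row.names
  out
}

#' Plot state-probability trajectories
#'
#' @param x a `dbn_trajectory`.
#' @param node node name to plot (default: first node).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dbn_trajectory <- function(x, node = names(x$marginals)[1], ...) {
  m <- x$marginals[[node]]
  graphics::matplot(x$slice_index, m, type = "l", lty = 1,
                    xlab = "slice (month)", ylab = "probability",
                    main = node, ...)
  graphics::legend("topright", colnames(m), lty = 1,
                   col = seq_len(ncol(m)), bty = "n", cex = 0.8)
  invisible(x)
}

#' Brute-force exact filtering oracle
#'
#' Reference implementation for [forward_infer()]: at each slice the complete
#' joint distribution over *all* nodes is obtained by direct enumeration of
#' every (previous interface state, current full state) assignment pair and
#' multiplication of the corresponding table entries, then marginalized. No
#' factor algebra is shared with [forward_infer()].
#'
#' @inheritParams forward_infer
#' @param cap resource guard on the enumeration size
#'   (`interface states x full slice states`).
#' @return a `dbn_trajectory` (interface joints included).
#' @export
brute_force_trajectory_joint <- function(schema, initial, start_month,
                                         n_slices, drivers, cap = 1e7) {
  nm <- names(schema$nodes)
  cards <- vapply(nm, function(n) node_card(schema, n), integer(1))
  iface <- schema$interface
  icards <- cards[iface]
  n_full <- prod(cards)
  n_pre <- max(1L, prod(icards))
  if (n_pre * n_full > cap)
    stop("enumeration size ", n_pre * n_full, " exceeds cap ", cap)
  dr <- normalize_drivers(schema, drivers, n_slices)
  months <- month_seq(start_month, n_slices)

  # full grid of current-slice assignments, one row per joint state
  grid <- as.matrix(expand.grid(lapply(cards, seq_len)))
  colnames(grid) <- nm
  pre_grid <- if (length(iface))
    as.matrix(expand.grid(lapply(icards, seq_len))) else
      matrix(0L, 1, 0)
  if (length(iface)) colnames(pre_grid) <- iface

  # initial joint over interface as a vector over pre_grid rows
  pf <- initial_joint_factor(schema, initial, prefix = "")
  if (length(iface)) {
    i <- f_index_map(iface, icards, f_index_map_vars <- pf$vars, pf$card)
    prev <- pf$val[i]
  } else prev <- 1

  marg <- lapply(nm, function(n)
    matrix(NA_real_, n_slices, cards[[n]],
           dimnames = list(NULL, schema$nodes[[n]]$states$labels)))
  names(marg) <- nm
  ijoint <- matrix(NA_real_, n_slices, n_pre)

  # interface index of each full-grid row (for projecting to next prev)
  if (length(iface)) {
    istride <- cumprod(c(1, icards))[seq_along(icards)]
    full_to_iface <- as.integer(
      (grid[, iface, drop = FALSE] - 1L) %*% istride) + 1L
  }

  for (t in seq_len(n_slices)) {
    m <- months[t]
    joint <- numeric(n_full)
    for (p in seq_len(n_pre)) {
      if (prev[p] == 0) next
      w <- rep.int(prev[p], n_full)
      for (nd in nm) {
        spec <- schema$nodes[[nd]]
        child_idx <- grid[, nd]
        if (spec$role == "environment") {
          w <- w * dr[[nd]][t, child_idx]
          next
        }
        id <- resolve_table_id(schema$selectors[[nd]], t - 1L, m)
        tab <- schema$tables[[id]]
        if (length(tab$parent_order) == 0L) {
          w <- w * tab$prob[1L, child_idx]
        } else {
          pcards <- parent_cards(schema, tab$parent_order)
          stride <- cumprod(c(1, pcards))[seq_along(pcards)]
          row_idx <- rep.int(1L, n_full)
          for (k in seq_along(tab$parent_order)) {
            pref <- tab$parent_order[k]
            if (is_prev_ref(pref)) {
              st <- pre_grid[p, strip_prev(pref)]
              row_idx <- row_idx + (st - 1L) * stride[k]
            } else {
              row_idx <- row_idx + (grid[, pref] - 1L) * stride[k]
            }
          }
          w <- w * tab$prob[cbind(row_idx, child_idx)]
        }
      }
      joint <- joint + w
    }
    joint <- joint / sum(joint)
    for (nd in nm) {
      agg <- rowsum(joint, grid[, nd])
      marg[[nd]][t, ] <- agg[, 1L]
    }
    if (length(iface)) {
      agg <- rowsum(joint, full_to_iface)
      prev <- numeric(n_pre)
      prev[as.integer(rownames(agg))] <- agg[, 1L]
      ijoint[t, ] <- prev
    } else ijoint[t, 1L] <- 1
  }
  structure(list(slice_index = seq_len(n_slices) - 1L, month = months,
                 marginals = marg, interface = iface,
                 interface_card = icards, interface_joint = ijoint,
                 renorm = rep(0, n_slices), schema = schema),
            class = "dbn_trajectory")
}

#' Detect a settled seasonal limit cycle
#'
#' A trajectory has settled into a limit cycle of the given period when the
#' month-matched marginals of two consecutive periods agree within `tol` in
#' total-variation distance for all tracked nodes.
#'
#' @param traj a `dbn_trajectory` with at least `2 * period` slices.
#' @param period cycle length in slices (12 for an annual cycle).
#' @param tol total-variation tolerance.
#' @param nodes nodes to track (default: all).
#' @return `list(converged =, cycle_start_slice =)`; `cycle_start_slice` is
#'   the first slice (0-based) of the earliest detected cycle, or `NULL`.
#' @export
detect_limit_cycle <- function(traj, period = 12L, tol = 1e-3, nodes = NULL) {
  n <- length(traj$slice_index)
  if (n < 2L * period) stop("need at least 2*period slices")
  if (is.null(nodes)) nodes <- names(traj$marginals)
  for (c0 in 0:(n - 2L * period)) {
    ok <- TRUE
    for (s in c0:(c0 + period - 1L)) {
      for (nd in nodes) {
        tv <- 0.5 * sum(abs(traj$marginals[[nd]][s + 1L, ] -
                              traj$marginals[[nd]][s + period + 1L, ]))
        if (tv >= tol) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(list(converged = TRUE, cycle_start_slice = c0))
  }
  list(converged = FALSE, cycle_start_slice = NULL)
}
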