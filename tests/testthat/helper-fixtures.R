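# Shared fixtures, cached across test files. Bundles and compiled networks
# are deterministic (seed 1), so caching changes nothing but runtime.

.fx <- new.env(parent = emptyenv())

fx_site <- function(lh) example_sites()[[lh]]

fx_bundle <- function(lh) {
  key <- paste0("bundle.", lh)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- synth_site_archetype_cpts(archetype_params(lh), seed = 1)
  .fx[[key]]
}

fx_schema <- function(lh) {
  key <- paste0("schema.", lh)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- build_reference_network(fx_site(lh), fx_bundle(lh))
  .fx[[key]]
}

fx_compiled <- function(lh) {
  key <- paste0("compiled.", lh)
  if (is.null(.fx[[key]])) .fx[[key]] <- dbn_compile(fx_schema(lh))
  .fx[[key]]
}

# Run one scenario on a fixture site with a per-(life history, phase,
# horizon) baseline cache.
fx_run <- function(lh, total, rest = 0, month = 1, level = 0,
                   windows = run_windows()) {
  site <- fx_site(lh)
  design <- if (total == 0) dredge_design(0) else dredge_design(total, rest)
  scn <- scenario(site, design, month, level)
  stress <- apply_stressor_to_light(site$light_p, scn, windows)
  key <- sprintf("base.%s.%d.%d", lh, stress$start_month, stress$n_slices)
  cmp <- fx_compiled(lh)
  if (is.null(.fx[[key]])) {
    base_p <- site$light_p[stress$months]
    .fx[[key]] <- forward_infer_compiled(
      cmp, ecowindows:::uniform_initial(cmp$schema), stress$start_month,
      stress$n_slices, list(light = cbind(1 - base_p, base_p)))
  }
  run_scenario(scn, cmp, windows, baseline = .fx[[key]])
}

fx_assess <- function(...) assess_scenario(fx_run(...))

rt_num <- function(cr) {
  if (is.character(cr$recovery_time_months)) Inf else cr$recovery_time_months
}

# Random small DBN for the oracle-equivalence sweep: 2-4 nodes, 2-3 states,
# random intra-slice DAG edges, random cross-slice parents, a regime switch
# on one node, and one optional environment root.
random_small_net <- function(seed) {
  set.seed(seed)
  n_nodes <- sample(2:4, 1)
  cards <- sample(2:3, n_nodes, replace = TRUE)
  names_ <- paste0("n", seq_len(n_nodes))
  with_env <- n_nodes > 2 && runif(1) < 0.5
  rrow <- function(nr, k) {
    m <- matrix(rgamma(nr * k, 1) + 0.05, nr, k)
    m / rowSums(m)
  }
  nodes <- list()
  tables <- list()
  selectors <- list()
  for (i in seq_len(n_nodes)) {
    nm <- names_[i]
    if (with_env && i == 1L) {
      nodes[[i]] <- node_spec(nm, paste0("s", seq_len(cards[i])),
                              role = "environment")
      next
    }
    prev_pool <- names_[seq_len(max(0, i - 1))]
    intra <- prev_pool[runif(length(prev_pool)) < 0.5]
    inter_pool <- setdiff(names_, character(0))
    inter <- inter_pool[runif(length(inter_pool)) < 0.3]
    if (i == n_nodes && length(inter) == 0 && !any(
      vapply(nodes, function(n) length(n$inter_parents) > 0, logical(1))))
      inter <- names_[1 + with_env]  # ensure a non-empty interface
    nodes[[i]] <- node_spec(nm, paste0("s", seq_len(cards[i])),
                            intra_parents = intra, inter_parents = inter)
    po <- c(intra, if (length(inter)) paste0(inter, "@prev"))
    nr <- prod(cards[match(c(intra, inter), names_)])
    if (length(po) == 0L) nr <- 1L
    id1 <- paste0("t.", nm)
    tables[[id1]] <- cpt(nm, po, rrow(nr, cards[i]))
    if (runif(1) < 0.4) {
      id2 <- paste0("t2.", nm)
      tables[[id2]] <- cpt(nm, po, rrow(nr, cards[i]))
      selectors[[nm]] <- regime_selector(
        id1, list(list(months = sample(1:12, 4), table = id2)))
    } else selectors[[nm]] <- id1
  }
  schema <- network_schema(nodes, tables, selectors)
  n_slices <- sample(4:24, 1)
  drivers <- list()
  env_nodes <- names_[vapply(nodes, function(n) n$role == "environment",
                             logical(1))]
  for (e in env_nodes) {
    m <- matrix(runif(n_slices * cards[match(e, names_)]), n_slices)
    drivers[[e]] <- m / rowSums(m)
  }
  init <- lapply(schema$interface, function(nd) {
    v <- runif(cards[match(nd, names_)]) + 0.05
    v / sum(v)
  })
  names(init) <- schema$interface
  list(schema = schema, init = init, start_month = sample(1:12, 1),
       n_slices = n_slices, drivers = drivers)
}
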