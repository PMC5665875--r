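# YAML serialization of network schemas and site configurations. The wire
# format is described normatively by inst/schema/network-schema.json;
# validate_schema() enforces strictly more (dense grids, row sums,
# acyclicity) after loading.

#' Write a network schema to YAML
#'
#' CPT rows are keyed by their full parent-state combination
#' (`"p1=s1,p2=s2"`), previous-slice parents referenced as `"<name>@prev"`.
#'
#' @param schema a [network_schema].
#' @param path output file.
#' @export
write_network_yaml <- function(schema, path) {
  nodes <- lapply(schema$nodes, function(n)
    list(name = n$name, states = n$states$labels,
         zero_label = n$states$zero_label,
         intra_parents = as.list(n$intra_parents),
         inter_parents = as.list(n$inter_parents), role = n$role))
  tables <- lapply(names(schema$tables), function(id) {
    tab <- schema$tables[[id]]
    keys <- parent_grid_labels(schema, tab$parent_order)
    rows <- lapply(seq_len(nrow(tab$prob)), function(r)
      as.numeric(tab$prob[r, ]))
    names(rows) <- keys
    list(id = id, child = tab$child,
         parent_order = as.list(tab$parent_order), rows = rows)
  })
  selectors <- lapply(names(schema$selectors), function(nd) {
    sel <- schema$selectors[[nd]]
    if (is.character(sel)) return(list(node = nd, default = sel))
    list(node = nd, default = sel$default,
         rules = lapply(sel$rules, function(r) {
           out <- list(table = r$table)
           if (!is.null(r$months)) out$months <- as.integer(r$months)
           if (!is.null(r$slices)) out$slices <- as.integer(r$slices)
           out
         }))
  })
  yaml::write_yaml(list(nodes = unname(nodes), tables = unname(tables),
                        selectors = unname(selectors)), path,
                   precision = 15)
  invisible(path)
}

#' Read a network schema from YAML
#'
#' @param path file written by [write_network_yaml()] (or hand-authored in
#'   the same format).
#' @param validate run [validate_schema()] and stop on diagnostics?
#' @return a [network_schema].
#' @export
read_network_yaml <- function(path, validate = TRUE) {
  doc <- yaml::read_yaml(path)
  nodes <- lapply(doc$nodes, function(n)
    node_spec(n$name,
              state_space(unlist(n$states), n$zero_label),
              intra_parents = unlist(n$intra_parents) %||% character(0),
              inter_parents = unlist(n$inter_parents) %||% character(0),
              role = n$role))
  names(nodes) <- vapply(nodes, function(n) n$name, character(1))
  pre <- network_schema(nodes, list(), list())  # for grid-label computation
  tables <- list()
  diags <- character(0)
  for (t in doc$tables) {
    po <- unlist(t$parent_order) %||% character(0)
    keys <- tryCatch(parent_grid_labels(pre, po), error = function(e) NULL)
    if (is.null(keys)) {
      diags <- c(diags, sprintf("table '%s': unresolvable parents", t$id))
      next
    }
    have <- names(t$rows)
    miss <- setdiff(keys, have)
    extra <- setdiff(have, keys)
    if (length(miss) || length(extra)) {
      # keep what we can; validate_schema reports the rest
      prob <- matrix(NA_real_, length(keys),
                     length(t$rows[[1]]))
      for (k in intersect(keys, have))
        prob[match(k, keys), ] <- unlist(t$rows[[k]])
      prob <- prob[stats::complete.cases(prob), , drop = FALSE]
      rownames(prob) <- intersect(keys, have)
      diags <- c(diags, sprintf(
        "table '%s': %s", t$id,
        paste(c(if (length(miss)) paste("missing rows:",
                                        paste(miss, collapse = "; ")),
                if (length(extra)) paste("unknown rows:",
                                         paste(extra, collapse = "; "))),
              collapse = "; ")))
    } else {
      prob <- do.call(rbind, lapply(keys, function(k) unlist(t$rows[[k]])))
      rownames(prob) <- keys
    }
    tables[[t$id]] <- cpt(t$child, po, prob)
  }
  selectors <- list()
  for (s in doc$selectors) {
    selectors[[s$node]] <- if (is.null(s$rules)) s$default else
      regime_selector(s$default, lapply(s$rules, function(r)
        list(months = if (!is.null(r$months)) as.integer(unlist(r$months)),
             slices = if (!is.null(r$slices)) as.integer(unlist(r$slices)),
             table = r$table)))
  }
  schema <- network_schema(nodes, tables, selectors)
  if (validate) {
    d <- c(diags, validate_schema(schema))
    if (length(d))
      stop("schema failed validation:\n  ", paste(d, collapse = "\n  "))
  }
  schema
}

#' Write a site configuration to YAML
#'
#' @param site a [site_config].
#' @param path output file.
#' @export
write_site_yaml <- function(site, path) {
  yaml::write_yaml(list(
    site_name = site$site_name, latitude = site$latitude,
    climate = site$climate, tidal = site$tidal,
    meadow_type = site$meadow_type, life_history = site$life_history,
    genus_label = site$genus_label,
    light_p = as.numeric(site$light_p),
    reference_value = site$reference_value), path)
  invisible(path)
}

#' Read a site configuration from YAML
#'
#' @param path a file written by [write_site_yaml()].
#' @return a [site_config].
#' @export
read_site_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  site_config(doc$site_name, doc$latitude, doc$climate, doc$tidal,
              doc$meadow_type, doc$life_history, unlist(doc$light_p),
              doc$genus_label %||% "",
              doc$reference_value %||% NA_real_)
}
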