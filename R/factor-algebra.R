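# Internal discrete factor algebra used by the exact inference routines.
# A factor is a list(vars, card, val) with val laid out so that the FIRST
# variable cycles fastest (column-major, like R arrays).

fct <- function(vars, card, val) {
  stopifnot(length(vars) == length(card), length(val) == prod(card))
  list(vars = as.character(vars), card = as.integer(card), val = as.numeric(val))
}

# For each cell of the full grid over (all_vars, all_card), the index into a
# factor over a subset of those variables.
f_index_map <- function(all_vars, all_card, sub_vars, sub_card) {
  n <- prod(all_card)
  if (length(sub_vars) == 0L) return(rep.int(1L, n))
  stride_all <- cumprod(c(1, all_card))[seq_along(all_card)]
  stride_sub <- cumprod(c(1, sub_card))[seq_along(sub_card)]
  idx <- numeric(n)
  cell <- seq_len(n) - 1L
  for (k in seq_along(sub_vars)) {
    pos <- match(sub_vars[k], all_vars)
    if (is.na(pos)) stop("variable not present: ", sub_vars[k])
    a <- (cell %/% stride_all[pos]) %% all_card[pos]
    idx <- idx + a * stride_sub[k]
  }
  as.integer(idx) + 1L
}

f_product <- function(f1, f2) {
  if (is.null(f1)) return(f2)
  if (is.null(f2)) return(f1)
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  m <- match(vars, f1$vars)
  card[!is.na(m)] <- f1$card[m[!is.na(m)]]
  m2 <- match(vars, f2$vars)
  card[!is.na(m2)] <- f2$card[m2[!is.na(m2)]]
  i1 <- f_index_map(vars, card, f1$vars, f1$card)
  i2 <- f_index_map(vars, card, f2$vars, f2$card)
  fct(vars, card, f1$val[i1] * f2$val[i2])
}

# Sum out every variable not in `keep`; result variables follow the order of
# `keep` as given.
f_marginalize <- function(f, keep) {
  keep <- keep[keep %in% f$vars]
  if (length(keep) == length(f$vars) && all(keep == f$vars)) return(f)
  kcard <- f$card[match(keep, f$vars)]
  if (length(keep) == 0L) return(fct(character(0), integer(0), sum(f$val)))
  grp <- f_index_map(f$vars, f$card, keep, kcard)
  val <- numeric(prod(kcard))
  agg <- rowsum(f$val, group = grp)
  val[as.integer(rownames(agg))] <- agg[, 1L]
  fct(keep, kcard, val)
}

f_total <- function(f) sum(f$val)

# Sequential sum-product elimination over a list of factors processed in the
# given order. `keep` variables are never summed out. When `marginal_of` is
# supplied (parallel to `factors`, NA for none), the marginal of that variable
# jointly with any `keep` variables present in the frontier is recorded right
# after its factor is absorbed -- valid for pure forward filtering because the
# unprocessed downstream factors are conditional distributions that sum to 1.
f_eliminate <- function(factors, keep = character(0), marginal_of = NULL) {
  nref <- new.env(parent = emptyenv())
  for (f in factors) for (v in f$vars) {
    assign(v, (if (exists(v, nref)) get(v, nref) else 0L) + 1L, nref)
  }
  frontier <- NULL
  marginals <- list()
  for (i in seq_along(factors)) {
    f <- factors[[i]]
    frontier <- f_product(frontier, f)
    for (v in f$vars) assign(v, get(v, nref) - 1L, nref)
    if (!is.null(marginal_of) && !is.na(marginal_of[i])) {
      node <- marginal_of[i]
      marginals[[node]] <- f_marginalize(
        frontier, c(intersect(keep, frontier$vars), node))
    }
    dead <- frontier$vars[vapply(frontier$vars, function(v)
      get(v, nref) == 0L, logical(1)) & !(frontier$vars %in% keep)]
    if (length(dead)) {
      frontier <- f_marginalize(frontier, setdiff(frontier$vars, dead))
    }
  }
  list(frontier = frontier, marginals = marginals)
}
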