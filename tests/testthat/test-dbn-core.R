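make_chain <- function() {
  # 3-node chain a -> b -> c with a carrying its own past
  rrowd <- function(m) m / rowSums(m)
  nodes <- list(
    node_spec("a", c("x", "y"), inter_parents = "a"),
    node_spec("b", c("x", "y"), intra_parents = "a"),
    node_spec("c", c("x", "y"), intra_parents = "b"))
  tables <- list(
    ta = cpt("a", "a@prev", rrowd(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))),
    tb = cpt("b", "a", rrowd(matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE))),
    tc = cpt("c", "b", rrowd(matrix(c(0.6, 0.4, 0.1, 0.9), 2, byrow = TRUE))))
  network_schema(nodes, tables, list(a = "ta", b = "tb", c = "tc"))
}

test_that("a well-formed chain validates with no diagnostics", {
  expect_identical(validate_schema(make_chain()), character(0))
})

test_that("validation reports unnormalized rows, naming the table and row", {
  sch <- make_chain()
  sch$tables$tb$prob[2, ] <- c(0.5, 0.4)
  d <- validate_schema(sch)
  expect_length(d, 1L)
  expect_match(d, "tb")
  expect_match(d, "row 2")
  expect_match(d, "0.9")
})

test_that("validation reports a missing parent-combination row by name", {
  sch <- make_chain()
  keys <- c("a=x", "a=y")
  sch$tables$tb$prob <- sch$tables$tb$prob[1, , drop = FALSE]
  rownames(sch$tables$tb$prob) <- keys[1]
  d <- validate_schema(sch)
  expect_true(any(grepl("missing parent-combination", d)))
  expect_true(any(grepl("a=y", d)))
})

test_that("validation catches self-parents, bad references and cycles", {
  sch <- make_chain()
  sch$nodes$b$intra_parents <- c("a", "b")
  expect_true(any(grepl("self-parent", validate_schema(sch))))

  sch2 <- make_chain()
  sch2$nodes$c$intra_parents <- "ghost"
  expect_true(any(grepl("unresolved parent 'ghost'", validate_schema(sch2))))

  sch3 <- make_chain()
  sch3$nodes$a$intra_parents <- "c"
  expect_true(any(grepl("cycle", validate_schema(sch3))))
})

test_that("validation checks state spaces and selector coverage", {
  sch <- make_chain()
  sch$nodes$a$states$labels <- "only"
  expect_true(any(grepl("fewer than 2 states", validate_schema(sch))))

  sch2 <- make_chain()
  sch2$selectors$b <- NULL
  expect_true(any(grepl("no selector", validate_schema(sch2))))

  sch3 <- make_chain()
  sch3$selectors$b <- "nonexistent"
  expect_true(any(grepl("month", validate_schema(sch3))))
})

test_that("identity transition keeps a point mass at every slice", {
  n1 <- node_spec("x", c("A", "B"), inter_parents = "x")
  t1 <- cpt("x", "x@prev", diag(2))
  sch <- network_schema(list(n1), list(tx = t1), list(x = "tx"))
  tr <- forward_infer(sch, list(x = c(1, 0)), 1, 5, drivers = list())
  expect_equal(unname(tr$marginals$x),
               matrix(rep(c(1, 0), each = 5), 5), tolerance = 0)
})

test_that("two-node chain matches a hand-propagated calculation", {
  # a_t | a_{t-1}: stay with 0.9/0.8; b_t = noisy copy of a_t
  nodes <- list(node_spec("a", c("u", "v"), inter_parents = "a"),
                node_spec("b", c("u", "v"), intra_parents = "a"))
  Ta <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  Tb <- matrix(c(0.75, 0.25, 0.3, 0.7), 2, byrow = TRUE)
  sch <- network_schema(nodes, list(ta = cpt("a", "a@prev", Ta),
                                    tb = cpt("b", "a", Tb)),
                        list(a = "ta", b = "tb"))
  tr <- forward_infer(sch, list(a = c(0.6, 0.4)), 3, 3, drivers = list())
  v <- c(0.6, 0.4)
  for (t in 1:3) {
    v <- as.vector(v %*% Ta)
    expect_equal(unname(tr$marginals$a[t, ]), v, tolerance = 1e-12)
    expect_equal(unname(tr$marginals$b[t, ]), as.vector(v %*% Tb),
                 tolerance = 1e-12)
  }
})

test_that("a single-table selector reproduces a homogeneous Markov chain", {
  Tm <- matrix(c(0.55, 0.30, 0.15,
                 0.10, 0.60, 0.30,
                 0.05, 0.25, 0.70), 3, byrow = TRUE)
  nodes <- list(node_spec("x", c("s1", "s2", "s3"), inter_parents = "x"))
  sch <- network_schema(nodes, list(tx = cpt("x", "x@prev", Tm)),
                        list(x = "tx"))
  v0 <- c(0.2, 0.5, 0.3)
  tr <- forward_infer(sch, list(x = v0), 7, 10, drivers = list())
  v <- v0
  for (t in 1:10) {
    v <- as.vector(v %*% Tm)
    expect_equal(unname(tr$marginals$x[t, ]), v, tolerance = 1e-12)
  }
})

test_that("forward filtering is deterministic", {
  net <- random_small_net(99)
  t1 <- forward_infer(net$schema, net$init, net$start_month, net$n_slices,
                      net$drivers)
  t2 <- forward_infer(net$schema, net$init, net$start_month, net$n_slices,
                      net$drivers)
  expect_identical(t1$marginals, t2$marginals)
  expect_identical(t1$interface_joint, t2$interface_joint)
})

test_that("missing drivers and oversized interfaces raise errors", {
  nodes <- list(node_spec("e", c("lo", "hi"), role = "environment"),
                node_spec("x", c("A", "B"), intra_parents = "e",
                          inter_parents = "x"))
  sch <- network_schema(
    nodes, list(tx = cpt("x", c("e", "x@prev"),
                         matrix(0.5, 4, 2))), list(x = "tx"))
  expect_error(forward_infer(sch, list(x = c(1, 0)), 1, 3, drivers = list()),
               "driver missing")
  expect_error(forward_infer(sch, list(x = c(1, 0)), 1, 3,
                             drivers = list(e = c(0.5, 0.5)),
                             interface_cap = 1),
               "exceeding the cap")
})

test_that("calendar months advance cyclically from the start month", {
  net <- random_small_net(5)
  tr <- forward_infer(net$schema, net$init, 11, 5, net$drivers)
  expect_equal(tr$month, c(11, 12, 1, 2, 3))
})

test_that("limit-cycle detection: stationary, drifting and seasonal cases", {
  mk_traj <- function(mats) {
    structure(list(slice_index = seq_len(nrow(mats[[1]])) - 1L,
                   month = rep(1:12, length.out = nrow(mats[[1]])),
                   marginals = mats), class = "dbn_trajectory")
  }
  stat <- mk_traj(list(x = matrix(rep(c(0.3, 0.7), each = 30), 30)))
  expect_equal(detect_limit_cycle(stat, 12), list(converged = TRUE,
                                                  cycle_start_slice = 0))
  drift <- mk_traj(list(x = cbind(seq(0.2, 0.4, length.out = 30),
                                  1 - seq(0.2, 0.4, length.out = 30))))
  res <- detect_limit_cycle(drift, 12, tol = 1e-6)
  expect_false(res$converged)
  expect_null(res$cycle_start_slice)
  expect_error(detect_limit_cycle(stat, 20), "2\\*period")

  # seasonal reference model settles within two cycles
  site <- fx_site("opportunistic")
  cmp <- fx_compiled("opportunistic")
  p <- site$light_p[ecowindows:::month_seq(1, 48)]
  tr <- forward_infer_compiled(cmp, ecowindows:::uniform_initial(cmp$schema),
                               1, 48, list(light = cbind(1 - p, p)))
  res <- detect_limit_cycle(tr, 12, tol = 1e-3,
                            nodes = c("realised_shoot_density",
                                      "realised_biomass"))
  expect_true(res$converged)
  expect_lte(res$cycle_start_slice, 24)
})
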