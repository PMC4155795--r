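test_that("a deterministic rule produces the expected chain", {
  res <- run(straight_config(seed = 1L, steps = 10L))
  expect_length(res$morphologies, 1L)
  tr <- res$morphologies[[1]]
  ## soma + stem + 2 extensions + final front that terminates
  expect_equal(nrow(tr), 4L)
  expect_true(all(diff(tr$x) > 0))
  expect_equal(sum(arborsim:::grid_active(res$grid)), 0L)
  expect_equal(branch_points(tr), 0L)
})

test_that("a config with 0 steps yields only somata", {
  res <- run(straight_config(seed = 1L, steps = 0L))
  expect_equal(nrow(res$morphologies[[1]]), 1L)
  expect_equal(res$morphologies[[1]]$parent, -1L)
})

test_that("runs are deterministic for a fixed seed and differ across seeds", {
  cfg <- tiny_forest_config(seed = 9L, count = 6L)
  r1 <- run(cfg); r2 <- run(cfg)
  expect_identical(r1$morphologies, r2$morphologies)
  expect_identical(r1$synapses, r2$synapses)
  expect_identical(r1$event_log, r2$event_log)
  r3 <- run(tiny_forest_config(seed = 10L, count = 6L))
  expect_false(identical(r1$morphologies, r3$morphologies))
})

test_that("validate_update accepts, perturbs, or terminates", {
  h <- list()
  g <- decompose(c(100, 100, 100), c(1L, 1L, 1L))
  g$neuron_n <- 2L
  g$neuron_soma[1L, ] <- c(10, 50, 50); g$neuron_type[1L] <- 1L
  g$neuron_soma[2L, ] <- c(90, 50, 50); g$neuron_type[2L] <- 1L
  f1 <- arborsim:::add_front(g, 1L, 1L, 0L, c(10, 50, 50), 2, 0L, 1L,
                             "motor", 0L)
  g$neuron_soma_front[1L] <- f1
  ## empty neighborhood (only the parent itself): accepted unchanged
  res <- validate_update(g, f1, c(20, 50, 50), 1, integer(0),
                         list(attempts = 10L, magnitude = 2))
  expect_identical(res$status, "accepted")
  expect_equal(res$position, c(20, 50, 50))
  ## other-neuron obstacle right on top of the proposal
  f2 <- arborsim:::add_front(g, 2L, 1L, 0L, c(90, 50, 50), 2, 0L, 1L,
                             "motor", 0L)
  g$neuron_soma_front[2L] <- f2
  obst <- arborsim:::add_front(g, 2L, 1L, f2, c(20, 52, 50), 2, 1L, 3L,
                               "motor", 0L)
  ## attempts = 0: any conflict terminates, nothing is added
  n_before <- g$fr_n
  res0 <- validate_update(g, f1, c(20, 50, 50), 1, integer(0),
                          list(attempts = 0L, magnitude = 2))
  expect_identical(res0$status, "terminated")
  expect_true(res0$conflicted)
  expect_equal(g$fr_n, n_before)
  ## generous perturbation budget: resolvable nearby
  set.seed(4)
  resp <- validate_update(g, f1, c(20, 50, 50), 1, integer(0),
                          list(attempts = 50L, magnitude = 5))
  expect_identical(resp$status, "accepted_after_perturbation")
  expect_lte(sqrt(sum((resp$position - c(20, 50, 50))^2)), 5)
  ## the perturbed position really is conflict-free
  d <- minimal_segment_distance(
    segment(c(10, 50, 50), resp$position, 1),
    segment(c(90, 50, 50), c(20, 52, 50), 2))
  expect_gte(d, 1 + 2)
  ## out-of-bounds proposal terminates without conflict
  reso <- validate_update(g, f1, c(-5, 50, 50), 1, integer(0),
                          list(attempts = 10L, magnitude = 2))
  expect_identical(reso$status, "terminated")
  expect_false(reso$conflicted)
})

test_that("migration conserves fronts and keeps owner boxes consistent", {
  g <- decompose(c(100, 100, 100), c(2L, 1L, 1L))
  g$neuron_n <- 1L; g$neuron_soma[1L, ] <- c(49, 50, 50)
  g$neuron_type[1L] <- 1L
  f1 <- arborsim:::add_front(g, 1L, 1L, 0L, c(49, 50, 50), 2, 0L, 1L,
                             "motor", 0L)
  g$neuron_soma_front[1L] <- f1
  ## child created across the internal face is registered in SV 2
  f2 <- arborsim:::add_front(g, 1L, 1L, f1, c(55, 50, 50), 1, 1L, 3L,
                             "motor", 1L)
  expect_identical(g$fr_sv[f2], 2L)
  expect_error(migrate_front(g, f2, 2L, 1L), "consistency error")
  total <- g$fr_n
  b <- sv_bounds(g, g$fr_sv[f2])
  pos <- arborsim:::front_position(g, f2)
  expect_true(all(pos >= b$min_corner) && all(pos < b$max_corner))
  expect_equal(g$fr_n, total)
  ## exactly one SV owns the front
  owners <- vapply(seq_len(g$nsv),
                   function(s) f2 %in% g$sv_fronts[[s]], TRUE)
  expect_equal(sum(owners), 1L)
})

test_that("detect_synapses respects neuron identity and the gap threshold", {
  mk <- function(max_distance, same_neuron = FALSE, gap_geom = 3) {
    g <- decompose(c(100, 100, 100), c(1L, 1L, 1L))
    g$neuron_n <- 2L
    g$neuron_soma[1L, ] <- c(10, 50, 50); g$neuron_type[1L] <- 1L
    g$neuron_soma[2L, ] <- c(70, 50 + gap_geom, 50); g$neuron_type[2L] <- 1L
    f1 <- arborsim:::add_front(g, 1L, 1L, 0L, c(10, 50, 50), 1, 0L, 1L,
                               "motor", 0L)
    f2 <- arborsim:::add_front(g, 2L, 1L, 0L, c(70, 50 + gap_geom, 50), 1,
                               0L, 1L, "motor", 0L)
    g$neuron_soma_front[1:2] <- c(f1, f2)
    a <- arborsim:::add_front(g, 1L, 1L, f1, c(40, 50, 50), 1, 1L, 3L,
                              "motor", 1L)
    nb <- if (same_neuron) 1L else 2L
    pf <- if (same_neuron) f1 else f2
    b <- arborsim:::add_front(g, nb, 1L, pf, c(40, 50 + gap_geom, 50), 1, 1L,
                              3L, "motor", 1L)
    n <- detect_synapses(g, g$fr_segrow[b], max_distance)
    list(n = n, g = g)
  }
  r <- mk(2.0)
  expect_equal(r$n, 1L)
  syn <- r$g$syn[1L, ]
  expect_equal(unname(syn[8]), 1.0)            # gap = 3 - (1 + 1)
  expect_equal(r$g$syn_n, 1L)
  expect_equal(mk(2.0, same_neuron = TRUE)$n, 0L)
  expect_equal(mk(0.5)$n, 0L)                  # gap 1.0 > max 0.5
})

test_that("a small forest keeps the zero-overlap and tree invariants", {
  res <- run(tiny_forest_config(seed = 3L))
  expect_equal(nrow(audit_overlaps(res)), 0L)
  for (tr in res$morphologies) {
    expect_equal(sum(tr$parent == -1L), 1L)
    ## connected and acyclic: every node reaches the root
    depth <- rep(NA_integer_, nrow(tr)); depth[tr$parent == -1L] <- 0L
    for (pass in seq_len(nrow(tr))) {
      todo <- which(is.na(depth) & tr$parent > 0L &
                    !is.na(depth[pmax(tr$parent, 1L)]))
      if (!length(todo)) break
      depth[todo] <- depth[tr$parent[todo]] + 1L
    }
    expect_false(anyNA(depth))
  }
  ## synapse invariants: gap below the configured max, distinct neurons,
  ## unordered pairs unique
  syn <- res$synapses
  if (nrow(syn)) {
    expect_true(all(syn$gap <= res$config$run$synapse_max_distance + 1e-9))
    expect_true(all(syn$pre_neuron != syn$post_neuron))
    key <- apply(cbind(pmin(syn$pre_front, syn$post_front),
                       pmax(syn$pre_front, syn$post_front)), 1, paste,
                 collapse = "-")
    expect_false(anyDuplicated(key) > 0)
  }
  ## event log accounting
  ev <- res$event_log
  expect_true(all(c("extensions", "branches", "terminations", "conflicts",
                    "migrations", "active") %in% names(ev)))
  expect_equal(ev$active[nrow(ev)], 0L)
})

test_that("a failing rule flags the neuron but the run continues", {
  register_rule("broken_test", function(front, context, params) {
    if (front$order >= 1L) stop("boom")
    list(kind = "branch", children = list(list(
      position = front$position + c(6, 0, 0), radius = 1, swc_type = 3L,
      rule = "broken_test", aux = c(NA, NA, NA, 1),
      layer_entry = NA_character_)))
  })
  cfg <- simulation_config(
    substrate = list(dims = c(100, 100, 100)),
    cell_types = list(list(name = "bad", count = 1L, soma_radius = 5,
                           rule_entry = "broken_test",
                           soma = list(mode = "explicit",
                                       positions = matrix(c(50, 50, 50), 1L)))),
    run = list(steps = 5L, seed = 2L))
  res <- run(cfg)
  expect_gte(length(res$errors), 1L)
  expect_match(res$errors[1], "boom")
  expect_equal(sum(arborsim:::grid_active(res$grid)), 0L)
})
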