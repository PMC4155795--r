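## Rule-level tests drive the rule functions directly with synthetic
## fronts/contexts, plus structural audits on small generated trees.

fake_context <- function(dims = c(1000, 1000, 1000), laminar = NULL,
                         soma = dims / 2, same_neuron = NULL) {
  if (is.null(same_neuron))
    same_neuron <- matrix(numeric(0), 0L, 7L)
  structure(list(
    same_neuron_segments = same_neuron,
    same_type_segments = matrix(numeric(0), 0L, 7L),
    other_segments = matrix(numeric(0), 0L, 7L),
    entities = NULL, distant_cues = NULL,
    layer = if (is.null(laminar)) NA_character_ else NA_character_,
    distance_to_pia = NA_real_,
    substrate_bounds = list(min_corner = c(0, 0, 0), max_corner = dims),
    laminar = laminar, soma_position = soma), class = "arbor_context")
}

fake_front <- function(position, heading = c(1, 0, 0), order = 1L,
                       radius = 1, rule = "motor", aux = c(NA, NA, NA, 1),
                       layer_entry = NA_character_, path_length = 50) {
  list(id = 1L, neuron_id = 1L, cell_type = 1L, position = position,
       parent_position = position - 10 * heading, heading = heading,
       radius = radius, order = order, path_length = path_length,
       swc_type = 3L, rule = rule, aux = aux, layer_entry = layer_entry)
}

pyr_laminar <- function() {
  laminar_structure(data.frame(
    name = c("L1", "L2", "L3", "L4", "L5"),
    lower = c(1300, 1150, 1000, 850, 0),
    upper = c(1400, 1300, 1150, 1000, 850)), depth_axis = "z")
}

pyr_ctx <- function(z, ...) {
  lam <- pyr_laminar()
  ctx <- fake_context(dims = c(800, 800, 1400), laminar = lam, ...)
  ctx$layer <- layer_of(c(400, 400, z), lam)
  ctx$distance_to_pia <- distance_to_pia(c(400, 400, z), lam)
  ctx
}

test_that("branch_probability follows min(1, base/order^decay) with cap", {
  p <- list(branch_base = 0.5, max_branch_order = Inf)
  expect_equal(branch_probability(1L, p), 0.5)
  expect_equal(branch_probability(5L, p), 0.1)
  expect_equal(branch_probability(1L, list(branch_base = 3,
                                           max_branch_order = Inf)), 1)
  expect_equal(branch_probability(2L, list(branch_base = 0.8,
                                           branch_decay = 2,
                                           max_branch_order = Inf)), 0.2)
  ## pyramidal basal: no branching above order 6, whatever the base
  pb <- default_params("pyramidal")$basal
  expect_equal(branch_probability(7L, pb), 0)
  expect_gt(branch_probability(6L, pb), 0)
  expect_error(branch_probability(0L, p), ">= 1")
})

test_that("assign_radius tapers monotonically with a floor", {
  p <- list(taper = 0.97, branch_taper = 0.9, min_radius = 0.3)
  expect_equal(assign_radius(1, "extend", p), 0.97)
  expect_equal(assign_radius(1, "branch", p), 0.873)
  r <- 1
  for (i in 1:300) {
    r2 <- assign_radius(r, "extend", p)
    expect_lte(r2, r); r <- r2
  }
  expect_equal(r, 0.3)
})

test_that("rules are pure given the RNG state", {
  f <- fake_front(c(500, 500, 500), order = 2L)
  ctx <- fake_context()
  p <- default_params("motor")
  set.seed(10); o1 <- motor_rule(f, ctx, p)
  set.seed(10); o2 <- motor_rule(f, ctx, p)
  expect_identical(o1, o2)
})

test_that("motor soma emits spread stems on the soma sphere", {
  p <- default_params("motor")
  f <- fake_front(c(700, 700, 700), order = 0L, radius = 25, rule = "motor")
  set.seed(2)
  out <- motor_rule(f, fake_context(dims = c(1400, 1400, 1400)), p)
  n <- length(out$children)
  expect_gte(n, p$n_stems[1]); expect_lte(n, p$n_stems[2])
  for (ch in out$children) {
    expect_equal(sqrt(sum((ch$position - f$position)^2)),
                 25 + p$initial_radius, tolerance = 1e-9)
    expect_equal(ch$swc_type, 3L)
  }
})

test_that("motor fronts terminate when every proposal leaves the substrate", {
  p <- default_params("motor")
  f <- fake_front(c(2, 2, 2), order = 3L)
  ctx <- fake_context(dims = c(5, 5, 5), soma = c(2.5, 2.5, 2.5))
  set.seed(1)
  for (i in 1:20) expect_identical(motor_rule(f, ctx, p)$kind, "terminate")
})

test_that("motor branch outcomes produce two divergent children", {
  p <- default_params("motor")
  p$branch_base <- 100          # force branching
  p$term_prob <- 0
  f <- fake_front(c(700, 700, 700), order = 1L)
  set.seed(8)
  out <- motor_rule(f, fake_context(dims = c(1400, 1400, 1400)), p)
  expect_identical(out$kind, "branch")
  expect_length(out$children, 2L)
  d1 <- out$children[[1]]$position - f$position
  d2 <- out$children[[2]]$position - f$position
  ang <- acos(sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))) * 180 / pi
  expect_equal(ang, p$branch_angle, tolerance = 15)
})

test_that("granule soma emits exactly two stems", {
  p <- default_params("granule")
  f <- fake_front(c(65, 50, 56), order = 0L, radius = 5, rule = "granule")
  for (s in 1:5) {
    set.seed(s)
    out <- granule_rule(f, fake_context(dims = c(130, 300, 112.5)), p)
    expect_length(out$children, 2L)
  }
})

test_that("symmetric same-neuron surroundings cancel self-repulsion", {
  segs <- rbind(c(490, 490, 490, 490, 510, 510, 1),
                c(510, 490, 490, 510, 510, 510, 1))
  ## midpoints symmetric about x = 500
  v <- arborsim:::self_repulsion(c(500, 500, 500), segs, 15)
  expect_equal(v[1], 0, tolerance = 1e-9)
})

test_that("pyramidal soma makes basal stems plus exactly one apical stem", {
  p <- default_params("pyramidal")
  f <- fake_front(c(400, 400, 820), order = 0L, radius = 10,
                  rule = "pyramidal_soma")
  for (s in 1:5) {
    set.seed(s)
    out <- pyramidal_soma_rule(f, pyr_ctx(820), p)
    ap <- Filter(function(ch) ch$swc_type == 4L, out$children)
    ba <- Filter(function(ch) ch$swc_type == 3L, out$children)
    expect_length(ap, 1L)
    expect_gte(length(ba), p$n_stems[1]); expect_lte(length(ba), p$n_stems[2])
    ## apical stem aims at the pia, basal stems do not
    expect_gt(ap[[1]]$position[3] - f$position[3], 0)
    for (ch in ba) expect_lte(ch$position[3], f$position[3])
    expect_identical(ap[[1]]$rule, "pyramidal_apical")
    expect_identical(ba[[1]]$rule, "pyramidal_basal")
  }
})

test_that("basal fronts above order 6 never branch", {
  p <- default_params("pyramidal")
  f <- fake_front(c(400, 400, 700), order = 7L, rule = "pyramidal_basal")
  ctx <- pyr_ctx(700)
  set.seed(31)
  for (i in 1:300) {
    out <- pyramidal_basal_rule(f, ctx, p)
    expect_lte(length(out$children), 1L)
  }
})

test_that("apical fronts terminate inside the 35 um pia band", {
  p <- default_params("pyramidal")
  f <- fake_front(c(400, 400, 1370), order = 10L, rule = "pyramidal_apical",
                  heading = c(0, 0, 1), aux = c(NA, NA, NA, 8),
                  layer_entry = "L1")
  ctx <- pyr_ctx(1370)   # 30 um below the pia
  set.seed(6)
  for (i in 1:50)
    expect_identical(pyramidal_apical_rule(f, ctx, p)$kind, "terminate")
})

test_that("an exhausted per-layer order budget forbids branching", {
  p <- default_params("pyramidal")
  budget <- p$apical$max_order_per_layer[["L2"]]
  f <- fake_front(c(400, 400, 1200), order = 10L + budget,
                  rule = "pyramidal_apical", heading = c(0, 0, 1),
                  aux = c(NA, NA, NA, 10), layer_entry = "L2")
  ctx <- pyr_ctx(1200)
  set.seed(13)
  for (i in 1:300) {
    out <- pyramidal_apical_rule(f, ctx, p)
    expect_lte(length(out$children), 1L)   # extend or terminate only
  }
  ## one order of budget left: branching must occur eventually
  f2 <- fake_front(c(400, 400, 1200), order = 9L + budget,
                   rule = "pyramidal_apical", heading = c(0, 0, 1),
                   aux = c(NA, NA, NA, 10), layer_entry = "L2")
  set.seed(14)
  kinds <- replicate(300, pyramidal_apical_rule(f2, ctx, p)$kind)
  expect_true(any(kinds == "branch"))
})

test_that("oblique sprouts leave the trunk sideways and carry their origin", {
  p <- default_params("pyramidal")
  p$apical$oblique_sprout_prob$L4 <- 1   # force a sprout
  f <- fake_front(c(400, 400, 900), order = 3L, rule = "pyramidal_apical",
                  heading = c(0, 0, 1), aux = c(NA, NA, NA, 2),
                  layer_entry = "L4")
  set.seed(9)
  out <- pyramidal_apical_rule(f, pyr_ctx(900), p)
  expect_identical(out$kind, "branch")
  obl <- Filter(function(ch) identical(ch$rule, "pyramidal_oblique"),
                out$children)
  expect_length(obl, 1L)
  ## initial direction is perpendicular to the trunk: positive projection
  ## away from the sprout point, near-zero along the trunk axis
  d <- obl[[1]]$position - f$position
  expect_gt(sqrt(sum(d[1:2]^2)), 0)
  expect_lt(abs(d[3]), 1e-6)
  expect_equal(obl[[1]]$aux[1:3], f$position)
  ## obliques respect their length budget
  po <- default_params("pyramidal")
  fo <- fake_front(c(420, 400, 900), order = 4L, rule = "pyramidal_oblique",
                   heading = c(1, 0, 0), aux = c(400, 400, 900, 100),
                   path_length = 100 + po$oblique$max_length + 1)
  set.seed(10)
  for (i in 1:20)
    expect_identical(pyramidal_oblique_rule(fo, pyr_ctx(900), po)$kind,
                     "terminate")
})

test_that("generated trees keep radius and order structure", {
  res <- run(example_config("granule-isolation", seed = 77))
  tr <- res$morphologies[[1]]
  kids <- arborsim:::tree_children(tr)
  deg <- lengths(kids)
  for (i in seq_len(nrow(tr))) {
    p <- tr$parent[i]
    if (p > 0L) {
      expect_lte(tr$radius[i], tr$radius[p] + 1e-9)   # monotone taper
      expected <- tr$order[p] +
        (if (deg[p] >= 2L || tr$parent[p] == -1L) 1L else 0L)
      expect_equal(tr$order[i], expected)   # +1 only below branch/soma
    }
  }
  ## recomputed centrifugal orders match the engine's bookkeeping
  expect_equal(arborsim:::node_orders(tr), tr$order)
})

test_that("doubling branch_base does not decrease median branch points", {
  grow_with_base <- function(bb, seeds) {
    vapply(seeds, function(s) {
      cfg <- example_config("granule-isolation", seed = s)
      cfg$cell_types[[1]]$params <- list(branch_base = bb)
      cfg <- arborsim:::validate_config(unclass(cfg))
      branch_points(run(cfg)$morphologies[[1]])
    }, 0)
  }
  seeds <- 300 + 1:12
  lo <- grow_with_base(0.4, seeds)
  hi <- grow_with_base(0.8, seeds)
  expect_gte(median(hi), median(lo))
})
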