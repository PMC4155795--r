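test_that("decompose tiles the substrate with half-open boxes", {
  g <- decompose(c(100, 100, 100), c(2L, 2L, 2L))
  expect_equal(g$nsv, 8L)
  b <- sv_bounds(g, 1L)
  expect_equal(b$min_corner, c(0, 0, 0))
  expect_equal(b$max_corner, c(50, 50, 50))
  expect_length(sv_neighbors(g, 1L), 7L)   # corner SV
  g1 <- decompose(c(10, 10, 10), c(1L, 1L, 1L))
  expect_length(sv_neighbors(g1, 1L), 0L)
  expect_error(decompose(c(0, 100, 100), c(2L, 2L, 2L)), "config error")
})

test_that("every in-bounds point maps to exactly one SV whose box holds it", {
  g <- decompose(c(130, 40, 75), c(5L, 2L, 3L))
  set.seed(21)
  for (i in 1:2000) {
    p <- runif(3) * g$dims
    id <- locate(p, g)
    expect_false(is.na(id))
    b <- sv_bounds(g, id)
    expect_true(all(p >= b$min_corner) &&
                all(p < b$max_corner | p == g$dims))
    ## no other SV claims it (half-open partition)
    others <- setdiff(seq_len(g$nsv), id)
    inside <- vapply(others, function(j) {
      bj <- sv_bounds(g, j)
      all(p >= bj$min_corner) && all(p < bj$max_corner)
    }, TRUE)
    expect_false(any(inside))
  }
})

test_that("locate follows the half-open and clamping conventions", {
  g <- decompose(c(100, 100, 100), c(2L, 2L, 2L))
  expect_identical(locate(c(0, 0, 0), g), 1L)
  ## internal face belongs to the higher-x SV
  expect_identical(locate(c(50, 10, 10), g), 2L)
  ## global max corner clamps to the last SV
  expect_identical(locate(c(100, 100, 100), g), 8L)
  expect_true(is.na(locate(c(101, 50, 50), g)))
  expect_true(is.na(locate(c(-1, 50, 50), g)))
})

test_that("layer_of and distance_to_pia follow the laminar conventions", {
  lam <- laminar_structure(data.frame(
    name = c("L1", "L2", "L3"),
    lower = c(90, 80, 0), upper = c(100, 90, 80)), depth_axis = "y")
  expect_identical(layer_of(c(0, 95, 0), lam), "L1")
  expect_identical(layer_of(c(0, 90, 0), lam), "L1")   # half-open
  expect_identical(layer_of(c(0, 89.999, 0), lam), "L2")
  expect_true(is.na(layer_of(c(0, 101, 0), lam)))      # above pia
  expect_equal(distance_to_pia(c(0, 100, 0), lam), 0)
  expect_equal(distance_to_pia(c(0, 0, 0), lam), 100)
  expect_true(is.na(distance_to_pia(c(0, 101, 0), lam)))
  ## pyramidal-scale example: pia 1400, depth 1365 -> 35
  lam2 <- laminar_structure(data.frame(name = "L1", lower = 0, upper = 1400),
                            depth_axis = "z")
  expect_equal(distance_to_pia(c(0, 0, 1365), lam2), 35)
  expect_error(laminar_structure(data.frame(name = c("L1", "L2"),
                                            lower = c(90, 70),
                                            upper = c(100, 85))),
               "contiguous")
})

## Minimal harness: one registered front so local_context can be queried.
context_harness <- function(dims, shape) {
  g <- decompose(dims, shape)
  g$neuron_n <- 1L
  g$neuron_soma[1L, ] <- dims / 2
  g$neuron_type[1L] <- 1L
  fid <- arborsim:::add_front(g, neuron = 1L, type = 1L, parent = 0L,
                              position = dims / 2, radius = 1, order = 0L,
                              swc_type = 1L, rule = "motor", step_index = 0L)
  g$neuron_soma_front[1L] <- fid
  list(grid = g, front = fid)
}

test_that("entities are visible directly or summarized by distance", {
  h <- context_harness(c(1300, 100, 100), c(13L, 1L, 1L))
  g <- h$grid
  ## front sits at x = 650 (SV 7); neighbors are SVs 6 and 8
  add_entity(list(name = "netrin", position = c(655, 50, 50),
                  magnitude = 1, scale = 50), g)      # host SV
  add_entity(list(name = "netrin", position = c(900, 50, 50),
                  magnitude = 2, scale = 50), g)      # distant
  add_entity(list(name = "netrin", position = c(1100, 50, 50),
                  magnitude = 4, scale = 50), g)      # distant
  expect_warning(add_entity(list(name = "lost", position = c(2000, 0, 0),
                                 magnitude = 1, scale = 50), g), "rejected")
  ctx <- local_context(h$front, g)
  expect_equal(nrow(ctx$entities), 1L)
  expect_equal(ctx$entities$x, 655)
  expect_equal(nrow(ctx$distant_cues), 1L)
  expect_equal(ctx$distant_cues$count, 2L)
  expect_equal(ctx$distant_cues$total_magnitude, 6)
  expect_equal(ctx$distant_cues$x, 1000)              # averaged position
  ## completeness: near + summarized account for every entity once
  expect_equal(nrow(ctx$entities) + ctx$distant_cues$count, nrow(g$entities))
})

test_that("context partitions segments by identity", {
  h <- context_harness(c(100, 100, 100), c(1L, 1L, 1L))
  g <- h$grid
  ## a second neuron of the same type and a third of another type
  g$neuron_n <- 3L
  g$neuron_soma[2L, ] <- c(20, 20, 20); g$neuron_type[2L] <- 1L
  g$neuron_soma[3L, ] <- c(80, 80, 80); g$neuron_type[3L] <- 2L
  f2 <- arborsim:::add_front(g, 2L, 1L, 0L, c(20, 20, 20), 1, 0L, 1L,
                             "motor", 0L)
  f3 <- arborsim:::add_front(g, 3L, 2L, 0L, c(80, 80, 80), 1, 0L, 1L,
                             "motor", 0L)
  g$neuron_soma_front[2:3] <- c(f2, f3)
  ctx <- local_context(h$front, g)
  expect_equal(nrow(ctx$same_neuron_segments), 1L)   # own soma
  expect_equal(nrow(ctx$same_type_segments), 1L)
  expect_equal(nrow(ctx$other_segments), 1L)
  expect_error(local_context(99L, g), "consistency error")
})
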