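## Shared test fixtures, all built in code.

## Random segment in [0, 100]^3 with radius in [0.5, 3].
random_segment <- function() {
  segment(runif(3, 0, 100), runif(3, 0, 100), runif(1, 0.5, 3))
}

## Full binary tree grown from one stem: the stem node bifurcates `depth`
## times. Geometry is a planar fan (coordinates only matter for lengths).
full_binary_tree <- function(depth) {
  nodes <- data.frame(id = 1:2, type = c(1L, 3L), x = c(0, 10),
                      y = c(0, 0), z = c(0, 0), radius = c(5, 1),
                      parent = c(-1L, 1L))
  frontier <- 2L
  for (d in seq_len(depth)) {
    nxt <- integer(0)
    for (p in frontier) {
      for (s in c(-1, 1)) {
        id <- nrow(nodes) + 1L
        nodes[id, ] <- list(id, 3L, nodes$x[p] + 10,
                            nodes$y[p] + s * 50 / 2^d, 0, 1, p)
        nxt <- c(nxt, id)
      }
    }
    frontier <- nxt
  }
  class(nodes) <- c("arbor_tree", "data.frame")
  nodes
}

## Unbranched chain of n segments along +x.
chain_tree <- function(n = 5) {
  nodes <- data.frame(id = seq_len(n + 1L), type = c(1L, rep(3L, n)),
                      x = seq(0, 10 * n, by = 10), y = 0, z = 0,
                      radius = c(5, rep(1, n)),
                      parent = c(-1L, seq_len(n)))
  class(nodes) <- c("arbor_tree", "data.frame")
  nodes
}

## Tiny granule forest used by engine tests: a handful of interacting
## cells in a small box, quick to grow.
tiny_forest_config <- function(seed = 1L, count = 8L, outputs = NULL) {
  simulation_config(
    substrate = list(dims = c(260, 300, 112.5)),
    cell_types = list(list(
      name = "granule", count = count, soma_radius = 5,
      rule_entry = "granule",
      soma = list(mode = "uniform", box_min = c(15, 30, 15),
                  box_max = c(245, 60, 100)))),
    run = list(steps = 80L, seed = seed),
    outputs = list(dir = outputs))
}

## A minimal deterministic rule: extend straight +x for `n_ext` updates,
## then terminate. Used to pin down engine bookkeeping.
register_straight_rule <- function(n_ext = 3L) {
  register_rule("straight_test", function(front, context, params) {
    if (front$order == 0L) {
      return(list(kind = "branch", children = list(list(
        position = front$position + c(front$radius + 1, 0, 0),
        radius = 1, swc_type = 3L, rule = "straight_test",
        aux = c(NA, NA, NA, 1), layer_entry = NA_character_))))
    }
    if (front$path_length >= front$radius + 1 + 10 * (n_ext - 1L))
      return(list(kind = "terminate", children = list()))
    list(kind = "extend", children = list(list(
      position = front$position + c(10, 0, 0),
      radius = 1, swc_type = 3L, rule = "straight_test",
      aux = front$aux, layer_entry = front$layer_entry)))
  })
}

straight_config <- function(seed = 1L, steps = 10L) {
  register_straight_rule()
  simulation_config(
    substrate = list(dims = c(200, 100, 100)),
    cell_types = list(list(
      name = "probe", count = 1L, soma_radius = 5,
      rule_entry = "straight_test",
      soma = list(mode = "explicit", positions = matrix(c(50, 50, 50), 1L)))),
    run = list(steps = steps, seed = seed))
}
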