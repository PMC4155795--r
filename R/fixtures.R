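## Shipped example configurations (the calibrated "stated world" for each
## demonstration) and tiny fixtures. These are the single source of truth:
## the .cfg files under inst/extdata/ are written by write_config() from
## these builders.

#' Toy morphology T1
#'
#' Four-node hand-checkable tree: soma at the origin, one stem to
#' (10,0,0), which branches to (20,0,0) and (10,10,0). Ground truth:
#' 1 branch point, tips at 20 and sqrt(200) um, total length 30 um,
#' max order 2.
#'
#' @return an `arbor_tree` node table.
#' @export
toy_tree <- function() {
  tree <- data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 10, 20, 10), y = c(0, 0, 0, 10), z = c(0, 0, 0, 0),
    radius = c(5, 1, 1, 1), parent = c(-1L, 1L, 2L, 2L))
  class(tree) <- c("arbor_tree", "data.frame")
  tree
}

#' Shipped example configuration
#'
#' Builds one of the demonstration setups:
#' \describe{
#'   \item{motor-isolation}{one alpha motor neuron, soma centered in a
#'     1400^3 um box.}
#'   \item{granule-isolation}{one granule cell in a 130 x 300 x 112.5 um
#'     box (the forest volume scaled down 20-fold, keeping the full
#'     dentate depth), superficial surface at max y.}
#'   \item{granule-forest}{100 granule cells grown simultaneously in
#'     1300 x 300 x 225 um.}
#'   \item{pyramidal-isolation}{one L5 pyramidal neuron in a laminar
#'     800 x 800 x 1400 um substrate, pia at z = 1400.}
#'   \item{pyramidal-forest}{100 pyramidal neurons in 6000 x 1800 x
#'     1400 um.}
#' }
#'
#' @param name configuration name (see above).
#' @param seed RNG seed (mandatory for every run).
#' @param outputs optional output directory.
#' @return validated `arbor_config`.
#' @export
example_config <- function(name, seed = 1L, outputs = NULL) {
  pyramidal_layers <- data.frame(
    name = c("L1", "L2", "L3", "L4", "L5"),
    lower = c(1300, 1150, 1000, 850, 0),
    upper = c(1400, 1300, 1150, 1000, 850))
  cfg <- switch(name,
    "motor-isolation" = list(
      substrate = list(dims = c(1400, 1400, 1400)),
      cell_types = list(list(
        name = "motor", count = 1L, soma_radius = 25,
        rule_entry = "motor",
        soma = list(mode = "explicit",
                    positions = matrix(c(700, 700, 700), 1L)))),
      run = list(steps = 300L, seed = seed)),
    "granule-isolation" = list(
      substrate = list(dims = c(130, 300, 112.5)),
      cell_types = list(list(
        name = "granule", count = 1L, soma_radius = 5,
        rule_entry = "granule",
        soma = list(mode = "explicit",
                    positions = matrix(c(65, 50, 56.25), 1L)))),
      run = list(steps = 120L, seed = seed)),
    "granule-forest" = list(
      substrate = list(dims = c(1300, 300, 225)),
      cell_types = list(list(
        name = "granule", count = 100L, soma_radius = 5,
        rule_entry = "granule",
        soma = list(mode = "uniform", box_min = c(20, 30, 15),
                    box_max = c(1280, 60, 210)))),
      run = list(steps = 120L, seed = seed)),
    "pyramidal-isolation" = list(
      substrate = list(dims = c(800, 800, 1400),
                       laminar = laminar_structure(pyramidal_layers,
                                                   depth_axis = "z")),
      cell_types = list(list(
        name = "pyramidal", count = 1L, soma_radius = 10,
        rule_entry = "pyramidal_soma",
        soma = list(mode = "uniform", box_min = c(380, 380, 790),
                    box_max = c(420, 420, 850)))),
      run = list(steps = 250L, seed = seed)),
    "pyramidal-forest" = list(
      substrate = list(dims = c(6000, 1800, 1400),
                       laminar = laminar_structure(pyramidal_layers,
                                                   depth_axis = "z")),
      cell_types = list(list(
        name = "pyramidal", count = 100L, soma_radius = 10,
        rule_entry = "pyramidal_soma",
        soma = list(mode = "uniform", box_min = c(150, 150, 790),
                    box_max = c(5850, 1650, 850)))),
      run = list(steps = 250L, seed = seed)),
    stop("unknown example config: ", name))
  cfg$outputs <- list(dir = outputs)
  validate_config(cfg)
}

#' Grow a population of isolated neurons
#'
#' Runs the named isolation configuration `n` times with per-replicate
#' seeds derived from `seed`, returning one morphology per replicate.
#'
#' @param name an isolation config name from [example_config()].
#' @param n number of replicates.
#' @param seed base seed; replicate i uses `seed * 1000 + i` (mod 2^31).
#' @return list of `arbor_tree` node tables.
#' @export
grow_isolated <- function(name, n, seed = 1L) {
  lapply(seq_len(n), function(i) {
    s <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    res <- run(example_config(name, seed = s))
    res$morphologies[[1L]]
  })
}
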