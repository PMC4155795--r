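## The simulated brain substrate: an axis-aligned box [0, dims) tiled by a
## grid of half-open sub-volumes (SVs). Each SV owns the fronts and segments
## whose distal endpoint lies inside it, plus any guidance entities. The
## grid is a mutable environment because the engine updates it in place.

#' Decompose a substrate into a sub-volume grid
#'
#' Tiles the box `[0, dims)` with `prod(grid_shape)` half-open axis-aligned
#' sub-volumes. Each SV knows its (up to 26) face/edge/corner neighbors.
#'
#' @param substrate_dims numeric length-3, substrate extent in um.
#' @param grid_shape integer length-3, number of SVs per axis.
#' @return a mutable grid environment (class `arbor_grid`).
#' @export
decompose <- function(substrate_dims, grid_shape) {
  substrate_dims <- as.numeric(substrate_dims)
  grid_shape <- as.integer(grid_shape)
  if (length(substrate_dims) != 3L || any(!is.finite(substrate_dims)) ||
      any(substrate_dims <= 0))
    stop("config error: substrate dims must be three positive lengths")
  if (length(grid_shape) != 3L || any(is.na(grid_shape)) || any(grid_shape < 1L))
    stop("config error: grid shape must be three positive integers")
  g <- new.env(parent = emptyenv())
  g$dims <- substrate_dims
  g$shape <- grid_shape
  g$cell <- substrate_dims / grid_shape
  g$nsv <- prod(grid_shape)
  g$sv_segments <- vector("list", g$nsv)
  g$sv_fronts <- vector("list", g$nsv)
  g$neighbors <- vector("list", g$nsv)   # lazily filled cache
  g$entities <- data.frame(name = character(), x = numeric(), y = numeric(),
                           z = numeric(), magnitude = numeric(),
                           scale = numeric(), sv = integer(),
                           stringsAsFactors = FALSE)
  g$laminar <- NULL
  init_front_store(g)
  class(g) <- c("arbor_grid", "environment")
  g
}

sv_id_from_index <- function(g, ijk) {
  1L + ijk[1L] + g$shape[1L] * (ijk[2L] + g$shape[2L] * ijk[3L])
}

sv_index_from_id <- function(g, id) {
  id0 <- id - 1L
  i <- id0 %% g$shape[1L]
  j <- (id0 %/% g$shape[1L]) %% g$shape[2L]
  k <- id0 %/% (g$shape[1L] * g$shape[2L])
  c(i, j, k)
}

#' Bounds of one sub-volume
#' @param grid an `arbor_grid`.
#' @param id SV id (1-based).
#' @return list with `min_corner` and `max_corner` (half-open box).
#' @export
sv_bounds <- function(grid, id) {
  ijk <- sv_index_from_id(grid, id)
  list(min_corner = ijk * grid$cell, max_corner = (ijk + 1) * grid$cell)
}

#' Locate the sub-volume containing a point
#'
#' Half-open convention: a point on an internal face belongs to the
#' higher-index SV; points exactly on the global max boundary are clamped to
#' the last SV. Points outside the substrate yield `NA` (callers treat this
#' as a termination trigger).
#'
#' @param p numeric length-3 point, um.
#' @param grid an `arbor_grid`.
#' @return SV id, or `NA_integer_` when `p` is out of bounds.
#' @export
locate <- function(p, grid) {
  p <- as.numeric(p)
  if (any(p < 0) || any(p > grid$dims)) return(NA_integer_)
  ijk <- pmin(as.integer(floor(p / grid$cell)), grid$shape - 1L)
  sv_id_from_index(grid, ijk)
}

#' Neighbor SV ids (26-connectivity)
#' @param grid an `arbor_grid`.
#' @param id SV id.
#' @return integer vector of neighbor ids (excluding `id` itself).
#' @export
sv_neighbors <- function(grid, id) {
  nb <- grid$neighbors[[id]]
  if (!is.null(nb)) return(nb)
  ijk <- sv_index_from_id(grid, id)
  out <- integer(0)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0L && dj == 0L && dk == 0L) next
    q <- ijk + c(di, dj, dk)
    if (any(q < 0L) || any(q >= grid$shape)) next
    out <- c(out, sv_id_from_index(grid, q))
  }
  grid$neighbors[[id]] <- out
  out
}

## ---------------------------------------------------------------- laminar

#' Define a laminar structure
#'
#' Contiguous, non-overlapping cortical/dentate layers stacked along one
#' axis, ordered from the pia downward; the pia coordinate is the upper
#' bound of the top layer. Layer membership uses half-open depth intervals
#' `[lower, upper)`.
#'
#' @param layers data.frame with columns `name`, `lower`, `upper` (um),
#'   ordered from the most superficial layer down.
#' @param depth_axis which coordinate is depth: "x", "y" or "z".
#' @return object of class `arbor_laminar`.
#' @export
laminar_structure <- function(layers, depth_axis = "y") {
  ax <- match(depth_axis, c("x", "y", "z"))
  if (is.na(ax)) stop("config error: depth_axis must be x, y or z")
  layers <- as.data.frame(layers)
  if (!all(c("name", "lower", "upper") %in% names(layers)))
    stop("config error: layers need name, lower, upper")
  if (any(layers$lower >= layers$upper))
    stop("config error: layer lower bound must be below upper bound")
  if (nrow(layers) > 1L &&
      any(abs(layers$upper[-1L] - layers$lower[-nrow(layers)]) > 1e-9))
    stop("config error: layers must be contiguous from the pia downward")
  structure(list(axis = ax, pia = layers$upper[1L], layers = layers),
            class = "arbor_laminar")
}

#' Layer containing a point
#'
#' @param p numeric length-3 point, um.
#' @param laminar an `arbor_laminar`.
#' @return layer name, or `NA_character_` when the depth is above the pia
#'   (or below the deepest declared layer).
#' @export
layer_of <- function(p, laminar) {
  d <- as.numeric(p)[laminar$axis]
  hit <- which(d >= laminar$layers$lower & d < laminar$layers$upper)
  if (length(hit) == 0L) return(NA_character_)
  laminar$layers$name[hit[1L]]
}

#' Distance from a point to the pia
#'
#' @param p numeric length-3 point, um, at or below the pia.
#' @param laminar an `arbor_laminar`.
#' @return distance in um (>= 0); `NA` above the pia.
#' @export
distance_to_pia <- function(p, laminar) {
  d <- as.numeric(p)[laminar$axis]
  if (d > laminar$pia) return(NA_real_)
  laminar$pia - d
}

## --------------------------------------------------------------- entities

#' Register a secreted guidance entity
#'
#' A phenomenological point source of a secretion molecule; its influence on
#' fronts decays with [distance_weight()] at the entity's own `scale`.
#' Entities outside the substrate are rejected with a warning.
#'
#' @param e list with `name`, `position` (length-3), `magnitude` (>= 0),
#'   `scale` (> 0, um).
#' @param grid an `arbor_grid`.
#' @return the grid, invisibly.
#' @export
add_entity <- function(e, grid) {
  sv <- locate(e$position, grid)
  if (is.na(sv)) {
    warning("entity outside substrate rejected: ", e$name)
    return(invisible(grid))
  }
  if (e$magnitude < 0 || e$scale <= 0)
    stop("config error: entity magnitude >= 0 and scale > 0 required")
  grid$entities <- rbind(grid$entities, data.frame(
    name = e$name, x = e$position[1L], y = e$position[2L],
    z = e$position[3L], magnitude = e$magnitude, scale = e$scale,
    sv = sv, stringsAsFactors = FALSE))
  invisible(grid)
}

## ---------------------------------------------------------- local context

#' Assemble the local context visible to a front
#'
#' Everything a growth cone can sense: segments and guidance entities in the
#' host SV and its direct neighbors, partitioned by the front's identity
#' (same neuron / same cell type / other), plus one averaged `CueSummary`
#' per entity name for all entities beyond the direct neighborhood, the
#' laminar layer and pia distance at the front position, the substrate
#' bounds, and the position of the front's own soma.
#'
#' @param front_id id of a registered front.
#' @param grid an `arbor_grid`.
#' @return list of class `arbor_context`.
#' @export
local_context <- function(front_id, grid) {
  if (front_id < 1L || front_id > grid$fr_n || is.na(grid$fr_sv[front_id]))
    stop("consistency error: front not registered in grid")
  sv <- grid$fr_sv[front_id]
  svs <- c(sv, sv_neighbors(grid, sv))
  rows <- unlist(grid$sv_segments[svs], use.names = FALSE)
  nid <- grid$fr_neuron[front_id]
  tid <- grid$fr_type[front_id]
  pos <- front_position(grid, front_id)

  same_neuron <- rows[grid$seg_neuron[rows] == nid]
  same_type <- rows[grid$seg_neuron[rows] != nid & grid$seg_type[rows] == tid]
  other <- rows[grid$seg_neuron[rows] != nid & grid$seg_type[rows] != tid]

  ent <- grid$entities
  near <- ent[ent$sv %in% svs, , drop = FALSE]
  far <- ent[!(ent$sv %in% svs), , drop = FALSE]
  distant <- NULL
  if (nrow(far) > 0L) {
    distant <- do.call(rbind, lapply(split(far, far$name), function(d) {
      data.frame(name = d$name[1L],
                 x = mean(d$x), y = mean(d$y), z = mean(d$z),
                 total_magnitude = sum(d$magnitude),
                 scale = mean(d$scale), count = nrow(d),
                 stringsAsFactors = FALSE)
    }))
    rownames(distant) <- NULL
  }

  lam <- grid$laminar
  structure(list(
    same_neuron_segments = seg_view(grid, same_neuron),
    same_type_segments = seg_view(grid, same_type),
    other_segments = seg_view(grid, other),
    entities = near,
    distant_cues = distant,
    layer = if (is.null(lam)) NA_character_ else layer_of(pos, lam),
    distance_to_pia = if (is.null(lam)) NA_real_ else distance_to_pia(pos, lam),
    substrate_bounds = list(min_corner = c(0, 0, 0), max_corner = grid$dims),
    laminar = lam,
    soma_position = grid$neuron_soma[grid$fr_neuron[front_id], ]
  ), class = "arbor_context")
}

## Matrix view (n x 7: endpoints + radius) of stored segment rows.
seg_view <- function(grid, rows) {
  m <- grid$seg[rows, , drop = FALSE]
  colnames(m) <- c("x0", "y0", "z0", "x1", "y1", "z1", "r")
  m
}
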