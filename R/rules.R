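## Growth rules: front automata. A rule is a pure function of
## (front, context, params, RNG state) returning a RuleOutcome:
##   list(kind = "extend" | "branch" | "terminate",
##        children = list(list(position, radius, swc_type, rule,
##                             aux, layer_entry)))
## Soma rules return kind "branch" with one child per stem; the engine
## assigns stems order 1, extend children the parent order, and branch
## children parent order + 1.

.rule_registry <- new.env(parent = emptyenv())

#' Register a growth rule under a name
#'
#' Configs select rules by name via each cell type's `rule_entry`. The
#' shipped rules ("motor", "granule", "pyramidal_soma", ...) are registered
#' at load time; user rules can be added the same way.
#'
#' @param name rule name.
#' @param fn function `(front, context, params)` returning a rule outcome.
#' @export
register_rule <- function(name, fn) {
  assign(name, fn, envir = .rule_registry)
  invisible(name)
}

rule_exists <- function(name) exists(name, envir = .rule_registry,
                                     inherits = FALSE)

dispatch_rule <- function(name, front, context, params) {
  if (!rule_exists(name)) stop("unknown rule_entry: ", name)
  get(name, envir = .rule_registry, inherits = FALSE)(front, context, params)
}

#' Branching probability as a function of centrifugal order
#'
#' `min(1, branch_base / order)`: bifurcation becomes less likely the more
#' branch events separate a front from the soma. Above
#' `params$max_branch_order` (pyramidal basal trees cap at 6) no branching
#' is allowed at all.
#'
#' @param order centrifugal order (>= 1; the soma is handled by soma rules).
#' @param params rule parameter list (`branch_base`, `max_branch_order`).
#' @return probability in \[0, 1\].
#' @export
branch_probability <- function(order, params) {
  if (order < 1L) stop("branch_probability: order must be >= 1")
  cap <- params$max_branch_order
  if (!is.null(cap) && is.finite(cap) && order > cap) return(0)
  decay <- params$branch_decay %||% 1
  min(1, params$branch_base / order^decay)
}

#' Child radius from the parent radius
#'
#' Neurites taper gently: `max(min_radius, parent_radius * taper)`, with an
#' extra `branch_taper` factor applied to branch children. Radii are
#' monotone non-increasing along any root-to-tip path.
#'
#' @param parent_radius parent front radius, um.
#' @param kind "extend" or "branch".
#' @param params rule parameter list (`taper`, `branch_taper`, `min_radius`).
#' @return child radius, um.
#' @export
assign_radius <- function(parent_radius, kind, params) {
  f <- params$taper
  if (identical(kind, "branch")) f <- f * params$branch_taper
  max(params$min_radius, parent_radius * f)
}

in_bounds <- function(p, ctx) {
  b <- ctx$substrate_bounds
  all(p >= b$min_corner) && all(p <= b$max_corner)
}

## Net self-repulsion from same-neuron segments: weighted sum of unit
## vectors from each segment midpoint to the front, weights decaying with
## distance. Returned unnormalized so crowding increases its pull.
self_repulsion <- function(pos, segs, scale) {
  if (nrow(segs) == 0L) return(c(0, 0, 0))
  mid <- 0.5 * (segs[, 1:3, drop = FALSE] + segs[, 4:6, drop = FALSE])
  dvec <- matrix(pos, nrow(mid), 3L, byrow = TRUE) - mid
  d <- sqrt(rowSums(dvec^2))
  keep <- d > 1e-9
  if (!any(keep)) return(c(0, 0, 0))
  w <- distance_weight(d[keep], scale) / d[keep]
  colSums(dvec[keep, , drop = FALSE] * w)
}

axis_unit <- function(axis) { v <- c(0, 0, 0); v[axis] <- 1; v }

## Directions of the two children of a bifurcation: symmetric about the
## composed base direction, separated by the rule's branch angle, in a
## random plane through the base direction. Guarantees sibling segments
## diverge instead of lying on top of each other.
branch_pair_dirs <- function(base, branch_angle_deg) {
  half <- branch_angle_deg * pi / 360
  perp <- oblique_perp(base)
  list(normalize3(cos(half) * base + sin(half) * perp),
       normalize3(cos(half) * base - sin(half) * perp))
}

oblique_perp <- function(h) {
  repeat {
    r <- random_unit_vector()
    perp <- r - sum(r * h) * h
    if (sqrt(sum(perp^2)) > 1e-6) return(normalize3(perp))
  }
}

terminate_outcome <- function() list(kind = "terminate", children = list())

child_spec <- function(front, ctx, params, dir, kind,
                       rule = front$rule, swc_type = front$swc_type,
                       aux = front$aux, layer_entry = front$layer_entry,
                       step_length = params$step_length) {
  list(position = front$position + step_length * dir,
       radius = assign_radius(front$radius, kind, params),
       swc_type = swc_type, rule = rule, aux = aux,
       layer_entry = layer_entry)
}

## ------------------------------------------------------------------ motor

#' Growth rule for spinal alpha motor neurons
#'
#' At the soma, several stems sprout in random directions on the soma
#' sphere. Thereafter a front bifurcates with probability inversely
#' proportional to its centrifugal order, terminates with a small fixed
#' probability or when it leaves the substrate, and extends otherwise.
#' Direction: current heading, distance-weighted repulsion from the soma,
#' and a random component.
#'
#' @param front,context,params see [register_rule()].
#' @return a rule outcome.
#' @export
motor_rule <- function(front, context, params) {
  if (front$order == 0L) return(stem_outcome(front, context, params))
  if (runif(1) < params$term_prob) return(terminate_outcome())
  branch <- runif(1) < branch_probability(front$order, params)
  to_soma <- front$position - context$soma_position
  d_soma <- sqrt(sum(to_soma^2))
  base <- compose_direction(list(
    list(v = front$heading, w = params$w_heading),
    list(v = to_soma / max(d_soma, 1e-9),
         w = params$w_soma * distance_weight(d_soma, params$soma_scale)),
    list(v = random_unit_vector(), w = params$w_random)))
  finish_outcome(front, context, params, base, branch)
}

## Shared tail of the stochastic automata: one child along the base
## direction, or two divergent children at the rule's branch angle.
finish_outcome <- function(front, context, params, base, branch,
                           p = params, step_length = p$step_length) {
  kind <- if (branch) "branch" else "extend"
  dirs <- if (branch) branch_pair_dirs(base, p$branch_angle) else list(base)
  children <- list()
  for (dir in dirs) {
    ch <- child_spec(front, context, params, dir, kind,
                     step_length = step_length)
    if (in_bounds(ch$position, context)) children <- c(children, list(ch))
  }
  if (length(children) == 0L) return(terminate_outcome())
  list(kind = kind, children = children)
}

## Random stems on the soma sphere, placed just outside the soma capsule so
## the strict overlap test never trips on the soma itself.
stem_outcome <- function(front, context, params, n = NULL, dirs = NULL,
                         swc_type = 3L, rule = front$rule) {
  if (is.null(n)) {
    rng <- params$n_stems
    n <- if (rng[1L] == rng[2L]) rng[1L]
         else sample(seq.int(rng[1L], rng[2L]), 1L)
  }
  r0 <- params$initial_radius
  if (is.null(dirs)) {
    ## random stem directions, kept at least ~25 degrees apart so sibling
    ## lineages do not start on top of each other
    dirs <- list(); tries <- 0L
    while (length(dirs) < n) {
      d <- random_unit_vector()
      tries <- tries + 1L
      seps <- vapply(dirs, function(e) sum(e * d), 0)
      if (length(seps) == 0L || max(seps) < cos(25 * pi / 180) ||
          tries > 100L)
        dirs <- c(dirs, list(d))
    }
  }
  children <- vector("list", n)
  for (i in seq_len(n)) {
    dir <- dirs[[i]]
    pos <- front$position + (front$radius + r0) * dir
    lay <- if (is.null(context$laminar)) NA_character_
           else layer_of(pos, context$laminar)
    children[[i]] <- list(position = pos, radius = r0, swc_type = swc_type,
                          rule = rule, aux = c(NA, NA, NA, 1),
                          layer_entry = lay)
  }
  children <- Filter(function(ch) in_bounds(ch$position, context), children)
  if (length(children) == 0L) return(terminate_outcome())
  list(kind = "branch", children = children)
}

## ---------------------------------------------------------------- granule

#' Growth rule for dentate granule cells
#'
#' The soma emits exactly two stems aimed at the superficial side of the
#' substrate. Branching probability decreases with centrifugal order;
#' direction combines repulsion away from same-neuron dendrites, the
#' current heading, attraction toward the superficial substrate surface
#' (the depth axis), and a random component.
#'
#' @param front,context,params see [register_rule()].
#' @return a rule outcome.
#' @export
granule_rule <- function(front, context, params) {
  up <- axis_unit(params$depth_axis)
  if (front$order == 0L) {
    ## two divergent stems aimed at the superficial surface
    base <- compose_direction(list(
      list(v = up, w = params$w_superficial),
      list(v = random_unit_vector(), w = params$w_random * 0.5)))
    dirs <- branch_pair_dirs(base, params$stem_angle)
    return(stem_outcome(front, context, params, n = 2L, dirs = dirs))
  }
  if (runif(1) < params$term_prob) return(terminate_outcome())
  branch <- runif(1) < branch_probability(front$order, params)
  rep_v <- self_repulsion(front$position, context$same_neuron_segments,
                          params$self_scale)
  base <- compose_direction(list(
    list(v = front$heading, w = params$w_heading),
    list(v = rep_v, w = params$w_self),
    list(v = up, w = params$w_superficial),
    list(v = random_unit_vector(), w = params$w_random)))
  finish_outcome(front, context, params, base, branch)
}

## -------------------------------------------------------------- pyramidal

#' Soma rule for layer 5 pyramidal neurons
#'
#' Generates `n_stems` basal stems in downward/lateral random directions
#' plus exactly one apical stem aimed at the pia.
#'
#' @param front,context,params see [register_rule()].
#' @return a rule outcome.
#' @export
pyramidal_soma_rule <- function(front, context, params) {
  if (is.null(context$laminar))
    stop("config error: pyramidal rules require a laminar structure")
  ax <- context$laminar$axis
  up <- axis_unit(ax)
  rng <- params$n_stems
  nb <- if (rng[1L] == rng[2L]) rng[1L]
        else sample(seq.int(rng[1L], rng[2L]), 1L)
  basal_dirs <- lapply(seq_len(nb), function(i) {
    d <- random_unit_vector()
    d[ax] <- -abs(d[ax])                 # basal stems never aim at the pia
    normalize3(d)
  })
  basal <- stem_outcome(front, context, params, n = nb, dirs = basal_dirs,
                        swc_type = 3L, rule = "pyramidal_basal")
  apical_dir <- compose_direction(list(
    list(v = up, w = 1), list(v = random_unit_vector(), w = 0.2)))
  apical <- stem_outcome(front, context, params, n = 1L,
                         dirs = list(apical_dir), swc_type = 4L,
                         rule = "pyramidal_apical")
  children <- c(if (identical(basal$kind, "branch")) basal$children,
                if (identical(apical$kind, "branch")) apical$children)
  if (length(children) == 0L) return(terminate_outcome())
  list(kind = "branch", children = children)
}

#' Basal-dendrite rule for pyramidal neurons
#'
#' Motor-style stochastic automaton with a hard branching cap: above
#' centrifugal order `max_branch_order` (6) no branching is allowed.
#' Direction combines heading, same-neuron repulsion and a random factor;
#' volume-limited termination applies.
#'
#' @param front,context,params see [register_rule()].
#' @return a rule outcome.
#' @export
pyramidal_basal_rule <- function(front, context, params) {
  p <- params$basal
  if (runif(1) < p$term_prob) return(terminate_outcome())
  branch <- runif(1) < branch_probability(front$order, p)
  rep_v <- self_repulsion(front$position, context$same_neuron_segments,
                          p$self_scale)
  base <- compose_direction(list(
    list(v = front$heading, w = p$w_heading),
    list(v = rep_v, w = p$w_self),
    list(v = random_unit_vector(), w = p$w_random)))
  finish_outcome(front, context, params, base, branch, p = p)
}

## Book-keeping for the per-layer branching budget: the order a front had
## when its lineage entered the current layer is carried in aux[4], the
## layer name in layer_entry.
apical_child_meta <- function(front, ctx, child_pos, child_order) {
  lay <- layer_of(child_pos, ctx$laminar)
  if (is.na(lay) || identical(lay, front$layer_entry))
    list(aux = front$aux, layer = front$layer_entry)
  else
    list(aux = c(front$aux[1:3], child_order), layer = lay)
}

#' Apical-dendrite rule for pyramidal neurons (laminar dispatch)
#'
#' Behavior depends on the layer the front is in. In L5 and L4 the trunk
#' extends toward the pia and oblique dendrites sprout with a per-layer
#' probability, growing away from their sprout point. In L3, L2 and L1 the
#' front branches with layer-specific probabilities as long as the order
#' increase within the current layer is below `max_order_per_layer`, and
#' may terminate stochastically. Any apical front closer to the pia than
#' `pia_stop` (35 um) terminates unconditionally. Direction combines
#' same-neuron repulsion, heading, a distance-dependent pia attraction and
#' a random component.
#'
#' @param front,context,params see [register_rule()].
#' @return a rule outcome.
#' @export
pyramidal_apical_rule <- function(front, context, params) {
  if (is.null(context$laminar))
    stop("config error: pyramidal apical rule requires a laminar structure")
  p <- params$apical
  dp <- context$distance_to_pia
  if (is.na(dp) || dp < p$pia_stop) return(terminate_outcome())
  lay <- context$layer
  entry_order <- front$aux[4L]
  if (is.na(entry_order)) entry_order <- front$order
  deep <- lay %in% p$oblique_layers
  if (deep) {
    sprout <- runif(1) < p$oblique_sprout_prob[[lay]]
    kind <- if (sprout) "branch" else "extend"
    child_order <- if (sprout) front$order + 1L else front$order
    dir <- apical_direction(front, context, p)
    trunk <- child_spec(front, context, params, dir, kind,
                        step_length = p$step_length)
    meta <- apical_child_meta(front, context, trunk$position, child_order)
    trunk$aux <- meta$aux; trunk$layer_entry <- meta$layer
    children <- if (in_bounds(trunk$position, context)) list(trunk) else list()
    if (sprout) {
      odir <- oblique_initial_direction(front, context)
      obl <- child_spec(front, context, params, odir, "branch",
                        rule = "pyramidal_oblique",
                        step_length = p$step_length)
      obl$aux <- c(front$position, front$path_length)
      obl$layer_entry <- lay
      if (in_bounds(obl$position, context)) children <- c(children, list(obl))
    }
    if (length(children) == 0L) return(terminate_outcome())
    return(list(kind = kind, children = children))
  }
  ## superficial layers (and anything above the oblique zone)
  if (runif(1) < p$term_prob_superficial) return(terminate_outcome())
  budget <- p$max_order_per_layer
  if (is.list(budget)) budget <- budget[[lay]] %||% 0
  may_branch <- (front$order - entry_order) < budget &&
    !is.na(lay) && !is.null(p$layer_branch_probs[[lay]])
  branch <- may_branch && runif(1) < p$layer_branch_probs[[lay]]
  kind <- if (branch) "branch" else "extend"
  child_order <- if (branch) front$order + 1L else front$order
  base <- apical_direction(front, context, p)
  dirs <- if (branch) branch_pair_dirs(base, p$branch_angle) else list(base)
  children <- list()
  for (dir in dirs) {
    ch <- child_spec(front, context, params, dir, kind,
                     step_length = p$step_length)
    meta <- apical_child_meta(front, context, ch$position, child_order)
    ch$aux <- meta$aux; ch$layer_entry <- meta$layer
    if (in_bounds(ch$position, context) &&
        !is.na(distance_to_pia(ch$position, context$laminar)))
      children <- c(children, list(ch))
  }
  if (length(children) == 0L) return(terminate_outcome())
  list(kind = kind, children = children)
}

apical_direction <- function(front, ctx, p) {
  up <- axis_unit(ctx$laminar$axis)
  rep_v <- self_repulsion(front$position, ctx$same_neuron_segments,
                          p$self_scale)
  compose_direction(list(
    list(v = front$heading, w = p$w_heading),
    list(v = rep_v, w = p$w_self),
    list(v = up, w = p$w_pia * distance_weight(ctx$distance_to_pia,
                                               p$pia_scale)),
    list(v = random_unit_vector(), w = p$w_random)))
}

## Obliques leave the trunk roughly perpendicular to it.
oblique_initial_direction <- function(front, ctx) {
  oblique_perp(front$heading)
}

#' Oblique-dendrite rule
#'
#' Side branches of the apical trunk in the deep layers: they grow away
#' from their sprout point (stored on the front), branch sparsely, and
#' terminate stochastically or once they exceed their length budget.
#'
#' @param front,context,params see [register_rule()].
#' @return a rule outcome.
#' @export
pyramidal_oblique_rule <- function(front, context, params) {
  p <- params$oblique
  grown <- front$path_length - front$aux[4L]
  if (is.na(grown)) grown <- 0
  if (runif(1) < p$term_prob || grown > p$max_length)
    return(terminate_outcome())
  ## flat branch probability: an oblique's global centrifugal order is
  ## already high (it counts the trunk's sprout events), so the 1/order
  ## form would never let obliques ramify
  branch <- runif(1) < p$branch_prob
  kind <- if (branch) "branch" else "extend"
  away <- front$position - front$aux[1:3]
  d_away <- sqrt(sum(away^2))
  up <- axis_unit(context$laminar$axis)
  base <- compose_direction(list(
    list(v = front$heading, w = p$w_heading),
    list(v = away / max(d_away, 1e-9), w = p$w_away),
    list(v = up, w = p$w_up %||% 0),
    list(v = random_unit_vector(), w = p$w_random)))
  dirs <- if (branch) branch_pair_dirs(base, p$branch_angle) else list(base)
  children <- list()
  for (dir in dirs) {
    ch <- child_spec(front, context, params, dir, kind,
                     step_length = p$step_length)
    ch$aux <- front$aux
    if (in_bounds(ch$position, context)) children <- c(children, list(ch))
  }
  if (length(children) == 0L) return(terminate_outcome())
  list(kind = kind, children = children)
}

## Built-in registry entries (evaluated at package load).
register_rule("motor", motor_rule)
register_rule("granule", granule_rule)
register_rule("pyramidal_soma", pyramidal_soma_rule)
register_rule("pyramidal_basal", pyramidal_basal_rule)
register_rule("pyramidal_apical", pyramidal_apical_rule)
register_rule("pyramidal_oblique", pyramidal_oblique_rule)
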