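## Simulation engine: a centrally clocked loop in which every sub-volume
## updates its active fronts in randomized order, validates each proposed
## front against the local neighborhood with the capsule test, resolves
## conflicts by random perturbation (or terminates the front), migrates
## fronts that cross SV boundaries, and records putative synapses at the
## same time as the overlap checks.
##
## Fronts live for exactly one update: an active front either terminates or
## produces one (continuation) or two or more (branch / soma stems) new
## active fronts, after which it is inactive forever.

GROW_BLOCK <- 4096L

init_front_store <- function(g) {
  n <- GROW_BLOCK
  g$fr_n <- 0L
  g$fr_x <- numeric(n); g$fr_y <- numeric(n); g$fr_z <- numeric(n)
  g$fr_r <- numeric(n); g$fr_path <- numeric(n)
  g$fr_parent <- integer(n); g$fr_neuron <- integer(n)
  g$fr_type <- integer(n); g$fr_order <- integer(n)
  g$fr_sv <- integer(n); g$fr_step <- integer(n); g$fr_swc <- integer(n)
  g$fr_active <- logical(n)
  g$fr_rule <- character(n)
  g$fr_layer <- character(n)
  g$fr_aux <- matrix(NA_real_, n, 4L)
  g$fr_segrow <- integer(n)
  g$seg_n <- 0L
  g$seg <- matrix(0, n, 7L)
  g$seg_front <- integer(n); g$seg_parent <- integer(n)
  g$seg_neuron <- integer(n); g$seg_type <- integer(n)
  g$neuron_n <- 0L
  g$neuron_soma <- matrix(0, 64L, 3L)
  g$neuron_type <- integer(64L)
  g$neuron_soma_front <- integer(64L)
  g$neuron_error <- character(0)
  g$syn_n <- 0L
  g$syn <- matrix(0, 256L, 8L)
  g$events <- list()
  invisible(g)
}

grow_front_store <- function(g, need) {
  cap <- length(g$fr_x)
  if (need <= cap) return(invisible(g))
  new_cap <- max(need, 2L * cap)
  pad_n <- function(v) c(v, numeric(new_cap - cap))
  pad_i <- function(v) c(v, integer(new_cap - cap))
  g$fr_x <- pad_n(g$fr_x); g$fr_y <- pad_n(g$fr_y); g$fr_z <- pad_n(g$fr_z)
  g$fr_r <- pad_n(g$fr_r); g$fr_path <- pad_n(g$fr_path)
  g$fr_parent <- pad_i(g$fr_parent); g$fr_neuron <- pad_i(g$fr_neuron)
  g$fr_type <- pad_i(g$fr_type); g$fr_order <- pad_i(g$fr_order)
  g$fr_sv <- pad_i(g$fr_sv); g$fr_step <- pad_i(g$fr_step)
  g$fr_swc <- pad_i(g$fr_swc)
  g$fr_active <- c(g$fr_active, logical(new_cap - cap))
  g$fr_rule <- c(g$fr_rule, character(new_cap - cap))
  g$fr_layer <- c(g$fr_layer, character(new_cap - cap))
  g$fr_aux <- rbind(g$fr_aux, matrix(NA_real_, new_cap - cap, 4L))
  g$fr_segrow <- pad_i(g$fr_segrow)
  invisible(g)
}

grow_seg_store <- function(g, need) {
  cap <- nrow(g$seg)
  if (need <= cap) return(invisible(g))
  new_cap <- max(need, 2L * cap)
  g$seg <- rbind(g$seg, matrix(0, new_cap - cap, 7L))
  g$seg_front <- c(g$seg_front, integer(new_cap - cap))
  g$seg_parent <- c(g$seg_parent, integer(new_cap - cap))
  g$seg_neuron <- c(g$seg_neuron, integer(new_cap - cap))
  g$seg_type <- c(g$seg_type, integer(new_cap - cap))
  invisible(g)
}

front_position <- function(g, id) c(g$fr_x[id], g$fr_y[id], g$fr_z[id])

## Register a new front plus its segment; returns the front id.
add_front <- function(g, neuron, type, parent, position, radius, order,
                      swc_type, rule, step_index, aux = NULL,
                      layer_entry = NA_character_, active = TRUE) {
  id <- g$fr_n + 1L
  grow_front_store(g, id)
  g$fr_n <- id
  g$fr_x[id] <- position[1L]; g$fr_y[id] <- position[2L]
  g$fr_z[id] <- position[3L]
  g$fr_r[id] <- radius
  g$fr_parent[id] <- parent
  g$fr_neuron[id] <- neuron
  g$fr_type[id] <- type
  g$fr_order[id] <- order
  g$fr_swc[id] <- swc_type
  g$fr_rule[id] <- rule
  g$fr_step[id] <- step_index
  g$fr_layer[id] <- layer_entry
  if (!is.null(aux)) g$fr_aux[id, seq_along(aux)] <- aux
  if (parent > 0L) {
    pp <- front_position(g, parent)
    g$fr_path[id] <- g$fr_path[parent] + sqrt(sum((position - pp)^2))
  } else {
    g$fr_path[id] <- 0
    pp <- position                      # soma: degenerate segment
  }
  sv <- locate(position, g)
  if (is.na(sv)) stop("consistency error: front created out of bounds")
  g$fr_sv[id] <- sv
  g$fr_active[id] <- active
  if (active) g$sv_fronts[[sv]] <- c(g$sv_fronts[[sv]], id)
  row <- g$seg_n + 1L
  grow_seg_store(g, row)
  g$seg_n <- row
  g$seg[row, ] <- c(pp, position, radius)
  g$seg_front[row] <- id
  g$seg_parent[row] <- if (parent > 0L) parent else -1L
  g$seg_neuron[row] <- neuron
  g$seg_type[row] <- type
  g$fr_segrow[id] <- row
  g$sv_segments[[sv]] <- c(g$sv_segments[[sv]], row)
  id
}

deactivate_front <- function(g, id) {
  if (!g$fr_active[id]) return(invisible(g))
  g$fr_active[id] <- FALSE
  sv <- g$fr_sv[id]
  g$sv_fronts[[sv]] <- setdiff(g$sv_fronts[[sv]], id)
  invisible(g)
}

#' Move a front between sub-volumes
#'
#' Transfers ownership of a front from one SV to another; position and
#' identity are unchanged and the global front count is conserved. Called
#' by the engine when a newly created front lies outside its parent's SV.
#'
#' @param grid an `arbor_grid`.
#' @param front_id front id.
#' @param from_sv,to_sv SV ids; `to_sv` must contain the front's position.
#' @return the grid, invisibly.
#' @export
migrate_front <- function(grid, front_id, from_sv, to_sv) {
  pos <- front_position(grid, front_id)
  if (!identical(locate(pos, grid), as.integer(to_sv)))
    stop("consistency error: target SV does not contain the front")
  grid$sv_fronts[[from_sv]] <- setdiff(grid$sv_fronts[[from_sv]], front_id)
  if (grid$fr_active[front_id])
    grid$sv_fronts[[to_sv]] <- c(grid$sv_fronts[[to_sv]], front_id)
  row <- grid$fr_segrow[front_id]
  grid$sv_segments[[from_sv]] <- setdiff(grid$sv_segments[[from_sv]], row)
  grid$sv_segments[[to_sv]] <- c(grid$sv_segments[[to_sv]], row)
  grid$fr_sv[front_id] <- to_sv
  invisible(grid)
}

## Candidate segment rows near a proposed segment: host + direct neighbors
## of both endpoints' SVs.
candidate_rows <- function(g, sv_a, sv_b) {
  svs <- if (is.na(sv_b) || sv_b == sv_a) c(sv_a, sv_neighbors(g, sv_a))
         else unique(c(sv_a, sv_neighbors(g, sv_a), sv_b, sv_neighbors(g, sv_b)))
  unlist(g$sv_segments[svs], use.names = FALSE)
}

#' Validate a proposed front against the local neighborhood
#'
#' Capsule-overlap test of the proposed segment (parent position to proposed
#' position) against every committed segment in the host SV and its direct
#' neighbors, excluding the parent's own segment and sibling segments
#' sharing the proximal endpoint. On conflict, up to
#' `resolution$attempts` random perturbations (uniform in a ball of radius
#' `resolution$magnitude`) are tried; if none resolves the conflict the
#' proposal is rejected and the parent front becomes a terminal tip.
#'
#' @param grid an `arbor_grid`.
#' @param parent_id id of the (still active) parent front.
#' @param position proposed child position, um.
#' @param radius proposed child radius, um.
#' @param siblings front ids of siblings committed in the same update.
#' @param resolution list with `attempts` (>= 0) and `magnitude` (um).
#' @return list with `status` ("accepted", "accepted_after_perturbation" or
#'   "terminated"), the final `position`, `conflicted` flag, and (on
#'   acceptance) the candidate rows and distances used, for synapse
#'   detection.
#' @export
validate_update <- function(grid, parent_id, position, radius, siblings,
                            resolution) {
  sv_a <- grid$fr_sv[parent_id]
  sv_b <- locate(position, grid)
  if (is.na(sv_b))
    return(list(status = "terminated", conflicted = FALSE))
  rows <- candidate_rows(grid, sv_a, sv_b)
  excl <- c(parent_id, siblings)
  rows <- rows[!(grid$seg_front[rows] %in% excl)]
  p0 <- front_position(grid, parent_id)
  test <- function(p) {
    if (length(rows) == 0L) return(list(ok = TRUE, d = numeric(0)))
    d <- cpp_seg_dist_many(c(p0, p), grid$seg[rows, 1:6, drop = FALSE])
    list(ok = all(d >= radius + grid$seg[rows, 7L]), d = d)
  }
  t0 <- test(position)
  if (t0$ok)
    return(list(status = "accepted", position = position, conflicted = FALSE,
                rows = rows, dists = t0$d))
  attempts <- resolution$attempts
  if (attempts > 0L) {
    for (i in seq_len(attempts)) {
      cand <- position + runif_ball(resolution$magnitude)
      if (is.na(locate(cand, grid))) next
      ti <- test(cand)
      if (ti$ok)
        return(list(status = "accepted_after_perturbation", position = cand,
                    conflicted = TRUE, rows = rows, dists = ti$d))
    }
  }
  list(status = "terminated", conflicted = TRUE)
}

#' Detect putative synapses for a newly committed segment
#'
#' Emits one record for every segment of a *different* neuron in the host
#' SV and its direct neighbors whose surface gap (axis distance minus the
#' two radii) does not exceed `max_distance`. The contact location is the
#' closest-approach midpoint. Same-neuron pairs never emit. Each unordered
#' pair is recorded once because only the newer segment scans.
#'
#' @param grid an `arbor_grid`.
#' @param seg_row row index of the new segment.
#' @param max_distance maximum surface gap, um.
#' @param rows,dists optional precomputed candidate rows and axis distances
#'   (reused from validation).
#' @return number of records appended.
#' @export
detect_synapses <- function(grid, seg_row, max_distance, rows = NULL,
                            dists = NULL) {
  if (max_distance < 0) return(0L)
  fid <- grid$seg_front[seg_row]
  if (is.null(rows)) {
    sv <- grid$fr_sv[fid]
    rows <- candidate_rows(grid, sv, NA_integer_)
    rows <- rows[rows != seg_row]
    dists <- if (length(rows))
      cpp_seg_dist_many(grid$seg[seg_row, 1:6], grid$seg[rows, 1:6, drop = FALSE])
      else numeric(0)
  }
  if (length(rows) == 0L) return(0L)
  keep <- grid$seg_neuron[rows] != grid$seg_neuron[seg_row]
  gaps <- dists - (grid$seg[seg_row, 7L] + grid$seg[rows, 7L])
  keep <- keep & gaps <= max_distance
  hit <- which(keep)
  for (h in hit) {
    other <- rows[h]
    loc <- closest_approach_point(grid$seg[seg_row, ], grid$seg[other, ])
    n <- grid$syn_n + 1L
    if (n > nrow(grid$syn))
      grid$syn <- rbind(grid$syn, matrix(0, nrow(grid$syn), 8L))
    grid$syn_n <- n
    grid$syn[n, ] <- c(grid$seg_neuron[seg_row], fid,
                       grid$seg_neuron[other], grid$seg_front[other],
                       loc, max(gaps[h], 0))
  }
  length(hit)
}

## Deterministic per-(step, SV) RNG substream key (kept below 2^31).
substream_seed <- function(seed, step_index, sv) {
  as.integer((as.numeric(seed %% 100000L) * 10007 +
              as.numeric(step_index) * 101 + as.numeric(sv)) %% 2147483647)
}

front_view <- function(g, id) {
  parent <- g$fr_parent[id]
  pos <- front_position(g, id)
  pp <- if (parent > 0L) front_position(g, parent) else pos
  heading <- if (parent > 0L && any(pos != pp)) normalize3(pos - pp) else NULL
  list(id = id, neuron_id = g$fr_neuron[id], cell_type = g$fr_type[id],
       position = pos, parent_position = pp, heading = heading,
       radius = g$fr_r[id], order = g$fr_order[id],
       path_length = g$fr_path[id], swc_type = g$fr_swc[id],
       rule = g$fr_rule[id], aux = g$fr_aux[id, ],
       layer_entry = g$fr_layer[id])
}

#' Advance the simulation by one synchronized clock tick
#'
#' Every SV (in fixed lexicographic order, each with its own RNG substream
#' keyed by seed, step and SV id) updates its contained active fronts in
#' randomized order: the front's growth rule proposes an update, each
#' proposed child is validated against the neighborhood, conflicts are
#' perturbed or terminated, accepted fronts are committed (and migrated to
#' their own SV when they cross a boundary), and new segments are scanned
#' for putative synapses. A rule error flags the neuron and terminates the
#' front; the simulation continues.
#'
#' @param grid an `arbor_grid` initialized by [run()] (or manually).
#' @param cfg validated simulation config.
#' @param step_index 1-based step number.
#' @return list of per-step event counts (also appended to the grid log).
#' @export
step <- function(grid, cfg, step_index) {
  counts <- c(extensions = 0L, branches = 0L, terminations = 0L,
              conflicts = 0L, resolved = 0L, migrations = 0L)
  res_cfg <- list(attempts = cfg$run$resolution_attempts,
                  magnitude = cfg$run$resolution_magnitude)
  occupied <- which(lengths(grid$sv_fronts) > 0L)
  for (sv in occupied) {
    ids <- grid$sv_fronts[[sv]]
    ids <- ids[grid$fr_step[ids] < step_index & grid$fr_active[ids]]
    if (length(ids) == 0L) next
    set.seed(substream_seed(cfg$run$seed, step_index, sv))
    ids <- ids[sample.int(length(ids))]
    for (id in ids) {
      fv <- front_view(grid, id)
      params <- cfg$.params[[grid$fr_type[id]]]
      ctx <- local_context(id, grid)
      outcome <- tryCatch(
        dispatch_rule(grid$fr_rule[id], fv, ctx, params),
        error = function(e) {
          grid$neuron_error <- c(grid$neuron_error, sprintf(
            "step %d neuron %d front %d: %s", step_index,
            grid$fr_neuron[id], id, conditionMessage(e)))
          list(kind = "terminate", children = list())
        })
      accepted <- 0L
      last_cid <- NA_integer_
      if (!identical(outcome$kind, "terminate")) {
        committed <- integer(0)
        mag <- res_cfg$magnitude
        for (ch in outcome$children) {
          res <- validate_update(grid, id, ch$position, ch$radius, committed,
                                 list(attempts = res_cfg$attempts,
                                      magnitude = if (is.null(mag)) ch$radius
                                                  else mag))
          if (res$conflicted) counts["conflicts"] <- counts["conflicts"] + 1L
          if (res$status == "terminated") next
          if (res$status == "accepted_after_perturbation")
            counts["resolved"] <- counts["resolved"] + 1L
          order <- if (fv$order == 0L) 1L
                   else if (identical(outcome$kind, "branch")) fv$order + 1L
                   else fv$order
          cid <- add_front(grid, neuron = fv$neuron_id, type = fv$cell_type,
                           parent = id, position = res$position,
                           radius = ch$radius, order = order,
                           swc_type = ch$swc_type,
                           rule = ch$rule, step_index = step_index,
                           aux = ch$aux, layer_entry = ch$layer_entry)
          if (grid$fr_sv[cid] != sv) {
            ## add_front registered the child in its own SV already; count
            ## the boundary crossing as a brokered migration.
            counts["migrations"] <- counts["migrations"] + 1L
          }
          detect_synapses(grid, grid$fr_segrow[cid],
                          cfg$run$synapse_max_distance,
                          rows = res$rows, dists = res$dists)
          committed <- c(committed, cid)
          accepted <- accepted + 1L
          last_cid <- cid
        }
        ## a bifurcation that lost one child to a conflict is really a
        ## continuation: demote the survivor so engine orders always
        ## equal topological (centrifugal) orders
        if (identical(outcome$kind, "branch") && accepted == 1L &&
            fv$order > 0L)
          grid$fr_order[last_cid] <- fv$order
      }
      if (accepted == 0L) {
        counts["terminations"] <- counts["terminations"] + 1L
      } else if (accepted >= 2L || identical(outcome$kind, "branch")) {
        counts["branches"] <- counts["branches"] + 1L
      } else {
        counts["extensions"] <- counts["extensions"] + 1L
      }
      deactivate_front(grid, id)
    }
  }
  rec <- c(list(step = step_index), as.list(counts),
           list(active = sum(grid$fr_active[seq_len(grid$fr_n)])))
  grid$events[[length(grid$events) + 1L]] <- rec
  rec
}

#' Run a full simulation
#'
#' Builds the substrate, places the somata (explicit positions or sampled
#' uniformly within a declared region, non-overlapping, under the seed),
#' then repeats [step()] until `run$steps` ticks have elapsed or no active
#' fronts remain. Writes SWC / synapse / event-log outputs when an output
#' directory is configured.
#'
#' @param config a validated config from [simulation_config()] or
#'   [read_config()].
#' @return an `arbor_result`: `morphologies` (list of SWC-style node
#'   tables), `synapses`, `event_log`, plus the grid for auditing.
#' @export
run <- function(config) {
  cfg <- validate_config(config)
  g <- decompose(cfg$substrate$dims, cfg$substrate$grid_shape)
  if (!is.null(cfg$substrate$laminar)) g$laminar <- cfg$substrate$laminar
  set.seed(cfg$run$seed)
  for (e in cfg$substrate$entities) add_entity(e, g)
  place_somata(g, cfg)
  step_i <- 0L
  while (step_i < cfg$run$steps) {
    step_i <- step_i + 1L
    step(g, cfg, step_i)
    if (sum(grid_active(g)) == 0L) break
  }
  result <- assemble_result(g, cfg, steps_run = step_i)
  if (!is.null(cfg$outputs$dir)) write_outputs(result, cfg$outputs$dir)
  result
}

grid_active <- function(g) g$fr_active[seq_len(g$fr_n)]

place_somata <- function(g, cfg) {
  placed <- matrix(numeric(0), 0L, 4L)      # x, y, z, r
  for (ti in seq_along(cfg$cell_types)) {
    ct <- cfg$cell_types[[ti]]
    if (identical(ct$soma$mode, "explicit")) {
      pos <- ct$soma$positions
      if (nrow(pos) != ct$count)
        stop("config error: explicit soma positions must match count")
    } else {
      lo <- ct$soma$box_min; hi <- ct$soma$box_max
      pos <- matrix(0, ct$count, 3L)
      for (i in seq_len(ct$count)) {
        ok <- FALSE
        for (try in 1:200) {
          p <- lo + runif(3) * (hi - lo)
          if (nrow(placed) == 0L ||
              all(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - p)^2)) >
                  placed[, 4L] + ct$soma_radius)) { ok <- TRUE; break }
        }
        if (!ok) stop("config error: could not place non-overlapping somata")
        pos[i, ] <- p
        placed <- rbind(placed, c(p, ct$soma_radius))
      }
    }
    for (i in seq_len(ct$count)) {
      n <- g$neuron_n + 1L
      if (n > nrow(g$neuron_soma)) {
        g$neuron_soma <- rbind(g$neuron_soma, matrix(0, nrow(g$neuron_soma), 3L))
        g$neuron_type <- c(g$neuron_type, integer(length(g$neuron_type)))
        g$neuron_soma_front <- c(g$neuron_soma_front,
                                 integer(length(g$neuron_soma_front)))
      }
      g$neuron_n <- n
      g$neuron_soma[n, ] <- pos[i, ]
      g$neuron_type[n] <- ti
      fid <- add_front(g, neuron = n, type = ti, parent = 0L,
                       position = pos[i, ], radius = ct$soma_radius,
                       order = 0L, swc_type = 1L, rule = ct$rule_entry,
                       step_index = 0L)
      g$neuron_soma_front[n] <- fid
    }
  }
  invisible(g)
}

## ------------------------------------------------------------- results

assemble_result <- function(g, cfg, steps_run) {
  n_fr <- g$fr_n
  morphologies <- vector("list", g$neuron_n)
  type_names <- vapply(cfg$cell_types, `[[`, "", "name")
  for (nid in seq_len(g$neuron_n)) {
    ids <- which(g$fr_neuron[seq_len(n_fr)] == nid)
    ## pre-order traversal, children in creation order, for determinism
    kids <- split(ids, g$fr_parent[ids])
    root <- g$neuron_soma_front[nid]
    ord <- integer(length(ids)); k <- 0L
    stack <- root
    while (length(stack)) {
      cur <- stack[1L]; stack <- stack[-1L]
      k <- k + 1L; ord[k] <- cur
      ch <- kids[[as.character(cur)]]
      if (!is.null(ch)) stack <- c(sort(ch), stack)
    }
    idx <- setNames(seq_along(ord), ord)
    nodes <- data.frame(
      id = seq_along(ord),
      type = g$fr_swc[ord],
      x = g$fr_x[ord], y = g$fr_y[ord], z = g$fr_z[ord],
      radius = g$fr_r[ord],
      parent = ifelse(g$fr_parent[ord] > 0L,
                      as.integer(idx[as.character(g$fr_parent[ord])]), -1L),
      order = g$fr_order[ord],
      rule = g$fr_rule[ord],
      stringsAsFactors = FALSE)
    attr(nodes, "neuron_id") <- nid
    attr(nodes, "cell_type") <- type_names[g$neuron_type[nid]]
    class(nodes) <- c("arbor_tree", "data.frame")
    morphologies[[nid]] <- nodes
  }
  syn <- as.data.frame(g$syn[seq_len(g$syn_n), , drop = FALSE])
  names(syn) <- c("pre_neuron", "pre_front", "post_neuron", "post_front",
                  "x", "y", "z", "gap")
  ev <- if (length(g$events)) do.call(rbind, lapply(g$events, as.data.frame))
        else data.frame()
  structure(list(morphologies = morphologies, synapses = syn,
                 event_log = ev, errors = g$neuron_error,
                 steps_run = steps_run, config = cfg, grid = g),
            class = "arbor_result")
}

#' @export
print.arbor_result <- function(x, ...) {
  cat(sprintf("arbor_result: %d morphologies, %d fronts, %d synapses, %d steps\n",
              length(x$morphologies), x$grid$fr_n, nrow(x$synapses),
              x$steps_run))
  invisible(x)
}

#' Brute-force all-pairs capsule overlap audit
#'
#' Independent post-hoc check of the engine's zero-overlap guarantee: every
#' pair of committed segments, except tree-adjacent ones (parent/child and
#' siblings sharing their proximal endpoint), is tested with the capsule
#' criterion.
#'
#' @param result an `arbor_result` (or an `arbor_grid`).
#' @return 2-column matrix of offending segment-row pairs (0 rows = clean).
#' @export
audit_overlaps <- function(result) {
  g <- if (inherits(result, "arbor_grid")) result else result$grid
  n <- g$seg_n
  cpp_audit_overlaps(g$seg[seq_len(n), 1:6, drop = FALSE],
                     g$seg[seq_len(n), 7L],
                     g$seg_front[seq_len(n)], g$seg_parent[seq_len(n)])
}
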