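## Simulation configuration: an R-list contract plus a sectioned key-value
## text format. Seeds are mandatory; every run is reproducible from its
## config alone.

#' Build a simulation configuration
#'
#' @param substrate list: `dims` (length-3, um), optional `grid_shape`
#'   (length-3 integer; auto-chosen when NULL so each SV edge is at least
#'   twice the interaction radius), optional `laminar`
#'   (an `arbor_laminar` or `list(depth_axis, layers)`), optional
#'   `entities` (list of entity lists, see [add_entity()]).
#' @param cell_types list of cell-type blocks: `name`, `count`,
#'   `soma_radius` (um), `rule_entry`, a soma placement spec (`soma =
#'   list(mode = "explicit", positions = matrix)` or `list(mode =
#'   "uniform", box_min =, box_max =)`), and optional `params` overrides.
#' @param run list: `steps`, `seed` (mandatory), `synapse_max_distance`
#'   (default 2 um), `resolution_attempts` (default 10),
#'   `resolution_magnitude` (default NULL = the new segment's radius).
#' @param outputs list: optional `dir`.
#' @return validated config of class `arbor_config`.
#' @export
simulation_config <- function(substrate, cell_types, run, outputs = list()) {
  validate_config(list(substrate = substrate, cell_types = cell_types,
                       run = run, outputs = outputs))
}

validate_config <- function(cfg) {
  if (inherits(cfg, "arbor_config")) return(cfg)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  s <- cfg$substrate
  if (is.null(s$dims) || length(s$dims) != 3L || any(!is.finite(s$dims)) ||
      any(s$dims <= 0))
    note("substrate dims must be three positive lengths (um)")
  if (!is.null(s$laminar) && !inherits(s$laminar, "arbor_laminar"))
    s$laminar <- laminar_structure(s$laminar$layers,
                                   s$laminar$depth_axis %||% "y")
  if (is.null(s$entities)) s$entities <- list()

  r <- cfg$run
  if (is.null(r$seed)) note("run seed is mandatory (reproducibility policy)")
  if (is.null(r$steps) || r$steps < 0) note("run steps must be >= 0")
  r$synapse_max_distance <- r$synapse_max_distance %||% 2
  r$resolution_attempts <- r$resolution_attempts %||% 10L
  if (is.null(r$resolution_magnitude)) r$resolution_magnitude <- NULL

  if (length(cfg$cell_types) == 0L) note("at least one cell type is required")
  params <- vector("list", length(cfg$cell_types))
  max_r <- 0; max_step <- 0
  for (i in seq_along(cfg$cell_types)) {
    ct <- cfg$cell_types[[i]]
    if (is.null(ct$name)) note(sprintf("cell type %d: name missing", i))
    if (is.null(ct$count) || ct$count < 1)
      note(sprintf("cell type %d: count must be >= 1", i))
    if (is.null(ct$soma_radius) || ct$soma_radius <= 0)
      note(sprintf("cell type %d: soma_radius must be > 0", i))
    if (is.null(ct$rule_entry) || !rule_exists(ct$rule_entry))
      note(sprintf("cell type %d: unknown rule_entry '%s'", i,
                   ct$rule_entry %||% "<missing>"))
    else {
      ## user-registered rules without a shipped parameter set get a
      ## minimal generic base
      base <- tryCatch(default_params(params_base_for(ct$rule_entry)),
                       error = function(e)
                         list(step_length = 10, initial_radius = 1,
                              taper = 1, branch_taper = 1, min_radius = 0.1,
                              branch_angle = 60))
      params[[i]] <- modifyList(base, ct$params %||% list())
      max_r <- max(max_r, ct$soma_radius)
      max_step <- max(max_step, params[[i]]$step_length %||% 10)
    }
    if (is.null(ct$soma$mode))
      note(sprintf("cell type %d: soma placement spec missing", i))
    cfg$cell_types[[i]] <- ct
  }
  if (length(problems))
    stop("config error:\n  - ", paste(problems, collapse = "\n  - "))

  if (is.null(s$grid_shape))
    s$grid_shape <- auto_grid_shape(s$dims, interaction_radius = max_r + max_step)
  cfg$substrate <- s
  cfg$run <- r
  cfg$.params <- params
  class(cfg) <- "arbor_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## SV edge must cover the largest interaction neighborhood (max soma radius
## plus one extension step, doubled) so host + direct neighbors always
## contain every segment a new front could touch. Total SV count is capped
## to keep per-SV bookkeeping light.
auto_grid_shape <- function(dims, interaction_radius, max_sv = 40000) {
  edge <- 2 * interaction_radius
  shape <- pmax(1L, as.integer(floor(dims / edge)))
  while (prod(shape) > max_sv) {
    f <- (max_sv / prod(shape))^(1 / 3)
    shape2 <- pmax(1L, as.integer(floor(shape * f)))
    if (identical(shape2, shape)) shape2 <- pmax(1L, shape - 1L)
    shape <- shape2
  }
  shape
}

## ------------------------------------------------- sectioned text format

#' Read a simulation configuration file
#'
#' Sectioned key-value text format: `[substrate]`, `[layers]`,
#' `[cell_type NAME]` (one per cell type), `[entity NAME]`, `[run]`,
#' `[outputs]`. Values are whitespace-separated scalars; `#` starts a
#' comment. See the files under `inst/extdata/` for complete examples.
#'
#' @param path file path.
#' @return validated `arbor_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sections <- list(); current <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[", ln)) {
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      sections[[length(sections) + 1L]] <- list(header = current,
                                                keys = list())
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) stop("config parse error at line: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      k <- length(sections)
      sections[[k]]$keys[[key]] <- parse_value(val)
    } else stop("config parse error at line: ", ln)
  }
  build_config_from_sections(sections)
}

parse_value <- function(val) {
  parts <- strsplit(val, "[[:space:]]+")[[1L]]
  num <- suppressWarnings(as.numeric(parts))
  if (length(parts) > 0L && !anyNA(num)) num else parts
}

build_config_from_sections <- function(sections) {
  get_sec <- function(h) {
    hit <- Filter(function(s) identical(s$header, h), sections)
    if (length(hit)) hit[[1L]]$keys else NULL
  }
  sub_keys <- get_sec("substrate")
  if (is.null(sub_keys)) stop("config error: [substrate] section missing")
  substrate <- list(dims = sub_keys$dims)
  if (!is.null(sub_keys$grid)) substrate$grid_shape <- as.integer(sub_keys$grid)

  lay_keys <- get_sec("layers")
  if (!is.null(lay_keys)) {
    ax <- lay_keys$depth_axis %||% "y"
    lay_keys$depth_axis <- NULL
    layers <- data.frame(
      name = names(lay_keys),
      lower = vapply(lay_keys, `[`, 0, 1L),
      upper = vapply(lay_keys, `[`, 0, 2L),
      stringsAsFactors = FALSE)
    substrate$laminar <- laminar_structure(layers, depth_axis = ax)
  }

  entities <- list()
  for (s in sections) {
    if (grepl("^entity ", s$header)) {
      k <- s$keys
      entities[[length(entities) + 1L]] <- list(
        name = sub("^entity ", "", s$header), position = k$position,
        magnitude = k$magnitude %||% 1, scale = k$scale %||% 50)
    }
  }
  substrate$entities <- entities

  cell_types <- list()
  for (s in sections) {
    if (!grepl("^cell_type ", s$header)) next
    k <- s$keys
    ct <- list(name = sub("^cell_type ", "", s$header),
               count = as.integer(k$count),
               soma_radius = k$soma_radius,
               rule_entry = k$rule_entry)
    if (!is.null(k$soma_box)) {
      ct$soma <- list(mode = "uniform", box_min = k$soma_box[1:3],
                      box_max = k$soma_box[4:6])
    } else if (!is.null(k$soma_positions)) {
      ct$soma <- list(mode = "explicit",
                      positions = matrix(k$soma_positions, ncol = 3L,
                                         byrow = TRUE))
    }
    over <- k[grepl("^param\\.", names(k))]
    if (length(over)) {
      names(over) <- sub("^param\\.", "", names(over))
      ct$params <- unflatten_params(over)
    }
    cell_types[[length(cell_types) + 1L]] <- ct
  }

  run_keys <- get_sec("run") %||% list()
  run <- list(steps = as.integer(run_keys$steps),
              seed = if (!is.null(run_keys$seed)) as.integer(run_keys$seed),
              synapse_max_distance = run_keys$synapse_max_distance,
              resolution_attempts =
                if (!is.null(run_keys$resolution_attempts))
                  as.integer(run_keys$resolution_attempts),
              resolution_magnitude = run_keys$resolution_magnitude)
  run <- run[!vapply(run, is.null, TRUE)]

  out_keys <- get_sec("outputs") %||% list()
  outputs <- list(dir = out_keys$dir)

  validate_config(list(substrate = substrate, cell_types = cell_types,
                       run = run, outputs = outputs))
}

## "apical.pia_stop" -> list(apical = list(pia_stop = ...))
unflatten_params <- function(flat) {
  out <- list()
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) out[[nm]] <- flat[[nm]]
    else {
      if (is.null(out[[parts[1L]]])) out[[parts[1L]]] <- list()
      out[[parts[1L]]][[parts[2L]]] <- flat[[nm]]
    }
  }
  out
}

#' Serialize a configuration back to the text format
#'
#' Round-trip contract: re-parsing the written file yields an equal
#' validated config. Parameter overrides present in the original file are
#' re-emitted; resolved defaults are not.
#'
#' @param cfg an `arbor_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  fmt <- function(v) paste(v, collapse = " ")
  out <- c("[substrate]",
           paste("dims =", fmt(cfg$substrate$dims)),
           paste("grid =", fmt(cfg$substrate$grid_shape)))
  lam <- cfg$substrate$laminar
  if (!is.null(lam)) {
    out <- c(out, "", "[layers]",
             paste("depth_axis =", c("x", "y", "z")[lam$axis]),
             sprintf("%s = %s %s", lam$layers$name, lam$layers$lower,
                     lam$layers$upper))
  }
  for (e in cfg$substrate$entities) {
    out <- c(out, "", sprintf("[entity %s]", e$name),
             paste("position =", fmt(e$position)),
             paste("magnitude =", e$magnitude),
             paste("scale =", e$scale))
  }
  for (ct in cfg$cell_types) {
    out <- c(out, "", sprintf("[cell_type %s]", ct$name),
             paste("count =", ct$count),
             paste("soma_radius =", ct$soma_radius),
             paste("rule_entry =", ct$rule_entry))
    if (identical(ct$soma$mode, "uniform"))
      out <- c(out, paste("soma_box =", fmt(c(ct$soma$box_min,
                                              ct$soma$box_max))))
    else
      out <- c(out, paste("soma_positions =",
                          fmt(as.numeric(t(ct$soma$positions)))))
    if (!is.null(ct$params))
      out <- c(out, flatten_params(ct$params))
  }
  out <- c(out, "", "[run]",
           paste("steps =", cfg$run$steps),
           paste("seed =", cfg$run$seed),
           paste("synapse_max_distance =", cfg$run$synapse_max_distance),
           paste("resolution_attempts =", cfg$run$resolution_attempts))
  if (!is.null(cfg$run$resolution_magnitude))
    out <- c(out, paste("resolution_magnitude =",
                        cfg$run$resolution_magnitude))
  if (!is.null(cfg$outputs$dir))
    out <- c(out, "", "[outputs]", paste("dir =", cfg$outputs$dir))
  writeLines(out, path)
  invisible(path)
}

flatten_params <- function(params, prefix = "param.") {
  out <- character(0)
  for (nm in names(params)) {
    v <- params[[nm]]
    if (is.list(v)) out <- c(out, flatten_params(v, paste0(prefix, nm, ".")))
    else out <- c(out, paste0(prefix, nm, " = ", paste(v, collapse = " ")))
  }
  out
}
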