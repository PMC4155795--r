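## SWC morphology I/O, synapse tables, event logs, and output bundling.
## SWC dialect: 7 whitespace-separated columns, 1-based indices, '#'
## comments, exactly one root with parent -1; type codes 1 soma, 3 basal
## dendrite, 4 apical dendrite.

#' Read an SWC morphology file
#'
#' Parses 7-column whitespace-separated records, skipping `#` comments, and
#' validates that the tree has a single root, no dangling parents and no
#' cycles. Parse errors name the offending line.
#'
#' @param path file path.
#' @return an `arbor_tree` node table (id, type, x, y, z, radius, parent),
#'   re-indexed to 1..n.
#' @export
read_swc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("SWC parse error: no records in ", path)
  parts <- strsplit(trimws(lines[rows]), "[[:space:]]+")
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop("SWC parse error at line ", rows[bad[1L]], ": expected 7 columns")
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 7L,
                               byrow = TRUE))
  if (anyNA(m)) {
    bad <- rows[which(rowSums(is.na(m)) > 0L)[1L]]
    stop("SWC parse error at line ", bad, ": non-numeric field")
  }
  idx <- as.integer(m[, 1L]); parent <- as.integer(m[, 7L])
  if (anyDuplicated(idx)) stop("SWC parse error: duplicate sample index")
  pos <- match(parent, idx)
  root <- which(parent == -1L)
  if (length(root) != 1L)
    stop("SWC parse error: exactly one root (parent -1) required, found ",
         length(root))
  dangle <- which(is.na(pos) & parent != -1L)
  if (length(dangle))
    stop("SWC parse error at line ", rows[dangle[1L]],
         ": parent index ", parent[dangle[1L]], " does not exist")
  tree <- data.frame(id = seq_along(idx), type = as.integer(m[, 2L]),
                     x = m[, 3L], y = m[, 4L], z = m[, 5L],
                     radius = m[, 6L],
                     parent = ifelse(parent == -1L, -1L, pos))
  ## cycle check: every node must reach the root
  depth <- rep(NA_integer_, nrow(tree)); depth[root] <- 0L
  for (pass in seq_len(nrow(tree))) {
    todo <- which(is.na(depth) & !is.na(depth[pmax(tree$parent, 1L)]) &
                  tree$parent > 0L)
    if (length(todo) == 0L) break
    depth[todo] <- depth[tree$parent[todo]] + 1L
  }
  if (anyNA(depth)) stop("SWC parse error: cycle or unreachable nodes in ",
                         path)
  class(tree) <- c("arbor_tree", "data.frame")
  tree
}

#' Write a morphology to SWC
#'
#' Nodes are emitted in deterministic pre-order (children in creation
#' order, as stored); two writes of the same tree are byte-identical. The
#' header comment records the provenance metadata passed in.
#'
#' @param tree an `arbor_tree` node table.
#' @param path output path.
#' @param meta optional named character vector echoed into `#` header lines
#'   (e.g. seed, config hash, cell type).
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path, meta = NULL) {
  tree <- tree_nodes(tree)
  hdr <- c("# SWC generated by arborsim",
           if (!is.null(meta)) sprintf("# %s: %s", names(meta), meta),
           "# index type x y z radius parent")
  rec <- sprintf("%d %d %.6g %.6g %.6g %.6g %d", tree$id, tree$type,
                 tree$x, tree$y, tree$z, tree$radius, tree$parent)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write putative synapse records as TSV
#'
#' Columns pre_neuron, pre_front, post_neuron, post_front, x, y, z, gap;
#' rows sorted deterministically. Each unordered pair appears once.
#'
#' @param records synapse data.frame (from an `arbor_result`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synapses <- function(records, path) {
  if (nrow(records)) {
    ord <- order(records$pre_neuron, records$pre_front, records$post_neuron,
                 records$post_front)
    records <- records[ord, , drop = FALSE]
    records[] <- lapply(records, function(col) round(col, 6))
  }
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a full simulation result to a directory
#'
#' One SWC file per neuron (`neuron_<id>_<type>.swc`), `synapses.tsv`, and
#' `events.json`. Byte-reproducible under a fixed config and seed.
#'
#' @param result an `arbor_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg_hash <- config_hash(cfg)
  for (i in seq_along(result$morphologies)) {
    tree <- result$morphologies[[i]]
    ct <- attr(tree, "cell_type")
    write_swc(tree, file.path(dir, sprintf("neuron_%04d_%s.swc", i, ct)),
              meta = c(seed = cfg$run$seed, config = cfg_hash,
                       cell_type = ct))
  }
  write_synapses(result$synapses, file.path(dir, "synapses.tsv"))
  ev <- result$event_log
  jsonlite::write_json(ev, file.path(dir, "events.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

## Hash of the scientific configuration only: output paths do not change
## what is simulated, so they are excluded (two runs of one config into
## different directories must still be byte-identical).
config_hash <- function(cfg) {
  cfg$outputs <- list()
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Read a directory of SWC files
#'
#' @param dir directory containing `.swc` files.
#' @return named list of `arbor_tree` tables (sorted by file name).
#' @export
read_swc_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.swc$", full.names = TRUE))
  if (length(files) == 0L) stop("no .swc files in ", dir)
  setNames(lapply(files, read_swc), basename(files))
}
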