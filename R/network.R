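#' Construct a sigmoid belief network specification
#'
#' Defines the fixed structure of the belief network: binary latent causes,
#' observable nodes (auditory stimuli, levers, foods), a single action node
#' (lever pressing), and the directed edges along which influence flows.
#' Edges are only permitted from a latent cause to an observable node, or
#' from the action node to a food node; latent causes and the action node
#' have no parents. The structure is fixed before learning: only edge
#' weights and node biases are estimated.
#'
#' @param latent_nodes character vector of latent-cause node names.
#' @param stimulus_nodes character vector of stimulus (sound) node names.
#' @param lever_nodes character vector of lever node names.
#' @param food_nodes character vector of food node names.
#' @param action_node single action node name (lever pressing).
#' @param edges two-column data frame (or matrix) with columns `parent` and
#'   `child`, one row per directed edge.
#' @return An object of class `sbn_spec`.
#' @seealso [default_network_spec()] for the standard PIT network.
#' @export
network_spec <- function(latent_nodes, stimulus_nodes, lever_nodes,
                         food_nodes, action_node, edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges))) {
    stop("`edges` must have columns `parent` and `child`")
  }
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  stopifnot(length(action_node) == 1L)
  all_nodes <- c(latent_nodes, stimulus_nodes, lever_nodes, food_nodes,
                 action_node)
  if (anyDuplicated(all_nodes)) {
    stop("node names must be unique across roles")
  }
  observable <- c(stimulus_nodes, lever_nodes, food_nodes)
  ok_latent <- edges$parent %in% latent_nodes & edges$child %in% observable
  ok_action <- edges$parent == action_node & edges$child %in% food_nodes
  if (!all(ok_latent | ok_action)) {
    bad <- edges[!(ok_latent | ok_action), , drop = FALSE]
    stop("invalid edge(s): ", paste(bad$parent, "->", bad$child, collapse = ", "),
         "; edges must run latent->observable or action->food")
  }
  if (anyDuplicated(paste(edges$parent, edges$child))) {
    stop("duplicate edges are not allowed")
  }
  structure(
    list(latent_nodes = as.character(latent_nodes),
         stimulus_nodes = as.character(stimulus_nodes),
         lever_nodes = as.character(lever_nodes),
         food_nodes = as.character(food_nodes),
         action_node = as.character(action_node),
         edges = edges),
    class = "sbn_spec")
}

#' Default PIT network
#'
#' The standard network for the two-lever, three-sound PIT paradigm: latent
#' causes H1-H3 each generate one sound/food pair (Pavlovian contexts),
#' instrumental contexts H4 and H5 generate one lever each and influence both
#' instrumental foods (allowing the cross-inhibition that underlies PIT
#' inhibition), and the action node A influences only the two instrumental
#' foods F1 and F2 -- pressing cannot conjure the purely Pavlovian food F3,
#' nor any sound or lever.
#'
#' @return An `sbn_spec` with 5 latent causes, 9 observables, one action
#'   node and 14 edges.
#' @examples
#' spec <- default_network_spec()
#' nrow(spec$edges)  # 14
#' @export
default_network_spec <- function() {
  edges <- rbind(
    data.frame(parent = c("H1", "H1", "H2", "H2", "H3", "H3"),
               child  = c("S1", "F1", "S2", "F2", "S3", "F3")),
    data.frame(parent = rep("H4", 3), child = c("L1", "F1", "F2")),
    data.frame(parent = rep("H5", 3), child = c("L2", "F1", "F2")),
    data.frame(parent = c("A", "A"), child = c("F1", "F2")))
  network_spec(latent_nodes = paste0("H", 1:5),
               stimulus_nodes = paste0("S", 1:3),
               lever_nodes = c("L1", "L2"),
               food_nodes = paste0("F", 1:3),
               action_node = "A",
               edges = edges)
}

#' @export
print.sbn_spec <- function(x, ...) {
  cat("Sigmoid belief network specification\n")
  cat("  latent causes:", paste(x$latent_nodes, collapse = ", "), "\n")
  cat("  stimuli:      ", paste(x$stimulus_nodes, collapse = ", "), "\n")
  cat("  levers:       ", paste(x$lever_nodes, collapse = ", "), "\n")
  cat("  foods:        ", paste(x$food_nodes, collapse = ", "), "\n")
  cat("  action:       ", x$action_node, "\n")
  cat("  edges:        ", nrow(x$edges), "\n")
  invisible(x)
}

#' Observable node names of a network
#'
#' @param spec an `sbn_spec`.
#' @param include_action also include the action node (last).
#' @return character vector of node names.
#' @export
observable_nodes <- function(spec, include_action = TRUE) {
  out <- c(spec$stimulus_nodes, spec$lever_nodes, spec$food_nodes)
  if (include_action) out <- c(out, spec$action_node)
  out
}

#' Does the network contain a given edge?
#'
#' @param spec an `sbn_spec`.
#' @param parent,child node names.
#' @return logical.
#' @export
has_edge <- function(spec, parent, child) {
  any(spec$edges$parent == parent & spec$edges$child == child)
}

edge_names <- function(spec) {
  sort(paste0(spec$edges$parent, "->", spec$edges$child))
}

all_nodes <- function(spec) {
  c(spec$latent_nodes, observable_nodes(spec))
}

# Canonical parameter order: biases for every node (latents first, then
# stimuli, levers, foods, action), then edge weights sorted by edge name.
# This order fixes the Metropolis update sweep and all CSV columns.
param_names <- function(spec) {
  en <- edge_names(spec)
  c(paste0("b_", all_nodes(spec)),
    paste0("w_", sub("->", "_", en, fixed = TRUE)))
}

#' Write / read a network specification as a YAML document
#'
#' Serializes node lists and the edge list to a structured text file that
#' round-trips through [read_network_spec()].
#'
#' @param spec an `sbn_spec`.
#' @param path file path.
#' @return `write_network_spec` returns `path` invisibly;
#'   `read_network_spec` returns an `sbn_spec`.
#' @export
write_network_spec <- function(spec, path) {
  doc <- list(latent_nodes = spec$latent_nodes,
              stimulus_nodes = spec$stimulus_nodes,
              lever_nodes = spec$lever_nodes,
              food_nodes = spec$food_nodes,
              action_node = spec$action_node,
              edges = lapply(seq_len(nrow(spec$edges)), function(i) {
                list(parent = spec$edges$parent[i], child = spec$edges$child[i])
              }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  edges <- do.call(rbind, lapply(doc$edges, function(e) {
    data.frame(parent = e$parent, child = e$child, stringsAsFactors = FALSE)
  }))
  network_spec(doc$latent_nodes, doc$stimulus_nodes, doc$lever_nodes,
               doc$food_nodes, doc$action_node, edges)
}

#' Export the edge list as a two-column CSV
#'
#' @param spec an `sbn_spec`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(spec, path) {
  utils::write.csv(spec$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Integer encoding of the network consumed by the C++ kernels.
# Observable columns are ordered as observable_nodes(spec); theta is ordered
# as param_names(spec). All indices 0-based.
build_model <- function(spec) {
  obs <- observable_nodes(spec)
  pn <- param_names(spec)
  bias_idx <- function(node) match(paste0("b_", node), pn) - 1L
  en <- paste0(spec$edges$parent, "->", spec$edges$child)
  w_idx <- match(paste0("w_", sub("->", "_", en, fixed = TRUE)), pn) - 1L
  is_action <- spec$edges$parent == spec$action_node
  list(
    n_latent = length(spec$latent_nodes),
    n_obs = length(obs),
    action_col = match(spec$action_node, obs) - 1L,
    bias_latent = vapply(spec$latent_nodes, bias_idx, integer(1), USE.NAMES = FALSE),
    bias_obs = vapply(obs, bias_idx, integer(1), USE.NAMES = FALSE),
    e_child = match(spec$edges$child, obs) - 1L,
    e_type = as.integer(is_action),
    e_parent = ifelse(is_action, -1L,
                      match(spec$edges$parent, spec$latent_nodes) - 1L),
    e_w = w_idx)
}
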