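#' Sign-parity path semantics
#'
#' A signed path is a simple directed path (no node revisited) whose net
#' effect is the product of its edge signs: a path activates its endpoint
#' iff it contains an even number of inhibition edges — inhibition of an
#' inhibitor yields activation. Depth is counted in edges starting at the
#' query compound, so the compound-to-receptor binding edge is step 1.
#'
#' @name signed-paths
NULL

#' Construct a signed path
#'
#' @param node_ids ordered entity ids, length `steps + 1`.
#' @param effects edge signs (+1/-1), one per traversed edge.
#' @return An object of class `signed_path` with elements `node_ids`,
#'   `effects`, `steps` and `net`.
#' @export
signed_path <- function(node_ids, effects) {
  effects <- as.integer(effects)
  if (length(node_ids) != length(effects) + 1L) {
    abort_value("signed path needs one more node than edges")
  }
  if (anyDuplicated(node_ids)) {
    abort_value("signed paths are simple: node '%s' repeats",
                node_ids[duplicated(node_ids)][1])
  }
  if (!length(effects) || !all(effects %in% c(1L, -1L))) {
    abort_value("path effects must be a non-empty vector of +1/-1")
  }
  structure(list(node_ids = node_ids, effects = effects,
                 steps = length(effects), net = as.integer(prod(effects))),
            class = "signed_path")
}

#' @export
print.signed_path <- function(x, ...) {
  arrows <- ifelse(x$effects == 1L, " -> ", " -| ")
  cat(paste0(x$node_ids[1],
             paste0(arrows, x$node_ids[-1], collapse = "")),
      sprintf("  [%d steps, net %s]\n", x$steps,
              if (x$net == 1L) "activation" else "inhibition"))
  invisible(x)
}

#' Net effect of a sign sequence
#'
#' @param effects vector of edge signs, entries +1 or -1.
#' @return +1 if the count of inhibition (-1) entries is even, else -1.
#' @export
net_effect <- function(effects) {
  effects <- as.integer(effects)
  if (!length(effects)) abort_value("effects must be non-empty")
  if (!all(effects %in% c(1L, -1L))) {
    abort_value("effects entries must be +1 or -1")
  }
  as.integer(prod(effects))
}

#' All sign sequences of a given length with a given net effect
#'
#' Enumerates the `2^(length-1)` sequences over \{+1, -1\} whose product
#' equals `net`, in lexicographic order with +1 ordered before -1.
#' For two-step activation these are (activation, activation) and
#' (inhibition, inhibition); for three steps the four sequences AAA, AII,
#' IAI, IIA.
#'
#' @param length number of edges, >= 1.
#' @param net required net effect, +1 or -1.
#' @return List of integer vectors.
#' @export
valid_sign_sequences <- function(length, net = 1L) {
  if (!is.numeric(length) || length < 1 || length != as.integer(length)) {
    abort_value("length must be an integer >= 1")
  }
  if (!net %in% c(1L, -1L)) abort_value("net must be +1 or -1")
  length <- as.integer(length)
  out <- vector("list", 2L^(length - 1L))
  k <- 0L
  for (i in 0:(2L^length - 1L)) {
    # most-significant bit = first position; bit 0 -> +1, bit 1 -> -1
    bits <- bitwAnd(bitwShiftR(i, (length - 1L):0L), 1L)
    seq <- ifelse(bits == 1L, -1L, 1L)
    if (prod(seq) == net) {
      k <- k + 1L
      out[[k]] <- as.integer(seq)
    }
  }
  out
}

# Adjacency structure for path traversal: per source node, the unique
# (target, sign) pairs among signed edges. Self-loops are stored in the
# network but never traversed; parallel same-sign edges collapse to one
# traversal step (they yield distinct paths only when their signs differ).
# Unspecified-effect edges are invisible to path search.
path_adjacency <- function(network) {
  ia <- network$interactions
  keep <- ia$effect != 0L & ia$source != ia$target
  ia <- ia[keep, c("source", "target", "effect")]
  ia <- unique(ia)
  split(ia[, c("target", "effect")], factor(ia$source))
}

assert_path_args <- function(network, source_id, max_steps) {
  stopifnot(inherits(network, "interaction_network"))
  if (!source_id %in% network$entities$id) {
    abort_lookup("unknown source id '%s'", source_id)
  }
  if (!is.numeric(max_steps) || max_steps < 1 || max_steps > 10) {
    abort_value("max_steps must be between 1 and 10")
  }
}

# Depth-first enumeration of all simple paths of 1..max_steps edges from
# `source_id`. `visit(nodes, signs)` is called once per path endpoint.
walk_simple_paths <- function(adj, source_id, max_steps, visit) {
  recurse <- function(nodes, signs) {
    here <- nodes[length(nodes)]
    nbrs <- adj[[here]]
    if (is.null(nbrs)) return(invisible())
    for (i in seq_len(nrow(nbrs))) {
      v <- nbrs$target[i]
      if (v %in% nodes) next
      nodes2 <- c(nodes, v)
      signs2 <- c(signs, nbrs$effect[i])
      visit(nodes2, signs2)
      if (length(signs2) < max_steps) recurse(nodes2, signs2)
    }
  }
  recurse(source_id, integer(0))
  invisible()
}

#' Enumerate sign-constrained simple paths from a source
#'
#' Returns every simple directed path of 1..`max_steps` edges starting at
#' `source_id` whose net effect equals `net`, optionally restricted to a
#' set of terminal nodes. The network must already be evidence-filtered:
#' unspecified-effect edges are never traversed. Output order is
#' deterministic: terminal node id, then step count, then the node
#' sequence, then the sign sequence (lexicographically).
#'
#' @param network an evidence-filtered [interaction_network()].
#' @param source_id starting entity id.
#' @param max_steps depth bound in edges, 1..10.
#' @param net required net effect (+1 activation, default, or -1).
#' @param restrict_targets optional character vector of admissible
#'   terminal ids.
#' @return List of [signed_path()] objects.
#' @export
enumerate_paths <- function(network, source_id, max_steps, net = 1L,
                            restrict_targets = NULL) {
  assert_path_args(network, source_id, max_steps)
  if (!net %in% c(1L, -1L)) abort_value("net must be +1 or -1")
  adj <- path_adjacency(network)
  acc <- new.env(parent = emptyenv())
  acc$paths <- list()
  acc$n <- 0L
  visit <- function(nodes, signs) {
    if (prod(signs) != net) return(invisible())
    term <- nodes[length(nodes)]
    if (!is.null(restrict_targets) && !term %in% restrict_targets) {
      return(invisible())
    }
    acc$n <- acc$n + 1L
    acc$paths[[acc$n]] <- signed_path(nodes, signs)
  }
  walk_simple_paths(adj, source_id, max_steps, visit)
  paths <- acc$paths
  if (!length(paths)) return(paths)
  term <- vapply(paths, function(p) p$node_ids[length(p$node_ids)],
                 character(1))
  steps <- vapply(paths, function(p) p$steps, integer(1))
  chain <- vapply(paths, function(p) paste(p$node_ids, collapse = "\x01"),
                  character(1))
  signs <- vapply(paths, function(p)
    paste(ifelse(p$effects == 1L, "+", "-"), collapse = ""), character(1))
  paths[lex_order(term, steps, chain, signs)]
}

#' Minimal net-activation depth from a source to a target
#'
#' The smallest number of edges among simple net-activation paths from
#' `source_id` to `target_id` within `max_steps`; `NA` when no such path
#' exists (including `source_id == target_id`: paths have at least one
#' edge and never revisit their start).
#'
#' @inheritParams enumerate_paths
#' @param target_id terminal entity id.
#' @return Integer depth, or `NA_integer_`.
#' @export
min_activation_depth <- function(network, source_id, target_id, max_steps) {
  assert_path_args(network, source_id, max_steps)
  if (!target_id %in% network$entities$id) {
    abort_lookup("unknown target id '%s'", target_id)
  }
  reach <- signed_reachability(network, source_id, max_steps)
  d <- reach$activation[[target_id]]
  if (is.null(d)) NA_integer_ else d
}

# Per-source reachability summary over all simple paths within max_steps:
# for every reachable node, the minimal depth at which it is reached with
# net activation and with net inhibition. One DFS per call.
signed_reachability <- function(network, source_id, max_steps) {
  assert_path_args(network, source_id, max_steps)
  adj <- path_adjacency(network)
  act <- new.env(parent = emptyenv())
  inh <- new.env(parent = emptyenv())
  visit <- function(nodes, signs) {
    term <- nodes[length(nodes)]
    d <- length(signs)
    env <- if (prod(signs) == 1L) act else inh
    prev <- env[[term]]
    if (is.null(prev) || d < prev) env[[term]] <- d
  }
  walk_simple_paths(adj, source_id, max_steps, visit)
  list(activation = as.list(act), inhibition = as.list(inh))
}

#' Convert signed paths to a data frame
#'
#' One row per path: source, terminal, steps, the node chain joined with
#' `|`, the sign chain as `+`/`-` characters, and the net effect.
#'
#' @param paths list of [signed_path()] objects.
#' @return A data frame.
#' @export
paths_as_data_frame <- function(paths) {
  if (!length(paths)) {
    return(data.frame(source = character(0), terminal = character(0),
                      steps = integer(0), nodes = character(0),
                      signs = character(0), net = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    source = vapply(paths, function(p) p$node_ids[1], character(1)),
    terminal = vapply(paths, function(p) p$node_ids[length(p$node_ids)],
                      character(1)),
    steps = vapply(paths, function(p) p$steps, integer(1)),
    nodes = vapply(paths, function(p) paste(p$node_ids, collapse = "|"),
                   character(1)),
    signs = vapply(paths, function(p)
      paste(ifelse(p$effects == 1L, "+", "-"), collapse = ""), character(1)),
    net = vapply(paths, function(p) p$net, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Write signed paths as TSV
#'
#' @param paths list of [signed_path()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paths <- function(paths, path) {
  write_tsv_file(paths_as_data_frame(paths), path)
}
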