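# Builders and independent oracles shared across the suite.

# Build an interaction_network from a compact edge spec:
# list of c(source, target, sign) with sign "+"/"-"/"0".
toy_network <- function(edges, mechanism = "binding") {
  sign_code <- c("+" = 1L, "-" = -1L, "0" = 0L)
  interaction_network(data.frame(
    source = vapply(edges, `[`, character(1), 1),
    target = vapply(edges, `[`, character(1), 2),
    effect = unname(sign_code[vapply(edges, `[`, character(1), 3)]),
    mechanism = mechanism, trust = "high", directness = "direct",
    provenance = "", stringsAsFactors = FALSE
  ))
}

write_temp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random signed digraph for property tests: up to `n_nodes` nodes,
# `n_edges` draws of ordered pairs (parallel edges and the occasional
# self-loop included on purpose).
random_network <- function(n_nodes = 8, n_edges = 20) {
  nodes <- LETTERS[seq_len(n_nodes)]
  src <- sample(nodes, n_edges, replace = TRUE)
  dst <- sample(nodes, n_edges, replace = TRUE)
  eff <- sample(c(1L, -1L), n_edges, replace = TRUE)
  interaction_network(
    data.frame(source = src, target = dst, effect = eff,
               mechanism = "binding", trust = "high", directness = "direct",
               provenance = "", stringsAsFactors = FALSE),
    data.frame(id = nodes, stringsAsFactors = FALSE)
  )
}

path_key <- function(nodes, signs) {
  paste0(paste(nodes, collapse = "|"), ":",
         paste(ifelse(signs == 1L, "+", "-"), collapse = ""))
}

paths_to_keys <- function(paths) {
  vapply(paths, function(p) path_key(p$node_ids, p$effects), character(1))
}

# Independent brute-force oracle built on igraph: enumerate node
# sequences of simple paths with all_simple_paths, then expand every
# combination of per-hop signs from the edge table and filter on parity.
oracle_paths <- function(network, source_id, max_steps, net,
                         restrict_targets = NULL) {
  ia <- network$interactions
  ia <- unique(ia[ia$effect != 0L & ia$source != ia$target,
                  c("source", "target", "effect")])
  g <- igraph::graph_from_data_frame(
    unique(ia[, c("source", "target")]), directed = TRUE,
    vertices = network$entities$id
  )
  seqs <- igraph::all_simple_paths(g, from = source_id, cutoff = max_steps,
                                   mode = "out")
  keys <- character(0)
  for (s in seqs) {
    nodes <- names(s)
    if (length(nodes) < 2) next
    if (!is.null(restrict_targets) &&
        !nodes[length(nodes)] %in% restrict_targets) next
    hop_signs <- lapply(seq_len(length(nodes) - 1), function(j) {
      ia$effect[ia$source == nodes[j] & ia$target == nodes[j + 1]]
    })
    for (combo in seq_len(prod(lengths(hop_signs)))) {
      idx <- arrayInd(combo, lengths(hop_signs))
      signs <- vapply(seq_along(hop_signs), function(j)
        hop_signs[[j]][idx[j]], integer(1))
      if (prod(signs) == net) keys <- c(keys, path_key(nodes, signs))
    }
  }
  sort(unique(keys))
}

fixture_net <- function() filter_evidence(pop_fixture()$network)
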