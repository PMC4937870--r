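#' Shortest-paths network assembly with conflict removal
#'
#' The displayed network is the union, over all (source, target) pairs,
#' of qualifying net-activation simple paths; with `shortest_only` all
#' minimal-length paths per pair are retained (ties included).
#' "Shortest" is measured among net-activation paths only — a shorter
#' net-inhibition path neither contributes edges nor redefines the
#' minimum. Mixed-message intermediate nodes (net activation from one
#' source but net inhibition from another along retained path prefixes)
#' are removed iteratively until the network is concordant.
#'
#' @name network-assembly
NULL

new_assembled <- function(network, source_ids, path_records,
                          terminal_targets, removed, max_steps,
                          shortest_only) {
  nodes <- character(0)
  if (length(path_records)) {
    nodes <- unique(unlist(lapply(path_records,
                                  function(r) r$path$node_ids)))
  }
  edges <- derive_edges(network, path_records)
  structure(list(
    nodes = lex_sort(nodes),
    edges = edges,
    terminal_targets = lex_sort(terminal_targets),
    removed_conflicts = removed,
    source_ids = source_ids,
    paths = path_records,
    max_steps = max_steps,
    shortest_only = shortest_only
  ), class = "assembled_network")
}

# Map the unique (u, v, sign) steps of the retained paths back to
# interaction rows of the base network; every assembled edge therefore
# lies on at least one retained net-activation path. on_minimal_path
# flags edges used by some minimal-length path of their (source, target)
# pair.
derive_edges <- function(network, path_records) {
  cols <- c(interaction_columns(), "on_minimal_path")
  if (!length(path_records)) {
    e <- empty_interactions()
    e$on_minimal_path <- logical(0)
    return(e)
  }
  pair_key <- vapply(path_records, function(r) paste(r$source, r$target),
                     character(1))
  steps <- vapply(path_records, function(r) r$path$steps, integer(1))
  min_by_pair <- tapply(steps, pair_key, min)
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(path_records)) {
    r <- path_records[[i]]
    minimal <- steps[i] == min_by_pair[[paste(r$source, r$target)]]
    p <- r$path
    for (j in seq_len(p$steps)) {
      key <- paste(p$node_ids[j], p$node_ids[j + 1], p$effects[j],
                   sep = "\x01")
      prev <- seen[[key]]
      if (is.null(prev) || (minimal && !prev)) seen[[key]] <- minimal
    }
  }
  ia <- network$interactions
  keys <- ls(seen)
  parts <- strsplit(keys, "\x01", fixed = TRUE)
  rows <- lapply(seq_along(keys), function(k) {
    u <- parts[[k]][1]; v <- parts[[k]][2]; s <- as.integer(parts[[k]][3])
    hit <- which(ia$source == u & ia$target == v & ia$effect == s)[1]
    cbind(ia[hit, , drop = FALSE],
          data.frame(on_minimal_path = seen[[keys[k]]]))
  })
  edges <- do.call(rbind, rows)
  edges <- edges[lex_order(edges$source, edges$target, edges$effect), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges[, cols]
}

# Shared builder: enumerate net-activation paths per (source, target)
# pair, optionally keeping only minimal-length ones.
assemble_paths <- function(network, source_ids, target_ids, max_steps,
                           shortest_only) {
  stopifnot(inherits(network, "interaction_network"))
  if (!length(target_ids)) abort_value("target_ids must be non-empty")
  ids <- network$entities$id
  missing <- setdiff(c(source_ids, target_ids), ids)
  if (length(missing)) abort_lookup("unknown entity id '%s'", missing[1])

  records <- list()
  reached <- character(0)
  for (s in source_ids) {
    paths <- enumerate_paths(network, s, max_steps, net = 1L,
                             restrict_targets = target_ids)
    for (t in target_ids) {
      pt <- Filter(function(p) p$node_ids[length(p$node_ids)] == t, paths)
      if (!length(pt)) {
        warning(sprintf("no net-activation path %s -> %s within %d steps",
                        s, t, max_steps), call. = FALSE)
        next
      }
      if (shortest_only) {
        lens <- vapply(pt, function(p) p$steps, integer(1))
        pt <- pt[lens == min(lens)]
      }
      reached <- union(reached, t)
      records <- c(records, lapply(pt, function(p)
        list(source = s, target = t, path = p)))
    }
  }
  new_assembled(network, source_ids, records, reached, character(0),
                max_steps, shortest_only)
}

#' Build the union-of-shortest-paths activation network
#'
#' For every (source, target) pair, all minimal-length net-activation
#' simple paths within `max_steps` are retained (ties all kept) and their
#' union forms the assembled network. Conflict removal is not yet
#' applied; see [remove_conflicts()]. Pairs with no qualifying path
#' contribute nothing (with a warning); an error is raised only when no
#' pair has any path.
#'
#' @param network an evidence-filtered [interaction_network()].
#' @param source_ids query source entity ids.
#' @param target_ids terminal target entity ids (non-empty).
#' @param max_steps depth bound in edges, 1..10 (default 3).
#' @return An object of class `assembled_network` with elements `nodes`,
#'   `edges` (interaction rows plus `on_minimal_path`),
#'   `terminal_targets`, `removed_conflicts`, `source_ids`, `paths`.
#' @export
build_shortest_paths_network <- function(network, source_ids, target_ids,
                                         max_steps = 3) {
  asm <- assemble_paths(network, source_ids, target_ids, max_steps,
                        shortest_only = TRUE)
  if (!length(asm$paths)) {
    abort_value("no net-activation path found for any (source, target) pair")
  }
  asm
}

#' @export
print.assembled_network <- function(x, ...) {
  cat(sprintf(paste0("assembled_network: %d nodes, %d edges, ",
                     "%d terminal targets, %d removed conflicts\n"),
              length(x$nodes), nrow(x$edges), length(x$terminal_targets),
              length(x$removed_conflicts)))
  invisible(x)
}

#' Detect mixed-message intermediate nodes
#'
#' An intermediate node (a displayed node that is neither a source nor a
#' terminal target) receives a mixed message when one source signals it
#' with net activation and another source — or the same source along a
#' different route — signals it with net inhibition within the depth
#' bound. Signals are evaluated over the base network with any
#' already-removed nodes excluded: a molecule deleted from the final
#' network no longer transmits.
#'
#' @param assembled an `assembled_network`.
#' @param network the base [interaction_network()] the assembly was
#'   built from.
#' @return Conflicted node ids in lexicographic order.
#' @export
detect_conflicts <- function(assembled, network) {
  stopifnot(inherits(assembled, "assembled_network"),
            inherits(network, "interaction_network"))
  intermediates <- setdiff(assembled$nodes,
                           c(assembled$source_ids,
                             assembled$terminal_targets))
  if (!length(intermediates)) return(character(0))
  net <- delete_entities(network, assembled$removed_conflicts)
  reach <- reach_by_source(net, assembled$source_ids, assembled$max_steps)
  conflicted <- Filter(function(n) {
    act <- any(vapply(reach, function(r) !is.null(r$activation[[n]]),
                      logical(1)))
    inh <- any(vapply(reach, function(r) !is.null(r$inhibition[[n]]),
                      logical(1)))
    act && inh
  }, intermediates)
  lex_sort(conflicted)
}

#' Iteratively remove conflicted nodes until the network is concordant
#'
#' Each round removes the currently conflicted intermediate nodes and
#' every retained path through them, then drops terminal targets no
#' longer reachable with net activation from all sources, and re-detects
#' conflicts; the fixpoint satisfies
#' `detect_conflicts(result, network) == []`.
#' Removal order is recorded in `removed_conflicts`. By default paths are
#' not re-routed through edges absent from the original assembly; with
#' `rerun_on_conflict = TRUE` the shortest-paths build is re-run on the
#' base network with the conflicted nodes excluded, which can recover
#' alternative routes.
#'
#' @param assembled an `assembled_network` from
#'   [build_shortest_paths_network()] or [extract_target_subnetwork()].
#' @param network the base [interaction_network()] the assembly was built
#'   from (needed for edge metadata and re-running).
#' @param rerun_on_conflict re-run path building with conflicted nodes
#'   excluded instead of pruning retained paths (default `FALSE`).
#' @return A concordant `assembled_network` (possibly with zero targets).
#' @export
remove_conflicts <- function(assembled, network, rerun_on_conflict = FALSE) {
  stopifnot(inherits(assembled, "assembled_network"))
  removed <- assembled$removed_conflicts
  all_targets <- assembled$terminal_targets

  # a terminal target survives only while every source still reaches it
  # with net activation over retained paths
  enforce_coverage <- function(asm) {
    keep <- asm$paths
    by_target <- split(vapply(keep, `[[`, character(1), "source"),
                       vapply(keep, `[[`, character(1), "target"))
    ok_targets <- names(by_target)[vapply(by_target, function(srcs)
      setequal(unique(srcs), asm$source_ids), logical(1))]
    keep <- Filter(function(r) r$target %in% ok_targets, keep)
    new_assembled(network, asm$source_ids, keep, ok_targets,
                  asm$removed_conflicts, asm$max_steps, asm$shortest_only)
  }

  current <- enforce_coverage(assembled)
  repeat {
    conf <- detect_conflicts(current, network)
    if (!length(conf)) break
    removed <- c(removed, conf)
    if (rerun_on_conflict) {
      pruned_net <- delete_entities(network, removed)
      keep_targets <- setdiff(all_targets, removed)
      if (!length(keep_targets)) {
        current <- new_assembled(network, assembled$source_ids, list(),
                                 character(0), removed,
                                 assembled$max_steps,
                                 assembled$shortest_only)
        break
      }
      current <- suppressWarnings(
        assemble_paths(pruned_net, assembled$source_ids, keep_targets,
                       assembled$max_steps, assembled$shortest_only))
    } else {
      keep <- Filter(function(r) !any(r$path$node_ids %in% conf),
                     current$paths)
      current <- new_assembled(network, assembled$source_ids, keep,
                               unique(vapply(keep, `[[`, character(1),
                                             "target")),
                               removed, assembled$max_steps,
                               assembled$shortest_only)
    }
    current$removed_conflicts <- removed
    current <- enforce_coverage(current)
  }
  current$removed_conflicts <- removed
  current
}

#' Write an assembled network to GraphML
#'
#' Node attributes: `entity_class`, `is_source`, `is_terminal`, `role`;
#' edge attributes: `effect`, `mechanism`, `on_minimal_path`. No
#' timestamps are emitted, so re-running a pipeline rewrites identical
#' files.
#'
#' @param assembled an `assembled_network`.
#' @param network the base [interaction_network()] (for entity classes).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assembled_graphml <- function(assembled, network, path) {
  doc <- xml2::xml_new_root("graphml", xmlns = graphml_ns)
  keydefs <- list(
    c("d_class", "node", "entity_class", "string"),
    c("d_role", "node", "role", "string"),
    c("d_src", "node", "is_source", "boolean"),
    c("d_term", "node", "is_terminal", "boolean"),
    c("d_effect", "edge", "effect", "int"),
    c("d_mech", "edge", "mechanism", "string"),
    c("d_min", "edge", "on_minimal_path", "boolean")
  )
  for (k in keydefs) {
    xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                        "attr.name" = k[3], "attr.type" = k[4])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  classes <- stats::setNames(network$entities$entity_class,
                             network$entities$id)
  for (n in assembled$nodes) {
    role <- if (n %in% assembled$source_ids) "source"
            else if (n %in% assembled$terminal_targets) "target"
            else "intermediate"
    nd <- xml2::xml_add_child(g, "node", id = n)
    xml2::xml_add_child(nd, "data", key = "d_class",
                        classes[[n]] %||% "generic_protein")
    xml2::xml_add_child(nd, "data", key = "d_role", role)
    xml2::xml_add_child(nd, "data", key = "d_src",
                        tolower(as.character(n %in% assembled$source_ids)))
    xml2::xml_add_child(nd, "data", key = "d_term",
                        tolower(as.character(n %in% assembled$terminal_targets)))
  }
  e <- assembled$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(g, "edge", source = e$source[i],
                              target = e$target[i])
    xml2::xml_add_child(ed, "data", key = "d_effect",
                        as.character(e$effect[i]))
    xml2::xml_add_child(ed, "data", key = "d_mech", e$mechanism[i])
    xml2::xml_add_child(ed, "data", key = "d_min",
                        tolower(as.character(e$on_minimal_path[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write an assembled network in DOT format
#'
#' Activating edges render solid green, inhibiting edges red with `tee`
#' arrowheads; edges on a minimal path are drawn bold ("thick lines"),
#' non-minimal ones thin. Layout is left to the renderer.
#'
#' @inheritParams write_assembled_graphml
#' @return `path`, invisibly.
#' @export
write_assembled_dot <- function(assembled, network, path) {
  quote_id <- function(x) paste0('"', gsub('"', '\\"', x, fixed = TRUE), '"')
  lines <- c("digraph pathway {", "  rankdir=LR;")
  for (n in assembled$nodes) {
    role <- if (n %in% assembled$source_ids) "source"
            else if (n %in% assembled$terminal_targets) "target"
            else "intermediate"
    shape <- switch(role, source = "hexagon", target = "doublecircle",
                    "ellipse")
    lines <- c(lines, sprintf("  %s [shape=%s, role=%s];",
                              quote_id(n), shape, role))
  }
  e <- assembled$edges
  for (i in seq_len(nrow(e))) {
    col <- if (e$effect[i] == 1L) "green" else "red"
    head <- if (e$effect[i] == 1L) "normal" else "tee"
    width <- if (isTRUE(e$on_minimal_path[i])) 2 else 1
    lines <- c(lines, sprintf(
      '  %s -> %s [color=%s, arrowhead=%s, penwidth=%d, sign=%d, mechanism="%s"];',
      quote_id(e$source[i]), quote_id(e$target[i]), col, head, width,
      e$effect[i], e$mechanism[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write the conflict-removal log as TSV
#'
#' @param assembled an `assembled_network` after [remove_conflicts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(assembled, path) {
  removed <- assembled$removed_conflicts
  write_tsv_file(
    data.frame(order = seq_along(removed), removed_node = removed,
               stringsAsFactors = FALSE),
    path
  )
}
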