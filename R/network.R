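#' Signed directed molecular-interaction networks
#'
#' An `interaction_network` holds a curated-knowledge-base-style signed
#' digraph: a table of molecular entities (nodes) and an ordered table of
#' directed interactions (edges), each carrying an effect sign
#' (+1 activation, -1 inhibition, 0 unspecified), a mechanism label
#' (e.g. binding, phosphorylation, promoter binding), an evidence trust
#' level (high/low), a directness flag (direct/indirect) and free-text
#' provenance. Parallel edges between the same ordered pair are permitted,
#' including with different signs: curated databases record
#' context-dependent opposite findings and both are retained.
#'
#' @param interactions data frame with columns `source`, `target`,
#'   `effect` (integer +1/-1/0), `mechanism`, `trust`, `directness`,
#'   `provenance`.
#' @param entities optional data frame with columns `id`, `display_name`,
#'   `entity_class`; entities seen only in edges are auto-created with
#'   class `generic_protein`.
#' @return An object of class `interaction_network` with elements
#'   `entities` and `interactions`.
#' @seealso [load_network()], [filter_evidence()], [primary_targets()]
#' @export
interaction_network <- function(interactions = NULL, entities = NULL) {
  if (is.null(interactions)) {
    interactions <- empty_interactions()
  }
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  for (col in c("mechanism", "trust", "directness", "provenance")) {
    if (is.null(interactions[[col]])) {
      interactions[[col]] <- rep(
        switch(col, trust = "high", directness = "direct", ""),
        nrow(interactions)
      )
    }
  }
  interactions <- interactions[, interaction_columns()]
  interactions$effect <- as.integer(interactions$effect)
  rownames(interactions) <- NULL

  edge_ids <- unique(c(interactions$source, interactions$target))
  if (is.null(entities)) {
    entities <- data.frame(id = character(0), display_name = character(0),
                           entity_class = character(0),
                           stringsAsFactors = FALSE)
  }
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  if (is.null(entities$display_name)) entities$display_name <- entities$id
  entities$display_name <- ifelse(is.na(entities$display_name) |
                                    entities$display_name == "",
                                  entities$id, entities$display_name)
  if (is.null(entities$entity_class)) {
    entities$entity_class <- rep("generic_protein", nrow(entities))
  }
  entities$entity_class[is.na(entities$entity_class) |
                          entities$entity_class == ""] <- "generic_protein"
  missing <- setdiff(edge_ids, entities$id)
  if (length(missing)) {
    entities <- rbind(entities[, c("id", "display_name", "entity_class")],
                      data.frame(id = missing, display_name = missing,
                                 entity_class = "generic_protein",
                                 stringsAsFactors = FALSE))
  } else {
    entities <- entities[, c("id", "display_name", "entity_class")]
  }
  rownames(entities) <- NULL

  net <- structure(list(entities = entities, interactions = interactions),
                   class = "interaction_network")
  validate_network(net)
  net
}

interaction_columns <- function() {
  c("source", "target", "effect", "mechanism", "trust", "directness",
    "provenance")
}

empty_interactions <- function() {
  data.frame(source = character(0), target = character(0),
             effect = integer(0), mechanism = character(0),
             trust = character(0), directness = character(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d entities, %d interactions\n",
              nrow(x$entities), nrow(x$interactions)))
  eff <- table(factor(x$interactions$effect, levels = c(1L, -1L, 0L)))
  cat(sprintf("  activation %d | inhibition %d | unspecified %d\n",
              eff[["1"]], eff[["-1"]], eff[["0"]]))
  invisible(x)
}

entity_classes <- function() {
  c("compound", "receptor", "transcription_factor", "cytokine", "enzyme",
    "adaptor", "lipoprotein", "generic_protein", "complex")
}

effect_tokens <- c(activation = 1L, inhibition = -1L, unspecified = 0L)

effect_to_code <- function(tok) unname(effect_tokens[tok])
code_to_effect <- function(code) names(effect_tokens)[match(code, effect_tokens)]

validate_network <- function(net) {
  ent <- net$entities
  if (anyDuplicated(ent$id)) {
    abort_value("duplicate entity id: %s", ent$id[duplicated(ent$id)][1])
  }
  bad <- ent$id == "" | is.na(ent$id) | grepl("[[:space:]]", ent$id)
  if (any(bad)) {
    abort_value("entity ids must be non-empty and whitespace-free (offending id: '%s')",
                ent$id[bad][1])
  }
  unknown_class <- setdiff(unique(ent$entity_class), entity_classes())
  if (length(unknown_class)) {
    abort_value("unknown entity_class '%s'", unknown_class[1])
  }
  ia <- net$interactions
  dangling <- setdiff(unique(c(ia$source, ia$target)), ent$id)
  if (length(dangling)) {
    abort_value("interaction endpoint '%s' has no entity record", dangling[1])
  }
  if (!all(ia$effect %in% c(1L, -1L, 0L))) {
    abort_value("interaction effects must be +1, -1 or 0")
  }
  invisible(net)
}

#' Load a signed interaction network from a TSV edge table
#'
#' The edge table is UTF-8, tab-separated, with a header row naming at
#' least `source`, `target`, `effect` and `mechanism`; `trust`,
#' `directness` and `provenance` are optional and default to
#' `high` / `direct` / `""`. Effect tokens are `activation`, `inhibition`
#' and `unspecified`, stored as +1/-1/0. An optional entity table supplies
#' `id`, `display_name` and `entity_class`; ids seen only in edges are
#' auto-created as `generic_protein`. Row order of the edge table is
#' preserved.
#'
#' @param edge_table_path path to the TSV edge table.
#' @param entity_table_path optional path to the TSV entity table.
#' @return An [interaction_network()].
#' @export
load_network <- function(edge_table_path, entity_table_path = NULL) {
  tab <- read_tsv_file(edge_table_path)
  for (col in c("source", "target", "effect", "mechanism")) {
    if (is.null(tab[[col]])) {
      abort_format("edge table %s is missing required column '%s'",
                   edge_table_path, col)
    }
  }
  n <- nrow(tab)
  if (is.null(tab$trust)) tab$trust <- rep("high", n)
  if (is.null(tab$directness)) tab$directness <- rep("direct", n)
  if (is.null(tab$provenance)) tab$provenance <- rep("", n)

  check_tokens <- function(values, allowed, column) {
    bad <- which(!values %in% allowed)
    if (length(bad)) {
      abort_value("row %d: unknown %s token '%s' (allowed: %s)",
                  bad[1], column, values[bad[1]],
                  paste(allowed, collapse = ", "))
    }
  }
  check_tokens(tab$effect, names(effect_tokens), "effect")
  check_tokens(tab$trust, c("high", "low"), "trust")
  check_tokens(tab$directness, c("direct", "indirect"), "directness")
  empty_id <- which(tab$source == "" | tab$target == "" |
                      is.na(tab$source) | is.na(tab$target))
  if (length(empty_id)) {
    abort_value("row %d: empty source or target id", empty_id[1])
  }

  interactions <- data.frame(
    source = tab$source, target = tab$target,
    effect = effect_to_code(tab$effect),
    mechanism = tab$mechanism, trust = tab$trust,
    directness = tab$directness, provenance = tab$provenance,
    stringsAsFactors = FALSE
  )

  entities <- NULL
  if (!is.null(entity_table_path)) {
    ent <- read_tsv_file(entity_table_path)
    if (is.null(ent$id)) {
      abort_format("entity table %s is missing required column 'id'",
                   entity_table_path)
    }
    entities <- ent
  }
  interaction_network(interactions, entities)
}

#' Filter interactions by evidence quality
#'
#' Restricts a network to the evidence tier used for pathway queries:
#' typically only high-trust, direct interactions with a known effect
#' (activation or inhibition) are retained. Entities are kept even when
#' they become isolated; the input network is not modified. The filter is
#' idempotent and monotone.
#'
#' @param network an [interaction_network()].
#' @param require_trust keep only edges with this trust level
#'   (`"high"`, default), or `NULL` to disable the criterion.
#' @param require_directness keep only edges with this directness
#'   (`"direct"`, default), or `NULL` to disable.
#' @param require_known_effect drop edges with unspecified effect
#'   (default `TRUE`).
#' @return A new `interaction_network` with the surviving edges.
#' @export
filter_evidence <- function(network, require_trust = "high",
                            require_directness = "direct",
                            require_known_effect = TRUE) {
  stopifnot(inherits(network, "interaction_network"))
  ia <- network$interactions
  keep <- rep(TRUE, nrow(ia))
  if (!is.null(require_trust)) keep <- keep & ia$trust == require_trust
  if (!is.null(require_directness)) {
    keep <- keep & ia$directness == require_directness
  }
  if (isTRUE(require_known_effect)) keep <- keep & ia$effect != 0L
  out <- network
  out$interactions <- ia[keep, , drop = FALSE]
  rownames(out$interactions) <- NULL
  out
}

#' Primary binding targets of a query compound
#'
#' A primary target is an entity the compound binds directly
#' (a direct edge with mechanism `binding`) that itself has at least one
#' outgoing direct signed interaction — direct binding targets without
#' further downstream interactions are not useful path roots and are
#' dropped.
#'
#' @param network an evidence-filtered [interaction_network()].
#' @param compound_id entity id of the query compound.
#' @return Character vector of target ids, sorted lexicographically.
#' @export
primary_targets <- function(network, compound_id) {
  stopifnot(inherits(network, "interaction_network"))
  if (!compound_id %in% network$entities$id) {
    abort_lookup("unknown compound id '%s'", compound_id)
  }
  ia <- network$interactions
  bound <- unique(ia$target[ia$source == compound_id &
                              ia$mechanism == "binding" &
                              ia$directness == "direct"])
  has_downstream <- vapply(bound, function(t) {
    any(ia$source == t & ia$directness == "direct" & ia$effect != 0L)
  }, logical(1))
  lex_sort(bound[has_downstream])
}

#' Remove entities (and all incident interactions) from a network
#'
#' @param network an [interaction_network()].
#' @param ids entity ids to remove; unknown ids are ignored.
#' @return A new network without those entities or their edges.
#' @export
delete_entities <- function(network, ids) {
  stopifnot(inherits(network, "interaction_network"))
  out <- network
  out$entities <- network$entities[!network$entities$id %in% ids, ,
                                   drop = FALSE]
  ia <- network$interactions
  out$interactions <- ia[!(ia$source %in% ids | ia$target %in% ids), ,
                         drop = FALSE]
  rownames(out$entities) <- NULL
  rownames(out$interactions) <- NULL
  out
}

#' Write a network to TSV, SIF or GraphML
#'
#' TSV round-trips losslessly through [load_network()] (equal edge
#' multiset and entity table). The SIF dialect encodes one edge per line
#' as `source<TAB>relation<TAB>target` with relations
#' `activates` / `inhibits` / `interacts` (the last for unspecified
#' effects). GraphML stores all edge fields as typed attributes and
#' round-trips through [read_graphml()].
#'
#' @param network an [interaction_network()].
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param entity_path optional path for the companion entity TSV
#'   (tsv format only).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "graphml"),
                          entity_path = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  format <- match.arg(format)
  ia <- network$interactions
  if (format == "tsv") {
    out <- ia
    out$effect <- code_to_effect(out$effect)
    write_tsv_file(out, path)
    if (!is.null(entity_path)) write_tsv_file(network$entities, entity_path)
  } else if (format == "sif") {
    rel <- c("inhibits", "interacts", "activates")[ia$effect + 2L]
    lines <- paste(ia$source, rel, ia$target, sep = "\t")
    ok <- tryCatch({
      writeLines(lines, path)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) abort_io("cannot write %s: %s", path, conditionMessage(ok))
  } else {
    write_graphml_network(network, path)
  }
  invisible(path)
}

graphml_ns <- "http://graphml.graphdrawing.org/xmlns"

write_graphml_network <- function(network, path) {
  doc <- xml2::xml_new_root("graphml", xmlns = graphml_ns)
  keydefs <- list(
    c("d_display", "node", "display_name", "string"),
    c("d_class", "node", "entity_class", "string"),
    c("d_effect", "edge", "effect", "int"),
    c("d_mech", "edge", "mechanism", "string"),
    c("d_trust", "edge", "trust", "string"),
    c("d_direct", "edge", "directness", "string"),
    c("d_prov", "edge", "provenance", "string")
  )
  for (k in keydefs) {
    xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                        "attr.name" = k[3], "attr.type" = k[4])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  ent <- network$entities
  for (i in seq_len(nrow(ent))) {
    nd <- xml2::xml_add_child(g, "node", id = ent$id[i])
    xml2::xml_add_child(nd, "data", key = "d_display", ent$display_name[i])
    xml2::xml_add_child(nd, "data", key = "d_class", ent$entity_class[i])
  }
  ia <- network$interactions
  for (i in seq_len(nrow(ia))) {
    ed <- xml2::xml_add_child(g, "edge", source = ia$source[i],
                              target = ia$target[i])
    xml2::xml_add_child(ed, "data", key = "d_effect",
                        as.character(ia$effect[i]))
    xml2::xml_add_child(ed, "data", key = "d_mech", ia$mechanism[i])
    xml2::xml_add_child(ed, "data", key = "d_trust", ia$trust[i])
    xml2::xml_add_child(ed, "data", key = "d_direct", ia$directness[i])
    xml2::xml_add_child(ed, "data", key = "d_prov", ia$provenance[i])
  }
  ok <- tryCatch({
    xml2::write_xml(doc, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_io("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a network written by `write_network(..., format = "graphml")`
#'
#' @param path GraphML file path.
#' @return An [interaction_network()].
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  keymap <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                            xml2::xml_attr(keys, "id"))
  grab <- function(node, attr_name) {
    data <- xml2::xml_find_all(node, "./data")
    ids <- xml2::xml_attr(data, "key")
    hit <- which(keymap[ids] == attr_name)
    if (length(hit)) xml2::xml_text(data[[hit[1]]]) else NA_character_
  }
  nodes <- xml2::xml_find_all(doc, ".//graph/node")
  entities <- data.frame(
    id = xml2::xml_attr(nodes, "id"),
    display_name = vapply(nodes, grab, character(1), "display_name"),
    entity_class = vapply(nodes, grab, character(1), "entity_class"),
    stringsAsFactors = FALSE
  )
  edges <- xml2::xml_find_all(doc, ".//graph/edge")
  interactions <- data.frame(
    source = xml2::xml_attr(edges, "source"),
    target = xml2::xml_attr(edges, "target"),
    effect = as.integer(vapply(edges, grab, character(1), "effect")),
    mechanism = vapply(edges, grab, character(1), "mechanism"),
    trust = vapply(edges, grab, character(1), "trust"),
    directness = vapply(edges, grab, character(1), "directness"),
    provenance = vapply(edges, grab, character(1), "provenance"),
    stringsAsFactors = FALSE
  )
  interactions$provenance[is.na(interactions$provenance)] <- ""
  interaction_network(interactions, entities)
}
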