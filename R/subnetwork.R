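#' Per-target subnetwork extraction
#'
#' The assembled network is subdivided into one subnetwork per downstream
#' target for increased resolution: the union of qualifying
#' net-activation paths from every source to that single target. By
#' default all paths within the depth bound are shown (both the closest
#' and the farther interactions, distinguished by the `on_minimal_path`
#' edge attribute); with `shortest_only = TRUE` only minimal paths are
#' kept, as in the global assembly. Mixed-message conflict removal is
#' applied the same way as in [remove_conflicts()].
#'
#' @param network an evidence-filtered [interaction_network()].
#' @param source_ids query source entity ids.
#' @param target_id the single downstream target.
#' @param max_steps depth bound in edges, 1..10 (default 3).
#' @param shortest_only keep only minimal-length paths (default `FALSE`).
#' @return A concordant `assembled_network` focused on `target_id`.
#' @export
extract_target_subnetwork <- function(network, source_ids, target_id,
                                      max_steps = 3, shortest_only = FALSE) {
  if (!target_id %in% network$entities$id) {
    abort_lookup("unknown target id '%s'", target_id)
  }
  asm <- suppressWarnings(
    assemble_paths(network, source_ids, target_id, max_steps, shortest_only))
  remove_conflicts(asm, network)
}

#' Nodes shared by two subnetworks
#'
#' Intersection of the non-source node sets of two assembled networks
#' built over the same base network; reveals shared intermediate
#' machinery (e.g. a receptor and transcription factor on the routes to
#' two different cytokines).
#'
#' @param subnetwork_a,subnetwork_b `assembled_network` objects.
#' @return Character vector of shared node ids, sorted lexicographically.
#' @export
shared_nodes <- function(subnetwork_a, subnetwork_b) {
  stopifnot(inherits(subnetwork_a, "assembled_network"),
            inherits(subnetwork_b, "assembled_network"))
  a <- setdiff(subnetwork_a$nodes, subnetwork_a$source_ids)
  b <- setdiff(subnetwork_b$nodes, subnetwork_b$source_ids)
  lex_sort(intersect(a, b))
}
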