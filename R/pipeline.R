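#' Run the end-to-end convergence analysis
#'
#' Wires the stages in the analysis order: load and evidence-filter the
#' network, (optionally) merge a compound-binding table, discover common
#' activation targets, overlay disease annotations and narrow to
#' disease-associated targets, assemble the shortest-paths network,
#' remove mixed-message conflicts, and extract one subnetwork per
#' surviving target. Deterministic: identical inputs and parameters
#' rewrite byte-identical TSV/GraphML/DOT outputs (no timestamps).
#'
#' Written to `out_dir`: `convergence.tsv`, `network.graphml`,
#' `network.dot`, `removal_log.tsv`, `subnet_<target>.graphml` /
#' `subnet_<target>.dot`, and `manifest.json` recording inputs,
#' parameters and package version. On error, files already written for
#' this run are removed.
#'
#' @param network_path TSV edge table (see [load_network()]).
#' @param sources character vector of query compound ids (>= 2).
#' @param out_dir output directory (created if missing).
#' @param entity_path optional entity TSV.
#' @param bindings_path optional TSV with columns `compound`, `target`,
#'   `effect`: direct binding edges merged into the network before
#'   analysis (for inputs that keep compound-target bindings separate
#'   from the interaction table).
#' @param annotations_path optional annotation TSV (see
#'   [load_annotations()]); when given, targets are narrowed to the
#'   disease-associated ones.
#' @param max_steps depth bound in edges (default 3).
#' @param disease_panel disease panel for the overlay.
#' @param shortest_only use only minimal paths for the global assembly
#'   (default `TRUE`); per-target subnetworks always include farther
#'   interactions.
#' @param rerun_on_conflict see [remove_conflicts()].
#' @param include_partial report partially reachable targets in the
#'   convergence TSV.
#' @param seed optional integer recorded in the manifest (the analysis
#'   itself is deterministic).
#' @return Invisibly, a list with the convergence records, the final
#'   assembled network, the per-target subnetworks and the written file
#'   paths.
#' @export
run_pipeline <- function(network_path, sources, out_dir,
                         entity_path = NULL, bindings_path = NULL,
                         annotations_path = NULL, max_steps = 3,
                         disease_panel = default_disease_panel(),
                         shortest_only = TRUE, rerun_on_conflict = FALSE,
                         include_partial = FALSE, seed = NULL) {
  if (length(sources) < 2) abort_value("at least two sources are required")
  network <- load_network(network_path, entity_path)
  if (!is.null(bindings_path)) {
    network <- merge_bindings(network, bindings_path)
  }
  annotations <- NULL
  if (!is.null(annotations_path)) {
    annotations <- load_annotations(annotations_path)
  }

  filtered <- filter_evidence(network)
  records <- find_common_activation_targets(filtered, sources, max_steps,
                                            include_partial = include_partial)
  if (!is.null(annotations)) {
    records <- overlay(records, annotations, disease_panel)
    final_records <- filter_to_disease(records)
  } else {
    final_records <- records[records$status == "common_activated", ,
                             drop = FALSE]
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, name, ...) {
    p <- file.path(out_dir, name)
    writer(..., path = p)
    written <<- c(written, p)
    p
  }
  on_error_cleanup <- function(e) {
    unlink(written)
    stop(e)
  }

  tryCatch({
    emit(function(path) write_convergence(records, path), "convergence.tsv")
    assembled <- NULL
    subnets <- list()
    if (nrow(final_records)) {
      assembled <- build_shortest_paths_network(filtered, sources,
                                                final_records$target,
                                                max_steps)
      assembled <- remove_conflicts(assembled, filtered,
                                    rerun_on_conflict = rerun_on_conflict)
      emit(function(path) write_assembled_graphml(assembled, filtered, path),
           "network.graphml")
      emit(function(path) write_assembled_dot(assembled, filtered, path),
           "network.dot")
      emit(function(path) write_removal_log(assembled, path),
           "removal_log.tsv")
      for (t in assembled$terminal_targets) {
        sn <- extract_target_subnetwork(filtered, sources, t, max_steps,
                                        shortest_only = FALSE)
        subnets[[t]] <- sn
        safe <- gsub("[^A-Za-z0-9_.-]", "_", t)
        emit(function(path) write_assembled_graphml(sn, filtered, path),
             sprintf("subnet_%s.graphml", safe))
        emit(function(path) write_assembled_dot(sn, filtered, path),
             sprintf("subnet_%s.dot", safe))
      }
    }
    manifest <- list(
      inputs = list(network = network_path, entities = entity_path,
                    bindings = bindings_path,
                    annotations = annotations_path),
      parameters = list(sources = as.list(sources), max_steps = max_steps,
                        disease_panel = as.list(disease_panel),
                        shortest_only = shortest_only,
                        rerun_on_conflict = rerun_on_conflict,
                        include_partial = include_partial,
                        seed = seed),
      tool = list(package = "popnet",
                  version = as.character(utils::packageVersion("popnet")))
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
    written <- c(written, manifest_path)
    invisible(list(records = records, final_records = final_records,
                   assembled = assembled, subnetworks = subnets,
                   files = written))
  }, popnet_error = on_error_cleanup, error = on_error_cleanup)
}

merge_bindings <- function(network, bindings_path) {
  tab <- read_tsv_file(bindings_path)
  for (col in c("compound", "target", "effect")) {
    if (is.null(tab[[col]])) {
      abort_format("bindings table %s is missing required column '%s'",
                   bindings_path, col)
    }
  }
  bad <- which(!tab$effect %in% names(effect_tokens))
  if (length(bad)) {
    abort_value("row %d: unknown effect token '%s'", bad[1], tab$effect[bad[1]])
  }
  extra <- data.frame(
    source = tab$compound, target = tab$target,
    effect = effect_to_code(tab$effect), mechanism = "binding",
    trust = "high", directness = "direct", provenance = "bindings table",
    stringsAsFactors = FALSE
  )
  interaction_network(rbind(network$interactions, extra), network$entities)
}
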