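#' Packaged three-POP study fixture network
#'
#' A small signed interaction network encoding the worked pathway
#' examples of the three-POP metabolic-disease study: TCDD binds and
#' activates AhR; PCB 153 and p,p'-DDE bind and inhibit PXR and AR
#' respectively; downstream edges connect the receptors, the
#' transcription factors CREB1, RelA and c-Jun, and the readouts IL-8,
#' IL-6, TNF-alpha, fetuin A and cyclin D1. All edges are high-trust,
#' direct and signed. The AhR/ARNT complex is modelled as the single
#' path-carrying node `AhR` (ARNT noted in its display name only).
#' Annotations tag IL-6, IL-8 and TNF-alpha with all three panel
#' diseases and fetuin A with diabetes/insulin resistance.
#'
#' @return List with elements `network` (an [interaction_network()]) and
#'   `annotations` (entity -> disease set).
#' @export
pop_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "popnet",
                                 mustWork = TRUE)
  network <- load_network(ext("pop_fixture_edges.tsv"),
                          ext("pop_fixture_entities.tsv"))
  annotations <- load_annotations(ext("pop_fixture_annotations.tsv"))
  list(network = network, annotations = annotations)
}

#' Ids of the fixture query compounds
#'
#' @return Character vector `c("TCDD", "PCB153", "ppDDE")`.
#' @export
fixture_sources <- function() c("TCDD", "PCB153", "ppDDE")

#' Configuration for the planted-structure network generator
#'
#' Defaults emulate the study conditions of the convergence analysis:
#' three query compounds, each binding one distinct primary receptor, and
#' two planted groups of common activation targets — 6 with depth
#' profile (2, 2, 3) and 35 with (2, 3, 3) — embedded in a modest signed
#' background graph.
#'
#' @param n_sources number of query compounds (default 3).
#' @param planted_groups list of groups, each
#'   `list(count = <n>, profile = <per-source depths>)`; depths count
#'   edges from the compound, so each entry is >= 2 (binding edge plus at
#'   least one downstream edge) and <= `max_steps`.
#' @param n_background_nodes extra nodes carrying random signed edges
#'   among themselves only (default 100).
#' @param background_edge_probability per ordered-pair edge probability
#'   among background nodes (default 0.02).
#' @param inhibition_fraction probability a background edge is inhibitory
#'   (default 0.3).
#' @param n_conflicted_decoys decoys receiving a net-activation chain
#'   from one source and a net-inhibition chain from another (default 0).
#' @param n_deep_decoys decoys reachable only at `max_steps + 1`
#'   (default 0).
#' @param n_unannotated_decoys genuine common activation targets with no
#'   disease annotation (default 0).
#' @param disease_panel diseases used to annotate planted targets and
#'   decoys other than the unannotated ones.
#' @param max_steps the query depth bound the planting is relative to
#'   (default 3).
#' @param seed integer seed; mandatory, drives all randomness.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_sources = 3,
                             planted_groups = list(
                               list(count = 6, profile = c(2, 2, 3)),
                               list(count = 35, profile = c(2, 3, 3))),
                             n_background_nodes = 100,
                             background_edge_probability = 0.02,
                             inhibition_fraction = 0.3,
                             n_conflicted_decoys = 0,
                             n_deep_decoys = 0,
                             n_unannotated_decoys = 0,
                             disease_panel = default_disease_panel(),
                             max_steps = 3,
                             seed) {
  if (missing(seed) || !is.numeric(seed)) {
    abort_value("generator_config requires an integer seed")
  }
  cfg <- list(n_sources = as.integer(n_sources),
              planted_groups = planted_groups,
              n_background_nodes = as.integer(n_background_nodes),
              background_edge_probability = background_edge_probability,
              inhibition_fraction = inhibition_fraction,
              n_conflicted_decoys = as.integer(n_conflicted_decoys),
              n_deep_decoys = as.integer(n_deep_decoys),
              n_unannotated_decoys = as.integer(n_unannotated_decoys),
              disease_panel = disease_panel,
              max_steps = as.integer(max_steps),
              seed = as.integer(seed))
  if (cfg$n_sources < 2) abort_value("n_sources must be >= 2")
  for (p in c(cfg$background_edge_probability, cfg$inhibition_fraction)) {
    if (p < 0 || p > 1) abort_value("probabilities must lie in [0, 1]")
  }
  counts <- c(cfg$n_background_nodes, cfg$n_conflicted_decoys,
              cfg$n_deep_decoys, cfg$n_unannotated_decoys)
  if (any(counts < 0)) abort_value("counts must be >= 0")
  for (g in cfg$planted_groups) {
    if (length(g$profile) != cfg$n_sources) {
      abort_value("each depth profile needs one entry per source")
    }
    if (any(g$profile < 2)) {
      abort_value("depth profile entries must be >= 2 (binding edge plus >= 1 downstream edge)")
    }
    if (any(g$profile > cfg$max_steps)) {
      abort_value("depth profile entries must be <= max_steps")
    }
  }
  structure(cfg, class = "generator_config")
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the [generator_config()] arguments; `planted_groups` is a
#' list of `{count, profile}` mappings.
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_groups)) {
    raw$planted_groups <- lapply(raw$planted_groups, function(g)
      list(count = g$count, profile = as.numeric(unlist(g$profile))))
  }
  do.call(generator_config, raw)
}

#' Generate a random signed network with planted convergence structure
#'
#' Builds, deterministically for a fixed seed: one compound node and one
#' distinct primary receptor per source connected by a binding edge of
#' random sign; for each planted target and each source, a chain of
#' fresh intermediate nodes realising the requested depth, with a sign
#' sequence drawn uniformly from the valid sequences conditioned on the
#' already-fixed binding sign so the whole chain nets to activation;
#' conflicted decoys with a net-activation chain from one source and a
#' net-inhibition chain from another; deep decoys reachable only at
#' `max_steps + 1`; background Erdos-Renyi signed edges among background
#' nodes only. A post-generation audit recomputes every planted minimal
#' activation depth and decoy classification against the ground truth
#' and regenerates (bounded retries) on any violation, so the returned
#' truth is exact by construction.
#'
#' Planted targets and conflicted/deep decoys are annotated with the full
#' disease panel; unannotated decoys are not.
#'
#' @param config a [generator_config()].
#' @return List with elements `network`, `annotations`, and `truth`
#'   (class `planted_truth`: `source_ids`, `primary_target_by_source`,
#'   `planted_targets` data frame, `conflicted_decoys`, `deep_decoys`,
#'   `unannotated_decoys`, `seed`).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  for (attempt in 0:4) {
    seed <- config$seed + attempt * 1000003L
    gen <- with_seed(seed, build_planted(config))
    if (audit_planted(gen, config)) {
      gen$truth$seed <- config$seed
      return(gen)
    }
  }
  abort_value("generator could not realise the planted structure after 5 attempts")
}

build_planted <- function(config) {
  ns <- config$n_sources
  sources <- sprintf("POP%d", seq_len(ns))
  receptors <- sprintf("R%d", seq_len(ns))
  edges <- new.env(parent = emptyenv())
  edges$src <- character(0); edges$dst <- character(0)
  edges$eff <- integer(0); edges$mech <- character(0)
  add_edge <- function(u, v, sign, mech = "transcription regulation") {
    edges$src <- c(edges$src, u); edges$dst <- c(edges$dst, v)
    edges$eff <- c(edges$eff, as.integer(sign))
    edges$mech <- c(edges$mech, mech)
  }
  binding_sign <- sample(c(1L, -1L), ns, replace = TRUE)
  for (i in seq_len(ns)) {
    add_edge(sources[i], receptors[i], binding_sign[i], "binding")
  }
  # chain from source i's receptor to `terminal`, total depth `depth`
  # (compound edge included), net effect `net` for the whole chain
  add_chain <- function(i, terminal, depth, net, tag) {
    rest_net <- as.integer(net * binding_sign[i])
    seqs <- valid_sign_sequences(depth - 1L, rest_net)
    signs <- seqs[[sample.int(length(seqs), 1)]]
    mids <- if (depth > 2L) {
      sprintf("%s_%s_v%d", tag, sources[i], seq_len(depth - 2L))
    } else character(0)
    chain <- c(receptors[i], mids, terminal)
    for (j in seq_len(length(chain) - 1L)) {
      add_edge(chain[j], chain[j + 1L], signs[j])
    }
  }

  planted <- data.frame(target = character(0), group = character(0),
                        stringsAsFactors = FALSE)
  depth_cols <- matrix(integer(0), nrow = 0, ncol = ns)
  tcount <- 0L
  for (gi in seq_along(config$planted_groups)) {
    g <- config$planted_groups[[gi]]
    profile <- as.integer(g$profile)
    label <- paste(profile, collapse = "-")
    for (k in seq_len(g$count)) {
      tcount <- tcount + 1L
      id <- sprintf("T%04d", tcount)
      for (i in seq_len(ns)) add_chain(i, id, profile[i], 1L, id)
      planted <- rbind(planted, data.frame(target = id, group = label,
                                           stringsAsFactors = FALSE))
      depth_cols <- rbind(depth_cols, profile)
    }
  }
  colnames(depth_cols) <- sources
  planted <- cbind(planted, as.data.frame(depth_cols))
  rownames(planted) <- NULL

  conflicted <- sprintf("X%04d", seq_len(config$n_conflicted_decoys))
  for (j in seq_along(conflicted)) {
    a <- ((j - 1L) %% ns) + 1L
    b <- (a %% ns) + 1L
    add_chain(a, conflicted[j], 2L, 1L, conflicted[j])
    add_chain(b, conflicted[j], 2L, -1L, conflicted[j])
  }
  deep <- sprintf("D%04d", seq_len(config$n_deep_decoys))
  for (j in seq_along(deep)) {
    for (i in seq_len(ns)) {
      add_chain(i, deep[j], config$max_steps + 1L, 1L, deep[j])
    }
  }
  unannotated <- sprintf("U%04d", seq_len(config$n_unannotated_decoys))
  unann_depths <- matrix(integer(0), nrow = 0, ncol = ns)
  for (j in seq_along(unannotated)) {
    profile <- sample(2:config$max_steps, ns, replace = TRUE)
    for (i in seq_len(ns)) add_chain(i, unannotated[j], profile[i], 1L,
                                     unannotated[j])
    unann_depths <- rbind(unann_depths, profile)
  }

  # background edges live strictly among background nodes, so they can
  # never create source -> target shortcuts; the audit re-verifies anyway
  nb <- config$n_background_nodes
  background <- sprintf("B%04d", seq_len(nb))
  if (nb > 1 && config$background_edge_probability > 0) {
    pairs <- expand.grid(i = seq_len(nb), j = seq_len(nb))
    pairs <- pairs[pairs$i != pairs$j, ]
    hit <- stats::runif(nrow(pairs)) < config$background_edge_probability
    pairs <- pairs[hit, , drop = FALSE]
    if (nrow(pairs)) {
      sgn <- ifelse(stats::runif(nrow(pairs)) < config$inhibition_fraction,
                    -1L, 1L)
      for (k in seq_len(nrow(pairs))) {
        add_edge(background[pairs$i[k]], background[pairs$j[k]], sgn[k])
      }
    }
  }

  interactions <- data.frame(
    source = edges$src, target = edges$dst, effect = edges$eff,
    mechanism = edges$mech, trust = "high", directness = "direct",
    provenance = "synthetic", stringsAsFactors = FALSE
  )
  all_ids <- unique(c(interactions$source, interactions$target, background))
  entities <- data.frame(
    id = all_ids, display_name = all_ids,
    entity_class = ifelse(all_ids %in% sources, "compound",
                          ifelse(all_ids %in% receptors, "receptor",
                                 "generic_protein")),
    stringsAsFactors = FALSE
  )
  network <- interaction_network(interactions, entities)

  annotated <- c(planted$target, conflicted, deep)
  annotations <- stats::setNames(
    rep(list(canonical_disease(config$disease_panel)), length(annotated)),
    annotated
  )
  truth <- structure(list(
    source_ids = sources,
    primary_target_by_source = stats::setNames(receptors, sources),
    planted_targets = planted,
    conflicted_decoys = conflicted,
    deep_decoys = deep,
    unannotated_decoys = unannotated,
    unannotated_depths = unann_depths,
    seed = config$seed
  ), class = "planted_truth")
  list(network = network, annotations = annotations, truth = truth)
}

# Re-derive the planted structure from the generated network itself and
# compare with the intended truth: planted (and unannotated) minimal
# activation depths must equal the profiles with no inhibition route,
# conflicted decoys must classify conflicted, deep decoys unreachable.
audit_planted <- function(gen, config) {
  truth <- gen$truth
  reach <- reach_by_source(gen$network, truth$source_ids, config$max_steps)
  ok_target <- function(id, profile) {
    for (i in seq_along(truth$source_ids)) {
      r <- reach[[truth$source_ids[i]]]
      d <- r$activation[[id]]
      if (is.null(d) || d != profile[i]) return(FALSE)
      if (!is.null(r$inhibition[[id]])) return(FALSE)
    }
    TRUE
  }
  pt <- truth$planted_targets
  for (k in seq_len(nrow(pt))) {
    if (!ok_target(pt$target[k],
                   as.integer(pt[k, truth$source_ids]))) return(FALSE)
  }
  for (k in seq_along(truth$unannotated_decoys)) {
    if (!ok_target(truth$unannotated_decoys[k],
                   truth$unannotated_depths[k, ])) return(FALSE)
  }
  for (x in truth$conflicted_decoys) {
    if (classify_from_reach(reach, x) != "conflicted") return(FALSE)
  }
  for (d in truth$deep_decoys) {
    if (classify_from_reach(reach, d) != "unreachable") return(FALSE)
  }
  TRUE
}

#' Write a generated benchmark to disk
#'
#' Emits the standard edge TSV, entity TSV, annotation TSV, a ground
#' truth TSV (with the seed recorded on every row) and the configuration
#' as YAML into `dir`.
#'
#' @param gen result of [generate_network()].
#' @param config the [generator_config()] used.
#' @param dir output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_generated <- function(gen, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             entities = file.path(dir, "entities.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  write_network(gen$network, paths[["edges"]], "tsv",
                entity_path = paths[["entities"]])
  ann <- gen$annotations
  ann_df <- data.frame(
    entity = rep(names(ann), lengths(ann)),
    disease = unlist(ann, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_tsv_file(ann_df, paths[["annotations"]])
  truth <- gen$truth
  pt <- truth$planted_targets
  role_df <- function(ids, role, group = rep("", length(ids))) {
    data.frame(id = ids, role = rep(role, length(ids)), group = group,
               stringsAsFactors = FALSE)
  }
  truth_df <- rbind(
    role_df(pt$target, "planted_target", pt$group),
    role_df(truth$conflicted_decoys, "conflicted_decoy"),
    role_df(truth$deep_decoys, "deep_decoy"),
    role_df(truth$unannotated_decoys, "unannotated_decoy")
  )
  truth_df$seed <- config$seed
  write_tsv_file(truth_df, paths[["truth"]])
  yaml::write_yaml(unclass(config), paths[["config"]])
  invisible(paths)
}
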