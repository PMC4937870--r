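#' Convergence-target discovery
#'
#' A common activation target is an entity reachable with net activation
#' from every query source within the depth bound. Concordance is strict:
#' a target that any source can also reach with net inhibition within the
#' bound receives a mixed message and is classified `conflicted`, never
#' `common_activated`, regardless of relative path lengths.
#'
#' @name convergence
NULL

concordance_statuses <- function() {
  c("common_activated", "partial", "conflicted", "unreachable")
}

# Per-source signed reachability for a set of sources; memoised per call
# sites that need several classifications over the same query.
reach_by_source <- function(network, source_ids, max_steps) {
  stats::setNames(
    lapply(source_ids, function(s) signed_reachability(network, s, max_steps)),
    source_ids
  )
}

classify_from_reach <- function(reach, target_id) {
  act <- vapply(reach, function(r) !is.null(r$activation[[target_id]]),
                logical(1))
  inh <- vapply(reach, function(r) !is.null(r$inhibition[[target_id]]),
                logical(1))
  if (any(act) && any(inh)) return("conflicted")
  if (all(act)) return("common_activated")
  if (any(act)) return("partial")
  "unreachable"
}

#' Classify the concordance status of one target
#'
#' `conflicted` when some source reaches the target with net activation
#' and some source (possibly the same one) also reaches it with net
#' inhibition within `max_steps`; `common_activated` when every source
#' reaches it with net activation and none with net inhibition;
#' `partial` when only some sources reach it with activation (and none
#' with inhibition); `unreachable` otherwise.
#'
#' @param network an evidence-filtered [interaction_network()].
#' @param source_ids query source entity ids (>= 2).
#' @param target_id entity id to classify.
#' @param max_steps depth bound in edges (default 3).
#' @return One of `"common_activated"`, `"partial"`, `"conflicted"`,
#'   `"unreachable"`.
#' @export
classify_concordance <- function(network, source_ids, target_id,
                                 max_steps = 3) {
  if (!target_id %in% network$entities$id) {
    abort_lookup("unknown target id '%s'", target_id)
  }
  reach <- reach_by_source(network, source_ids, max_steps)
  classify_from_reach(reach, target_id)
}

#' Find common activation targets of a set of query sources
#'
#' For every entity other than the sources themselves, computes the
#' minimal net-activation depth from each source within `max_steps`,
#' classifies concordance, and reports the targets every source activates
#' concordantly. The mean depth is the arithmetic mean of the per-source
#' minima, rounded half-up to 2 decimals (a (2, 2, 3) profile averages
#' 2.33; (2, 3, 3) averages 2.67).
#'
#' @param network an evidence-filtered [interaction_network()].
#' @param source_ids query source entity ids (>= 2).
#' @param max_steps depth bound in edges (default 3).
#' @param include_partial also report targets reachable with activation
#'   from only some sources (status `partial`); default `FALSE`.
#' @return A data frame with one row per target: `target`, one
#'   `depth_<source>` column per source, `mean_depth`, `status`, and
#'   placeholder columns `disease_union` / `disease_intersection` filled
#'   by [overlay()]. Sorted by mean depth, then target id.
#' @export
find_common_activation_targets <- function(network, source_ids, max_steps = 3,
                                           include_partial = FALSE) {
  stopifnot(inherits(network, "interaction_network"))
  if (length(source_ids) < 2) {
    abort_value("at least two query sources are required")
  }
  missing <- setdiff(source_ids, network$entities$id)
  if (length(missing)) abort_lookup("unknown source id '%s'", missing[1])

  reach <- reach_by_source(network, source_ids, max_steps)
  candidates <- setdiff(network$entities$id, source_ids)

  depth_mat <- vapply(reach, function(r) {
    vapply(candidates, function(t) {
      d <- r$activation[[t]]
      if (is.null(d)) NA_integer_ else as.integer(d)
    }, integer(1))
  }, integer(length(candidates)))
  depth_mat <- matrix(depth_mat, nrow = length(candidates),
                      dimnames = list(candidates, source_ids))
  status <- vapply(candidates, function(t) classify_from_reach(reach, t),
                   character(1))

  keep <- status == "common_activated"
  if (isTRUE(include_partial)) keep <- keep | status == "partial"
  candidates <- candidates[keep]
  depth_mat <- depth_mat[keep, , drop = FALSE]
  status <- status[keep]

  mean_depth <- round_half_up(rowMeans(depth_mat), 2)
  records <- data.frame(target = candidates, stringsAsFactors = FALSE)
  for (s in source_ids) records[[paste0("depth_", s)]] <- depth_mat[, s]
  records$mean_depth <- as.numeric(mean_depth)
  records$status <- unname(status)
  records$disease_union <- rep(NA, nrow(records))
  records$disease_intersection <- rep(NA, nrow(records))
  records <- records[lex_order(records$mean_depth, records$target), ,
                     drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Group convergence records by rounded mean depth
#'
#' @param records data frame from [find_common_activation_targets()].
#' @return Named list: key is the 2-decimal mean depth (e.g. `"2.33"`),
#'   value the lexicographically sorted target ids in that group; keys in
#'   ascending depth order.
#' @export
group_by_mean_depth <- function(records) {
  if (!nrow(records)) return(stats::setNames(list(), character(0)))
  key <- sprintf("%.2f", records$mean_depth)
  groups <- split(records$target, key)
  groups <- lapply(groups, lex_sort)
  groups[order(as.numeric(names(groups)))]
}

#' Write convergence records as TSV
#'
#' @param records data frame from [find_common_activation_targets()]
#'   (optionally after [overlay()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_convergence <- function(records, path) {
  out <- records
  out$mean_depth <- sprintf("%.2f", out$mean_depth)
  write_tsv_file(out, path)
}
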