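#' Disease annotation overlay
#'
#' Convergence targets are narrowed to those with known positive disease
#' association. Association is modelled as set membership in an
#' annotation table (entity -> disease term); terms are canonicalised by
#' trimming and case-folding. A target is a *union* gene when associated
#' with at least one disease of the panel and an *intersection* gene when
#' associated with all of them. The default panel is the three metabolic
#' diseases of the study design: diabetes/insulin resistance, obesity and
#' metabolic syndrome X.
#'
#' @name disease-overlay
NULL

canonical_disease <- function(x) tolower(trimws(x))

#' Default disease panel
#'
#' @return Character vector of canonical disease terms.
#' @export
default_disease_panel <- function() {
  c("diabetes/insulin resistance", "obesity", "metabolic syndrome x")
}

#' Load entity-disease annotations from TSV
#'
#' The file has columns `entity` and `disease`, one association per row;
#' disease terms are canonicalised case-insensitively after trimming and
#' duplicates collapse.
#'
#' @param path TSV file path.
#' @return Named list mapping entity id to a character vector (set) of
#'   canonical disease terms.
#' @export
load_annotations <- function(path) {
  tab <- read_tsv_file(path)
  for (col in c("entity", "disease")) {
    if (is.null(tab[[col]])) {
      abort_format("annotation table %s is missing required column '%s'",
                   path, col)
    }
  }
  if (!nrow(tab)) return(stats::setNames(list(), character(0)))
  lapply(split(canonical_disease(tab$disease), tab$entity), unique)
}

#' Flag convergence records with disease union/intersection membership
#'
#' @param records data frame from [find_common_activation_targets()].
#' @param annotations named list from [load_annotations()] (or built in
#'   code), entity id -> disease terms.
#' @param disease_panel non-empty character vector of disease terms
#'   (default [default_disease_panel()]).
#' @return `records` with `disease_union` and `disease_intersection`
#'   filled: union = associated with >= 1 panel disease, intersection =
#'   associated with all of them.
#' @export
overlay <- function(records, annotations,
                    disease_panel = default_disease_panel()) {
  if (!length(disease_panel)) abort_value("disease_panel must be non-empty")
  panel <- unique(canonical_disease(disease_panel))
  flags <- vapply(records$target, function(t) {
    ann <- canonical_disease(annotations[[t]] %||% character(0))
    hits <- sum(panel %in% ann)
    c(hits >= 1, hits == length(panel))
  }, logical(2))
  records$disease_union <- if (nrow(records)) flags[1, ] else logical(0)
  records$disease_intersection <- if (nrow(records)) flags[2, ] else logical(0)
  records
}

#' Keep disease-associated, concordantly activated targets
#'
#' @param records data frame after [overlay()].
#' @return The subset with `disease_union == TRUE` and status
#'   `common_activated`. Idempotent.
#' @export
filter_to_disease <- function(records) {
  out <- records[which(records$disease_union &
                         records$status == "common_activated"), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}
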