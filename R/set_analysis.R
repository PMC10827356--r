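#' Per-pattern overlap analysis within a definition
#'
#' For every substructure pattern of a definition, counts how many records of
#' a corpus it matches (`total_hits`) and how many records it alone matches
#' (`unique_hits`: matched by this pattern and by no other pattern of the
#' definition). A pattern with zero unique hits is flagged `extraneous`:
#' removing it leaves every record-level verdict unchanged on that corpus.
#' This is the analysis that showed one substructure of the EPA structures
#' list v4 to be redundant.
#'
#' @param records Structures in any form accepted by [pfas_classify()].
#' @param definition A `definition_spec` (or built-in id) with >= 1 pattern.
#' @return An `overlap_report` tibble: `pattern_id`, `total_hits`,
#'   `unique_hits`, `extraneous`, plus attributes `corpus_size`,
#'   `definition_id`, and `hit_records` (named list of record-id vectors).
#' @export
pattern_overlap <- function(records, definition) {
  definition <- as_definition_list(list(definition))[[1]]
  if (length(definition$patterns) == 0L) {
    stop("definition '", definition$id, "' has no patterns", call. = FALSE)
  }
  recs <- as_record_list(records)
  recs <- recs[vapply(recs, record_ok, logical(1))]
  hit_records <- lapply(definition$patterns, function(pat) {
    hits <- vapply(recs, function(rec) {
      length(match_pattern(rec, pat)) > 0L
    }, logical(1))
    names(recs)[hits]
  })
  pattern_ids <- names(definition$patterns)
  out <- purrr::map(pattern_ids, function(pid) {
    mine <- hit_records[[pid]]
    others <- unique(unlist(hit_records[setdiff(pattern_ids, pid)]))
    uniq <- setdiff(mine, others)
    tibble::tibble(
      pattern_id = pid,
      total_hits = length(mine),
      unique_hits = length(uniq),
      extraneous = length(uniq) == 0L
    )
  }) |> dplyr::bind_rows()
  attr(out, "corpus_size") <- length(recs)
  attr(out, "definition_id") <- definition$id
  attr(out, "hit_records") <- hit_records
  class(out) <- c("overlap_report", class(out))
  out
}

#' Set difference between two definitions over a classified corpus
#'
#' @param matrix A `pfas_matrix` from [classify_all()].
#' @param a,b Definition ids (columns of the matrix).
#' @return A list with record-id vectors `only_a`, `only_b`, `both` —
#'   disjoint sets whose union is every record positive under `a` or `b`.
#' @examples
#' m <- classify_all(c(TFE = "FC(F)=C(F)F", CF4 = "FC(F)(F)F"),
#'                   definitions = c("oecd2021", "pfasstruct_v5"))
#' definition_diff(m, "pfasstruct_v5", "oecd2021")
#' @export
definition_diff <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "pfas_matrix"))
  cols <- names(matrix$matrix)[-1]
  for (d in c(a, b)) {
    if (!d %in% cols) {
      stop("definition '", d, "' not in matrix (has: ",
           paste(cols, collapse = ", "), ")", call. = FALSE)
    }
  }
  ids <- matrix$matrix$record_id
  pa <- ids[matrix$matrix[[a]]]
  pb <- ids[matrix$matrix[[b]]]
  list(only_a = setdiff(pa, pb), only_b = setdiff(pb, pa),
       both = intersect(pa, pb))
}

#' Candidate structures missed by a base definition
#'
#' The gap-narrowing pipeline used to discover substructures missing from a
#' definition: keep records with at least `min_f` fluorines, drop the
#' trivially fluorinated ones (a lone CF3, or two CF3 groups not sharing a
#' carbon — see [is_trivially_fluorinated()]), and drop everything the base
#' definition already captures. What remains are highly fluorinated
#' structures the base definition misses.
#'
#' @param records Structures in any form accepted by [pfas_classify()].
#' @param base The base definition (`definition_spec` or built-in id).
#' @param min_f Minimum whole-record fluorine count (default 3).
#' @param policy Passed to [classify()].
#' @return Character vector of record ids, in input order.
#' @export
gap_candidates <- function(records, base, min_f = 3L,
                           policy = c("per_component", "whole_record")) {
  policy <- match.arg(policy)
  base <- as_definition_list(list(base))[[1]]
  recs <- as_record_list(records)
  recs <- recs[vapply(recs, record_ok, logical(1))]
  keep <- vapply(recs, function(rec) {
    formula_count(rec$formula, "F") >= min_f &&
      !is_trivially_fluorinated(rec) &&
      !classify(rec, base, policy = policy)$is_pfas
  }, logical(1))
  names(recs)[keep]
}
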