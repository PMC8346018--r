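#' Identifier of the dummy Pfam family
#'
#' Targets without any family assignment are grouped into one shared dummy
#' family: their mutual similarity is unknown, so the conservative choice
#' is to treat them as one family rather than many.
#'
#' @return the string `"PF_DUMMY"`.
#' @export
dummy_family <- function() "PF_DUMMY"

#' Assign Pfam families to targets
#'
#' Multi-family targets keep all their families; targets absent from the
#' mapping table are assigned to the dummy family.
#'
#' @param target_ids character vector of target identifiers.
#' @param mapping data.frame with columns `target_id`, `family_id`
#'   (repeated rows for multi-family targets).
#' @return named list mapping each target id to a sorted character vector
#'   of family ids (never empty).
#' @export
assign_families <- function(target_ids, mapping) {
  check_columns(mapping, c("target_id", "family_id"), "family mapping")
  target_ids <- unique(as.character(target_ids))
  mapped <- lapply(split(as.character(mapping$family_id),
                         as.character(mapping$target_id)),
                   function(f) sort(unique(f)))
  assignment <- stats::setNames(vector("list", length(target_ids)), target_ids)
  for (t in target_ids) {
    fams <- mapped[[t]]
    assignment[[t]] <- if (is.null(fams) || length(fams) == 0) dummy_family()
                       else fams
  }
  assignment
}

#' Family novelty scores from dated bioactivity records
#'
#' For each family, the novelty score is the fraction of its dated
#' bioactivity records published in or after the cutoff year (2010 by
#' default):
#' `score = n_after / (n_after + n_before)`.
#' A record contributes to every family of its target; undated records are
#' excluded from the counts. Families with no dated records cannot be
#' scored directly and receive the fallback score, the arithmetic mean of
#' the directly scored families.
#'
#' @param records data.frame of (merged) bioactivity records with columns
#'   `target_id` and `year` (NA allowed).
#' @param assignment named list from [assign_families()]; its targets
#'   define the family universe to score.
#' @param cutoff_year first year counted as "recent" (default 2010; a
#'   record dated exactly at the cutoff counts in the numerator).
#' @return data.frame `family_id`, `score`, `n_after`, `n_before`,
#'   `is_fallback`, with the fallback score as attribute
#'   `"fallback_score"`.
#' @export
novelty_table <- function(records, assignment, cutoff_year = 2010) {
  check_columns(records, c("target_id", "year"), "dated records")
  families <- sort(unique(unlist(assignment, use.names = FALSE)))
  n_after <- stats::setNames(integer(length(families)), families)
  n_before <- n_after
  dated <- records[!is.na(records$year), , drop = FALSE]
  for (i in seq_len(nrow(dated))) {
    fams <- assignment[[as.character(dated$target_id[i])]]
    if (is.null(fams)) next  # record for a target outside the assignment
    if (dated$year[i] >= cutoff_year) {
      n_after[fams] <- n_after[fams] + 1L
    } else {
      n_before[fams] <- n_before[fams] + 1L
    }
  }
  denom <- n_after + n_before
  score <- ifelse(denom > 0, n_after / denom, NA_real_)
  fallback <- mean(score, na.rm = TRUE)
  is_fallback <- is.na(score)
  score[is_fallback] <- fallback
  out <- data.frame(
    family_id = families,
    score = as.numeric(score),
    n_after = as.integer(n_after),
    n_before = as.integer(n_before),
    is_fallback = is_fallback,
    stringsAsFactors = FALSE
  )
  attr(out, "fallback_score") <- fallback
  out
}

#' Per-target novelty
#'
#' A target's novelty is the mean of its families' novelty scores
#' (single-family targets simply inherit the family score). Used for
#' per-library median-novelty reporting.
#'
#' @param target_ids character vector of targets.
#' @param assignment named list from [assign_families()].
#' @param table novelty table from [novelty_table()].
#' @return named numeric vector of novelty scores.
#' @export
target_novelty <- function(target_ids, assignment, table) {
  scores <- stats::setNames(table$score, table$family_id)
  vapply(as.character(target_ids), function(t) {
    fams <- assignment[[t]]
    if (is.null(fams)) stop("target without family assignment: ", t)
    mean(scores[fams])
  }, numeric(1))
}
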