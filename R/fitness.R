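#' Sum of a finite geometric progression
#'
#' `scale * (1 - r^count) / (1 - r)`: the sum of `count` terms of a
#' geometric progression with first term `scale` and common ratio `r`.
#' This is the saturating per-family contribution of the fitness function:
#' each additional compound hitting the same family adds `scale * r^k`,
#' strictly positive but strictly smaller than the previous increment.
#'
#' @param scale first term (here: the family novelty score).
#' @param r common ratio, `0 <= r < 1`.
#' @param count non-negative integer number of terms.
#' @return the partial sum (0 for `count = 0`).
#' @export
geometric_sum <- function(scale, r, count) {
  if (any(r >= 1) || any(r < 0)) stop("common ratio must be in [0, 1)")
  if (any(count < 0)) stop("count must be non-negative")
  scale * (1 - r^count) / (1 - r)
}

#' Per-family compound counts of a library
#'
#' For each Pfam family, counts the number of *distinct* library compounds
#' predicted to interact with at least one target of that family: a
#' compound hitting two targets of one family counts once for it, while a
#' target belonging to two families increments both.
#'
#' @param library character vector of compound ids.
#' @param predictions data.frame from [predict_targets()] (or the
#'   synthetic generator) with columns `compound_id` and list-column
#'   `targets`.
#' @param assignment named list from [assign_families()].
#' @param count_mode `"compounds"` (default: distinct compounds per
#'   family) or `"predictions"` (each predicted compound-target pair
#'   increments all families of its target).
#' @return named integer vector, one entry per family with nonzero count.
#' @export
family_counts <- function(library, predictions, assignment,
                          count_mode = c("compounds", "predictions")) {
  count_mode <- match.arg(count_mode)
  idx <- match(library, predictions$compound_id)
  if (anyNA(idx)) {
    stop("compound id(s) absent from predictions: ",
         paste(utils::head(library[is.na(idx)], 5), collapse = ", "))
  }
  fams <- lapply(idx, function(i) {
    targets <- predictions$targets[[i]]
    if (length(targets) == 0) return(character())
    f <- unlist(assignment[targets], use.names = FALSE)
    if (count_mode == "compounds") unique(f) else f
  })
  counts <- table(unlist(fams, use.names = FALSE))
  stats::setNames(as.integer(counts), names(counts))
}

#' Fitness of a compound library
#'
#' The fitness of an N-compound library is the novelty-weighted sum of
#' saturating per-family contributions, normalized by the library size:
#'
#' `fitness = ( sum_family novelty_f * (1 - r^count_f) / (1 - r) ) / N`
#'
#' where `count_f` is the number of library compounds predicted to
#' interact with family `f` and `r` (default 0.99) controls how quickly
#' repeat hits on one family saturate. Scores are comparable only between
#' libraries of equal N; the returned object therefore carries N.
#'
#' @inheritParams family_counts
#' @param novelty novelty table from [novelty_table()].
#' @param r common ratio of the geometric progression (default 0.99).
#' @return numeric fitness score with attribute `"N"` (library size).
#' @export
library_fitness <- function(library, predictions, assignment, novelty,
                            r = 0.99, count_mode = "compounds") {
  counts <- family_counts(library, predictions, assignment,
                          count_mode = count_mode)
  score <- 0
  if (length(counts) > 0) {
    nov <- stats::setNames(novelty$score, novelty$family_id)[names(counts)]
    if (anyNA(nov)) {
      stop("family missing from the novelty table: ",
           paste(names(counts)[is.na(nov)], collapse = ", "))
    }
    score <- sum(geometric_sum(nov, r, counts)) / length(library)
  }
  structure(score, N = length(library))
}

#' Compiled fitness evaluator
#'
#' Precomputes per-compound family index sets so a library's fitness can
#' be evaluated in microseconds inside the genetic algorithm. The returned
#' closure is equivalent to [library_fitness()].
#'
#' @inheritParams library_fitness
#' @return function taking a character vector of compound ids and
#'   returning the fitness score.
#' @export
fitness_evaluator <- function(predictions, assignment, novelty, r = 0.99,
                              count_mode = c("compounds", "predictions")) {
  count_mode <- match.arg(count_mode)
  fam_ids <- novelty$family_id
  nov <- novelty$score
  fam_index <- stats::setNames(seq_along(fam_ids), fam_ids)
  compound_fams <- lapply(seq_len(nrow(predictions)), function(i) {
    targets <- predictions$targets[[i]]
    if (length(targets) == 0) return(integer())
    f <- unlist(assignment[targets], use.names = FALSE)
    if (count_mode == "compounds") f <- unique(f)
    idx <- fam_index[f]
    if (anyNA(idx)) stop("family missing from the novelty table")
    as.integer(idx)
  })
  names(compound_fams) <- predictions$compound_id
  nfam <- length(fam_ids)
  function(library) {
    fams <- compound_fams[library]
    if (anyNA(names(fams)) || length(fams) != length(library)) {
      stop("compound id(s) absent from predictions")
    }
    counts <- tabulate(unlist(fams, use.names = FALSE), nbins = nfam)
    hit <- counts > 0L
    if (!any(hit)) return(0)
    sum(nov[hit] * (1 - r^counts[hit])) / ((1 - r) * length(library))
  }
}
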