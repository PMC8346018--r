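#' Tanimoto similarity between two binary fingerprints
#'
#' `|a AND b| / |a OR b|` over fingerprint bits; defined as 0 when both
#' vectors are all-zero.
#'
#' @param a,b binary (0/1 or logical) vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0) return(0)
  sum(a & b) / union
}

#' Tanimoto similarity matrix between two fingerprint sets
#'
#' @param A,B binary integer matrices with one fingerprint per row and the
#'   same number of columns.
#' @return `nrow(A)` x `nrow(B)` similarity matrix; pairs of all-zero
#'   fingerprints score 0.
#' @export
tanimoto_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch")
  common <- tcrossprod(A, B)
  union <- outer(rowSums(A), rowSums(B), "+") - common
  sim <- ifelse(union == 0, 0, common / union)
  dimnames(sim) <- list(rownames(A), rownames(B))
  sim
}

#' Predict protein targets by 2D similarity
#'
#' For each query fingerprint, every reference entry with Tanimoto
#' similarity at or above the threshold contributes its active targets;
#' the prediction is the union over contributing entries. Queries whose
#' maximum similarity falls below the threshold receive no targets and are
#' flagged as dark chemical matter.
#'
#' @param query_fps binary fingerprint matrix of the query compounds (row
#'   names are compound ids).
#' @param ref_fps binary fingerprint matrix of the reference entries.
#' @param ref_targets list of character vectors, parallel to the rows of
#'   `ref_fps`: the active targets of each reference entry.
#' @param threshold minimum Tanimoto similarity for a reference entry to
#'   contribute targets (default 0.5).
#' @param chunk_size number of query rows scored per block (memory knob).
#' @return data.frame with one row per query: `compound_id`,
#'   `max_similarity`, `n_targets`, list-column `targets` (sorted unique
#'   target ids) and `dark` (no predicted targets).
#' @export
predict_targets <- function(query_fps, ref_fps, ref_targets,
                            threshold = 0.5, chunk_size = 1000L) {
  if (nrow(ref_fps) == 0) stop("reference set is empty")
  if (length(ref_targets) != nrow(ref_fps)) {
    stop("ref_targets must have one element per reference fingerprint")
  }
  ids <- rownames(query_fps)
  if (is.null(ids)) ids <- paste0("Q", seq_len(nrow(query_fps)))
  max_sim <- numeric(nrow(query_fps))
  targets <- vector("list", nrow(query_fps))
  starts <- seq.int(1L, nrow(query_fps), by = chunk_size)
  for (s in starts) {
    rows <- s:min(s + chunk_size - 1L, nrow(query_fps))
    sim <- tanimoto_matrix(query_fps[rows, , drop = FALSE], ref_fps)
    max_sim[rows] <- apply(sim, 1L, max)
    hit <- sim >= threshold
    targets[rows] <- lapply(seq_along(rows), function(i) {
      hits <- which(hit[i, ])
      if (length(hits) == 0) character() else
        sort(unique(unlist(ref_targets[hits], use.names = FALSE)))
    })
  }
  data.frame(
    compound_id = ids,
    max_similarity = max_sim,
    n_targets = lengths(targets),
    targets = I(targets),
    dark = lengths(targets) == 0L,
    stringsAsFactors = FALSE
  )
}

#' Assemble the pool of candidate compounds (PCC)
#'
#' The PCC is the subset of filtered query compounds with at least one
#' predicted target; dark-matter compounds are reported separately (they
#' remain eligible for baseline libraries, but not for optimization).
#'
#' @param predictions data.frame from [predict_targets()].
#' @return list with `pcc` (data.frame `compound_id`, `n_targets`),
#'   `dark_ids` (character vector) and `n_bioactivities` (total number of
#'   predicted compound-target pairs in the PCC).
#' @export
build_pcc <- function(predictions) {
  check_columns(predictions, c("compound_id", "n_targets"), "predictions")
  in_pcc <- predictions$n_targets > 0L
  pcc <- predictions[in_pcc, c("compound_id", "n_targets"), drop = FALSE]
  rownames(pcc) <- NULL
  list(pcc = pcc,
       dark_ids = predictions$compound_id[!in_pcc],
       n_bioactivities = sum(pcc$n_targets))
}
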