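#' Murcko scaffolds of a set of structures
#'
#' A molecule's Murcko scaffold is its ring systems plus the linkers
#' connecting them, with all substituents removed; it is the structural
#' diversity unit used when counting scaffold coverage. Acyclic molecules
#' have the empty scaffold (counted as one scaffold class).
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers.
#' @return character vector of scaffold SMILES (empty string for acyclic
#'   molecules), named by id.
#' @export
murcko_scaffolds <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    paste0("S", seq_along(smiles))
  out <- run_chemtool("murcko", ids, smiles)
  if (any(out$ok == "0")) {
    stop("unparseable SMILES for: ",
         paste(out$id[out$ok == "0"], collapse = ", "))
  }
  stats::setNames(ifelse(is.na(out$murcko), "", out$murcko), out$id)
}

#' Taylor-Butina exclusion-sphere clustering
#'
#' Leader-style unsupervised clustering at a fixed similarity threshold:
#' neighbor lists are all pairs with Tanimoto similarity at or above the
#' threshold; the unassigned compound with the most unassigned neighbors
#' becomes the next cluster centroid (ties broken by input order) and
#' claims its unassigned neighbors; compounds left without any unassigned
#' neighbors -- including "false singletons" whose neighbors were all
#' claimed by earlier clusters -- become singletons.
#'
#' @param fps binary fingerprint matrix (rows = compounds; row names used
#'   as compound ids).
#' @param threshold minimum Tanimoto similarity for two compounds to be
#'   neighbors (default 0.4).
#' @return data.frame `compound_id`, `cluster_id` (dense, from 0, in
#'   cluster creation order), `is_centroid`, `is_singleton`, in input
#'   order.
#' @export
taylor_butina <- function(fps, threshold = 0.4) {
  n <- nrow(fps)
  stopifnot(n >= 1)
  ids <- rownames(fps)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  sim <- tanimoto_matrix(fps, fps)
  neighbors <- lapply(seq_len(n), function(i) {
    nb <- which(sim[i, ] >= threshold)
    nb[nb != i]
  })
  cluster <- rep(NA_integer_, n)
  centroid <- rep(FALSE, n)
  next_id <- 0L
  repeat {
    unassigned <- which(is.na(cluster))
    if (length(unassigned) == 0) break
    n_free <- vapply(unassigned, function(i) {
      sum(is.na(cluster[neighbors[[i]]]))
    }, integer(1))
    if (max(n_free) == 0L) {
      # every remaining compound is a (possibly false) singleton
      for (i in unassigned) {
        cluster[i] <- next_id
        centroid[i] <- TRUE
        next_id <- next_id + 1L
      }
      break
    }
    lead <- unassigned[which.max(n_free)]  # ties -> input order
    members <- neighbors[[lead]][is.na(cluster[neighbors[[lead]]])]
    cluster[c(lead, members)] <- next_id
    centroid[lead] <- TRUE
    next_id <- next_id + 1L
  }
  counts <- table(cluster)
  data.frame(
    compound_id = ids,
    cluster_id = cluster,
    is_centroid = centroid,
    is_singleton = as.integer(counts[as.character(cluster)]) == 1L,
    stringsAsFactors = FALSE
  )
}

#' Characterization report of a compound library
#'
#' Computes the descriptor panel used to compare libraries: predicted
#' target/family/bioactivity counts, median target novelty, scaffold and
#' cluster coverage, and (when profiles are supplied) property summaries.
#'
#' @param library character vector of compound ids.
#' @param predictions predictions data.frame covering the library.
#' @param assignment named list from [assign_families()].
#' @param novelty novelty table from [novelty_table()].
#' @param clusters optional data.frame from [taylor_butina()] covering the
#'   library compounds.
#' @param scaffolds optional named character vector from
#'   [murcko_scaffolds()].
#' @param profiles optional data.frame from [property_profile()] (for QED
#'   and logP summaries).
#' @param r common ratio used for the fitness score.
#' @return object of class `library_report`: a list with `N`, `fitness`,
#'   `n_targets`, `n_families`, `n_bioactivities`, `median_novelty`,
#'   `n_scaffolds`, `n_clusters_represented` and `properties`.
#' @export
library_report <- function(library, predictions, assignment, novelty,
                           clusters = NULL, scaffolds = NULL,
                           profiles = NULL, r = 0.99) {
  N <- length(library)
  if (N == 0) {
    return(structure(list(N = 0L, fitness = 0, n_targets = 0L,
                          n_families = 0L, n_bioactivities = 0L,
                          median_novelty = NA_real_, n_scaffolds = 0L,
                          n_clusters_represented = 0L, properties = NULL),
                     class = "library_report"))
  }
  idx <- match(library, predictions$compound_id)
  if (anyNA(idx)) stop("library compound(s) absent from predictions")
  target_sets <- predictions$targets[idx]
  targets <- sort(unique(unlist(target_sets, use.names = FALSE)))
  families <- sort(unique(unlist(assignment[targets], use.names = FALSE)))
  med_nov <- if (length(targets) == 0) NA_real_ else
    stats::median(target_novelty(targets, assignment, novelty))
  n_scaffolds <- if (is.null(scaffolds)) NA_integer_ else
    length(unique(scaffolds[library]))
  n_clusters <- if (is.null(clusters)) NA_integer_ else
    length(unique(clusters$cluster_id[match(library, clusters$compound_id)]))
  properties <- if (!is.null(profiles)) {
    p <- profiles[match(library, profiles$id), , drop = FALSE]
    list(median_qed = stats::median(p$qed),
         median_logp = stats::median(p$logp),
         median_mw = stats::median(p$mw),
         median_heavy_atoms = stats::median(p$heavy_atoms))
  }
  structure(list(
    N = N,
    fitness = as.numeric(library_fitness(library, predictions, assignment,
                                         novelty, r = r)),
    n_targets = length(targets),
    n_families = length(families),
    n_bioactivities = sum(lengths(target_sets)),
    median_novelty = med_nov,
    n_scaffolds = n_scaffolds,
    n_clusters_represented = n_clusters,
    properties = properties
  ), class = "library_report")
}

#' @export
print.library_report <- function(x, ...) {
  cat("Compound library report\n")
  cat(sprintf("  compounds (N):          %d\n", x$N))
  cat(sprintf("  fitness (r-weighted):   %.4f\n", x$fitness))
  cat(sprintf("  predicted targets:      %d\n", x$n_targets))
  cat(sprintf("  Pfam families:          %d\n", x$n_families))
  cat(sprintf("  predicted bioactivities:%d\n", x$n_bioactivities))
  cat(sprintf("  median target novelty:  %s\n",
              formatC(x$median_novelty, digits = 3, format = "f")))
  if (!is.na(x$n_scaffolds)) {
    cat(sprintf("  Murcko scaffolds:       %d\n", x$n_scaffolds))
  }
  if (!is.na(x$n_clusters_represented)) {
    cat(sprintf("  clusters represented:   %d\n", x$n_clusters_represented))
  }
  if (!is.null(x$properties)) {
    cat(sprintf("  median QED / logP:      %.3f / %.2f\n",
                x$properties$median_qed, x$properties$median_logp))
  }
  invisible(x)
}
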