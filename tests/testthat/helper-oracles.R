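# shared fixtures and independent reference implementations used to
# cross-check the package's vectorized/optimized code paths

random_fp_matrix <- function(n, bits = 2048L, on = 30L, seed = NULL,
                             ids = sprintf("Q%03d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0L, n, bits, dimnames = list(ids, NULL))
  for (i in seq_len(n)) m[i, sample.int(bits, on)] <- 1L
  m
}

# builds a fingerprint pair with exact Tanimoto k_and / k_or
fp_pair_with_similarity <- function(k_and, k_or, bits = 2048L) {
  stopifnot(k_or <= bits, k_and <= k_or)
  extra <- k_or - k_and
  a_extra <- floor(extra / 2)
  a <- b <- integer(bits)
  a[seq_len(k_and + a_extra)] <- 1L
  b_bits <- seq_len(k_and)
  if (extra > a_extra) b_bits <- c(b_bits, seq.int(k_and + a_extra + 1L, k_or))
  b[b_bits] <- 1L
  list(a = a, b = b)
}

# term-by-term geometric summation; deliberately loop-based
oracle_fitness <- function(library, predictions, assignment, novelty,
                           r = 0.99) {
  fam_count <- list()
  for (cid in library) {
    targets <- predictions$targets[[match(cid, predictions$compound_id)]]
    fams <- unique(unlist(assignment[targets], use.names = FALSE))
    for (f in fams) {
      fam_count[[f]] <- (if (is.null(fam_count[[f]])) 0L else fam_count[[f]]) + 1L
    }
  }
  total <- 0
  for (f in names(fam_count)) {
    nov <- novelty$score[novelty$family_id == f]
    s <- 0
    for (k in seq_len(fam_count[[f]])) s <- s + nov * r^(k - 1)
    total <- total + s
  }
  total / length(library)
}

# exhaustive all-pairs prediction
oracle_predict <- function(query_fps, ref_fps, ref_targets, threshold = 0.5) {
  out <- vector("list", nrow(query_fps))
  max_sim <- numeric(nrow(query_fps))
  for (i in seq_len(nrow(query_fps))) {
    targets <- character()
    best <- 0
    for (j in seq_len(nrow(ref_fps))) {
      s <- tanimoto(query_fps[i, ], ref_fps[j, ])
      best <- max(best, s)
      if (s >= threshold) targets <- c(targets, ref_targets[[j]])
    }
    out[[i]] <- sort(unique(targets))
    max_sim[i] <- best
  }
  list(targets = out, max_similarity = max_sim)
}

# straightforward leader-algorithm clustering on a precomputed
# neighbor-list, following the classic description step by step
oracle_butina <- function(fps, threshold = 0.4) {
  n <- nrow(fps)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    nb[[i]] <- setdiff(which(vapply(seq_len(n), function(j)
      tanimoto(fps[i, ], fps[j, ]), numeric(1)) >= threshold), i)
  }
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  repeat {
    free <- which(is.na(cluster))
    if (!length(free)) break
    sizes <- vapply(free, function(i) sum(is.na(cluster[nb[[i]]])), integer(1))
    if (max(sizes) == 0L) {
      for (i in free) { cluster[i] <- cid; cid <- cid + 1L }
      break
    }
    lead <- free[which.max(sizes)]
    members <- nb[[lead]][is.na(cluster[nb[[lead]]])]
    cluster[c(lead, members)] <- cid
    cid <- cid + 1L
  }
  cluster
}

# small handmade annotation instance used across fitness/GA tests
tiny_annotation <- function() {
  predictions <- data.frame(
    compound_id = c("c1", "c2", "c3", "c4", "c5"),
    max_similarity = c(0.9, 0.8, 0.7, 0.6, 0.2),
    n_targets = c(2L, 1L, 2L, 1L, 0L),
    targets = I(list(c("tA", "tB"), "tA", c("tB", "tC"), "tC", character())),
    dark = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  family_map <- data.frame(
    target_id = c("tA", "tB", "tB"),
    family_id = c("F1", "F1", "F2"),
    stringsAsFactors = FALSE
  )  # tC unmapped -> dummy
  assignment <- assign_families(c("tA", "tB", "tC"), family_map)
  records <- data.frame(
    target_id = c("tA", "tA", "tA", "tA", "tB", "tB", "tC"),
    year = c(2015L, 2016L, 2017L, 2005L, 2012L, 2008L, NA_integer_),
    stringsAsFactors = FALSE
  )
  novelty <- novelty_table(records, assignment)
  list(predictions = predictions, assignment = assignment,
       novelty = novelty, records = records)
}
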