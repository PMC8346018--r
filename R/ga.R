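#' Genetic algorithm configuration
#'
#' @param N library size (compounds per individual); at least 2.
#' @param M population size (individuals per generation); at least 6, so
#'   that an even parent set of two or more can be formed.
#' @param generations number of generations to evolve (default 300).
#' @param mutation_rate fraction of each child's compounds replaced by
#'   random pool compounds (default 0.10); the realized number of
#'   replacements is `floor(mutation_rate * N)`.
#' @param parent_fraction fraction of the population carried over as
#'   parents (default 1/3; the realized parent count is the largest even
#'   number at or below `parent_fraction * M`).
#' @param r common ratio of the fitness function (default 0.99).
#' @param seed optional integer seed; a single seeded RNG stream governs
#'   initialization, parent pairing, repair and mutation.
#' @return a `ga_config` list.
#' @export
ga_config <- function(N, M, generations = 300L, mutation_rate = 0.10,
                      parent_fraction = 1 / 3, r = 0.99, seed = NULL) {
  stopifnot(N >= 2, M >= 3, mutation_rate >= 0, mutation_rate <= 1,
            generations >= 1, parent_fraction > 0, parent_fraction < 1)
  structure(list(N = as.integer(N), M = as.integer(M),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 parent_fraction = parent_fraction, r = r, seed = seed),
            class = "ga_config")
}

# draw k elements from x without the sample() scalar surprise
sample_vec <- function(x, k) x[sample.int(length(x), k)]

#' Initialize a random population
#'
#' Each individual is an ordered sequence of N distinct compound ids
#' sampled uniformly without replacement from the candidate pool.
#'
#' @param pool character vector of candidate compound ids.
#' @param cfg a [ga_config()].
#' @return list of M individuals (character vectors of length N).
#' @export
init_population <- function(pool, cfg) {
  if (length(pool) < cfg$N) {
    stop("pool smaller than the requested library size")
  }
  replicate(cfg$M, sample_vec(pool, cfg$N), simplify = FALSE)
}

#' Number of parents retained each generation
#'
#' The largest even number at or below `parent_fraction * M`, and never
#' below 2; even so parents can be paired without remainder.
#'
#' @param M population size.
#' @param parent_fraction fraction of M selected as parents.
#' @return even integer parent count.
#' @export
parent_count <- function(M, parent_fraction = 1 / 3) {
  p <- floor(M * parent_fraction)
  p <- p - (p %% 2)
  if (p < 2) {
    stop("population too small to form an even parent set (need M >= ",
         ceiling(2 / parent_fraction), ")")
  }
  as.integer(p)
}

#' Select the fittest individuals as parents
#'
#' @param population list of individuals.
#' @param fitness numeric vector of their fitness scores.
#' @param P number of parents ([parent_count()]).
#' @return integer indices of the P fittest individuals, ties broken by
#'   earlier position in the population.
#' @export
select_parents <- function(population, fitness, P) {
  stopifnot(length(population) == length(fitness), P <= length(population))
  order(-fitness, seq_along(fitness))[seq_len(P)]
}

#' Single-point midpoint crossover producing four children
#'
#' Both parents are split at position `floor(N/2)`. With halves
#' `A = A1|A2` and `B = B1|B2`, the four children are `A1+B2`, `B1+A2`,
#' `A1+B1'` and `A2+B2'` (for odd N the second halves are one longer than
#' the first, and `B1'`/`B2'` are the complementary-length prefix/suffix
#' of B so every child has exactly N slots). Children may contain
#' duplicate compounds at this stage and must be passed through
#' [repair_child()].
#'
#' @param A,B parent individuals (character vectors of equal length N).
#' @return list of four children, each of length N.
#' @export
crossover_pair <- function(A, B) {
  N <- length(A)
  stopifnot(length(B) == N, N >= 2)
  h <- N %/% 2
  list(c(A[seq_len(h)], B[seq.int(h + 1L, N)]),
       c(B[seq_len(h)], A[seq.int(h + 1L, N)]),
       c(A[seq_len(h)], B[seq_len(N - h)]),
       c(A[seq.int(h + 1L, N)], B[seq.int(h + 1L, 2L * h)]))
}

#' Replace duplicate compounds in a child
#'
#' When a child inherits the same compound from both parents, every later
#' occurrence is replaced by a uniform draw from the pool compounds not
#' already present in the child.
#'
#' @param child character vector of length N, possibly with duplicates.
#' @param pool character vector of candidate compound ids.
#' @return valid child: length N, all ids distinct.
#' @export
repair_child <- function(child, pool) {
  dup <- duplicated(child)
  n_dup <- sum(dup)
  if (n_dup == 0) return(child)
  avail <- setdiff(pool, child)
  if (length(avail) < n_dup) {
    stop("pool too small to repair duplicate compounds")
  }
  child[dup] <- sample_vec(avail, n_dup)
  child
}

#' Mutate a child
#'
#' Replaces `floor(rate * N)` uniformly chosen positions with pool
#' compounds not already present in the child (so the individual stays
#' duplicate-free).
#'
#' @param child valid individual (length N, distinct ids).
#' @param pool candidate pool ids.
#' @param rate mutation rate in \[0, 1\].
#' @return mutated child, still of length N with distinct ids.
#' @export
mutate_child <- function(child, pool, rate) {
  k <- floor(rate * length(child))
  if (k == 0) return(child)
  pos <- sample.int(length(child), k)
  avail <- setdiff(pool, child)
  if (length(avail) < k) stop("pool too small to mutate")
  child[pos] <- sample_vec(avail, k)
  child
}

#' Evolve an optimal compound library
#'
#' Elitist generational GA over N-compound subsets of the candidate pool.
#' Each generation the P fittest individuals are carried over unchanged as
#' parents; the remaining `M - P` slots are filled with children produced
#' by randomly paired parents (four children per pair via
#' [crossover_pair()]; pairings are redrawn until enough children exist,
#' surplus children are discarded in generation order). Every child is
#' duplicate-repaired and then mutated. Because parents are carried over
#' unchanged, the best fitness per generation is non-decreasing.
#'
#' @param pool character vector of candidate compound ids (the PCC).
#' @param predictions predictions data.frame covering the pool.
#' @param assignment named list from [assign_families()].
#' @param novelty novelty table from [novelty_table()].
#' @param cfg a [ga_config()].
#' @return list with `best` (character vector of N compound ids),
#'   `best_fitness`, `trajectory` (data.frame `generation`,
#'   `best_fitness`, `mean_fitness`; generation 0 is the initial
#'   population) and `config`.
#' @export
evolve <- function(pool, predictions, assignment, novelty, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  P <- parent_count(cfg$M, cfg$parent_fraction)
  evaluate <- fitness_evaluator(predictions, assignment, novelty, r = cfg$r)
  population <- init_population(pool, cfg)
  fitness <- vapply(population, evaluate, numeric(1))
  trajectory <- data.frame(generation = 0L,
                           best_fitness = max(fitness),
                           mean_fitness = mean(fitness))
  for (gen in seq_len(cfg$generations)) {
    parent_idx <- select_parents(population, fitness, P)
    parents <- population[parent_idx]
    parent_fit <- fitness[parent_idx]
    n_children <- cfg$M - P
    children <- vector("list", 0L)
    while (length(children) < n_children) {
      pairing <- sample.int(P, P)  # uniform random pairing w/o replacement
      for (p in seq_len(P %/% 2)) {
        if (length(children) >= n_children) break
        brood <- crossover_pair(parents[[pairing[2L * p - 1L]]],
                                parents[[pairing[2L * p]]])
        brood <- lapply(brood, function(ch) {
          mutate_child(repair_child(ch, pool), pool, cfg$mutation_rate)
        })
        take <- min(length(brood), n_children - length(children))
        children <- c(children, brood[seq_len(take)])
      }
    }
    population <- c(parents, children)
    fitness <- c(parent_fit, vapply(children, evaluate, numeric(1)))
    trajectory <- rbind(trajectory,
                        data.frame(generation = gen,
                                   best_fitness = max(fitness),
                                   mean_fitness = mean(fitness)))
  }
  best_idx <- which.max(fitness)
  list(best = population[[best_idx]],
       best_fitness = fitness[best_idx],
       trajectory = trajectory,
       config = cfg)
}

#' Baseline random library
#'
#' Draws `max(1, floor(0.1 * N))` uniformly random N-compound subsets from
#' the property-filtered pool (dark-matter compounds included) and returns
#' the fittest draw. This is the unoptimized comparison point for the
#' genetic algorithm.
#'
#' @param filtered_pool character vector of compound ids that passed the
#'   property filters (regardless of PCC membership).
#' @param predictions predictions data.frame covering the pool (dark
#'   compounds carry empty target sets).
#' @param assignment named list from [assign_families()].
#' @param novelty novelty table from [novelty_table()].
#' @param N library size.
#' @param seed optional integer seed.
#' @param draws number of random subsets; defaults to the 10%-of-N rule.
#' @return list with `best` (compound ids), `best_fitness`, `draws` and
#'   `fitnesses` (one score per draw).
#' @export
baseline_library <- function(filtered_pool, predictions, assignment,
                             novelty, N, seed = NULL, draws = NULL) {
  if (length(filtered_pool) < N) stop("pool smaller than library size")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(draws)) draws <- max(1L, floor(0.1 * N))
  evaluate <- fitness_evaluator(predictions, assignment, novelty)
  libraries <- replicate(draws, sample_vec(filtered_pool, N),
                         simplify = FALSE)
  fitnesses <- vapply(libraries, evaluate, numeric(1))
  best <- which.max(fitnesses)
  list(best = libraries[[best]], best_fitness = fitnesses[best],
       draws = draws, fitnesses = fitnesses)
}
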