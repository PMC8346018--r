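test_that("population initialization yields valid, seed-reproducible individuals", {
  pool <- sprintf("c%03d", 1:100)
  cfg <- ga_config(N = 10, M = 5, seed = 4)
  set.seed(cfg$seed)
  pop <- init_population(pool, cfg)
  expect_length(pop, 5L)
  for (ind in pop) {
    expect_length(ind, 10L)
    expect_false(anyDuplicated(ind) > 0)
    expect_true(all(ind %in% pool))
  }
  set.seed(cfg$seed)
  expect_identical(init_population(pool, cfg), pop)
  expect_error(init_population(pool[1:5], cfg), "smaller")
  # forced case: pool size equals N
  forced <- init_population(pool[1:10], cfg)
  expect_true(all(vapply(forced, function(x)
    setequal(x, pool[1:10]), logical(1))))
})

test_that("parent selection takes the largest even third, ties to earlier index", {
  expect_equal(parent_count(30), 10L)
  expect_equal(parent_count(9), 2L)    # floor(9/3)=3 -> largest even is 2
  expect_equal(parent_count(50), 16L)
  expect_error(parent_count(5), "even parent set")
  pop <- as.list(letters[1:9])
  fit <- c(5, 9, 7, 9, 3, 1, 2, 8, 4)
  idx <- select_parents(pop, fit, 4)
  expect_equal(idx, c(2L, 4L, 8L, 3L))  # tie at 9 -> earlier index first
})

test_that("midpoint crossover produces the four declared children", {
  kids <- crossover_pair(c("1", "2", "3", "4"), c("5", "6", "7", "8"))
  expect_equal(kids, list(c("1", "2", "7", "8"), c("5", "6", "3", "4"),
                          c("1", "2", "5", "6"), c("3", "4", "7", "8")))
  # identical parents: every child duplicates half its slots pre-repair
  same <- crossover_pair(c("1", "2", "3", "4"), c("1", "2", "3", "4"))
  expect_equal(sum(duplicated(same[[3]])), 2L)
  # odd length: all children still have N slots
  for (child in crossover_pair(as.character(1:5), as.character(6:10))) {
    expect_length(child, 5L)
  }
})

test_that("repair replaces later duplicate occurrences from outside the child", {
  pool <- as.character(1:9)
  set.seed(8)
  fixed <- repair_child(c("1", "2", "2", "3"), pool)
  expect_equal(fixed[1:2], c("1", "2"))
  expect_equal(fixed[4], "3")
  expect_false(fixed[3] %in% c("1", "2", "3"))
  expect_false(anyDuplicated(fixed) > 0)
  clean <- c("4", "5", "6")
  expect_identical(repair_child(clean, pool), clean)
  expect_error(repair_child(c("1", "1", "2", "3"), c("1", "2", "3")),
               "too small")
  set.seed(11); a <- repair_child(c("1", "1", "2", "2"), pool)
  set.seed(11); b <- repair_child(c("1", "1", "2", "2"), pool)
  expect_identical(a, b)
})

test_that("mutation replaces floor(rate*N) positions and keeps distinctness", {
  pool <- sprintf("c%02d", 1:50)
  child <- pool[1:10]
  set.seed(13)
  mutated <- mutate_child(child, pool, 0.10)
  expect_equal(sum(mutated != child), 1L)   # floor(0.1 * 10) = 1
  expect_false(anyDuplicated(mutated) > 0)
  expect_identical(mutate_child(child, pool, 0), child)
  set.seed(14)
  heavy <- mutate_child(child, pool, 0.55)  # floor(5.5) = 5 replacements
  expect_equal(sum(heavy != child), 5L)
  expect_true(all(heavy %in% pool))
})

test_that("evolution is elitist, size-conserving, deterministic and effective", {
  fx <- synth_annotation_pool(fixture_config(
    n_compounds = 120, n_targets = 30, n_families = 12,
    dark_fraction = 0.3, seed = 23))
  pcc <- fx$pool$compound_id[fx$pool$in_pcc]
  cfg <- ga_config(N = 12, M = 9, generations = 40, seed = 99)
  run1 <- evolve(pcc, fx$predictions, fx$assignment, fx$novelty, cfg)
  run2 <- evolve(pcc, fx$predictions, fx$assignment, fx$novelty, cfg)
  expect_identical(run1$best, run2$best)
  expect_identical(run1$trajectory, run2$trajectory)
  expect_false(is.unsorted(run1$trajectory$best_fitness))
  expect_equal(nrow(run1$trajectory), 41L)
  expect_length(run1$best, 12L)
  expect_false(anyDuplicated(run1$best) > 0)
  expect_true(all(run1$best %in% pcc))
  # the evolved library beats the typical random draw
  ev <- fitness_evaluator(fx$predictions, fx$assignment, fx$novelty)
  set.seed(1)
  random_scores <- replicate(50, ev(sample(pcc, 12)))
  expect_true(run1$best_fitness > max(random_scores))
})

test_that("the GA recovers the exhaustive optimum on a small instance", {
  fx <- synth_annotation_pool(fixture_config(
    n_compounds = 12, n_targets = 20, n_families = 8,
    dark_fraction = 0.15, promiscuity = 2.5, seed = 42))
  pool <- fx$pool$compound_id
  ev <- fitness_evaluator(fx$predictions, fx$assignment, fx$novelty)
  optimum <- max(apply(utils::combn(pool, 4), 2, ev))
  hits <- 0L
  for (s in 1:5) {
    run <- evolve(pool, fx$predictions, fx$assignment, fx$novelty,
                  ga_config(N = 4, M = 9, generations = 200, seed = 500 + s))
    hits <- hits + (abs(run$best_fitness - optimum) < 1e-12)
  }
  expect_equal(hits, 5L)
})

test_that("baseline libraries follow the 10%-of-N rule and return the argmax", {
  fx <- synth_annotation_pool(fixture_config(
    n_compounds = 400, n_targets = 40, n_families = 15, seed = 31))
  base <- baseline_library(fx$pool$compound_id, fx$predictions,
                           fx$assignment, fx$novelty, N = 50, seed = 2)
  expect_equal(base$draws, 5L)                    # floor(0.1 * 50)
  expect_length(base$fitnesses, 5L)
  expect_equal(base$best_fitness, max(base$fitnesses))
  small <- baseline_library(fx$pool$compound_id, fx$predictions,
                            fx$assignment, fx$novelty, N = 5, seed = 2)
  expect_equal(small$draws, 1L)                   # floor with minimum of one
  big_n <- baseline_library(fx$pool$compound_id, fx$predictions,
                            fx$assignment, fx$novelty, N = 50, seed = 2,
                            draws = 12)
  expect_equal(length(big_n$fitnesses), 12L)
})
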