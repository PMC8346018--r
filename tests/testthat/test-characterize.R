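test_that("Murcko scaffolds strip substituents and classify acyclics as empty", {
  sc <- murcko_scaffolds(c(toluene = "Cc1ccccc1",
                           o_cresol = "Cc1ccccc1O",
                           p_cresol = "Cc1ccc(O)cc1",
                           benzene = "c1ccccc1",
                           hexane = "CCCCCC"))
  expect_equal(unname(sc["toluene"]), "c1ccccc1")
  expect_equal(sc[["o_cresol"]], sc[["p_cresol"]])   # both reduce to benzene
  expect_equal(unname(sc["benzene"]), "c1ccccc1")    # fixed point
  expect_equal(unname(sc["hexane"]), "")
  expect_equal(length(unique(sc)), 2L)
})

test_that("Taylor-Butina clustering matches the leader-algorithm reference", {
  # two identical compounds form one cluster of two
  fps <- random_fp_matrix(1, on = 30, seed = 41)
  pair <- rbind(a = fps[1, ], b = fps[1, ])
  cl <- taylor_butina(pair)
  expect_equal(cl$cluster_id, c(0L, 0L))
  expect_equal(cl$is_centroid, c(TRUE, FALSE))
  expect_false(any(cl$is_singleton))

  # mutually dissimilar compounds are all singletons
  apart <- random_fp_matrix(6, on = 12, seed = 43)
  expect_true(all(tanimoto_matrix(apart, apart)[lower.tri(diag(6))] < 0.4))
  cl <- taylor_butina(apart)
  expect_equal(sort(cl$cluster_id), 0:5)
  expect_true(all(cl$is_singleton))

  # structured toy sets against the brute-force oracle (including
  # false singletons created when a leader claims shared neighbors)
  for (seed in c(51, 52, 53)) {
    set.seed(seed)
    base <- random_fp_matrix(4, on = 40, seed = seed)
    fps <- matrix(0L, 18, 2048)
    for (i in 1:18) {
      proto <- base[((i - 1) %% 4) + 1, ]
      flip <- sample(which(proto == 1L), sample(0:12, 1))
      row <- proto; row[flip] <- 0L
      row[sample(which(proto == 0L), sample(0:6, 1))] <- 1L
      fps[i, ] <- row
    }
    rownames(fps) <- sprintf("m%02d", 1:18)
    got <- taylor_butina(fps, threshold = 0.4)
    want <- oracle_butina(fps, threshold = 0.4)
    expect_equal(got$cluster_id, want)
    # partition + centroid property
    expect_false(anyNA(got$cluster_id))
    expect_equal(sort(unique(got$cluster_id)),
                 seq.int(0L, max(got$cluster_id)))
    sim <- tanimoto_matrix(fps, fps)
    for (cid in unique(got$cluster_id)) {
      members <- which(got$cluster_id == cid)
      if (length(members) > 1) {
        centroid <- members[got$is_centroid[members]]
        expect_length(centroid, 1L)
        expect_true(all(sim[centroid, members] >= 0.4))
      }
    }
  }
})

test_that("library reports count targets, families, bioactivities and novelty", {
  tiny <- tiny_annotation()
  rep3 <- library_report(c("c1", "c2", "c5"), tiny$predictions,
                         tiny$assignment, tiny$novelty)
  expect_equal(rep3$N, 3L)
  expect_equal(rep3$n_targets, 2L)         # tA, tB
  expect_equal(rep3$n_bioactivities, 3L)   # |{tA,tB}| + |{tA}| + 0
  expect_equal(rep3$n_families, 2L)        # F1, F2
  expect_equal(rep3$median_novelty,
               median(target_novelty(c("tA", "tB"), tiny$assignment,
                                     tiny$novelty)))
  expect_equal(rep3$fitness,
               as.numeric(library_fitness(c("c1", "c2", "c5"),
                                          tiny$predictions, tiny$assignment,
                                          tiny$novelty)))
  # permutation invariance
  perm <- library_report(c("c5", "c1", "c2"), tiny$predictions,
                         tiny$assignment, tiny$novelty)
  expect_equal(perm[c("n_targets", "n_families", "n_bioactivities",
                      "median_novelty", "fitness")],
               rep3[c("n_targets", "n_families", "n_bioactivities",
                      "median_novelty", "fitness")])
  empty <- library_report(character(), tiny$predictions, tiny$assignment,
                          tiny$novelty)
  expect_equal(empty$n_targets, 0L)
  expect_equal(empty$fitness, 0)

  # cluster coverage: a pool reported against itself represents all clusters
  fps <- random_fp_matrix(5, on = 30, seed = 61,
                          ids = tiny$predictions$compound_id)
  clusters <- taylor_butina(fps)
  full <- library_report(tiny$predictions$compound_id, tiny$predictions,
                         tiny$assignment, tiny$novelty, clusters = clusters)
  expect_equal(full$n_clusters_represented,
               length(unique(clusters$cluster_id)))
})
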