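# Q-analysis: shared faces, q-connected components, the full structure
# profile, plateau detection and shared-face clustering, all checked
# against brute-force oracles.

test_that("shared-face matrix matches brute-force set intersection on toys", {
  set.seed(1)
  for (i in 1:20) {
    M <- random_incidence(sample(3:8, 1), sample(2:6, 1))
    S <- shared_face_matrix(M)
    expect_identical(unclass(S), bf_shared_face(M))
  }
  expect_error(shared_face_matrix(matrix(0L, 0, 3)), "empty")
})

test_that("simplex dimension is occurrence count minus one", {
  M <- matrix(0L, 10, 2, dimnames = list(NULL, c("A", "B")))
  M[1:7, "A"] <- 1L
  M[3:5, "B"] <- 1L
  S <- shared_face_matrix(M)
  expect_equal(diag(S), c(A = 6, B = 2))
  expect_equal(S["A", "B"], 2)  # B's patients all inside A
  # descriptors sharing no patient get the empty-face value -1
  M[, "B"] <- 0L; M[8:10, "B"] <- 1L
  expect_equal(shared_face_matrix(M)["A", "B"], -1)
})

test_that("q_components matches the brute-force transitive closure", {
  set.seed(2)
  for (i in 1:30) {
    M <- random_incidence(sample(4:12, 1), 6, p = runif(1, 0.2, 0.7))
    if (all(colSums(M) == 0)) next
    S <- shared_face_matrix(M)
    for (q in 0:max(diag(S))) {
      expect_identical(canon_partition(q_components(S, q)),
                       canon_partition(bf_q_components(unclass(S), q)))
    }
  }
})

test_that("q_components handles hubs, isolation and range errors", {
  # hub descriptor co-occurring with everything: one component at q = 0
  M <- matrix(0L, 6, 4, dimnames = list(NULL, c("hub", "a", "b", "c")))
  M[, "hub"] <- 1L
  M[1, "a"] <- 1L; M[2, "b"] <- 1L; M[3, "c"] <- 1L
  S <- shared_face_matrix(M)
  expect_length(q_components(S, 0), 1)
  # above every off-diagonal value all survivors are isolated singletons
  q_iso <- max(S[upper.tri(S)]) + 1
  comps <- q_components(S, q_iso)
  expect_true(all(lengths(comps) == 1))
  expect_equal(length(comps), sum(diag(S) >= q_iso))
  expect_error(q_components(S, max(diag(S)) + 1), "range")
  expect_error(q_components(S, -1), "range")
})

test_that("structure_profile equals per-level recomputation", {
  set.seed(3)
  for (i in 1:15) {
    M <- random_incidence(sample(5:12, 1), sample(3:10, 1),
                          p = runif(1, 0.2, 0.8))
    if (all(colSums(M) == 0)) next
    S <- shared_face_matrix(M)
    profile <- structure_profile(S)
    for (q in 0:max(diag(S))) {
      expect_identical(canon_partition(profile_partition(profile, q)),
                       canon_partition(q_components(S, q)))
      lv <- profile$levels[profile$levels$q == q, ]
      comps <- q_components(S, q)
      expect_equal(lv$n_components, length(comps))
      expect_equal(lv$max_component_size, max(lengths(comps)))
    }
  }
})

test_that("profile obeys the max-dimension law and monotone coarsening", {
  set.seed(4)
  for (i in 1:15) {
    M <- random_incidence(10, 8, p = runif(1, 0.3, 0.7))
    if (all(colSums(M) == 0)) next
    S <- shared_face_matrix(M)
    profile <- structure_profile(S)
    expect_true(all(diff(profile$levels$max_component_size) <= 0))
    for (d in colnames(S)) {
      appears <- vapply(profile$levels$q, function(q)
        d %in% names(profile$membership[[q + 1]]), NA)
      # a descriptor occurring n times is present exactly up to q = n - 1
      expect_identical(appears, profile$levels$q <= S[d, d])
    }
    for (q in seq_len(max(diag(S)))) {
      finer <- profile_partition(profile, q)
      coarser <- profile_partition(profile, q - 1)
      for (comp in finer) {
        host <- Filter(function(g) all(comp %in% g), coarser)
        expect_length(host, 1)
      }
    }
  }
})

test_that("permuting patient rows changes neither S nor the profile", {
  set.seed(5)
  M <- random_incidence(12, 7)
  S <- shared_face_matrix(M)
  Sp <- shared_face_matrix(M[sample(nrow(M)), ])
  expect_identical(unclass(S), unclass(Sp))
  expect_identical(structure_profile(S)$levels, structure_profile(Sp)$levels)
})

test_that("plateau finds the constructed stability zone [529, 707]", {
  S <- shared_face_matrix(plateau_fixture())
  profile <- structure_profile(S)
  report <- plateau(profile, "Final diagnosis[1]")
  expect_equal(report$q_lo, 529)
  expect_equal(report$q_hi, 707)
  expect_length(report$members, 12)
  expect_true(report$contains_positive_diagnosis)
  expect_setequal(report$members, c(paste0("core", 1:11), "Final diagnosis[1]"))
})

test_that("plateau ties break toward the higher q-interval", {
  # anchor X: members {A, C, X} on q = 0..3 and {A, X} on q = 4..7,
  # both runs of length 4; the high-q run must win
  M <- matrix(0L, 10, 3, dimnames = list(NULL, c("A", "X", "C")))
  M[1:9, "A"] <- 1L
  M[1:8, "X"] <- 1L
  M[1:4, "C"] <- 1L
  profile <- structure_profile(shared_face_matrix(M))
  report <- plateau(profile, "X")
  expect_equal(c(report$q_lo, report$q_hi), c(4, 7))
  expect_setequal(report$members, c("A", "X"))
})

test_that("an always-isolated anchor yields a flagged empty report", {
  M <- matrix(0L, 6, 3, dimnames = list(NULL, c("A", "B", "lone")))
  M[1:4, "A"] <- 1L; M[1:4, "B"] <- 1L
  M[5:6, "lone"] <- 1L
  profile <- structure_profile(shared_face_matrix(M))
  expect_warning(report <- plateau(profile, "lone"), "size >= 2")
  expect_true(report$empty)
  expect_length(report$members, 0)
  expect_error(plateau(profile, "absent"), "absent")
})

test_that("feature sets partition the non-diagnosis descriptors", {
  S <- shared_face_matrix(plateau_fixture())
  report <- plateau(structure_profile(S), "Final diagnosis[1]")
  all_desc <- colnames(S)
  sets <- split_feature_sets(report, all_desc)
  feats <- setdiff(all_desc, diagnosis_descriptors())
  expect_setequal(c(sets$connected, sets$unconnected), feats)
  expect_length(intersect(sets$connected, sets$unconnected), 0)
  expect_false("Final diagnosis[1]" %in% c(sets$connected, sets$unconnected))
  # random plateau membership keeps the partition property
  set.seed(6)
  for (i in 1:10) {
    fake <- structure(list(members = sample(all_desc, sample(2:8, 1)),
                           empty = FALSE), class = "plateau_report")
    s <- split_feature_sets(fake, all_desc)
    expect_setequal(c(s$connected, s$unconnected), feats)
    expect_length(intersect(s$connected, s$unconnected), 0)
  }
})

test_that("shared-face clustering is deterministic and merges duplicates first", {
  M <- random_incidence(15, 5, p = 0.5)
  M[, 5] <- M[, 4]                       # duplicate descriptor rows in S
  S <- shared_face_matrix(M)
  cl <- cluster_shared_faces(S)
  expect_equal(cl$hclust$height[1], 0)
  first_pair <- sort(abs(cl$hclust$merge[1, ]))
  expect_equal(colnames(S)[first_pair], c("D4", "D5"))
  expect_identical(cl$order, cluster_shared_faces(S)$order)
})

test_that("average-linkage cophenetic distances match the naive agglomerator", {
  set.seed(7)
  M <- random_incidence(10, 5, p = 0.5)
  S <- unclass(shared_face_matrix(M))
  cl <- cluster_shared_faces(S)
  coph <- as.matrix(stats::cophenetic(cl$hclust))
  oracle <- bf_average_linkage_cophenetic(S)
  dimnames(oracle) <- dimnames(coph)
  expect_equal(coph, oracle, tolerance = 1e-12)
})
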