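test_that("dihedral distance follows the wrapped RMS formula", {
  # identity
  expect_equal(dihedral_distance(c(10, -20), c(30, 40), c(10, -20), c(30, 40)),
               0)
  # single-position hand arithmetic: phi differs by 30, psi equal
  expect_equal(dihedral_distance(30, 0, 0, 0), sqrt(30^2 / 2),
               tolerance = 1e-12)
  expect_equal(sqrt(30^2 / 2), 21.2132, tolerance = 1e-4)
  # wrap-around: 179 vs -179 contributes 2 degrees, not 358
  expect_equal(dihedral_distance(179, 0, -179, 0), sqrt(2^2 / 2),
               tolerance = 1e-12)
  # symmetry and bounds
  set.seed(1)
  a <- runif(10, -180, 180); b <- runif(10, -180, 180)
  c1 <- runif(10, -180, 180); c2 <- runif(10, -180, 180)
  expect_equal(dihedral_distance(a, b, c1, c2), dihedral_distance(c1, c2, a, b))
  expect_lte(dihedral_distance(a, b, c1, c2), 180)
  expect_error(dihedral_distance(1:3, 1:3, 1:2, 1:2), "length mismatch")
  expect_error(dihedral_distance(c(1, NA), c(1, 1), c(1, 1), c(1, 1)),
               "undefined")
})

test_that("degenerate clustering inputs behave per the recipe", {
  segs1 <- make_segments(list(c(-60, -60)), list(c(-45, -45)))
  cl1 <- single_pass_cluster(segs1, d_th = 30)
  expect_equal(length(cl1$clusters), 1L)
  expect_equal(cl1$assignment, 1L)

  segs2 <- make_segments(rep(list(c(-60, -60)), 2), rep(list(c(-45, -45)), 2))
  cl2 <- single_pass_cluster(segs2, d_th = 30)
  expect_equal(length(cl2$clusters), 1L)
  expect_equal(cl2$clusters[[1]]$centroid_phi, c(-60, -60))
  expect_equal(cl2$clusters[[1]]$centroid_psi, c(-45, -45))

  cl0 <- single_pass_cluster(segs1[0, ], d_th = 30)
  expect_equal(length(cl0$clusters), 0L)
})

test_that("planted clusters are recovered exactly", {
  pop <- generate_segment_population(seed = 1, L = 15, k_clusters = 3,
                                     members_per_cluster = 50,
                                     angular_noise_deg = 3)
  cl <- single_pass_cluster(pop$segments, d_th = 30)
  expect_equal(length(cl$clusters), 3L)
  expect_equal(mclust::adjustedRandIndex(cl$assignment, pop$labels), 1)
})

test_that("assignments match a step-by-step hand simulation", {
  set.seed(23)
  for (case in 1:3) {
    n <- sample(8:20, 1)
    phi <- lapply(seq_len(n), function(i) runif(4, -180, 180))
    psi <- lapply(seq_len(n), function(i) runif(4, -180, 180))
    segs <- make_segments(phi, psi)
    d_th <- sample(c(40, 80, 120), 1)
    cl <- single_pass_cluster(segs, d_th = d_th)
    expect_equal(cl$assignment, oracle_leader_cluster(phi, psi, d_th))
  }
})

test_that("clustering partitions the input", {
  pop <- generate_segment_population(seed = 4, L = 9, k_clusters = 3,
                                     members_per_cluster = 20,
                                     angular_noise_deg = 8)
  cl <- single_pass_cluster(pop$segments, d_th = 30)
  sizes <- vapply(cl$clusters, function(c) length(c$members), integer(1))
  expect_equal(sum(sizes), nrow(pop$segments))
  all_members <- sort(unlist(lapply(cl$clusters, `[[`, "members")))
  expect_equal(all_members, seq_len(nrow(pop$segments)))
  for (j in seq_along(cl$clusters)) {
    expect_true(cl$clusters[[j]]$medoid %in% cl$clusters[[j]]$members)
  }
})

test_that("raising the threshold never increases the cluster count", {
  for (seed in c(2, 9)) {
    pop <- generate_segment_population(seed = seed, L = 9, k_clusters = 3,
                                       members_per_cluster = 25,
                                       angular_noise_deg = 10)
    counts <- vapply(c(10, 20, 30, 40, 60), function(th) {
      length(single_pass_cluster(pop$segments, d_th = th)$clusters)
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("cluster count is stable over the 30-40 degree threshold band", {
  pop <- generate_segment_population(seed = 6, L = 15, k_clusters = 3,
                                     members_per_cluster = 50,
                                     angular_noise_deg = 3)
  counts <- vapply(seq(30, 40, by = 2.5), function(th) {
    length(single_pass_cluster(pop$segments, d_th = th)$clusters)
  }, integer(1))
  expect_true(all(counts == counts[1]))
})

test_that("medoid selection is the brute-force argmin with low-index ties", {
  # three members along one coordinate: the middle one is the medoid
  segs <- make_segments(list(c(-20, 0), c(0, 0), c(20, 0)),
                        rep(list(c(0, 0)), 3))
  cl <- single_pass_cluster(segs, d_th = 60)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(select_medoid(cl, 1), 2L)
  # brute force check
  ang <- cbind(do.call(rbind, segs$phi), do.call(rbind, segs$psi))
  tot <- sapply(1:3, function(i) sum(sapply(1:3, function(j) {
    dihedral_distance(ang[i, 1:2], ang[i, 3:4], ang[j, 1:2], ang[j, 3:4])
  })))
  expect_equal(select_medoid(cl, 1), which.min(tot))

  # all pairs tie -> lowest index
  segs2 <- make_segments(list(c(-10, 0), c(10, 0)), rep(list(c(0, 0)), 2))
  cl2 <- single_pass_cluster(segs2, d_th = 60)
  expect_equal(select_medoid(cl2, 1), 1L)
  # singleton
  segs3 <- make_segments(list(c(1, 2)), list(c(3, 4)))
  expect_equal(select_medoid(single_pass_cluster(segs3, d_th = 30), 1), 1L)
})

test_that("tidy/glance expose assignments and summaries", {
  pop <- generate_segment_population(seed = 5, L = 9, k_clusters = 2,
                                     members_per_cluster = 10,
                                     angular_noise_deg = 3)
  cl <- single_pass_cluster(pop$segments, d_th = 30)
  td <- tidy(cl)
  expect_equal(nrow(td), nrow(pop$segments))
  expect_true(all(td$distance_to_centroid >= 0))
  expect_equal(sum(td$is_medoid), length(cl$clusters))
  gl <- glance(cl)
  expect_equal(sum(gl$n_members), nrow(pop$segments))
})
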