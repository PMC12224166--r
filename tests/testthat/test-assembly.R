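test_that("chain topology carries polarity, charge and the tail bead", {
  topo <- chain_topology()
  expect_equal(nrow(topo), 9)  # 8 backbone + 1 tail
  expect_true(topo$is_tail[9])
  expect_equal(topo$class[9], "hydrophobic")
  # net chain charge at pH 6.7: His +0.5, three Glu and one Asp -1 each,
  # two Arg +1 each, conjugated Lys neutral
  expect_equal(sum(topo$charge), -1.5)
})

test_that("cluster finding is transitive and matches the brute-force oracle", {
  # two distant chains -> singletons
  fr <- make_frame(rbind(c(0, 0, 0), c(5, 0, 0)), chain = c(1, 2),
                   class = c("hydrophobic", "hydrophobic"), box = 20)
  p <- find_clusters(fr, cutoff = 0.6)
  expect_equal(sort(p$sizes), c(1, 1))

  # A-B close, B-C close, A-C far -> one cluster by transitivity
  fr3 <- make_frame(rbind(c(0, 0, 0), c(0.5, 0, 0), c(1.0, 0, 0)),
                    chain = 1:3, class = rep("hydrophilic", 3), box = 20)
  p3 <- find_clusters(fr3, cutoff = 0.6)
  expect_equal(p3$sizes, 3L)

  # periodic wrap: chains touching across the boundary
  frw <- make_frame(rbind(c(0.1, 0, 0), c(9.9, 0, 0)), chain = c(1, 2),
                    class = rep("hydrophilic", 2), box = 10)
  expect_equal(find_clusters(frw, cutoff = 0.6)$sizes, 2L)

  set.seed(61)
  for (rep in 1:8) {
    n <- 6; bpc <- 3
    coords <- matrix(runif(n * bpc * 3, 0, 6), ncol = 3)
    fr <- make_frame(coords, chain = rep(1:n, each = bpc),
                     class = sample(c("hydrophobic", "hydrophilic"),
                                    n * bpc, TRUE), box = 6)
    mine <- sort(find_clusters(fr, cutoff = 0.8)$sizes, decreasing = TRUE)
    oracle <- oracle_clusters(fr, cutoff = 0.8)
    expect_equal(mine, unname(oracle))
  }
})

test_that("partitions always cover every chain exactly once", {
  set.seed(62)
  coords <- matrix(runif(60, 0, 5), ncol = 3)
  fr <- make_frame(coords, chain = rep(1:5, each = 4),
                   class = rep("hydrophobic", 20), box = 5)
  p <- find_clusters(fr, cutoff = 0.7)
  expect_equal(sort(unlist(p$clusters)), 1:5)
  expect_equal(sum(p$sizes), 5)
})

test_that("hydrophobic core counting sees dense blobs only", {
  # all hydrophilic -> 0 cores
  fr <- make_frame(matrix(runif(30, 0, 2), ncol = 3), chain = rep(1, 10),
                   class = rep("hydrophilic", 10), box = 20)
  expect_equal(hydrophobic_core_count(fr), 0L)

  # two well-separated 8-bead blobs -> 2 cores
  set.seed(63)
  blob <- function(center) sweep(matrix(rnorm(24, 0, 0.2), ncol = 3), 2,
                                 center, "+")
  coords <- rbind(blob(c(2, 2, 2)), blob(c(8, 8, 8)))
  fr2 <- make_frame(coords, chain = rep(1:2, each = 8),
                    class = rep("hydrophobic", 16), box = 20)
  expect_equal(hydrophobic_core_count(fr2, eps = 0.8, min_beads = 5), 2L)

  # merging: the same two blobs within eps form a single core
  coords3 <- rbind(blob(c(2, 2, 2)), blob(c(2.4, 2, 2)))
  fr3 <- make_frame(coords3, chain = rep(1:2, each = 8),
                    class = rep("hydrophobic", 16), box = 20)
  expect_equal(hydrophobic_core_count(fr3, eps = 0.8, min_beads = 5), 1L)

  # sparse scatter is noise, not a core
  fr4 <- make_frame(matrix(seq(0, 18, length.out = 30), ncol = 3,
                           byrow = FALSE), chain = rep(1, 10),
                    class = rep("hydrophobic", 10), box = 20)
  expect_equal(hydrophobic_core_count(fr4, eps = 0.5, min_beads = 5), 0L)
})

test_that("interaction classification matches the paper's pair taxonomy", {
  # one Phe-palmitoyl style contact: both hydrophobic -> 100% hydrophobic
  fr <- make_frame(rbind(c(0, 0, 0), c(0.3, 0, 0)), chain = c(1, 2),
                   class = c("hydrophobic", "hydrophobic"), box = 10)
  p <- find_clusters(fr, cutoff = 0.6)
  tal <- classify_interactions(fr, p, 0.45)
  expect_equal(sum(tal$count), 1)
  expect_equal(tal$percent[tal$scope == "intra" & tal$type == "hydrophobic"],
               100)

  # no pairs in range -> zero counts, percentages absent
  fr0 <- make_frame(rbind(c(0, 0, 0), c(3, 0, 0)), chain = c(1, 2),
                    class = c("hydrophobic", "hydrophilic"), box = 10)
  tal0 <- classify_interactions(fr0, find_clusters(fr0), 0.45)
  expect_equal(sum(tal0$count), 0)
  expect_true(all(is.na(tal0$percent)))
})

test_that("interaction tallies equal the brute-force oracle and sum to 100%", {
  set.seed(64)
  for (rep in 1:5) {
    n <- 5; bpc <- 4
    coords <- matrix(runif(n * bpc * 3, 0, 3), ncol = 3)
    fr <- make_frame(coords, chain = rep(1:n, each = bpc),
                     class = sample(c("hydrophobic", "hydrophilic"),
                                    n * bpc, TRUE), box = 3)
    part <- find_clusters(fr, cutoff = 0.6)
    member <- integer(n)
    for (k in seq_along(part$clusters)) member[part$clusters[[k]]] <- k
    tal <- classify_interactions(fr, part, 0.45)
    oracle <- oracle_interactions(fr, member, 0.45)
    for (r in seq_len(nrow(tal)))
      expect_equal(tal$count[r], oracle[tal$scope[r], tal$type[r]])
    for (sc in c("intra", "inter")) {
      pc <- tal$percent[tal$scope == sc]
      if (!all(is.na(pc))) expect_equal(sum(pc), 100, tolerance = 0.1)
    }
  }
})

test_that("radius of gyration matches closed forms and the textbook formula", {
  one <- make_frame(matrix(c(1, 1, 1), 1), chain = 1, class = "hydrophobic",
                    box = 10)
  expect_equal(radius_of_gyration(one), 0)

  two <- make_frame(rbind(c(0, 0, 0), c(1, 0, 0)), chain = c(1, 1),
                    class = rep("hydrophobic", 2), box = 10)
  expect_equal(radius_of_gyration(two), 0.5)

  # periodic image: beads at 0.2 and 9.8 are 0.4 apart through the boundary
  wrap <- make_frame(rbind(c(0.2, 0, 0), c(9.8, 0, 0)), chain = c(1, 1),
                     class = rep("hydrophobic", 2), box = 10)
  expect_equal(radius_of_gyration(wrap), 0.2)

  set.seed(65)
  x <- matrix(runif(30, 4, 6), ncol = 3)  # central, no wrapping involved
  frr <- make_frame(x, chain = rep(1, 10), class = rep("hydrophobic", 10),
                    box = 100)
  cen <- colMeans(x)
  expect_equal(radius_of_gyration(frr),
               sqrt(mean(rowSums(sweep(x, 2, cen)^2))), tolerance = 1e-12)
  expect_error(radius_of_gyration(frr, integer(0)), "empty")
})

test_that("partition conservation checks the printed cluster lists", {
  expect_true(partition_conservation(c(8, 22), 30)$pass)
  expect_true(partition_conservation(c(5, 10, 15), 30)$pass)
  expect_true(partition_conservation(c(9, 10, 11, 15), 45)$pass)
  bad <- partition_conservation(c(1), 2)
  expect_equal(bad$sum, 1)
  expect_false(bad$pass)
})

test_that("the box concentrations of both simulated systems are ~3 mM", {
  expect_equal(round(box_molarity(30, 26.22) * 1000), 3)
  expect_equal(round(box_molarity(45, 29.20) * 1000), 3)
})

test_that("a single chain stays a single cluster and conserves chains", {
  traj <- simulate_assembly(n_chains = 1, box = 6, steps = 200, seed = 7)
  for (fr in traj$frames[c(1, length(traj$frames))]) {
    p <- find_clusters(fr)
    expect_equal(p$sizes, 1L)
    expect_equal(nrow(fr$coords), traj$beads_per_chain)
  }
})

test_that("simulated frames conserve chains and aggregate over time", {
  traj <- simulate_assembly(n_chains = 6, box = 6, steps = 2500, seed = 19)
  first <- find_clusters(traj$frames[[1]])
  last <- find_clusters(traj$frames[[length(traj$frames)]])
  expect_true(partition_conservation(first, 6)$pass)
  expect_true(partition_conservation(last, 6)$pass)
  expect_gte(mean(last$sizes), mean(first$sizes))
  expect_gt(max(last$sizes), 1)  # attraction produced at least one oligomer
})

test_that("zero attraction leaves an ideal-gas-like dispersed system", {
  p0 <- assembly_params(eps_hh = 0, eps_pp = 0, coulomb = 0)
  traj <- simulate_assembly(n_chains = 6, box = 8, steps = 800, params = p0,
                            seed = 23)
  sizes <- find_clusters(traj$frames[[length(traj$frames)]])$sizes
  expect_lte(mean(sizes), 1.5)
})

test_that("impossible initial placement is rejected with a geometry error", {
  expect_error(simulate_assembly(n_chains = 60, box = 3, steps = 1),
               "placement impossible")
})

test_that("trajectories round-trip through multi-frame XYZ", {
  traj <- simulate_assembly(n_chains = 2, box = 5, steps = 50,
                            save_every = 25, seed = 31)
  path <- tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, path)
  back <- read_trajectory_xyz(path)
  expect_equal(length(back$frames), length(traj$frames))
  expect_equal(back$frames[[1]]$coords, traj$frames[[1]]$coords,
               tolerance = 1e-5)
  expect_equal(back$frames[[2]]$beads$class, traj$frames[[2]]$beads$class)
})
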