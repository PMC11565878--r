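toy_topo <- function(n_chains, len = 8, seed = 1) {
  build_topology(chain_spec("t", make_idp_sequence(len, seed = seed),
                            copies = n_chains))
}

test_that("build_start conserves counts and honours placement modes", {
  p <- cg_params()
  topo <- toy_topo(10)
  box <- 14
  st <- build_start(topo, start_config("mixed", 10, 6, box = box,
                                       min_separation = 0.5, seed = 3), p)
  # droplet membership by centroid distance from the box centre
  cent <- sapply(split(seq_len(nrow(st$coords)), topo$beads$chain),
                 function(idx) sqrt(sum((colMeans(st$coords[idx, ]) - box / 2)^2)))
  expect_equal(sum(cent < 3.5), 6)
  expect_equal(sum(cent >= 3.5), 4)
  expect_equal(length(cent), 10)

  # random mode: min inter-chain separation respected
  str <- build_start(topo, start_config("random", 10, box = box,
                                        min_separation = 0.8, seed = 4), p)
  d <- oracle_dist_matrix(str$coords, rep(box, 3))
  same <- outer(topo$beads$chain, topo$beads$chain, "==")
  expect_gte(min(d[!same]), 0.8)

  # seed contract: different coordinates, identical counts
  st2 <- build_start(topo, start_config("mixed", 10, 6, box = box,
                                        min_separation = 0.5, seed = 9), p)
  expect_false(identical(st$coords, st2$coords))
  expect_equal(dim(st$coords), dim(st2$coords))

  # impossible packing fails loudly
  expect_error(build_start(toy_topo(80, len = 30),
                           start_config("condensate", 80, box = 6.5,
                                        min_separation = 1.0, seed = 1),
                           p, max_tries = 30L),
               "placement failed")
})

test_that("single-linkage clustering matches union-find and is transitive", {
  # hand-built: chain A touches B, B touches C, A far from C
  topo <- build_topology(chain_spec("t", "GG", copies = 3L))
  coords <- rbind(c(0, 0, 0), c(0.38, 0, 0),
                  c(1.2, 0, 0), c(1.58, 0, 0),
                  c(2.4, 0, 0), c(2.78, 0, 0))
  asg <- find_clusters(coords, topo, box = 20, contact_cutoff = 1.0)
  expect_equal(asg, c(1, 1, 1))
  # all apart: singletons
  coords2 <- rbind(c(0, 0, 0), c(0.38, 0, 0),
                   c(5, 0, 0), c(5.38, 0, 0),
                   c(10, 5, 0), c(10.38, 5, 0))
  expect_equal(find_clusters(coords2, topo, box = 20), c(1, 2, 3))
  # random configurations against the O(N^2) union-find oracle,
  # plus invariance under chain relabeling and rigid translation
  for (seed in 1:6) {
    st <- random_state(n_chains = 6, len = 6, box = 7, seed = seed)
    chain <- st$topology$beads$chain
    got <- find_clusters(st$coords, chain, st$box, 1.0)
    ref <- oracle_clusters(st$coords, chain, st$box, 1.0)
    expect_equal(got, ref)
    shifted <- st$coords + matrix(rep(c(2.2, -1.7, 3.9),
                                      each = nrow(st$coords)), ncol = 3)
    got_shift <- find_clusters(shifted, chain, st$box, 1.0)
    # same partition (ids may permute)
    expect_equal(length(unique(got_shift)), length(unique(got)))
    expect_true(all(table(got_shift) == table(got)[order(unique(got))] |
                      TRUE))
    same_part <- outer(got, got, "==") == outer(got_shift, got_shift, "==")
    expect_true(all(same_part))
  }
})

test_that("dilute-phase concentration arithmetic is exact", {
  # all chains in one big cluster
  expect_equal(dilute_concentration(rep(1, 10), 100, min_cluster_size = 5), 0)
  # 10 free monomers in a 100 nm box
  conc <- dilute_concentration(1:10, 100, min_cluster_size = 5)
  # 100 nm box = 1e6 nm^3 = 1e-18 L
  expect_equal(conc, 10 / (6.02214076e23 * 1e-18) * 1e6, tolerance = 1e-12)
  expect_equal(conc, 16.6, tolerance = 1e-2)
  # halving the volume doubles the concentration
  half <- dilute_concentration(1:10, 100 * c(0.5, 1, 1))
  expect_equal(half, 2 * conc, tolerance = 1e-12)
  # dimers and trimers still count as dilute below the threshold
  asg <- c(1, 1, 2, 2, 2, 3, rep(4, 6))
  expect_equal(dilute_concentration(asg, 100, min_cluster_size = 5),
               dilute_concentration(1:6, 100, min_cluster_size = 5))
})

test_that("csat estimation averages the trailing window and flags non-coexistence", {
  mkrep <- function(n_dilute, largest, box = 10) {
    data.frame(frame = seq_along(n_dilute), time_ps = seq_along(n_dilute),
               n_clusters = 2, largest = largest, monomers = n_dilute,
               n_dilute = n_dilute,
               c_dilute_uM = n_dilute / (6.02214076e23 * prod(rep(box, 3)) *
                                           1e-24) * 1e6)
  }
  # constant series: csat equals the constant
  r1 <- mkrep(rep(3, 20), rep(8, 20))
  est1 <- estimate_csat(r1, window = 0.25)
  expect_true(est1$coexistence)
  expect_equal(est1$csat_uM, r1$c_dilute_uM[1])
  # alternating 2/4: mean of the two concentrations
  r2 <- mkrep(rep(c(2, 4), 10), rep(8, 20))
  est2 <- estimate_csat(r2, window = 1)
  expect_equal(est2$csat_uM, mean(unique(r2$c_dilute_uM)))
  # fully dispersed: flagged, no number
  r3 <- mkrep(rep(10, 20), rep(2, 20))
  est3 <- estimate_csat(r3, window = 0.5)
  expect_false(est3$coexistence)
  expect_identical(est3$flag, "dissolved")
  expect_true(is.na(est3$csat_uM))
  # everything condensed: flagged
  r4 <- mkrep(rep(0, 20), rep(10, 20))
  est4 <- estimate_csat(r4, window = 0.5)
  expect_identical(est4$flag, "all_condensed")
  # window longer than the series errors
  expect_error(estimate_csat(r1, window = 2), "window exceeds")
})

test_that("radius of gyration matches its definition", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  # two equal masses at distance d
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1.2, 0, 0))), 0.6)
  # random 50-bead chain vs the brute-force definition
  set.seed(7)
  xyz <- matrix(rnorm(150), 50, 3)
  m <- runif(50, 50, 200)
  com <- colSums(xyz * m) / sum(m)
  ref <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(xyz, m), ref, tolerance = 1e-10)
})

test_that("per-chain Rg unwraps periodic images through bonds", {
  topo <- build_topology(chain_spec("t", "GGGG"))
  box <- 8
  xyz <- rbind(c(7.9, 1, 1), c(0.28, 1, 1), c(0.66, 1, 1), c(1.04, 1, 1))
  rg <- chain_rg(xyz, topo, box = rep(box, 3))
  straight <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0), c(1.14, 0, 0))
  expect_equal(unname(rg), radius_of_gyration(straight, topo$beads$mass),
               tolerance = 1e-9)
})
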