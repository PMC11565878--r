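# two-bead state without bonded exclusion, for isolated-pair checks
pair_state <- function(r, names = c("GLY", "GLY"), box = NULL,
                       params = cg_params(), xi = c(1, 1)) {
  topo <- build_topology(list(chain_spec("a", names[1]),
                              chain_spec("b", names[2])), params)
  topo$beads$xi <- xi
  system_state(topo, rbind(c(0, 0, 0), c(r, 0, 0)), box, params)
}

test_that("hand-arithmetic bonded energies are exact", {
  p <- cg_params()
  # one protein bond stretched to 0.48 nm: 0.5*4184*0.1^2
  topo <- build_topology(chain_spec("a", "GG"), p)
  st <- system_state(topo, rbind(c(0, 0, 0), c(0.48, 0, 0)), NULL, p)
  expect_equal(bond_energy(st), 0.5 * 4184 * 0.1^2, tolerance = 1e-12)
  expect_equal(bond_energy(st), 20.92, tolerance = 1e-12)
  # at l0 the bond energy vanishes
  st0 <- system_state(topo, rbind(c(0, 0, 0), c(0.38, 0, 0)), NULL, p)
  expect_equal(bond_energy(st0), 0)
  # two identical stretched bonds double the energy
  topo2 <- build_topology(chain_spec("a", "GG", copies = 2L), p)
  st2 <- system_state(topo2, rbind(c(0, 0, 0), c(0.48, 0, 0),
                                   c(10, 10, 10), c(10.48, 10, 10)), NULL, p)
  expect_equal(bond_energy(st2), 2 * 20.92, tolerance = 1e-9)
})

test_that("ENM energy is harmonic about the reference distances", {
  fx <- make_folded_fixture(28, seed = 1)
  topo <- build_topology(fx$spec)
  st <- system_state(topo, fx$spec$ref_coords, NULL, cg_params())
  expect_equal(enm_energy(st), 0, tolerance = 1e-12)
  # single restraint displaced by 0.02 nm: 0.5*500*4e-4
  xyz <- cbind(c(0, 0.38, 0.76), 0, 0)
  spec <- chain_spec("f", "GGG", folded_ranges = list(c(1, 3)),
                     ref_coords = xyz)
  t3 <- build_topology(spec)
  xyz2 <- xyz; xyz2[3, 1] <- 0.78
  st3 <- system_state(t3, xyz2, NULL, cg_params())
  expect_equal(enm_energy(st3), 0.5 * 500 * 0.02^2, tolerance = 1e-9)
  expect_equal(enm_energy(st3), 0.1, tolerance = 1e-9)
})

test_that("angle energy matches hand arithmetic and is frame-invariant", {
  p <- cg_params()
  topo <- build_topology(chain_spec("a", "GGG"), p)
  collinear <- cbind(c(0, 0.38, 0.76), 0, 0)
  st <- system_state(topo, collinear, NULL, p)
  expect_equal(angle_energy(st), 0, tolerance = 1e-12)
  right <- rbind(c(0.38, 0, 0), c(0, 0, 0), c(0, 0.38, 0))
  str <- system_state(topo, right, NULL, p)
  expect_equal(angle_energy(str), 0.5 * 4.184 * (pi / 2)^2, tolerance = 1e-9)
  expect_equal(angle_energy(str), 5.162, tolerance = 1e-3)
  # rigid rotation leaves every term unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  strot <- system_state(topo, right %*% R, NULL, p)
  expect_equal(angle_energy(strot), angle_energy(str), tolerance = 1e-9)
})

test_that("10-5 pair potential has the documented zero, minimum and cutoff", {
  p <- cg_params()
  pp <- combine_pair("GLY", "GLY", params = p)
  # zero at contact
  expect_equal(short_range_energy(pair_state(pp$sigma_ij)), 0,
               tolerance = 1e-12)
  # minimum -xi*(eps+eps_mod) at 2^(1/5) sigma
  rmin <- 2^(1 / 5) * pp$sigma_ij
  expect_equal(short_range_energy(pair_state(rmin)),
               -(pp$eps_ij), tolerance = 1e-9)
  # with an eps_mod pair and reduced xi
  qq <- combine_pair("ARG", "PHE", params = p)
  stm <- pair_state(2^(1 / 5) * qq$sigma_ij, c("ARG", "PHE"),
                    xi = c(0.5, 0.8))
  expect_equal(short_range_energy(stm),
               -0.4 * (qq$eps_ij + 0.3), tolerance = 1e-9)
  # beyond the 3 nm cutoff everything vanishes
  far <- pair_state(3.1, c("ARG", "ASP"))
  expect_equal(short_range_energy(far), 0)
  expect_equal(electrostatic_energy(far), 0)
})

test_that("screened electrostatics has the right signs and decay", {
  p <- cg_params("COCOMO")
  # neutral pair with zero A0 product contributes nothing
  st <- pair_state(0.6, c("GLY", "GLY"), params = p)  # A0_h = 0 in COCOMO
  expect_equal(electrostatic_energy(st), 0)
  # opposite unit charges attract
  stpm <- pair_state(0.6, c("ASP", "LYS"), params = p)
  e1 <- electrostatic_energy(stpm)
  expect_lt(e1, 0)
  expect_equal(e1, (-0.5625 + 0.05^2) * exp(-0.6) / 0.6, tolerance = 1e-9)
  # magnitude decays monotonically with distance
  rr <- seq(1.2, 2.8, by = 0.4)
  ee <- sapply(rr, function(r)
    electrostatic_energy(pair_state(r, c("ASP", "LYS"), params = p)))
  expect_true(all(diff(abs(ee)) < 0))
  # like charges with A0: repulsive
  stpp <- pair_state(0.6, c("LYS", "ARG"), params = p)
  expect_gt(electrostatic_energy(stpp), 0)
})

test_that("every term matches the brute-force oracle on random configurations", {
  n_cfg <- 0
  for (seed in 1:8) {
    for (folded in c(FALSE, TRUE)) {
      st <- random_state(n_chains = 2 + seed %% 3, len = 6 + seed,
                         box = 6.5, seed = seed, folded = folded)
      ref <- oracle_energy(st)
      for (nl in c(FALSE, TRUE)) {
        got <- total_energy(st, use_neighbour_list = nl)
        expect_equal(got$bond, ref$bond, tolerance = 1e-9)
        expect_equal(got$angle, ref$angle, tolerance = 1e-9)
        expect_equal(got$enm, ref$enm, tolerance = 1e-9)
        expect_equal(got$short_range, ref$short_range, tolerance = 1e-6)
        expect_equal(got$electrostatic, ref$electrostatic, tolerance = 1e-6)
      }
      n_cfg <- n_cfg + 1
    }
  }
  expect_gte(n_cfg, 16)
})

test_that("the breakdown total equals the component sum", {
  st <- random_state(3, 10, box = 7, seed = 42)
  e <- total_energy(st)
  expect_equal(e$total,
               e$bond + e$angle + e$enm + e$short_range + e$electrostatic,
               tolerance = 1e-9)
  # single isolated bead: all zero
  topo1 <- build_topology(chain_spec("m", "G"))
  e1 <- total_energy(system_state(topo1, matrix(0, 1, 3), NULL, cg_params()))
  expect_equal(unlist(e1), c(bond = 0, angle = 0, enm = 0, short_range = 0,
                             electrostatic = 0, total = 0))
})

test_that("minimum-image convention wraps pair distances", {
  p <- cg_params()
  box <- 8
  st <- pair_state(0.6, c("ASP", "LYS"), box = rep(box, 3), params = p)
  e0 <- total_energy(st)$total
  st$coords[2, 1] <- st$coords[2, 1] + box   # same minimum image
  expect_equal(total_energy(st)$total, e0, tolerance = 1e-9)
  # translation invariance of the whole system
  st2 <- random_state(3, 8, box = 7, seed = 9)
  e1 <- total_energy(st2)$total
  st2$coords <- st2$coords + matrix(rep(c(1.3, -2.1, 0.7), each = nrow(st2$coords)), ncol = 3)
  expect_equal(total_energy(st2)$total, e1, tolerance = 1e-8)
})

test_that("analytic forces match finite differences", {
  st <- random_state(2, 7, box = 6.5, seed = 5, folded = TRUE)
  f <- forces(st)
  h <- 1e-6
  set.seed(1)
  for (k in 1:12) {
    i <- sample(nrow(st$coords), 1); d <- sample(3, 1)
    stp <- st; stp$coords[i, d] <- stp$coords[i, d] + h
    stm <- st; stm$coords[i, d] <- stm$coords[i, d] - h
    num <- -(total_energy(stp)$total - total_energy(stm)$total) / (2 * h)
    expect_equal(f[i, d], num, tolerance = 1e-5)
  }
})

test_that("xi scaling suppresses only the short-range term of buried pairs", {
  fx <- make_folded_fixture(28, seed = 8, copies = 2L)
  p <- cg_params()
  topo <- build_topology(fx$spec, p)
  st <- build_start(topo, start_config("condensate", 2, box = 6.5,
                                       min_separation = 0.4, seed = 3), p)
  e_ref <- total_energy(st)
  topo0 <- topo
  topo0$beads$xi <- ifelse(topo0$beads$is_folded, 0, topo0$beads$xi)
  st0 <- st; st0$topology <- topo0
  e0 <- total_energy(st0)
  expect_equal(e0$bond, e_ref$bond)
  expect_equal(e0$enm, e_ref$enm)
  expect_equal(e0$angle, e_ref$angle)
  expect_equal(e0$short_range, 0)     # every bead here is folded
  expect_equal(e0$electrostatic, e_ref$electrostatic)  # xi spares electrostatics
})

test_that("bonded neighbours are excluded from nonbonded terms at any separation", {
  p <- cg_params()
  topo <- build_topology(chain_spec("a", "DK"), p)  # charged, bonded pair
  st <- system_state(topo, rbind(c(0, 0, 0), c(0.2, 0, 0)), NULL, p)
  expect_equal(short_range_energy(st), 0)
  expect_equal(electrostatic_energy(st), 0)
  expect_gt(bond_energy(st), 0)
})

test_that("overlapping nonbonded beads raise an error", {
  expect_error(total_energy(pair_state(0)), "overlap")
})
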