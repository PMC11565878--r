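# Independent reference implementations used as oracles. These share only
# the per-pair combination rules (checked separately against hand values)
# with the package; all energy summation, neighbour handling and cluster
# logic is re-derived here in plain vectorized R.

oracle_min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

oracle_dist_matrix <- function(coords, box = NULL) {
  n <- nrow(coords)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(coords[, k], coords[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# pairwise parameter matrices assembled via combine_pair on type pairs
oracle_pair_tables <- function(p) {
  bt <- bead_types(p, include_sref = FALSE)
  K <- nrow(bt)
  sig <- eps <- emod <- Aij <- A0ij <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K) {
    pp <- combine_pair(bt$name[a], bt$name[b], params = p)
    sig[a, b] <- pp$sigma_ij; eps[a, b] <- pp$eps_ij
    emod[a, b] <- pp$eps_mod_ij; Aij[a, b] <- pp$A_ij; A0ij[a, b] <- pp$A0_ij
  }
  list(sig = sig, eps = eps, emod = emod, Aij = Aij, A0ij = A0ij)
}

# full energy breakdown by direct double loop over all pairs
oracle_energy <- function(state, tables = NULL) {
  topo <- state$topology
  p <- state$params
  x <- state$coords
  box <- state$box
  n <- nrow(x)
  ti <- topo$beads$type_index
  if (is.null(tables)) tables <- oracle_pair_tables(p)
  sig <- tables$sig; eps <- tables$eps; emod <- tables$emod
  Aij <- tables$Aij; A0ij <- tables$A0ij
  d <- oracle_dist_matrix(x, box)
  excl <- matrix(FALSE, n, n)
  if (nrow(topo$exclusions)) {
    excl[topo$exclusions] <- TRUE
    excl[topo$exclusions[, c(2, 1), drop = FALSE]] <- TRUE
  }
  e_sr <- 0; e_el <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (excl[i, j]) next
    r <- d[i, j]
    if (r >= p$cutoff) next
    a <- ti[i]; b <- ti[j]
    xij <- topo$beads$xi[i] * topo$beads$xi[j]
    sr <- sig[a, b] / r
    e_sr <- e_sr + xij * 4 * (eps[a, b] + emod[a, b]) * (sr^10 - sr^5)
    esc <- if (isTRUE(p$xi_scales_electrostatics)) xij else 1
    e_el <- e_el + esc * p$elec_prefactor * (Aij[a, b] + A0ij[a, b]) *
      exp(-r / p$kappa) / r
  }
  e_bond <- 0
  if (nrow(topo$bonds)) {
    for (k in seq_len(nrow(topo$bonds))) {
      i <- topo$bonds[k, 1]; j <- topo$bonds[k, 2]
      l <- sqrt(sum((x[i, ] - x[j, ])^2))
      e_bond <- e_bond + 0.5 * p$kbond * (l - topo$bond_l0[k])^2
    }
  }
  e_enm <- 0
  if (nrow(topo$enm)) {
    for (k in seq_len(nrow(topo$enm))) {
      i <- topo$enm[k, 1]; j <- topo$enm[k, 2]
      l <- sqrt(sum((x[i, ] - x[j, ])^2))
      e_enm <- e_enm + 0.5 * p$kenm * (l - topo$enm_r0[k])^2
    }
  }
  e_ang <- 0
  if (nrow(topo$angles)) {
    for (k in seq_len(nrow(topo$angles))) {
      i <- topo$angles[k, 1]; j <- topo$angles[k, 2]; m <- topo$angles[k, 3]
      u <- x[i, ] - x[j, ]; v <- x[m, ] - x[j, ]
      ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      th <- acos(max(-1, min(1, ct)))
      e_ang <- e_ang + 0.5 * topo$angle_k[k] * (th - pi)^2
    }
  }
  list(bond = e_bond, angle = e_ang, enm = e_enm, short_range = e_sr,
       electrostatic = e_el,
       total = e_bond + e_ang + e_enm + e_sr + e_el)
}

# union-find single-linkage clustering over the full contact matrix
oracle_clusters <- function(coords, chain, box, cutoff) {
  nc <- max(chain)
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- oracle_dist_matrix(coords, box)
  n <- nrow(coords)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (chain[i] == chain[j]) next
    if (d[i, j] < cutoff) {
      ri <- find(chain[i]); rj <- find(chain[j])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(nc), find, 1L)
  match(roots, unique(roots))
}

# analytic exposed area of sphere 1 (radius R1) occluded by sphere 2
# (radius R2) at centre distance dist; radii include the probe
oracle_two_sphere_area <- function(R1, R2, dist) {
  if (dist >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (dist^2 + R1^2 - R2^2) / (2 * dist)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# ENM pair set by brute-force scan over a folded range
oracle_enm_pairs <- function(xyz, idx, r0max = 0.9) {
  out <- NULL
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (b <= a) next
    i <- idx[a]; j <- idx[b]
    if (abs(i - j) < 2) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r <= r0max) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# small random multi-chain test state
random_state <- function(n_chains = 3, len = 8, box = 7, seed = 1,
                         params = cg_params(), folded = FALSE) {
  set.seed(seed)
  if (folded) {
    fx <- make_folded_fixture(max(14, len), seed = seed, copies = n_chains)
    topo <- build_topology(fx$spec, params)
  } else {
    seqs <- make_idp_sequence(len, seed = seed)
    topo <- build_topology(chain_spec("t", seqs, copies = n_chains), params)
  }
  st <- build_start(topo, start_config("random", n_chains,
                                       box = box, min_separation = 0.4,
                                       seed = seed), params)
  st
}
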