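#' Starting-configuration settings for multi-chain systems
#'
#' Three modes: `"random"` (all chains dispersed uniformly), `"condensate"`
#' (all chains packed into a droplet), and `"mixed"` (a pre-formed droplet
#' of `n_chains_condensed` chains coexisting with dispersed monomers) -- the
#' mixed-phase start is the preferred protocol for saturation-concentration
#' estimates because it avoids the nucleation/melting hysteresis of the
#' extreme starts.
#'
#' @param mode Placement mode.
#' @param n_chains_total Total chain count (must match the topology).
#' @param n_chains_condensed Chains in the droplet (mixed mode).
#' @param box Box edge lengths (nm, length 1 or 3).
#' @param min_separation Minimum inter-chain bead distance at t = 0 (nm).
#' @param seed Integer seed.
#' @return A `start_config` object.
#' @export
start_config <- function(mode = c("mixed", "random", "condensate"),
                         n_chains_total, n_chains_condensed = 0L,
                         box, min_separation = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  box <- rep(as.numeric(box), length.out = 3)
  if (mode == "condensate") n_chains_condensed <- n_chains_total
  if (mode == "random") n_chains_condensed <- 0L
  stopifnot(n_chains_condensed <= n_chains_total, all(box > 0))
  structure(list(mode = mode, n_chains_total = as.integer(n_chains_total),
                 n_chains_condensed = as.integer(n_chains_condensed),
                 box = box, min_separation = min_separation,
                 seed = as.integer(seed)),
            class = "start_config")
}

# persistent random walk chain template with fixed bond length
.walk_template <- function(n, l0, persistence = 0.8) {
  xyz <- matrix(0, n, 3)
  d <- c(1, 0, 0)
  for (i in seq_len(n - 1)) {
    d <- d + persistence * stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    xyz[i + 1, ] <- xyz[i, ] + l0 * d
  }
  xyz
}

.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
           2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

#' Build a starting configuration
#'
#' Places every chain of the topology in the box according to the start
#' mode. Each chain's internal conformation is its reference structure
#' when complete, otherwise a persistent random walk at the chain's bond
#' length. Chains are placed whole (random rigid rotation + translation)
#' with all inter-chain bead distances at least `min_separation`, with
#' bounded retries.
#'
#' @param topology A `cg_topology`.
#' @param start A [start_config()].
#' @param params A `cg_params` object.
#' @param max_tries Placement attempts per chain before giving up.
#' @return A `cg_state` at the requested box and placement.
#' @export
build_start <- function(topology, start, params = cg_params(),
                        max_tries = 2000L) {
  if (start$n_chains_total != topology$n_chains)
    stop("start_config chain count (", start$n_chains_total,
         ") does not match topology (", topology$n_chains, ")")
  beads <- topology$beads
  box <- start$box
  centre <- box / 2
  with_local_seed(start$seed, {
    chains <- split(seq_len(nrow(beads)), beads$chain)
    # chain templates, centred
    templates <- lapply(chains, function(idx) {
      rc <- topology$ref_coords[idx, , drop = FALSE]
      if (!anyNA(rc)) {
        xyz <- rc
      } else {
        l0 <- if (beads$name[idx[1]] %in% .NT) params$l0_nucleic else params$l0_protein
        xyz <- .walk_template(length(idx), l0)
      }
      sweep(xyz, 2, colMeans(xyz))
    })
    v_bead <- 0.065  # nm^3 effective bead volume for droplet sizing
    n_cond <- start$n_chains_condensed
    n_beads_cond <- if (n_cond > 0)
      sum(lengths(chains[seq_len(n_cond)])) else 0
    r_drop <- if (n_cond > 0)
      (3 * n_beads_cond * v_bead / (4 * pi * 0.2))^(1 / 3) else 0
    placed <- matrix(numeric(0), 0, 3)
    coords <- matrix(NA_real_, nrow(beads), 3)
    for (ci in seq_along(chains)) {
      idx <- chains[[ci]]
      condensed <- ci <= n_cond
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        if (condensed) {
          repeat {
            u <- stats::runif(3, -1, 1)
            if (sum(u^2) <= 1) break
          }
          pos <- centre + r_drop * u
        } else {
          pos <- stats::runif(3, 0, 1) * box
          if (start$mode == "mixed" &&
              sqrt(sum(.min_image(pos - centre, box)^2)) < r_drop + 1.5) next
        }
        xyz <- templates[[ci]] %*% .random_rotation()
        xyz <- sweep(xyz, 2, pos, "+")
        if (nrow(placed)) {
          dmin <- .min_cross_distance(xyz, placed, box)
          if (dmin < start$min_separation) next
        }
        coords[idx, ] <- xyz
        placed <- rbind(placed, xyz)
        ok <- TRUE
        break
      }
      if (!ok) stop("chain placement failed after ", max_tries, " attempts")
    }
    system_state(topology, coords, box, params)
  })
}

.min_image <- function(d, box) d - box * round(d / box)

# minimum over minimum-image distances between two bead sets
.min_cross_distance <- function(a, b, box) {
  best <- Inf
  for (k in 1:3) {
    # accumulate squared component-wise minimum-image differences
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    if (k == 1) d2 <- dk^2 else d2 <- d2 + dk^2
  }
  sqrt(min(d2))
}

#' Assign chains to clusters by single-linkage contact
#'
#' Two chains are in direct contact when any inter-chain bead pair is
#' closer than `contact_cutoff` (minimum image); clusters are the
#' connected components of the contact graph.
#'
#' @param coords N x 3 bead coordinates (nm).
#' @param chain Integer chain index per bead (or a `cg_topology`).
#' @param box Box edges (nm) or `NULL`.
#' @param contact_cutoff Contact distance (nm).
#' @return Integer cluster id per chain (1..n_clusters, in order of first
#'   chain membership).
#' @export
find_clusters <- function(coords, chain, box = NULL, contact_cutoff = 1.0) {
  if (inherits(chain, "cg_topology")) chain <- chain$beads$chain
  adj <- cpp_chain_contacts(as.matrix(coords),
                            if (is.null(box)) c(-1, -1, -1) else rep(box, length.out = 3),
                            as.integer(chain - 1L), contact_cutoff)
  nc <- nrow(adj)
  comp <- integer(nc)
  cur <- 0L
  for (s in seq_len(nc)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Dilute-phase concentration from a cluster assignment
#'
#' Chains in clusters smaller than `min_cluster_size` count as the dilute
#' ("free monomer") phase.
#'
#' @param assignment Integer cluster id per chain.
#' @param box Box edges (nm, length 1 or 3).
#' @param min_cluster_size Smallest chain count regarded as condensate.
#' @return Concentration in micromolar.
#' @export
dilute_concentration <- function(assignment, box, min_cluster_size = 5L) {
  box <- rep(as.numeric(box), length.out = 3)
  sizes <- table(assignment)
  n_dilute <- sum(sizes[sizes < min_cluster_size])
  vol_l <- prod(box) * 1e-24
  n_dilute / (N_AVOGADRO * vol_l) * 1e6
}

#' Per-frame phase observables of a trajectory
#'
#' @param traj A `cg_trajectory` with stored frames.
#' @param topology The system's `cg_topology`.
#' @param contact_cutoff Chain-contact distance (nm).
#' @param min_cluster_size Condensate size threshold (chains).
#' @return Data.frame: frame, time_ps, n_clusters, largest, monomers,
#'   n_dilute, c_dilute_uM.
#' @export
phase_report <- function(traj, topology, contact_cutoff = 1.0,
                         min_cluster_size = 5L) {
  box <- traj$final$box
  chain <- topology$beads$chain
  rows <- lapply(seq_along(traj$frames), function(f) {
    asg <- find_clusters(traj$frames[[f]], chain, box, contact_cutoff)
    sizes <- table(asg)
    data.frame(frame = f,
               time_ps = traj$scalars$time_ps[f],
               n_clusters = length(sizes),
               largest = max(sizes),
               monomers = sum(sizes == 1),
               n_dilute = sum(sizes[sizes < min_cluster_size]),
               c_dilute_uM = dilute_concentration(asg, box, min_cluster_size))
  })
  do.call(rbind, rows)
}

#' Estimate the saturation concentration from a coexistence trajectory
#'
#' Averages the dilute-phase concentration over the trailing window of the
#' trajectory, provided dense and dilute phases actually coexist there.
#' When the condensate dissolved (largest cluster below threshold in most
#' window frames) or all chains condensed (no dilute chains), the estimate
#' is flagged instead of reported as a number.
#'
#' @param traj A `cg_trajectory`, or a data.frame as returned by
#'   [phase_report()].
#' @param topology Required when `traj` is a trajectory.
#' @param window Trailing fraction of frames to average over.
#' @param contact_cutoff,min_cluster_size Passed to [phase_report()].
#' @param n_blocks Blocks for the block-average spread.
#' @return List: `csat_uM`, `spread_uM` (block SD), `coexistence`
#'   (logical), `flag` (`"ok"`, `"dissolved"` or `"all_condensed"`),
#'   `report` (the per-frame table of the window).
#' @export
estimate_csat <- function(traj, topology = NULL, window = 0.2,
                          contact_cutoff = 1.0, min_cluster_size = 5L,
                          n_blocks = 4L) {
  rep_df <- if (is.data.frame(traj)) traj
            else phase_report(traj, topology, contact_cutoff, min_cluster_size)
  nf <- nrow(rep_df)
  nw <- max(1L, ceiling(window * nf))
  if (nw > nf) stop("window exceeds trajectory length")
  w <- rep_df[(nf - nw + 1):nf, , drop = FALSE]
  dissolved <- stats::median(w$largest) < min_cluster_size
  all_cond <- all(w$n_dilute == 0)
  flag <- if (dissolved) "dissolved" else if (all_cond) "all_condensed" else "ok"
  csat <- mean(w$c_dilute_uM)
  spread <- if (nrow(w) >= 2) {
    blocks <- split(w$c_dilute_uM,
                    cut(seq_len(nrow(w)),
                        breaks = max(2L, min(n_blocks, nrow(w) %/% 1L)),
                        labels = FALSE))
    stats::sd(vapply(blocks, mean, numeric(1)))
  } else NA_real_
  list(csat_uM = if (flag == "ok") csat else NA_real_,
       spread_uM = spread, coexistence = flag == "ok", flag = flag,
       report = w)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of beads from their centre of
#' mass.
#'
#' @param coords N x 3 coordinates (nm).
#' @param masses Bead masses; equal masses when `NULL`.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

# unwrap one chain across periodic images by walking its bonds
.unwrap_chain <- function(xyz, box) {
  if (is.null(box)) return(xyz)
  out <- xyz
  for (i in seq_len(nrow(xyz) - 1)) {
    d <- xyz[i + 1, ] - out[i, ]
    out[i + 1, ] <- out[i, ] + .min_image(d, box)
  }
  out
}

#' Per-chain radii of gyration of a configuration
#'
#' @param coords N x 3 coordinates (nm).
#' @param topology A `cg_topology`.
#' @param box Box edges for periodic unwrapping (bonded-connectivity walk),
#'   or `NULL` for already-whole chains.
#' @return Numeric vector, one Rg (nm) per chain.
#' @export
chain_rg <- function(coords, topology, box = NULL) {
  beads <- topology$beads
  vapply(split(seq_len(nrow(beads)), beads$chain), function(idx) {
    xyz <- .unwrap_chain(coords[idx, , drop = FALSE], box)
    radius_of_gyration(xyz, beads$mass[idx])
  }, numeric(1))
}
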