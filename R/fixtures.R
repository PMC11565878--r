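# Synthetic test-input generators: toy disordered sequences, procedurally
# built helix bundles with known burial, and self-consistent rescoring
# problems with known generating parameters. Everything is deterministic
# under the given seed and requires no external data.

.CLASS_POOLS <- list(
  polar = c("SER", "THR", "ASN", "GLN", "HIS", "CYS"),
  hydrophobic = c("ALA", "GLY", "ILE", "LEU", "MET", "PRO", "VAL"),
  charged = c("ASP", "GLU", "LYS", "ARG"),
  aromatic = c("PHE", "TYR", "TRP"))

#' Generate a random disordered-protein sequence
#'
#' Residue classes (uncharged polar, non-aromatic hydrophobic, charged,
#' aromatic) are drawn from the composition weights, then a residue is
#' drawn uniformly within the class.
#'
#' @param length Sequence length (>= 2).
#' @param composition Named weights over
#'   c("polar", "hydrophobic", "charged", "aromatic"); normalized
#'   internally.
#' @param seed Integer seed.
#' @return Character vector of three-letter residue codes.
#' @export
make_idp_sequence <- function(length,
                              composition = c(polar = 0.4, hydrophobic = 0.4,
                                              charged = 0.1, aromatic = 0.1),
                              seed = 1L) {
  stopifnot(length >= 2)
  if (is.null(names(composition)) || any(composition < 0) ||
      sum(composition) <= 0) stop("impossible composition")
  # weights may name residue classes or individual residues
  pools <- lapply(names(composition), function(nm) {
    if (nm %in% names(.CLASS_POOLS)) return(.CLASS_POOLS[[nm]])
    sequence_to_types(nm, "protein")
  })
  w <- composition / sum(composition)
  with_local_seed(seed, {
    cls <- sample(seq_along(pools), length, replace = TRUE, prob = w)
    vapply(cls, function(cl) {
      pool <- pools[[cl]]
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Procedurally built folded helix-bundle fixture
#'
#' Builds a compact bundle of seven ideal coarse-grained helices (six on a
#' hexagon around one central helix, adjacent helices antiparallel,
#' traversed as a single chain). Residues of the central helix away from
#' the chain ends are geometrically enclosed by the six outer helices and
#' labelled buried; the radially outermost outer-helix residues are
#' labelled exposed. A small seeded jitter breaks exact symmetry.
#'
#' @param n_residues Total residue count (>= 14; divided over 7 helices).
#' @param seed Integer seed.
#' @param spacing Axis-to-axis helix distance (nm).
#' @param sequence Optional residue codes (length `n_residues`); default a
#'   seeded polar/hydrophobic mix.
#' @param copies Copies of the chain in the built topology.
#' @return List: `spec` (a [chain_spec()] with the whole chain as one
#'   folded range), `buried`, `exposed` (residue index vectors).
#' @export
make_folded_fixture <- function(n_residues = 56L, seed = 1L, spacing = 1.0,
                                sequence = NULL, copies = 1L) {
  stopifnot(n_residues >= 14)
  n_hel <- 7L
  per <- diff(round(seq(0, n_residues, length.out = n_hel + 1)))
  centres <- rbind(
    spacing * cbind(cos(seq(0, 5) * pi / 3), sin(seq(0, 5) * pi / 3)),
    c(0, 0))
  with_local_seed(seed, {
    xyz <- matrix(NA_real_, n_residues, 3)
    helix_of <- integer(n_residues)
    at <- 0L
    for (h in seq_len(n_hel)) {
      seg <- .ideal_helix(per[h])
      if (h %% 2 == 0) seg[, 3] <- max(seg[, 3]) - seg[, 3]  # antiparallel
      seg[, 1] <- seg[, 1] + centres[h, 1]
      seg[, 2] <- seg[, 2] + centres[h, 2]
      idx <- at + seq_len(per[h])
      xyz[idx, ] <- seg
      helix_of[idx] <- h
      at <- at + per[h]
    }
    xyz <- xyz + matrix(stats::rnorm(3 * n_residues, sd = 0.01), n_residues, 3)
    if (is.null(sequence))
      sequence <- make_idp_sequence(n_residues,
                                    c(polar = 0.5, hydrophobic = 0.5),
                                    seed = seed + 1L)
    spec <- chain_spec("bundle", sequence, "protein",
                       folded_ranges = list(c(1L, n_residues)),
                       ref_coords = xyz, copies = copies)
    core <- which(helix_of == n_hel)
    buried <- core[core > min(core) + 1 & core < max(core) - 1]
    raxis <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
    outer_idx <- which(helix_of < n_hel)
    exposed <- outer_idx[raxis[outer_idx] >=
                           stats::quantile(raxis[outer_idx], 2 / 3)]
    list(spec = spec, buried = buried, exposed = exposed)
  })
}

#' Self-consistent rescoring/optimization fixture
#'
#' Builds a synthetic inverse problem with a known generating parameter
#' set: for each requested system, a small multi-chain condensate is
#' simulated briefly under `true_params` and strided snapshots stored;
#' per-system linear coefficients (a, b) linking per-residue potential
#' energy to log10 csat are drawn; "experimental" csat is assigned as
#' 10^(a U(true) + b) with optional lognormal noise, and probe parameter
#' sets with matching synthetic csat are emitted so that energy-csat fits
#' can be reconstructed. The full generating record is returned for
#' recovery scoring.
#'
#' @param true_params The generating `cg_params` (lambda must respect the
#'   0.7 optimization cap to be recoverable).
#' @param systems List of system descriptors:
#'   `list(name=, kind=c("idp","folded"), length=, n_chains=,
#'   composition=)`.
#' @param seed Integer seed.
#' @param n_snapshots Snapshots stored per system.
#' @param n_probe Probe parameter sets per system.
#' @param noise_sigma Lognormal noise SD (in log10 units) on synthetic
#'   csat values; 0 gives an exactly solvable problem.
#' @param box Box edge (nm) for the snapshot simulations.
#' @param n_steps Production steps for snapshot generation.
#' @return List: `systems` (each: `rset`, `probe_params`, `csat_probe`),
#'   `record` (true_params, per-system a/b, noise_sigma, seed).
#' @export
make_rescore_fixture <- function(true_params,
                                 systems = list(
                                   list(name = "polar_idp", kind = "idp",
                                        length = 20L, n_chains = 8L,
                                        composition = c(polar = 1)),
                                   list(name = "hydro_idp", kind = "idp",
                                        length = 20L, n_chains = 8L,
                                        composition = c(hydrophobic = 1)),
                                   list(name = "mixed_idp", kind = "idp",
                                        length = 24L, n_chains = 8L,
                                        composition = c(polar = 0.45,
                                                        hydrophobic = 0.35,
                                                        charged = 0.1,
                                                        aromatic = 0.1)),
                                   list(name = "bundle", kind = "folded",
                                        length = 42L, n_chains = 6L)),
                                 seed = 1L, n_snapshots = 10L, n_probe = 8L,
                                 noise_sigma = 0, box = 6.2,
                                 n_steps = 4000L) {
  params_box_ok <- box > 2 * true_params$cutoff
  if (!params_box_ok) {
    # keep the snapshot box small for speed by shortening the cutoff
    true_params <- cg_params(true_params$preset,
                             cutoff = box / 2.5,
                             eps_polar = true_params$eps_polar,
                             eps_hydrophobic = true_params$eps_hydrophobic,
                             A0_polar = true_params$A0_polar,
                             A0_hydrophobic = true_params$A0_hydrophobic,
                             lambda_surface = true_params$lambda_surface)
  }
  out_systems <- list()
  rec_ab <- list()
  for (si in seq_along(systems)) {
    sy <- systems[[si]]
    sseed <- seed + 1000L * si
    if (sy$kind == "idp") {
      seqs <- make_idp_sequence(sy$length, sy$composition, seed = sseed)
      spec <- chain_spec(sy$name, seqs, "protein", copies = sy$n_chains)
    } else {
      fx <- make_folded_fixture(sy$length, seed = sseed,
                                copies = sy$n_chains)
      spec <- fx$spec
    }
    topo <- build_topology(spec, true_params)
    st <- build_start(topo, start_config("condensate",
                                         n_chains_total = sy$n_chains,
                                         box = box, min_separation = 0.35,
                                         seed = sseed),
                      true_params)
    run <- run_config(n_equil_steps = 1000L, n_prod_steps = n_steps,
                      seed = sseed,
                      report_interval = max(1L, n_steps %/% n_snapshots))
    st <- minimize_then_equilibrate(st, run)
    tr <- run_langevin(st, run)
    frames <- tr$frames
    take <- utils::tail(seq_along(frames), n_snapshots)
    rset <- rescore_set(sy$name, topo, frames[take], box)
    u_true <- rescore(rset, true_params)
    with_local_seed(sseed + 7L, {
      a <- stats::runif(1, 0.5, 2.0)
      target <- stats::runif(1, -1.5, 0)
      b <- target - a * u_true
      csat_exp <- 10^(a * u_true + b +
                        stats::rnorm(1, sd = noise_sigma))
      probe <- lapply(seq_len(n_probe), function(k) {
        f <- stats::runif(4, 0.6, 1.4)
        lam <- min(0.7, max(0.05, true_params$lambda_surface +
                              stats::runif(1, -0.2, 0.2)))
        cg_params(true_params$preset,
                  cutoff = true_params$cutoff,
                  eps_polar = true_params$eps_polar * f[1],
                  eps_hydrophobic = true_params$eps_hydrophobic * f[2],
                  A0_polar = true_params$A0_polar * f[3],
                  A0_hydrophobic = true_params$A0_hydrophobic * f[4],
                  lambda_surface = lam)
      })
      csat_probe <- vapply(probe, function(p)
        10^(a * rescore(rset, p) + b + stats::rnorm(1, sd = noise_sigma)),
        numeric(1))
      rset$csat_exp <- csat_exp
      out_systems[[sy$name]] <- list(rset = rset, probe_params = probe,
                                      csat_probe = csat_probe)
      rec_ab[[sy$name]] <- c(a = a, b = b)
    })
  }
  list(systems = out_systems,
       record = list(true_params = unclass(true_params),
                     ab = rec_ab, noise_sigma = noise_sigma, seed = seed))
}

#' Write / read a fixture generating record
#'
#' @param record The `record` element of [make_rescore_fixture()] output.
#' @param file Path to a JSON file.
#' @return `read_fixture_record` returns the record list.
#' @export
write_fixture_record <- function(record, file) {
  jsonlite::write_json(record, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_fixture_record
#' @export
read_fixture_record <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
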