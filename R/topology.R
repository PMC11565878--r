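#' Declare a chain to be built into a topology
#'
#' @param chain_id Label for the chain.
#' @param sequence One-letter sequence string (or vector of residue codes).
#' @param kind `"protein"` or `"rna"`.
#' @param folded_ranges List of `c(start, end)` 1-based inclusive residue
#'   intervals treated as folded domains (elastic-network restrained,
#'   surface-exposure scaled). Must be sorted and non-overlapping.
#' @param ref_coords N x 3 matrix of reference coordinates (nm) covering at
#'   least every residue inside a folded range (rows for other residues may
#'   be `NA`). Required when `folded_ranges` is non-empty.
#' @param copies Number of identical copies of this chain in the system.
#' @return A `chain_spec` object.
#' @export
chain_spec <- function(chain_id, sequence, kind = c("protein", "rna"),
                       folded_ranges = list(), ref_coords = NULL,
                       copies = 1L) {
  kind <- match.arg(kind)
  types <- sequence_to_types(sequence, kind)
  n <- length(types)
  if (length(folded_ranges)) {
    fr <- do.call(rbind, lapply(folded_ranges, function(r) as.integer(r[1:2])))
    if (any(fr[, 1] > fr[, 2]) || any(fr < 1) || any(fr > n))
      stop("folded range outside sequence or reversed")
    o <- order(fr[, 1])
    fr <- fr[o, , drop = FALSE]
    if (nrow(fr) > 1 && any(fr[-1, 1] <= fr[-nrow(fr), 2]))
      stop("folded ranges overlap")
    if (is.null(ref_coords)) stop("reference coordinates required for folded ranges")
    ref_coords <- as.matrix(ref_coords)
    if (nrow(ref_coords) != n || ncol(ref_coords) != 3)
      stop("ref_coords must be an N x 3 matrix over the full sequence")
    for (k in seq_len(nrow(fr))) {
      idx <- fr[k, 1]:fr[k, 2]
      if (anyNA(ref_coords[idx, ]))
        stop("missing reference coordinates inside folded range")
    }
    folded_ranges <- lapply(seq_len(nrow(fr)), function(k) fr[k, ])
  }
  structure(list(chain_id = chain_id, sequence = types, kind = kind,
                 folded_ranges = folded_ranges, ref_coords = ref_coords,
                 copies = as.integer(copies)),
            class = "chain_spec")
}

.folded_mask <- function(spec) {
  m <- rep(FALSE, length(spec$sequence))
  for (r in spec$folded_ranges) m[r[1]:r[2]] <- TRUE
  m
}

# ENM pair scan for one chain spec: within-declared-range pairs (optionally
# across ranges), |i-j| >= 2, reference distance <= r0max.
.enm_pairs <- function(spec, r0max = 0.9, allow_cross_domain = FALSE) {
  out <- list()
  if (!length(spec$folded_ranges)) {
    return(list(pairs = matrix(integer(0), 0, 2), r0 = numeric(0)))
  }
  ranges <- spec$folded_ranges
  idx_sets <- if (allow_cross_domain) {
    list(sort(unlist(lapply(ranges, function(r) r[1]:r[2]))))
  } else {
    lapply(ranges, function(r) r[1]:r[2])
  }
  pi <- integer(0); pj <- integer(0); r0 <- numeric(0)
  for (idx in idx_sets) {
    xyz <- spec$ref_coords[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(xyz))
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        if (abs(i - j) < 2) next
        if (d[a, b] <= r0max) {
          pi <- c(pi, i); pj <- c(pj, j); r0 <- c(r0, d[a, b])
        }
      }
    }
  }
  list(pairs = cbind(pi, pj), r0 = r0)
}

#' Build the coarse-grained topology
#'
#' Expands every [chain_spec()] into beads (chain-major, residue-minor,
#' replicated `copies` times), consecutive-residue harmonic bonds
#' (l0 = 0.38 nm protein / 0.5 nm RNA), angle terms on all consecutive
#' triples, elastic-network restraints inside declared folded ranges
#' (reference distance <= 0.9 nm, sequence separation >= 2), nonbonded
#' exclusions (exactly the bonded pairs), and per-bead interaction scales
#' xi from surface exposure of the reference structure (xi = 1 outside
#' folded ranges).
#'
#' @param chains A `chain_spec` or list of them.
#' @param params A `cg_params` object (supplies l0, lambda, bead data).
#' @param enm_r0_max ENM distance threshold (nm).
#' @param allow_cross_domain Allow ENM restraints bridging two declared
#'   folded ranges of the same chain.
#' @return A `cg_topology` object: `beads` data.frame (name, type_index,
#'   chain, chain_id, resid, mass, sigma, is_folded, s_ratio, xi), `bonds`,
#'   `bond_l0`, `angles`, `angle_k`, `enm`, `enm_r0`, `exclusions`,
#'   `ref_coords` (NA where unknown), and the lambda used.
#' @export
build_topology <- function(chains, params = cg_params(),
                           enm_r0_max = 0.9, allow_cross_domain = FALSE) {
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  bt <- bead_types(params, include_sref = FALSE)
  type_of <- stats::setNames(seq_len(nrow(bt)), bt$name)

  beads <- list(); bonds <- list(); bl0 <- list(); angles <- list()
  angk <- list(); enm <- list(); enmr0 <- list(); refc <- list()
  offset <- 0L; chain_no <- 0L

  for (spec in chains) {
    n <- length(spec$sequence)
    fmask <- .folded_mask(spec)
    ep <- .enm_pairs(spec, enm_r0_max, allow_cross_domain)
    l0 <- if (spec$kind == "protein") params$l0_protein else params$l0_nucleic
    ka <- if (spec$kind == "protein") params$kangle_protein else params$kangle_nucleic
    s_ratio <- rep(NA_real_, n)
    xi <- rep(1, n)
    if (any(fmask)) {
      sr <- compute_surface_ratio(spec, params)
      s_ratio[sr$resid] <- sr$s_ratio
      xi[sr$resid] <- sr$xi
    }
    rc <- if (is.null(spec$ref_coords)) matrix(NA_real_, n, 3) else spec$ref_coords
    for (cp in seq_len(spec$copies)) {
      chain_no <- chain_no + 1L
      beads[[length(beads) + 1L]] <- data.frame(
        name = spec$sequence,
        type_index = unname(type_of[spec$sequence]),
        chain = chain_no,
        chain_id = if (spec$copies > 1L)
          paste0(spec$chain_id, "_", cp) else spec$chain_id,
        resid = seq_len(n),
        mass = unname(.MASS_AMU[spec$sequence]),
        sigma = .bead_sigma(spec$sequence),
        is_folded = fmask,
        s_ratio = s_ratio,
        xi = xi,
        stringsAsFactors = FALSE)
      if (n > 1) {
        bonds[[length(bonds) + 1L]] <- cbind(offset + 1:(n - 1), offset + 2:n)
        bl0[[length(bl0) + 1L]] <- rep(l0, n - 1)
      }
      if (n > 2) {
        angles[[length(angles) + 1L]] <-
          cbind(offset + 1:(n - 2), offset + 2:(n - 1), offset + 3:n)
        angk[[length(angk) + 1L]] <- rep(ka, n - 2)
      }
      if (nrow(ep$pairs)) {
        enm[[length(enm) + 1L]] <- ep$pairs + offset
        enmr0[[length(enmr0) + 1L]] <- ep$r0
      }
      refc[[length(refc) + 1L]] <- rc
      offset <- offset + n
    }
  }
  bondm <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  structure(list(
    beads = do.call(rbind, beads),
    bonds = bondm,
    bond_l0 = unlist(bl0, use.names = FALSE) %||% numeric(0),
    angles = if (length(angles)) do.call(rbind, angles) else matrix(integer(0), 0, 3),
    angle_k = unlist(angk, use.names = FALSE) %||% numeric(0),
    enm = if (length(enm)) do.call(rbind, enm) else matrix(integer(0), 0, 2),
    enm_r0 = unlist(enmr0, use.names = FALSE) %||% numeric(0),
    exclusions = bondm,
    ref_coords = do.call(rbind, refc),
    lambda = params$lambda_surface,
    n_chains = chain_no), class = "cg_topology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology>", nrow(x$beads), "beads,", x$n_chains, "chains,",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$enm), "ENM restraints\n")
  invisible(x)
}

#' Recompute per-bead interaction scales for a new lambda
#'
#' Used when rescoring stored conformations under candidate parameters:
#' surface ratios are fixed by the reference structure, so a changed
#' lambda only re-thresholds them.
#'
#' @param topology A `cg_topology`.
#' @param lambda New surface-exposure threshold.
#' @return The topology with updated `beads$xi` and `lambda`.
#' @export
update_xi <- function(topology, lambda) {
  b <- topology$beads
  b$xi <- interaction_scale(ifelse(is.na(b$s_ratio), 1, b$s_ratio),
                            lambda, b$is_folded)
  topology$beads <- b
  topology$lambda <- lambda
  topology
}
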