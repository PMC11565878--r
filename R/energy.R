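#' Bundle coordinates, box, topology and parameters into a system state
#'
#' @param topology A `cg_topology`.
#' @param coords N x 3 coordinates (nm); defaults to the topology's
#'   reference coordinates when they are complete.
#' @param box Orthorhombic box edge lengths (nm, length 1 or 3), or `NULL`
#'   for a non-periodic system. Periodic boxes must exceed twice the
#'   nonbonded cutoff in every direction.
#' @param params A `cg_params` object.
#' @param velocities Optional N x 3 velocities (nm/ps).
#' @return A `cg_state` object.
#' @export
system_state <- function(topology, coords = NULL, box = NULL,
                         params = cg_params(), velocities = NULL) {
  if (is.null(coords)) {
    coords <- topology$ref_coords
    if (anyNA(coords)) stop("topology has no complete reference coordinates; supply coords")
  }
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(topology$beads), ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(box)) {
    box <- rep(as.numeric(box), length.out = 3)
    if (any(box <= 2 * params$cutoff))
      stop("box edges must exceed 2 x cutoff (", 2 * params$cutoff, " nm)")
  }
  structure(list(topology = topology, coords = coords, box = box,
                 params = params, velocities = velocities),
            class = "cg_state")
}

# assemble the argument list for the compiled engine
.engine_args <- function(state) {
  topo <- state$topology
  pt <- pair_tables(state$params)
  zero2 <- matrix(integer(0), 0, 2)
  list(
    coords = state$coords,
    box = if (is.null(state$box)) c(-1, -1, -1) else state$box,
    type = as.integer(topo$beads$type_index - 1L),
    xi = as.numeric(topo$beads$xi),
    sigma = pt$sigma, epstot = pt$epstot, elec = pt$elec,
    cutoff = state$params$cutoff, kappa = state$params$kappa,
    xi_scales_elec = isTRUE(state$params$xi_scales_electrostatics),
    bonds = if (nrow(topo$bonds)) topo$bonds - 1L else zero2,
    bond_l0 = topo$bond_l0,
    kbond = state$params$kbond,
    angles = if (nrow(topo$angles)) topo$angles - 1L else matrix(integer(0), 0, 3),
    angle_k = topo$angle_k,
    enm = if (nrow(topo$enm)) topo$enm - 1L else zero2,
    enm_r0 = topo$enm_r0,
    kenm = state$params$kenm,
    exclusions = if (nrow(topo$exclusions)) topo$exclusions - 1L else zero2)
}

#' Potential energy breakdown of a configuration
#'
#' Evaluates every term of the model Hamiltonian: harmonic bonds,
#' elastic-network restraints, harmonic angles (equilibrium 180 deg), the
#' surface-scaled 10-5 short-range pair potential, and screened
#' Debye-Hueckel electrostatics, under the minimum-image convention with
#' plain truncation at the cutoff and one-bond exclusions.
#'
#' @param state A `cg_state`.
#' @param use_neighbour_list Evaluate nonbonded terms through the Verlet
#'   neighbour list instead of the direct double loop (identical result).
#' @return A `cg_energy` list: bond, angle, enm, short_range,
#'   electrostatic, total (kJ/mol).
#' @export
total_energy <- function(state, use_neighbour_list = FALSE) {
  a <- .engine_args(state)
  r <- do.call(cpp_energy_forces, c(a, list(use_neighbour_list = use_neighbour_list)))
  structure(r[c("bond", "angle", "enm", "short_range", "electrostatic",
                "total")], class = "cg_energy")
}

#' @export
print.cg_energy <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-14s %14.6f kJ/mol\n", nm, x[[nm]]))
  invisible(x)
}

#' @rdname total_energy
#' @export
bond_energy <- function(state) total_energy(state)$bond

#' @rdname total_energy
#' @export
enm_energy <- function(state) total_energy(state)$enm

#' @rdname total_energy
#' @export
angle_energy <- function(state) total_energy(state)$angle

#' @rdname total_energy
#' @export
short_range_energy <- function(state) total_energy(state)$short_range

#' @rdname total_energy
#' @export
electrostatic_energy <- function(state) total_energy(state)$electrostatic

#' Forces on every bead
#'
#' Analytic negative gradient of [total_energy()].
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces (kJ mol^-1 nm^-1).
#' @export
forces <- function(state, use_neighbour_list = FALSE) {
  a <- .engine_args(state)
  r <- do.call(cpp_energy_forces, c(a, list(use_neighbour_list = use_neighbour_list)))
  r$forces
}
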