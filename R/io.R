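# Readers/writers for standard formats: FASTA and PDB through bio3d,
# topology as a documented JSON schema, trajectories as multi-model PDB.

#' Read sequences from a FASTA file
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of one-letter sequence strings.
#' @export
read_fasta_sequences <- function(file) {
  fa <- bio3d::read.fasta(file)
  out <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  stats::setNames(as.character(out), rownames(fa$ali))
}

#' Read C-alpha reference coordinates from a PDB file
#'
#' Extracts one bead per residue (the C-alpha atom, or the P atom for
#' nucleic acids) in nm.
#'
#' @param file Path to a PDB file.
#' @param chain Optional chain identifier filter.
#' @return List: `coords` (N x 3 matrix, nm), `resnames`, `resid`.
#' @export
read_pdb_reference <- function(file, chain = NULL) {
  pdb <- bio3d::read.pdb(file)
  sel <- bio3d::atom.select(pdb, elety = c("CA", "P"), chain = chain)
  at <- pdb$atom[sel$atom, ]
  list(coords = as.matrix(at[, c("x", "y", "z")]) / 10,  # A -> nm
       resnames = at$resid, resid = at$resno)
}

#' Write a configuration as a PDB file
#'
#' One CA pseudo-atom per bead; coordinates converted nm -> Angstrom.
#'
#' @param coords N x 3 coordinates (nm).
#' @param topology A `cg_topology`.
#' @param file Output path.
#' @export
write_cg_pdb <- function(coords, topology, file) {
  b <- topology$beads
  xyz <- as.numeric(t(as.matrix(coords) * 10))
  chain_letters <- rep(c(LETTERS, letters), length.out = max(b$chain))
  bio3d::write.pdb(file = file, xyz = xyz, resno = b$resid,
                   resid = b$name, chain = chain_letters[b$chain],
                   elety = rep("CA", nrow(b)))
  invisible(file)
}

#' Write trajectory frames as a multi-model PDB
#'
#' @param traj A `cg_trajectory` with stored frames.
#' @param file Output path.
#' @export
write_trajectory_pdb <- function(traj, file) {
  topo <- traj$final$topology
  b <- topo$beads
  chain_letters <- rep(c(LETTERS, letters), length.out = max(b$chain))
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$frames[[f]] * 10
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(b)) %% 100000, b$name, chain_letters[b$chain],
      b$resid %% 10000, xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  invisible(file)
}

#' Serialize a topology to JSON
#'
#' Schema: `beads` (records), `bonds`/`bond_l0`, `angles`/`angle_k`,
#' `enm`/`enm_r0`, `exclusions`, `ref_coords`, `lambda`, `n_chains`.
#'
#' @param topology A `cg_topology`.
#' @param file Output path.
#' @export
write_topology_json <- function(topology, file) {
  payload <- list(
    beads = topology$beads,
    bonds = topology$bonds, bond_l0 = topology$bond_l0,
    angles = topology$angles, angle_k = topology$angle_k,
    enm = topology$enm, enm_r0 = topology$enm_r0,
    exclusions = topology$exclusions,
    ref_coords = topology$ref_coords,
    lambda = topology$lambda, n_chains = topology$n_chains)
  jsonlite::write_json(payload, file, digits = NA, na = "null")
  invisible(file)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  as_mat <- function(m, ncol) {
    if (is.null(m) || length(m) == 0) return(matrix(integer(0), 0, ncol))
    matrix(as.integer(m), ncol = ncol)
  }
  structure(list(
    beads = as.data.frame(p$beads),
    bonds = as_mat(p$bonds, 2), bond_l0 = as.numeric(p$bond_l0),
    angles = as_mat(p$angles, 3), angle_k = as.numeric(p$angle_k),
    enm = as_mat(p$enm, 2), enm_r0 = as.numeric(p$enm_r0),
    exclusions = as_mat(p$exclusions, 2),
    ref_coords = matrix(as.numeric(p$ref_coords), ncol = 3),
    lambda = p$lambda, n_chains = p$n_chains), class = "cg_topology")
}
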