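#' Force-field parameter sets
#'
#' Constructs the global parameter set of the coarse-grained model. Two
#' presets are shipped: `"COCOMO"` (the original IDP/RNA parameterization)
#' and `"COCOMO2"` (re-optimized against phase-separation and solubility
#' data, with surface-exposure scaling for folded domains and an added
#' aromatic-aromatic interaction bonus). Any field can be overridden via
#' `...`.
#'
#' Class-level parameters (kJ/mol unless noted):
#' \describe{
#'   \item{eps_polar, eps_hydrophobic, eps_nucleotide}{10-5 well depths per
#'     residue class. eps_ij = sqrt(eps_i eps_j).}
#'   \item{A0_polar, A0_hydrophobic, A0_nucleotide}{dimensionless per-class
#'     solvation-repulsion amplitudes entering the screened electrostatic
#'     term as A0_i * A0_j (always repulsive).}
#'   \item{lambda_surface}{surface-exposure threshold in [0,1]; residues in
#'     folded domains with S_ratio below it have interaction strength
#'     reduced linearly (see [interaction_scale()]). 1 means no scaling.}
#'   \item{eps_mod_cation_aromatic, eps_mod_cation_nucleic,
#'     eps_mod_aromatic_aromatic}{pair-class bonuses added to eps_ij inside
#'     the 10-5 bracket (Arg/Lys-Phe/Tyr/Trp 0.3, Arg/Lys-nucleotide 0.2,
#'     aromatic-aromatic 0.1 in COCOMO2).}
#'   \item{kappa}{Debye screening length (nm); 1 nm ~ 100 mM ionic strength.}
#'   \item{cutoff}{nonbonded truncation distance (nm).}
#'   \item{kbond, kenm}{harmonic bond / elastic-network force constants
#'     (kJ mol^-1 nm^-2).}
#'   \item{kangle_protein, kangle_nucleic}{harmonic angle constants
#'     (kJ mol^-1 rad^-2), equilibrium angle 180 degrees.}
#'   \item{l0_protein, l0_nucleic}{equilibrium bond lengths (nm).}
#'   \item{elec_prefactor}{prefactor of the screened electrostatic term
#'     (kJ nm mol^-1).}
#'   \item{charge_exponent}{exponent a in A_i = sign(q) 0.75 |q|^a; all
#'     standard residues carry integer charge 0 or +-1, for which any a
#'     gives A_i = +-0.75.}
#'   \item{xi_scales_electrostatics}{logical; if TRUE the surface-exposure
#'     scale xi_ij also multiplies the electrostatic term (default FALSE:
#'     xi scales the short-range term only).}
#' }
#'
#' @param preset `"COCOMO2"` (default) or `"COCOMO"`.
#' @param ... named overrides of individual fields.
#' @return An object of class `cg_params` (a named list).
#' @examples
#' p <- cg_params("COCOMO2")
#' p$eps_polar            # 0.176
#' cg_params("COCOMO", lambda_surface = 0.7)$lambda_surface
#' @export
cg_params <- function(preset = c("COCOMO2", "COCOMO"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    eps_polar = 0.40, eps_hydrophobic = 0.41, eps_nucleotide = 0.40,
    A0_polar = 0.05, A0_hydrophobic = 0.0, A0_nucleotide = 0.05,
    lambda_surface = 1.0,
    eps_mod_cation_aromatic = 0.3,
    eps_mod_cation_nucleic = 0.2,
    eps_mod_aromatic_aromatic = 0.0,
    kappa = 1.0, cutoff = 3.0,
    kbond = 4184, kenm = 500,
    kangle_protein = 4.184, kangle_nucleic = 4.184,
    l0_protein = 0.38, l0_nucleic = 0.5,
    elec_prefactor = 1.0,
    charge_exponent = 0.5,
    xi_scales_electrostatics = FALSE)
  if (preset == "COCOMO2") {
    base$eps_polar <- 0.176
    base$eps_hydrophobic <- 0.295
    base$A0_polar <- 0.0
    base$A0_hydrophobic <- 0.002
    base$lambda_surface <- 0.7
    base$eps_mod_aromatic_aromatic <- 0.1
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown)) stop("unknown parameter field(s): ",
                            paste(unknown, collapse = ", "))
  base[names(dots)] <- dots
  validate_cg_params(structure(base, class = "cg_params"))
}

validate_cg_params <- function(p) {
  stopifnot(
    p$eps_polar >= 0, p$eps_hydrophobic >= 0, p$eps_nucleotide >= 0,
    p$A0_polar >= 0, p$A0_hydrophobic >= 0, p$A0_nucleotide >= 0,
    p$eps_mod_cation_aromatic >= 0, p$eps_mod_cation_nucleic >= 0,
    p$eps_mod_aromatic_aromatic >= 0,
    p$lambda_surface >= 0, p$lambda_surface <= 1,
    p$kappa > 0, p$cutoff > 0, p$kbond > 0, p$kenm > 0)
  p
}

#' Load a parameter set from a preset name or a YAML config file
#'
#' A file config names a `preset` plus any number of field overrides; fields
#' not mentioned keep their preset values.
#'
#' @param preset Preset name, ignored when `file` is given and the file
#'   names its own preset.
#' @param file Optional path to a flat YAML mapping.
#' @return A `cg_params` object.
#' @export
load_parameter_set <- function(preset = "COCOMO2", file = NULL) {
  if (is.null(file)) return(cg_params(preset))
  cfg <- yaml::read_yaml(file)
  if (!is.list(cfg)) stop("malformed parameter config: ", file)
  if (!is.null(cfg$preset)) {
    preset <- cfg$preset
    cfg$preset <- NULL
  }
  do.call(cg_params, c(list(preset = preset), cfg))
}

#' Write a parameter set to a YAML file
#' @param params A `cg_params` object.
#' @param file Output path.
#' @export
write_parameter_set <- function(params, file) {
  yaml::write_yaml(unclass(params), file)
  invisible(file)
}

#' @export
print.cg_params <- function(x, ...) {
  cat("<cg_params> preset:", x$preset, "\n")
  flds <- setdiff(names(x), "preset")
  for (f in flds) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}

.class_eps <- function(params) c(polar = params$eps_polar,
                                 hydrophobic = params$eps_hydrophobic,
                                 nucleotide = params$eps_nucleotide)
.class_A0 <- function(params) c(polar = params$A0_polar,
                                hydrophobic = params$A0_hydrophobic,
                                nucleotide = params$A0_nucleotide)

#' Per-bead-type physical parameter table
#'
#' One row per residue/nucleotide type: bead diameter parameter sigma (nm),
#' well depth eps (kJ/mol), charge q (e), electrostatic amplitudes A
#' (signed) and A0 (>= 0), hydropathy class, reference surface area S_ref
#' (nm^2, from the ideal-helix embedding; see [reference_surface_areas()]),
#' and mass (amu).
#'
#' @param params A `cg_params` object.
#' @param include_sref Compute the S_ref column (requires the compiled SASA
#'   routine; cached after first use).
#' @return A data.frame with one row per bead type.
#' @export
bead_types <- function(params = cg_params(), include_sref = TRUE) {
  nm <- c(.AA3, .NT)
  cls <- .hydro_class(nm)
  q <- unname(.CHARGE[nm])
  A <- sign(q) * 0.75 * abs(q)^params$charge_exponent
  df <- data.frame(
    name = nm,
    sigma = .bead_sigma(nm),
    eps = unname(.class_eps(params)[cls]),
    charge = q,
    A = A,
    A0 = unname(.class_A0(params)[cls]),
    hydro_class = cls,
    mass = unname(.MASS_AMU[nm]),
    stringsAsFactors = FALSE)
  if (include_sref) df$sref <- reference_surface_areas()[nm]
  rownames(df) <- nm
  df
}

.eps_mod_pair <- function(name_i, name_j, params) {
  ca <- (name_i %in% .CATION_AA & name_j %in% .AROMATIC_AA) |
        (name_j %in% .CATION_AA & name_i %in% .AROMATIC_AA)
  cn <- (name_i %in% .CATION_AA & name_j %in% .NT) |
        (name_j %in% .CATION_AA & name_i %in% .NT)
  aa <- name_i %in% .AROMATIC_AA & name_j %in% .AROMATIC_AA
  ifelse(ca, params$eps_mod_cation_aromatic,
  ifelse(cn, params$eps_mod_cation_nucleic,
  ifelse(aa, params$eps_mod_aromatic_aromatic, 0)))
}

#' Combine two bead types into pairwise interaction parameters
#'
#' Applies the combination rules: sigma_ij = (sigma_i + sigma_j)/2,
#' eps_ij = sqrt(eps_i eps_j), xi_ij = xi_i xi_j, A_ij = A_i A_j,
#' A0_ij = A0_i A0_j, and resolves the pair-class interaction bonus
#' eps_mod_ij from the residue names (cation-aromatic, cation-nucleotide,
#' aromatic-aromatic; mutually exclusive).
#'
#' @param bead_i,bead_j Residue names (three-letter, or rows of
#'   [bead_types()]).
#' @param xi_i,xi_j Surface-exposure interaction scales of the two beads.
#' @param params A `cg_params` object.
#' @return A list with fields `sigma_ij`, `eps_ij`, `eps_mod_ij`, `xi_ij`,
#'   `A_ij`, `A0_ij`.
#' @examples
#' combine_pair("ARG", "PHE")$eps_mod_ij   # 0.3
#' @export
combine_pair <- function(bead_i, bead_j, xi_i = 1, xi_j = 1,
                         params = cg_params()) {
  bt <- bead_types(params, include_sref = FALSE)
  if (is.character(bead_i)) bead_i <- bt[toupper(bead_i), ]
  if (is.character(bead_j)) bead_j <- bt[toupper(bead_j), ]
  if (anyNA(bead_i$sigma) || anyNA(bead_j$sigma)) stop("unknown bead type")
  list(
    sigma_ij = (bead_i$sigma + bead_j$sigma) / 2,
    eps_ij = sqrt(bead_i$eps * bead_j$eps),
    eps_mod_ij = .eps_mod_pair(bead_i$name, bead_j$name, params),
    xi_ij = xi_i * xi_j,
    A_ij = bead_i$A * bead_j$A,
    A0_ij = bead_i$A0 * bead_j$A0)
}

# Dense per-type pair tables consumed by the compiled engine:
# epstot[i,j] = eps_ij + eps_mod_ij; elec[i,j] = prefactor*(A_ij + A0_ij).
pair_tables <- function(params) {
  bt <- bead_types(params, include_sref = FALSE)
  n <- nrow(bt)
  sigma <- outer(bt$sigma, bt$sigma, function(a, b) (a + b) / 2)
  eps <- sqrt(outer(bt$eps, bt$eps))
  emod <- outer(seq_len(n), seq_len(n), function(i, j)
    .eps_mod_pair(bt$name[i], bt$name[j], params))
  elec <- params$elec_prefactor *
    (outer(bt$A, bt$A) + outer(bt$A0, bt$A0))
  dimnames(sigma) <- dimnames(eps) <- dimnames(emod) <- dimnames(elec) <-
    list(bt$name, bt$name)
  list(types = bt$name, sigma = sigma, epstot = eps + emod, elec = elec,
       mass = bt$mass, bead_sigma = bt$sigma)
}
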