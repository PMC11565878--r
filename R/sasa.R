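#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA on a set of spheres: each sphere is covered with a
#' deterministic quasi-uniform point set; the accessible fraction of
#' points (those not inside any neighbouring probe-inflated sphere) gives
#' the area.
#'
#' @param coords N x 3 coordinates (nm).
#' @param radii N sphere radii (nm), excluding the probe.
#' @param probe Probe radius (nm); 0.14 nm approximates water.
#' @param n_points Surface points per sphere.
#' @return Numeric vector of per-sphere accessible areas (nm^2).
#' @export
shrake_rupley <- function(coords, radii, probe = 0.14, n_points = 960L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(radii))
  if (nrow(coords) > 1) {
    d <- stats::dist(coords)
    if (any(d < 1e-9)) stop("degenerate (coincident) coordinates")
  }
  cpp_sasa(coords, as.numeric(radii), probe, as.integer(n_points))
}

.cgphase_cache <- new.env(parent = emptyenv())

# Ideal CG alpha-helix backbone: radius 0.23 nm, rise 0.15 nm, 100 deg/residue.
.ideal_helix <- function(n, radius = 0.23, rise = 0.15, twist = 100) {
  i <- seq_len(n) - 1
  ang <- i * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), i * rise)
}

#' Reference surface areas per residue type
#'
#' S_ref for each bead type, computed once and cached: the type's bead is
#' embedded at the centre of an ideal 11-residue poly-alanine helix
#' (coarse-grained backbone geometry) and its Shrake-Rupley area recorded.
#' This mirrors the convention of referencing a residue's exposure to its
#' area in an alanine alpha-helix, evaluated at bead resolution so that
#' S_residue and S_ref share one representation.
#'
#' @param probe Probe radius (nm).
#' @param n_points Shrake-Rupley points per sphere.
#' @return Named numeric vector (nm^2) over all bead types.
#' @export
reference_surface_areas <- function(probe = 0.14, n_points = 960L) {
  key <- sprintf("sref_%g_%d", probe, n_points)
  if (!is.null(.cgphase_cache[[key]])) return(.cgphase_cache[[key]])
  nhelix <- 11L
  centre <- 6L
  xyz <- .ideal_helix(nhelix)
  types <- c(.AA3, .NT)
  sig_ala <- .bead_sigma(rep("ALA", nhelix))
  out <- vapply(types, function(tp) {
    radii <- sig_ala / 2
    radii[centre] <- .bead_sigma(tp) / 2
    shrake_rupley(xyz, radii, probe, n_points)[centre]
  }, numeric(1))
  .cgphase_cache[[key]] <- out
  out
}

#' Surface-exposure interaction scale
#'
#' Residues in folded domains interact with strength `xi = 1` when their
#' exposure ratio `S_ratio` reaches the threshold `lambda`, and linearly
#' reduced strength `S_ratio / lambda` below it (zero when fully buried).
#' Disordered residues always have `xi = 1`. `lambda = 0` disables
#' scaling.
#'
#' @param s_ratio S_residue / S_ref, >= 0 (vectorized).
#' @param lambda Threshold in [0, 1].
#' @param is_folded Logical (vectorized): bead inside a folded range.
#' @return Scale(s) in [0, 1].
#' @examples
#' interaction_scale(0.35, 0.7, TRUE)  # 0.5
#' @export
interaction_scale <- function(s_ratio, lambda, is_folded = TRUE) {
  stopifnot(all(s_ratio >= 0), lambda >= 0, lambda <= 1)
  n <- max(length(s_ratio), length(is_folded))
  s_ratio <- rep_len(s_ratio, n)
  is_folded <- rep_len(is_folded, n)
  if (lambda == 0) return(rep(1, n))
  ifelse(!is_folded, 1, pmin(1, s_ratio / lambda))
}

#' Per-residue surface exposure of a chain's folded domains
#'
#' Computes Shrake-Rupley areas on the chain's reference coordinates
#' (bead radii sigma_i/2), the exposure ratio against the per-type
#' reference areas, and the resulting interaction scale xi under the
#' parameter set's lambda. Only residues with reference coordinates enter
#' the calculation; only folded residues are reported.
#'
#' @param chain A [chain_spec()] with folded ranges and reference
#'   coordinates.
#' @param params A `cg_params` object.
#' @param probe,n_points SASA settings.
#' @return Data.frame: resid, resname, s_residue, s_ref, s_ratio, xi.
#' @export
compute_surface_ratio <- function(chain, params = cg_params(),
                                  probe = 0.14, n_points = 960L) {
  if (!length(chain$folded_ranges)) {
    return(data.frame(resid = integer(0), resname = character(0),
                      s_residue = numeric(0), s_ref = numeric(0),
                      s_ratio = numeric(0), xi = numeric(0)))
  }
  has_xyz <- !is.na(chain$ref_coords[, 1])
  xyz <- chain$ref_coords[has_xyz, , drop = FALSE]
  nm <- chain$sequence[has_xyz]
  area <- shrake_rupley(xyz, .bead_sigma(nm) / 2, probe, n_points)
  sref_all <- reference_surface_areas(probe, n_points)
  fmask <- .folded_mask(chain)[has_xyz]
  resid <- which(has_xyz)[fmask]
  nm <- nm[fmask]; area <- area[fmask]
  sref <- unname(sref_all[nm])
  s_ratio <- area / sref
  data.frame(resid = resid, resname = nm, s_residue = area, s_ref = sref,
             s_ratio = s_ratio,
             xi = interaction_scale(s_ratio, params$lambda_surface, TRUE),
             stringsAsFactors = FALSE)
}

#' Write a surface-exposure report as TSV
#' @param report Output of [compute_surface_ratio()].
#' @param file Output path.
#' @param chain_id Chain label column value.
#' @export
write_surface_report <- function(report, file, chain_id = "A") {
  out <- cbind(chain = chain_id, report)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
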