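# Per-residue physical data for the one-bead-per-residue model.
#
# Volumes (A^3): amino-acid residue volumes from Zamyatnin (1972);
# ribonucleotide-monophosphate volumes are approximate literature values.
# Bead radius r_i is the radius of the sphere with the residue's volume and
# sigma_i = 2 r_i 2^(-1/6), so the 10-5 potential crosses zero at bead contact.
# Masses are standard residue (monomer-in-chain) masses in amu.

.AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
.NT  <- c("ADE","GUA","CYT","URA")
.NT1 <- c("A","G","C","U")

.POLAR_AA <- c("ARG","ASN","ASP","CYS","GLN","GLU","HIS","LYS","SER","THR")
.HYDROPHOBIC_AA <- c("ALA","GLY","ILE","LEU","MET","PHE","PRO","TRP","TYR","VAL")
.CATION_AA <- c("ARG","LYS")
.AROMATIC_AA <- c("PHE","TYR","TRP")

.VOLUME_A3 <- c(
  ALA =  88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
  GLN = 143.8, GLU = 138.4, GLY =  60.1, HIS = 153.2, ILE = 166.7,
  LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
  SER =  89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0,
  ADE = 315.0, GUA = 323.0, CYT = 288.0, URA = 286.0)

.MASS_AMU <- c(
  ALA =  71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLN = 128.13, GLU = 129.12, GLY =  57.05, HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO =  97.12,
  SER =  87.08, THR = 101.10, TRP = 186.21, TYR = 163.18, VAL =  99.13,
  ADE = 329.21, GUA = 345.21, CYT = 305.18, URA = 306.17)

.CHARGE <- c(
  ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0,
  GLN = 0, GLU = -1, GLY = 0, HIS = 0, ILE = 0,
  LEU = 0, LYS = 1, MET = 0, PHE = 0, PRO = 0,
  SER = 0, THR = 0, TRP = 0, TYR = 0, VAL = 0,
  ADE = -1, GUA = -1, CYT = -1, URA = -1)

#' Convert a one-letter sequence to bead type names
#'
#' @param sequence Character scalar (one-letter codes) or character vector of
#'   codes (one- or three-letter).
#' @param kind `"protein"` or `"rna"`; disambiguates shared one-letter codes
#'   (e.g. "A" is Ala for proteins, adenosine for RNA).
#' @return Character vector of canonical three-letter bead type names.
#' @export
sequence_to_types <- function(sequence, kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  if (length(sequence) == 1L && nchar(sequence[1L]) > 3L ||
      (length(sequence) == 1L && kind == "protein" && !sequence %in% .AA3)) {
    sequence <- strsplit(sequence, "")[[1L]]
  }
  up <- toupper(sequence)
  if (all(nchar(up) == 1L)) {
    map <- if (kind == "protein") stats::setNames(.AA3, .AA1)
           else stats::setNames(.NT, .NT1)
    bad <- setdiff(unique(up), names(map))
    if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
    return(unname(map[up]))
  }
  valid <- if (kind == "protein") .AA3 else .NT
  bad <- setdiff(unique(up), valid)
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  up
}

.hydro_class <- function(name) {
  ifelse(name %in% .NT, "nucleotide",
         ifelse(name %in% .POLAR_AA, "polar", "hydrophobic"))
}

.bead_sigma <- function(name) {
  v_nm3 <- .VOLUME_A3[name] / 1000          # A^3 -> nm^3
  r <- (3 * v_nm3 / (4 * pi))^(1 / 3)
  unname(2 * r * 2^(-1 / 6))
}
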