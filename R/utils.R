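# Internal constants and helpers shared across modules.

# the 20 standard amino acids, 3-letter codes
.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# backbone heavy atoms; terminal oxygens are backbone, never side chain
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

# non-hydrogen polar head group atoms per residue; residues absent from this
# table are non-polar and have no polar head selection
.POLAR_HEAD_TABLE <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  ASP = c("CG", "OD1", "OD2"),
  CYS = c("SG"),
  GLN = c("CD", "OE1", "NE2"),
  GLU = c("CD", "OE1", "OE2"),
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2"),
  LYS = c("NZ"),
  SER = c("OG"),
  THR = c("OG1"),
  TRP = c("NE1"),
  TYR = c("OH")
)

# hydrogen detection: element symbol when present, else the atom-name
# convention (H..., 1H..., 2H..., 3H...)
.isHydrogen <- function(name, element = NA_character_) {
  name <- trimws(name)
  hasEl <- !is.na(element) & nzchar(trimws(element))
  el <- toupper(trimws(element))
  ifelse(hasEl, el == "H" | el == "D", grepl("^[123]?H", name))
}

.residueKey <- function(chain, resno) paste0(chain, ":", resno)

.seriesId <- function(chainA, resnameA, resnoA, chainB, resnameB, resnoB,
                      mode) {
  sprintf("%s:%s%d|%s:%s%d|%s", chainA, resnameA, resnoA,
          chainB, resnameB, resnoB, mode)
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
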