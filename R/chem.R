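# Low-level cheminformatics backend: SMILES handling, SMARTS counting and
# fingerprints via ChemmineR/ChemmineOB (OpenBabel), plus the element tables
# used for masses and van der Waals radii.

# SMARTS patterns for the two reactive groups of imine chemistry.
# A nitrogen in an amide context is excluded from the primary-amine count.
.SMARTS_ALDEHYDE <- "[CX3H1](=O)[#6]"
.SMARTS_PRIMARY_AMINE <- "[NX3;H2;!$(NC=O)]"
# Non-ring single bond between two non-terminal, non-triple-bonded atoms.
.SMARTS_ROTATABLE <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"

# Monoisotopic-independent standard atomic weights (g/mol) for the elements a
# two-component imine cage can realistically contain. "Du" is the massless
# dummy used by toy geometries (assigned unit mass so a centroid exists).
.ATOMIC_MASS <- c(
  H = 1.00794, B = 10.811, C = 12.0107, N = 14.0067, O = 15.9994,
  F = 18.9984, Si = 28.0855, P = 30.97376, S = 32.065, Cl = 35.453,
  Br = 79.904, I = 126.90447, Du = 1.0
)

.MW_WATER <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]

# Bondi van der Waals radii (A); Du falls back to 1.2 unless the structure
# carries its own per-atom radii.
.VDW_RADII <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Du = 1.20
)

# Covalent radii (A) used for fallback reference bond lengths.
.COV_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39, Du = 0.76
)

.METALS <- c(
  "Li", "Na", "K", "Rb", "Cs", "Fr", "Be", "Mg", "Ca", "Sr", "Ba", "Ra",
  "Al", "Ga", "In", "Tl", "Sn", "Pb", "Bi", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh",
  "Pd", "Ag", "Cd", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm",
  "Yb", "Lu", "Th", "U"
)

.FP_NBITS <- 2048L
.FP_RADIUS <- 1L

atomic_mass <- function(elements) {
  m <- .ATOMIC_MASS[elements]
  if (anyNA(m)) {
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

vdw_radius <- function(elements) {
  r <- .VDW_RADII[elements]
  r[is.na(r)] <- 1.5
  unname(r)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Unparseable inputs yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) NA_character_
    )
    if (is.na(out)) return(NA_character_)
    out <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
    out <- sub("\t.*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

smiles_parseable <- function(smiles) !is.na(canonical_smiles(smiles))

# One SDFset (2D, implicit H) per SMILES; errors propagate as NULL entries.
.smiles_to_sdfset <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ids <- utils::capture.output(
    out <- ChemmineR::makeUnique(ChemmineR::cid(sdf)))
  ChemmineR::cid(sdf) <- out
  sdf
}

#' Count SMARTS matches in molecules
#'
#' @param smiles Character vector of parseable SMILES.
#' @param smarts A single SMARTS pattern.
#' @return Integer vector of unique match counts.
#' @export
smarts_count <- function(smiles, smarts) {
  stopifnot(length(smarts) == 1L)
  if (length(smiles) == 0L) return(integer(0))
  sdf <- .smiles_to_sdfset(smiles)
  out <- suppressWarnings(
    ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE)
  )
  as.integer(out)
}

#' Morgan (ECFP, radius 1) fingerprints
#'
#' Computes OpenBabel ECFP2 fingerprints (circular, radius 1 - the Morgan
#' analog) and OR-folds them from 4096 to 2048 bits.
#'
#' @param smiles Character vector of parseable SMILES.
#' @param nbits Folded fingerprint length (default 2048).
#' @return A list of 0/1 integer vectors with attributes `nbits` and `radius`.
#' @export
morgan_fingerprint <- function(smiles, nbits = .FP_NBITS) {
  lapply(smiles, function(s) {
    raw <- ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", s, identity), "ECFP2"
    )
    raw <- as.integer(as.numeric(raw) != 0)
    nfold <- length(raw) %/% nbits
    if (nfold < 1L) stop("fingerprint shorter than requested fold length")
    folded <- as.integer(rowSums(matrix(raw[seq_len(nbits * nfold)],
                                        nrow = nbits)) > 0)
    structure(folded, nbits = nbits, radius = .FP_RADIUS)
  })
}

# TRUE when any atom carries a nonzero formal charge (detected from the
# "M  CHG" block of the molecule's SD record, so zwitterions are caught even
# at net charge zero).
is_charged <- function(smiles) {
  vapply(smiles, function(s) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = s)),
      error = function(e) NA_character_
    )
    if (is.na(sdf)) return(NA)
    grepl("M  CHG", sdf, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
}

# Parse a Hill formula such as "C2H8N2" -> named element counts.
parse_formula <- function(formula) {
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

contains_metal <- function(smiles) {
  vapply(smiles, function(s) {
    p <- tryCatch(
      ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", s, identity)),
      error = function(e) NULL
    )
    if (is.null(p)) return(NA)
    any(names(parse_formula(p$formula[1])) %in% .METALS)
  }, logical(1), USE.NAMES = FALSE)
}

# Bond statistics on the heavy-atom (implicit-H) connection table.
bond_stats <- function(smiles) {
  sdf <- .smiles_to_sdfset(smiles)
  rot <- smarts_count(smiles, .SMARTS_ROTATABLE)
  out <- lapply(seq_along(smiles), function(i) {
    bb <- ChemmineR::bondblock(sdf[[i]])
    n_bonds <- nrow(bb)
    n_double <- sum(bb[, 3] == 2)
    list(n_bonds = n_bonds, n_double = n_double, n_rotatable = rot[i])
  })
  out
}
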