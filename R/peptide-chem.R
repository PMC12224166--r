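# Elemental masses. Monoisotopic values are CODATA/IUPAC; average values are
# standard atomic weights. Only C,H,N,O,S occur in peptides and acyl conjugates.
.ELEMENTS <- list(
  monoisotopic = c(C = 12.000000, H = 1.007825, N = 14.003074, O = 15.994915,
                   S = 31.972071),
  average      = c(C = 12.011,    H = 1.008,    N = 14.007,    O = 15.999,
                   S = 32.06)
)

#: proton and electron masses (Da), CODATA, 6 decimals
PROTON_MASS   <- 1.007276
ELECTRON_MASS <- 0.000549

# Residue elemental compositions (the residue = amino acid minus water).
.RESIDUE_FORMULAS <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

# Kyte-Doolittle hydropathy sign: positive -> hydrophobic.
.POLARITY_DEFAULT <- c(
  A = "hydrophobic", C = "hydrophobic", F = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", M = "hydrophobic", V = "hydrophobic",
  G = "hydrophilic", S = "hydrophilic", T = "hydrophilic", P = "hydrophilic",
  Y = "hydrophilic", W = "hydrophilic", N = "hydrophilic", Q = "hydrophilic",
  D = "hydrophilic", E = "hydrophilic", K = "hydrophilic", R = "hydrophilic",
  H = "hydrophilic"
)

#' Parse an elemental formula
#'
#' Parses a compact elemental formula such as \code{"C21H37NO4"} into a named
#' count vector. Only the elements C, H, N, O and S are accepted; counts may be
#' negative (e.g. for net deltas that remove water), written as \code{"H-2O-1"}.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C2H3NO")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?(-?[0-9]+)?", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula))
    stop("malformed formula: '", formula, "'")
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (tok in tokens) {
    el <- sub("(-?[0-9]+)?$", "", tok)
    if (!el %in% names(counts))
      stop("unknown element '", el, "' in formula '", formula, "'")
    num <- sub("^[A-Za-z]+", "", tok)
    counts[el] <- counts[el] + if (nzchar(num)) as.integer(num) else 1L
  }
  counts
}

#' Mass of an elemental formula
#'
#' @param formula Formula string or named count vector from [parse_formula()].
#' @param mode `"monoisotopic"` or `"average"`.
#' @return Mass in Da.
#' @examples
#' formula_mass("H2O")
#' @export
formula_mass <- function(formula, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.ELEMENTS[[mode]][names(counts)] * counts)
}

#' Construct a peptide specification
#'
#' A peptide is described by its one-letter sequence plus a list of
#' site-specific modifications, each an elemental net delta applied at a
#' 1-based residue position. Termini default to the free peptide (H- / -OH),
#' i.e. the terminal water is always included in [monomer_mass()].
#'
#' @param sequence One-letter amino-acid string (canonical 20 codes).
#' @param modifications List of modifications, each a list with elements
#'   `site` (1-based residue index), `name`, and `formula` (net elemental
#'   delta as a string).
#' @return An object of class `peptide_spec`.
#' @seealso [liraglutide()] for the built-in lipidated analyte.
#' @examples
#' peptide_spec("GG")
#' @export
peptide_spec <- function(sequence, modifications = list()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  residues <- strsplit(sequence, "")[[1]]
  if (length(residues) < 1L) stop("empty sequence")
  bad <- setdiff(unique(residues), names(.RESIDUE_FORMULAS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  L <- length(residues)
  for (mod in modifications) {
    if (!all(c("site", "formula") %in% names(mod)))
      stop("each modification needs 'site' and 'formula'")
    if (mod$site < 1L || mod$site > L)
      stop("modification site ", mod$site, " outside 1..", L)
    parse_formula(mod$formula)  # validates elements
  }
  structure(
    list(sequence = sequence, residues = residues,
         modifications = modifications),
    class = "peptide_spec"
  )
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat("Peptide (", length(x$residues), " residues): ", x$sequence, "\n",
      sep = "")
  for (mod in x$modifications)
    cat("  mod at ", mod$site, " (", x$residues[mod$site], "): ",
        if (!is.null(mod$name)) mod$name else mod$formula,
        " [", mod$formula, "]\n", sep = "")
  invisible(x)
}

#' The liraglutide peptide specification
#'
#' Liraglutide is a 31-residue GLP-1 analogue carrying a palmitic acid (C16)
#' conjugated through a gamma-glutamate spacer to its single lysine. The
#' sequence and the conjugate are taken from the public drug monograph; the
#' net side-chain delta is one gamma-Glu residue (C5H7NO3) plus one
#' hexadecanoyl group (C16H30O), i.e. C21H37NO4. The resulting elemental
#' composition is C172H265N43O51 (monoisotopic 3748.946 Da, average
#' 3751.21 Da).
#'
#' @return A `peptide_spec` for liraglutide.
#' @examples
#' monomer_mass(liraglutide())
#' @export
liraglutide <- function() {
  peptide_spec(
    "HAEGTFTSDVSSYLEGQAAKEFIAWLVRGRG",
    modifications = list(list(site = 20L, name = "palmitoyl-gGlu",
                              formula = "C21H37NO4"))
  )
}

#' Monomer (intact peptide) mass
#'
#' Sum of residue masses plus terminal water plus all modification deltas.
#'
#' @param spec A [peptide_spec()].
#' @param mode `"monoisotopic"` or `"average"`.
#' @return Mass in Da.
#' @examples
#' monomer_mass(peptide_spec("G"))  # 75.03203
#' @export
monomer_mass <- function(spec, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "peptide_spec"))
  res <- sum(vapply(.RESIDUE_FORMULAS[spec$residues], formula_mass,
                    numeric(1), mode = mode))
  mods <- sum(vapply(spec$modifications,
                     function(m) formula_mass(m$formula, mode = mode),
                     numeric(1)))
  res + formula_mass("H2O", mode = mode) + mods
}

#' m/z of a protonated or charge-reduced ion
#'
#' For a protonated species, m/z = (M + z * m_p) / z. Electron capture
#' without dissociation (charge reduction) lowers the charge of a precursor
#' by `k` while the mass gains `k` electron masses: the spray-deposited
#' protons stay on the ion. In that case `z` is the precursor charge and the
#' returned m/z is that of the (z - k)+ product.
#'
#' @param mass Neutral mass in Da.
#' @param z Charge (protonated species) or precursor charge (when `k > 0`).
#' @param k Number of electrons captured (default 0, plain protonation).
#' @return m/z in Th.
#' @examples
#' mz_of(monomer_mass(liraglutide()), 3)        # ~1250.66, i.e. "m/z 1251"
#' mz_of(monomer_mass(liraglutide()), 3, k = 1) # ~1876, the 2+ product
#' @export
mz_of <- function(mass, z, k = 0L) {
  stopifnot(length(mass) >= 1L, all(mass >= 0))
  if (any(z < 1L) || any(z != round(z))) stop("z must be a positive integer")
  if (any(k < 0L)) stop("k must be >= 0")
  if (any(k >= z)) stop("k must be < z: a fully neutralized ion has no m/z")
  (mass + z * PROTON_MASS + k * ELECTRON_MASS) / (z - k)
}

#' Residue polarity classification
#'
#' Classifies a residue of a peptide as hydrophobic or hydrophilic. The
#' default table follows the sign of the Kyte-Doolittle hydropathy scale
#' (positive values hydrophobic). A residue carrying an acyl conjugate is
#' hydrophobic regardless of the bare residue's class: the lipid tail
#' dominates its interaction character.
#'
#' @param spec A [peptide_spec()].
#' @param site 1-based residue index.
#' @param table Optional named character vector overriding the default
#'   residue -> class table.
#' @return `"hydrophobic"` or `"hydrophilic"`.
#' @examples
#' classify_residue(liraglutide(), 6)   # Phe -> hydrophobic
#' classify_residue(liraglutide(), 20)  # conjugated Lys -> hydrophobic
#' @export
classify_residue <- function(spec, site, table = polarity_table()) {
  stopifnot(inherits(spec, "peptide_spec"))
  L <- length(spec$residues)
  if (site < 1L || site > L) stop("site ", site, " outside 1..", L)
  mod_sites <- vapply(spec$modifications, function(m) m$site, numeric(1))
  if (site %in% mod_sites) return("hydrophobic")
  unname(table[spec$residues[site]])
}

#' Default residue polarity table
#'
#' @return Named character vector residue code -> class.
#' @export
polarity_table <- function() .POLARITY_DEFAULT
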