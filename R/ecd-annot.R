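# Theoretical c/z fragment ladder for a modified peptide, ppm matching of
# observed neutral masses, coverage maps and monomer-vs-oligomer differential
# accounting.

.NH3 <- 17.026549   # N + 3H, monoisotopic
.H2O <- 18.010565
.H   <- 1.007825

#' Theoretical c / z-dot fragment ladder
#'
#' ECD cleaves the backbone N-Calpha bond, producing N-terminal c ions and
#' C-terminal z-radical (z-dot) ions. Neutral masses: c_i is the sum of the
#' first i residue masses (plus their modifications) plus NH3;
#' z-dot_j is the complementary piece, z-dot_j = (M + H) - c_(L-j), where M
#' is the monomer mass and H a hydrogen atom. Both series run over cleavage
#' counts 1..L-1. A fragment contains the conjugate iff it spans the
#' modified site. Monoisotopic masses throughout (fragments are
#' isotopically resolved). Even-electron z+1 ions can be emitted instead via
#' `z_plus_one`.
#'
#' @param spec A [peptide_spec()].
#' @param z_plus_one If `TRUE`, report even-electron z+1 masses
#'   (z-dot + H) instead of radical z-dot.
#' @return Data frame: `type` ("c"/"z"), `index`, `mass`,
#'   `contains_conjugate`.
#' @export
theoretical_ladder <- function(spec, z_plus_one = FALSE) {
  stopifnot(inherits(spec, "peptide_spec"))
  L <- length(spec$residues)
  if (L < 2L) stop("need at least 2 residues to fragment")
  res_mass <- vapply(.RESIDUE_FORMULAS[spec$residues], formula_mass,
                     numeric(1), mode = "monoisotopic")
  mod_mass <- numeric(L)
  for (mod in spec$modifications)
    mod_mass[mod$site] <- mod_mass[mod$site] +
      formula_mass(mod$formula, mode = "monoisotopic")
  cum <- cumsum(res_mass + mod_mass)
  M <- cum[L] + .H2O
  c_mass <- cum[1:(L - 1)] + .NH3
  z_mass <- (M + .H) - c_mass[(L - 1):1]
  if (z_plus_one) z_mass <- z_mass + .H
  mod_sites <- vapply(spec$modifications, function(m) m$site, numeric(1))
  c_conj <- vapply(1:(L - 1), function(i) any(mod_sites <= i), logical(1))
  z_conj <- vapply(1:(L - 1), function(j) any(mod_sites >= L - j + 1),
                   logical(1))
  rbind(
    data.frame(type = "c", index = 1:(L - 1), mass = c_mass,
               contains_conjugate = c_conj),
    data.frame(type = "z", index = 1:(L - 1), mass = z_mass,
               contains_conjugate = z_conj)
  )
}

#' Match observed neutral masses against a fragment ladder
#'
#' Each observed mass is matched to the ladder entry with the smallest
#' absolute ppm error within `ppm_tol` (boundary inclusive). Ties at
#' identical |ppm| are broken toward the c series, then the lower index.
#'
#' @param observed Numeric vector of neutral masses (Da).
#' @param ladder Data frame from [theoretical_ladder()].
#' @param ppm_tol Tolerance in ppm.
#' @return List with `matches` (data.frame: observed, type, index, mass,
#'   contains_conjugate, ppm_error) and `unmatched` (numeric vector).
#' @export
match_fragments <- function(observed, ladder, ppm_tol = 20) {
  if (ppm_tol <= 0) stop("ppm_tol must be > 0")
  # rank ladder so that order() tie-breaks fall toward c, then lower index
  lad <- ladder[order(ladder$type != "c", ladder$index), , drop = FALSE]
  rows <- list(); un <- numeric(0)
  for (m in observed) {
    ppm <- (m - lad$mass) / lad$mass * 1e6
    ok <- which(abs(ppm) <= ppm_tol)
    if (!length(ok)) { un <- c(un, m); next }
    best <- ok[order(abs(ppm[ok]))][1L]
    rows[[length(rows) + 1L]] <- data.frame(
      observed = m, type = lad$type[best], index = lad$index[best],
      mass = lad$mass[best], contains_conjugate = lad$contains_conjugate[best],
      ppm_error = ppm[best])
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observed = numeric(0), type = character(0), index = integer(0),
               mass = numeric(0), contains_conjugate = logical(0),
               ppm_error = numeric(0))
  list(matches = matches, unmatched = un)
}

#' Summarize fragment matches into a coverage map
#'
#' Cleavage sites are numbered 1..L-1 from the N-terminus; c_i covers site
#' i and z_j covers site L-j. Counts are over unique (type, index) pairs --
#' multiple observations (e.g. different charge states) of the same fragment
#' count once.
#'
#' @param matches Match data frame (the `matches` element of
#'   [match_fragments()]).
#' @param ladder The ladder the matches came from (defines L and conjugate
#'   flags).
#' @return List of class `coverage_map`: `L`, `c_detected`, `z_detected`
#'   (logical vectors over cleavage sites), and `counts` (total, c, z,
#'   conjugate).
#' @export
coverage_summary <- function(matches, ladder) {
  L <- max(ladder$index) + 1L
  uniq <- unique(matches[, c("type", "index", "contains_conjugate")])
  c_det <- rep(FALSE, L - 1L); z_det <- rep(FALSE, L - 1L)
  ci <- uniq$index[uniq$type == "c"]
  zj <- uniq$index[uniq$type == "z"]
  c_det[ci] <- TRUE
  z_det[L - zj] <- TRUE
  structure(list(
    L = L, c_detected = c_det, z_detected = z_det,
    counts = c(total = nrow(uniq),
               c = sum(uniq$type == "c"),
               z = sum(uniq$type == "z"),
               conjugate = sum(uniq$contains_conjugate))
  ), class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat("Coverage map (", x$L, " residues): ", x$counts["total"],
      " fragments (", x$counts["c"], " c, ", x$counts["z"], " z; ",
      x$counts["conjugate"], " conjugate-containing)\n", sep = "")
  invisible(x)
}

#' Differential coverage between two maps
#'
#' Reports cleavage sites detected in map A but lost in map B, per ion
#' type, and summarizes how contiguously the lost z sites sit at the
#' C-terminus (the longest run of lost z cleavages ending at the last
#' site). Sites losing z detection in the oligomeric form are flagged
#' "restricted/protected": reduced z-ion release marks buried or
#' motion-restricted C-terminal regions.
#'
#' @param map_a,map_b `coverage_map` objects from the same peptide (A is
#'   the reference, typically the monomer).
#' @return List: `c_lost`, `z_lost` (site indices), `z_cterm_run` (longest
#'   lost-z suffix run length), `flag`.
#' @export
differential_coverage <- function(map_a, map_b) {
  if (map_a$L != map_b$L) stop("coverage maps are from different peptides")
  c_lost <- which(map_a$c_detected & !map_b$c_detected)
  z_lost <- which(map_a$z_detected & !map_b$z_detected)
  # longest suffix (C-terminal) run of sites that are lost in B among those
  # detected in A
  run <- 0L
  for (s in (map_a$L - 1L):1L) {
    if (map_a$z_detected[s] && !map_b$z_detected[s]) run <- run + 1L
    else if (map_a$z_detected[s]) break
  }
  list(c_lost = c_lost, z_lost = z_lost, z_cterm_run = run,
       flag = if (length(z_lost)) "restricted/protected" else "none")
}

#' Infer charge and neutral mass from isotope spacing
#'
#' A minimal isotope-envelope reader for isotopically resolved fragment
#' envelopes: the charge is the reciprocal of the median m/z spacing
#' (isotope mass difference 1.00235 Da), and the neutral (monoisotopic)
#' mass follows from the lowest-m/z centroid. Envelopes whose spacings
#' spread by more than 20% are rejected as inconsistent.
#'
#' @param mz Centroid m/z values of one isotope envelope (>= 2 peaks).
#' @return List `z`, `neutral_mass`.
#' @export
charge_from_isotope_spacing <- function(mz) {
  if (length(mz) < 2L) stop("need >= 2 isotope peaks")
  mz <- sort(mz)
  d <- diff(mz)
  md <- stats::median(d)
  if ((max(d) - min(d)) / md > 0.2)
    stop("inconsistent isotope spacings (>20% spread): not a single envelope")
  z <- as.integer(round(1.00235 / md))
  if (z < 1L) stop("spacing too wide for an integer charge")
  list(z = z, neutral_mass = z * (mz[1] - PROTON_MASS))
}

#' Text coverage diagram
#'
#' Prints the sequence with tick marks at detected c (above) and z (below)
#' cleavage sites, and a dashed marker at modified residues.
#'
#' @param map A `coverage_map`.
#' @param spec The peptide the map describes.
#' @return The diagram lines, invisibly; printed as a side effect.
#' @export
coverage_diagram <- function(map, spec) {
  res <- spec$residues
  L <- length(res)
  stopifnot(L == map$L)
  mod_sites <- vapply(spec$modifications, function(m) m$site, numeric(1))
  seq_line <- paste(res, collapse = " ")
  mark <- function(det) {
    s <- rep(" ", 2 * L - 1)
    s[2 * which(det)] <- "|"
    paste(s, collapse = "")
  }
  mod_line <- {
    s <- rep(" ", 2 * L - 1)
    s[2 * mod_sites - 1] <- "-"
    paste(s, collapse = "")
  }
  lines <- c(paste0("c: ", mark(map$c_detected)),
             paste0("   ", seq_line),
             paste0("   ", mod_line),
             paste0("z: ", mark(map$z_detected)))
  cat(lines, sep = "\n")
  invisible(lines)
}
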