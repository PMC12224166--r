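# Peak picking and oligomer-state assignment for conventional native MS,
# plus time-course abundance tracking.

#' Pick peaks from a profile spectrum
#'
#' Local maxima above `min_snr` times a robust noise estimate
#' (1.4826 * MAD of the profile intensities) are centroided by the
#' intensity-weighted mean over the apex window; maxima closer than
#' `min_spacing` are merged into the taller one.
#'
#' @param spectrum Data frame with columns `mz` (sorted ascending) and
#'   `intensity`.
#' @param min_snr Signal-to-noise threshold.
#' @param min_spacing Minimum peak separation in Th.
#' @param window Half-width (grid points) of the centroiding window.
#' @return Data frame with columns `mz`, `intensity` (apex height), one row
#'   per peak; zero rows for a flat spectrum.
#' @export
pick_peaks <- function(spectrum, min_snr = 3, min_spacing = 2, window = 3L) {
  stopifnot(all(c("mz", "intensity") %in% names(spectrum)))
  if (is.unsorted(spectrum$mz, strictly = TRUE))
    stop("profile spectrum must be sorted by m/z")
  y <- spectrum$intensity
  noise <- 1.4826 * stats::mad(y, constant = 1)
  if (noise <= 0) noise <- max(stats::sd(y), .Machine$double.eps)
  thr <- min_snr * noise
  m <- length(y)
  if (m < 3L) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  apex <- which(y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m]) + 1L
  apex <- apex[y[apex] > thr]
  if (!length(apex)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  # merge maxima closer than min_spacing, keeping the taller
  apex <- apex[order(spectrum$mz[apex])]
  keep <- rep(TRUE, length(apex))
  i <- 1L
  while (i < length(apex)) {
    j <- i + 1L
    if (spectrum$mz[apex[j]] - spectrum$mz[apex[i]] < min_spacing) {
      if (y[apex[i]] >= y[apex[j]]) keep[j] <- FALSE else keep[i] <- FALSE
      apex <- apex[keep[seq_along(apex)]]
      keep <- rep(TRUE, length(apex))
      i <- max(i - 1L, 1L)
    } else i <- j
  }
  cen <- vapply(apex, function(a) {
    # Gaussian (parabolic-in-log) apex interpolation; exact for a sampled
    # Gaussian peak, robust fallback to the intensity-weighted mean
    if (a > 1L && a < m && y[a - 1L] > 0 && y[a + 1L] > 0 && y[a] > 0) {
      l1 <- log(y[a - 1L]); l2 <- log(y[a]); l3 <- log(y[a + 1L])
      den <- l1 - 2 * l2 + l3
      if (den < 0) {
        delta <- 0.5 * (l1 - l3) / den
        if (abs(delta) <= 1)
          return(spectrum$mz[a] + delta *
                   (spectrum$mz[min(m, a + 1L)] - spectrum$mz[a]))
      }
    }
    lo <- max(1L, a - window); hi <- min(m, a + window)
    w <- y[lo:hi]
    sum(spectrum$mz[lo:hi] * w) / sum(w)
  }, numeric(1))
  data.frame(mz = cen, intensity = y[apex])
}

# Oligomer mass rule: monoisotopic below n = 9 (isotopically resolvable),
# average at and above (unresolved envelopes).
.oligomer_mass <- function(n, m_mono, m_avg) n * ifelse(n <= 8, m_mono, m_avg)

#' Assign oligomer states to picked peaks
#'
#' Enumerates all (n, z) candidates whose theoretical m/z lies within
#' `ppm_tol` of an observed peak. A candidate's support is the number of
#' distinct peaks consistent with the same oligomer state n at any charge
#' (its charge-state series). Candidates with support below `s_min` are
#' dropped unless that would leave a peak unexplained -- a lone peak cannot
#' resolve the n <-> 2n, z <-> 2z degeneracy, so for it all candidates are
#' retained and the tie-breaks decide. Per peak, candidates are ranked by
#' larger support, then smaller |ppm|, then smaller n (parsimony: exact
#' mass-multiple degeneracies are resolved toward the simpler species).
#'
#' @param peaks Data frame from [pick_peaks()] (columns `mz`, `intensity`).
#' @param spec Peptide specification providing monomer masses.
#' @param n_max,z_max Search bounds.
#' @param ppm_tol Matching tolerance in ppm.
#' @param s_min Minimum charge-series support.
#' @return Data frame with one row per assigned peak: `n`, `z`, `mz_obs`,
#'   `mz_theo`, `ppm_error`, `support`, `intensity`.
#' @export
assign_oligomer_states <- function(peaks, spec = liraglutide(), n_max = 20L,
                                   z_max = 30L, ppm_tol = 50, s_min = 2L) {
  if (!nrow(peaks)) stop("no peaks to assign")
  if (ppm_tol <= 0) stop("ppm_tol must be > 0")
  m_mono <- monomer_mass(spec, "monoisotopic")
  m_avg <- monomer_mass(spec, "average")
  if (m_mono <= 0) stop("monomer mass must be > 0")

  grid <- expand.grid(n = seq_len(n_max), z = seq_len(z_max))
  grid$mz_theo <- mz_of(.oligomer_mass(grid$n, m_mono, m_avg), grid$z)

  cand <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    ppm <- (peaks$mz[i] - grid$mz_theo) / grid$mz_theo * 1e6
    sel <- abs(ppm) <= ppm_tol
    if (!any(sel)) return(NULL)
    data.frame(peak = i, n = grid$n[sel], z = grid$z[sel],
               mz_obs = peaks$mz[i], mz_theo = grid$mz_theo[sel],
               ppm_error = ppm[sel], intensity = peaks$intensity[i])
  }))
  if (is.null(cand))
    return(data.frame(n = integer(0), z = integer(0), mz_obs = numeric(0),
                      mz_theo = numeric(0), ppm_error = numeric(0),
                      support = integer(0), intensity = numeric(0)))
  # support: distinct peaks in the same-n series
  supp <- tapply(cand$peak, cand$n, function(p) length(unique(p)))
  cand$support <- as.integer(supp[as.character(cand$n)])

  out <- do.call(rbind, lapply(split(cand, cand$peak), function(cc) {
    ok <- cc[cc$support >= s_min, , drop = FALSE]
    if (!nrow(ok)) ok <- cc
    ok[order(-ok$support, abs(ok$ppm_error), ok$n)[1L], , drop = FALSE]
  }))
  rownames(out) <- NULL
  out[, c("n", "z", "mz_obs", "mz_theo", "ppm_error", "support", "intensity")]
}

#' Time-course oligomer abundance table
#'
#' Aggregates per-time-point assignments into intensity fractions per state
#' and reports the two diagnostic band fractions: small oligomers
#' (n = 2-8) and building blocks (n = 13-17).
#'
#' @param assignments Named list (names = time labels) of assignment data
#'   frames from [assign_oligomer_states()].
#' @return List with `table` (data.frame: time, n, fraction) and `bands`
#'   (data.frame: time, small_2_8, block_13_17).
#' @export
timecourse_abundance <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) >= 1L)
  rows <- list(); bands <- list()
  for (tp in names(assignments)) {
    a <- assignments[[tp]]
    tot <- sum(a$intensity)
    if (!is.finite(tot) || tot <= 0)
      stop("all-zero intensities at time point '", tp, "'")
    fr <- tapply(a$intensity, a$n, sum) / tot
    rows[[tp]] <- data.frame(time = tp, n = as.integer(names(fr)),
                             fraction = as.numeric(fr))
    st <- as.integer(names(fr))
    bands[[tp]] <- data.frame(
      time = tp,
      small_2_8 = sum(fr[st >= 2 & st <= 8]),
      block_13_17 = sum(fr[st >= 13 & st <= 17])
    )
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       bands = do.call(rbind, c(bands, make.row.names = FALSE)))
}

#' Read / write centroid spectra as two-column CSV
#'
#' @param x Data frame with `mz`, `intensity` columns (for writing).
#' @param path File path.
#' @return `read_spectrum_csv` returns an `ms_spectrum` data frame.
#' @export
write_spectrum_csv <- function(x, path) {
  utils::write.csv(x[, c("mz", "intensity")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("mz", "intensity") %in% names(x)))
  structure(x[order(x$mz), c("mz", "intensity")],
            class = c("ms_spectrum", "data.frame"))
}
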