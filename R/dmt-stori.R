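# Single-ion (STORI) slope fitting, charge assignment with bin-occupancy
# filtering, mass/state computation, state-domain region segmentation, and
# direct mass histograms.

#' Fit the STORI slope of one ion trace
#'
#' Ordinary least squares of cumulative intensity against analysis time. The
#' slope (intensity / s) is proportional to the ion's charge; the fit r2 and
#' the trace duration are the quality metrics used downstream.
#'
#' @param t Sample times (s), strictly increasing.
#' @param y Cumulative intensity at those times.
#' @return List `slope`, `r2`, `duration` (= max(t)).
#' @export
fit_stori_slope <- function(t, y) {
  if (length(t) < 3L) stop("trace too short: need >= 3 samples")
  stopifnot(length(t) == length(y))
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  tm <- mean(t); ym <- mean(y)
  slope <- sum((t - tm) * (y - ym)) / sum((t - tm)^2)
  ss_res <- sum((y - ym - slope * (t - tm))^2)
  ss_tot <- sum((y - ym)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = slope, r2 = r2, duration = max(t))
}

#' Fit STORI slopes for a full trace set
#'
#' @param traces Long data frame from [gen_ion_traces()] (columns `ion_id`,
#'   `t`, `cumulative_intensity`, `mz`, optionally `true_z`, `true_n`).
#' @return Data frame of ion records: `ion_id`, `mz`, `slope`, `fit_r2`,
#'   `duration` (plus any truth columns present). Traces with fewer than 3
#'   samples are flagged `too_short` and get NA fits.
#' @export
fit_stori_slopes <- function(traces) {
  stopifnot(all(c("ion_id", "t", "cumulative_intensity", "mz") %in%
                  names(traces)))
  sp <- split(traces, traces$ion_id)
  rows <- lapply(sp, function(tr) {
    rec <- data.frame(ion_id = tr$ion_id[1], mz = tr$mz[1])
    if (!is.null(tr$true_z)) rec$true_z <- tr$true_z[1]
    if (!is.null(tr$true_n)) rec$true_n <- tr$true_n[1]
    if (nrow(tr) < 3L) {
      rec$slope <- NA_real_; rec$fit_r2 <- NA_real_
      rec$duration <- max(tr$t); rec$flag <- "too_short"
    } else {
      f <- fit_stori_slope(tr$t, tr$cumulative_intensity)
      rec$slope <- f$slope; rec$fit_r2 <- f$r2
      rec$duration <- f$duration; rec$flag <- NA_character_
    }
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$ion_id), ]
}

#' Assign integer charges to ion records
#'
#' The raw charge is `slope / k_cal`. Ions failing the quality filters
#' (fit r2, duration) are rejected; surviving raw charges are histogrammed
#' in bins of width `bin_size` (anchored at 0) and ions falling in bins with
#' fewer than `min_ions` occupants are discarded -- this is the bin-size /
#' minimum-ion filtering that suppresses spurious tail assignments.
#' Survivors get `z_assigned = round(slope / k_cal)`.
#'
#' @param records Data frame from [fit_stori_slopes()].
#' @param k_cal Slope-per-charge calibration constant (> 0).
#' @param bin_size Charge-bin width.
#' @param min_ions Minimum occupancy of a charge bin.
#' @param min_r2 Minimum fit r2.
#' @param min_duration Minimum trace duration (s); default half the maximum
#'   duration in the record set.
#' @return `records` with columns `z_raw`, `z_assigned` (NA when rejected)
#'   and `reject_reason`.
#' @export
assign_charge <- function(records, k_cal = 1, bin_size = 0.5, min_ions = 3L,
                          min_r2 = 0.995, min_duration = NULL) {
  if (k_cal <= 0) stop("k_cal must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (is.null(min_duration))
    min_duration <- 0.5 * max(records$duration, na.rm = TRUE)
  records$z_raw <- records$slope / k_cal
  records$z_assigned <- NA_integer_
  records$reject_reason <- NA_character_

  bad <- !is.na(records$flag)
  records$reject_reason[bad] <- records$flag[bad]
  low_r2 <- !bad & records$fit_r2 < min_r2
  records$reject_reason[low_r2] <- "low_r2"
  short <- !bad & !low_r2 & records$duration < min_duration
  records$reject_reason[short] <- "short_duration"

  ok <- is.na(records$reject_reason)
  if (any(ok)) {
    bin <- floor(records$z_raw[ok] / bin_size)
    occ <- table(bin)
    sparse <- bin %in% as.numeric(names(occ)[occ < min_ions])
    idx <- which(ok)
    records$reject_reason[idx[sparse]] <- "sparse_bin"
    keep <- idx[!sparse]
    records$z_assigned[keep] <- as.integer(round(records$z_raw[keep]))
  }
  records
}

#' Compute ion mass and oligomer state
#'
#' Mass is `z * (mz - m_proton)` (electron mass neglected at oligomer
#' scale); the state is the nearest monomer multiple provided the residual
#' is within `state_tol` monomer masses, otherwise the state stays
#' unassigned.
#'
#' @param records Data frame with `mz` and `z_assigned`.
#' @param monomer_mass_avg Average monomer mass (Da).
#' @param state_tol Maximum |mass - n * M| as a fraction of M.
#' @return `records` with `mass` and `n_state` columns (NA where charge or
#'   state is unassigned).
#' @export
ion_mass_and_state <- function(records, monomer_mass_avg, state_tol = 0.25) {
  stopifnot(monomer_mass_avg > 0)
  z <- records$z_assigned
  records$mass <- ifelse(is.na(z), NA_real_, z * (records$mz - PROTON_MASS))
  n <- round(records$mass / monomer_mass_avg)
  ok <- !is.na(n) & n >= 1 &
    abs(records$mass - n * monomer_mass_avg) <= state_tol * monomer_mass_avg
  records$n_state <- ifelse(ok, as.integer(n), NA_integer_)
  records
}

#' Segment the oligomer-state axis into occupied regions
#'
#' Contiguous runs of occupied states separated by at least `min_gap` empty
#' states become regions, ordered by state. Segmentation depends only on
#' which states are occupied, so it is invariant to histogram rescaling and
#' idempotent.
#'
#' @param states Integer vector of assigned states (one entry per ion), or a
#'   named count vector/table (names = states).
#' @param min_gap Minimum number of empty states separating two regions.
#' @return Data frame with `region`, `state_lo`, `state_hi`, `ion_count`;
#'   zero rows for an empty input.
#' @export
segment_state_regions <- function(states, min_gap = 3L) {
  if (min_gap < 1L) stop("min_gap must be >= 1")
  if (is.table(states) || !is.null(names(states))) {
    counts <- as.numeric(states)
    vals <- as.integer(names(states))
  } else {
    states <- states[!is.na(states)]
    if (!length(states))
      return(data.frame(region = character(0), state_lo = integer(0),
                        state_hi = integer(0), ion_count = integer(0)))
    tb <- table(states)
    counts <- as.numeric(tb)
    vals <- as.integer(names(tb))
  }
  keep <- counts > 0
  vals <- vals[keep]; counts <- counts[keep]
  if (!length(vals))
    return(data.frame(region = character(0), state_lo = integer(0),
                      state_hi = integer(0), ion_count = integer(0)))
  o <- order(vals); vals <- vals[o]; counts <- counts[o]
  gap <- c(Inf, diff(vals) - 1L)          # empty states before each value
  grp <- cumsum(gap >= min_gap)
  lo <- tapply(vals, grp, min)
  hi <- tapply(vals, grp, max)
  cnt <- tapply(counts, grp, sum)
  data.frame(region = as.roman(seq_along(lo)) |> as.character(),
             state_lo = as.integer(lo), state_hi = as.integer(hi),
             ion_count = as.integer(cnt))
}

#' Direct mass histogram with per-region modal states
#'
#' @param records Data frame from [ion_mass_and_state()].
#' @param mass_bin Histogram bin width in Da.
#' @param min_gap Region-segmentation gap (states), passed through.
#' @return List with `histogram` (data.frame: mass_lo, mass_hi, count),
#'   `regions` (segmentation with an added `modal_n` column), and
#'   `n_records` (number of mass-assigned ions).
#' @export
direct_mass_histogram <- function(records, mass_bin = 2000, min_gap = 3L) {
  if (mass_bin <= 0) stop("mass_bin must be > 0")
  rec <- records[!is.na(records$mass), , drop = FALSE]
  if (!nrow(rec)) stop("no mass-assigned records")
  bin <- floor(rec$mass / mass_bin)
  tb <- table(bin)
  hist <- data.frame(mass_lo = as.numeric(names(tb)) * mass_bin,
                     mass_hi = (as.numeric(names(tb)) + 1) * mass_bin,
                     count = as.integer(tb))
  st <- rec$n_state[!is.na(rec$n_state)]
  regions <- segment_state_regions(st, min_gap = min_gap)
  if (nrow(regions)) {
    regions$modal_n <- vapply(seq_len(nrow(regions)), function(i) {
      s <- st[st >= regions$state_lo[i] & st <= regions$state_hi[i]]
      tbs <- table(s)
      as.integer(names(tbs)[which.max(tbs)])
    }, integer(1))
  }
  list(histogram = hist, regions = regions, n_records = nrow(rec))
}

#' Run the full single-ion pipeline on a trace set
#'
#' Convenience wrapper: slope fits, charge assignment, mass/state
#' computation, region segmentation and direct mass histogram.
#'
#' @param traces Long trace data frame (see [gen_ion_traces()]).
#' @param spec Peptide specification for the average monomer mass.
#' @param k_cal,bin_size,min_ions,min_r2,min_duration See [assign_charge()].
#' @param state_tol See [ion_mass_and_state()].
#' @param min_gap,mass_bin See [direct_mass_histogram()].
#' @return List `records`, `regions`, `histogram`.
#' @export
dmt_pipeline <- function(traces, spec = liraglutide(), k_cal = 1,
                         bin_size = 0.5, min_ions = 3L, min_r2 = 0.995,
                         min_duration = NULL, state_tol = 0.25,
                         min_gap = 3L, mass_bin = 2000) {
  rec <- fit_stori_slopes(traces)
  rec <- assign_charge(rec, k_cal = k_cal, bin_size = bin_size,
                       min_ions = min_ions, min_r2 = min_r2,
                       min_duration = min_duration)
  rec <- ion_mass_and_state(rec, monomer_mass(spec, "average"),
                            state_tol = state_tol)
  dh <- direct_mass_histogram(rec, mass_bin = mass_bin, min_gap = min_gap)
  list(records = rec, regions = dh$regions, histogram = dh$histogram)
}
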