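# Seeded generators for every input the analysis stages consume: oligomer
# time-course abundances, native profile spectra, single-ion cumulative
# intensity traces, and ECD fragment observations.

#' Kinetic parameters of the tiered oligomerization model
#'
#' The generator's kinetic model is a mass-action aggregation/fragmentation
#' scheme with three tiers: monomer and small oligomers (n = 2-8) grow by
#' monomer addition; pairs of small oligomers fuse into "building-block"
#' oligomers (n = 12-18); building blocks pair irreversibly into high
#' molecular weight (HMW) blocks-of-blocks. Shedding and splitting reverse
#' the first two tiers. All rate constants are per (monomer-equivalent
#' concentration) per minute.
#'
#' @param k_add Monomer addition onto monomer/small oligomers (n = 1-7).
#' @param k_add2 Slow monomer addition onto building blocks (n = 12-17);
#'   this is the channel that lets n = 17 emerge at long incubation.
#' @param k_shed Monomer shedding from n = 2-9 species.
#' @param k_fuse Fusion of two small oligomers whose sizes sum to 12-18.
#' @param k_split Splitting of a building block into two near-halves.
#' @param k_pair Pairing of two building blocks into an HMW species.
#' @param n_max Largest tracked state.
#' @return List of class `kinetic_params`.
#' @export
kinetic_params <- function(k_add = 1.5, k_add2 = 0.35, k_shed = 0.03,
                           k_fuse = 25, k_split = 0.002, k_pair = 0.02,
                           n_max = 36L) {
  p <- list(k_add = k_add, k_add2 = k_add2, k_shed = k_shed, k_fuse = k_fuse,
            k_split = k_split, k_pair = k_pair, n_max = as.integer(n_max))
  rates <- unlist(p[1:6])
  if (any(rates < 0)) stop("rate constants must be >= 0")
  if (p$n_max < 18L) stop("n_max must be >= 18 to hold the building-block tier")
  class(p) <- "kinetic_params"
  p
}

# Build the explicit reaction list once per parameter set.
.reaction_table <- function(p) {
  rx <- list()
  add <- function(i, j, prod, k) rx[[length(rx) + 1L]] <<-
    list(i = i, j = j, prod = prod, k = k)
  for (n in 1:7) add(1L, n, n + 1L, p$k_add)
  for (n in 12:17) add(1L, n, n + 1L, p$k_add2)
  for (n in 2:9) add(n, NA_integer_, c(n - 1L, 1L), p$k_shed)       # shed
  for (i in 2:8) for (j in i:8)
    if ((i + j) >= 12 && (i + j) <= 18) add(i, j, i + j, p$k_fuse)
  for (s in 12:18)
    add(s, NA_integer_, c(s %/% 2L, s - s %/% 2L), p$k_split)       # split
  for (i in 12:18) for (j in i:18)
    if ((i + j) <= p$n_max) add(i, j, i + j, p$k_pair)
  rx
}

#' Simulate an oligomerization time course
#'
#' Integrates the tiered mass-action model from an all-monomer start and
#' returns species concentrations (in monomer-equivalent units, so
#' \eqn{\sum_n n c_n} is conserved) at the requested times. A pH-jump
#' scenario is expressed as a change of rate constants at `jump$time`:
#' dissociation channels are accelerated and association slowed, reversing
#' the small/large balance as seen when a pre-incubated solution is brought
#' from pH 6.7 to 8.1.
#'
#' @param times Strictly increasing sampling times in minutes (may include 0).
#' @param params A [kinetic_params()] object.
#' @param jump Optional list `list(time =, diss_factor =, assoc_factor =)`;
#'   after `time`, dissociation rates are multiplied by `diss_factor` and
#'   association rates by `assoc_factor`.
#' @param seed Accepted for interface symmetry with the stochastic
#'   generators; the ODE integration is deterministic and ignores it.
#' @return Matrix (time x state) of concentrations; `rownames` are times,
#'   columns states `1..n_max`.
#' @examples
#' tc <- gen_timecourse(c(0, 10, 90, 270))
#' colSums(t(tc) * seq_len(ncol(tc)))  # conserved monomer count
#' @export
gen_timecourse <- function(times, params = kinetic_params(), jump = NULL,
                           seed = NULL) {
  stopifnot(is.numeric(times), length(times) >= 1L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be >= 0")
  n_max <- params$n_max

  deriv_for <- function(p) {
    rx <- .reaction_table(p)
    function(t, y, parms) {
      dy <- numeric(n_max)
      for (r in rx) {
        if (is.na(r$j[1])) {             # unimolecular split/shed
          rate <- r$k * y[r$i]
          dy[r$i] <- dy[r$i] - rate
          for (pr in r$prod) dy[pr] <- dy[pr] + rate
        } else {
          rate <- if (r$i == r$j) 0.5 * r$k * y[r$i]^2 else
            r$k * y[r$i] * y[r$j]
          dy[r$i] <- dy[r$i] - rate
          dy[r$j] <- dy[r$j] - rate
          dy[r$prod] <- dy[r$prod] + rate
        }
      }
      list(dy)
    }
  }

  y0 <- c(1, numeric(n_max - 1L))  # all monomer, total monomer units = 1
  run <- function(y, tt, p) {
    if (length(tt) == 1L) return(matrix(y, nrow = 1L))
    deSolve::ode(y, tt, deriv_for(p), NULL, method = "lsoda",
                 rtol = 1e-10, atol = 1e-12)[, -1, drop = FALSE]
  }

  if (is.null(jump) || all(times <= jump$time)) {
    tt <- unique(c(0, times))
    out <- run(y0, tt, params)
    res <- out[match(times, tt), , drop = FALSE]
  } else {
    p2 <- params
    p2$k_shed <- p2$k_shed * jump$diss_factor
    p2$k_split <- p2$k_split * jump$diss_factor
    p2$k_add <- p2$k_add * jump$assoc_factor
    p2$k_add2 <- p2$k_add2 * jump$assoc_factor
    p2$k_fuse <- p2$k_fuse * jump$assoc_factor
    p2$k_pair <- p2$k_pair * jump$assoc_factor
    pre_t <- times[times <= jump$time]
    post_t <- times[times > jump$time]
    tt1 <- unique(c(0, pre_t, jump$time))
    out1 <- run(y0, tt1, params)
    y_jump <- out1[length(tt1), ]
    tt2 <- unique(c(jump$time, post_t))
    out2 <- run(y_jump, tt2, p2)
    res <- rbind(out1[match(pre_t, tt1), , drop = FALSE],
                 out2[match(post_t, tt2), , drop = FALSE])
  }
  dimnames(res) <- list(format(times, trim = TRUE), seq_len(n_max))
  attr(res, "times") <- times
  res
}

#' The pH 6.7 incubation and pH-jump reversal scenarios
#'
#' Returns the preset arguments for [gen_timecourse()]. `"ph6.7"` is the
#' plain incubation time course (small n = 2-8 oligomers appear first, the
#' n = 13-17 building blocks dominate by a few hours, n = 17 emerges by
#' 24 h). `"ph_jump"` incubates 18 h at pH 6.7, then raises the pH to 8.1,
#' which roughly halves the n = 13-17 band within 10 min while small
#' oligomers reappear.
#'
#' @param name Scenario name.
#' @return List with elements `params` and `jump` (possibly `NULL`).
#' @export
timecourse_scenario <- function(name = c("ph6.7", "ph_jump")) {
  name <- match.arg(name)
  switch(name,
    "ph6.7" = list(params = kinetic_params(), jump = NULL),
    "ph_jump" = list(params = kinetic_params(),
                     jump = list(time = 1080, diss_factor = 40,
                                 assoc_factor = 0.05))
  )
}

#' Charge models for electrosprayed oligomers
#'
#' `default_charge_model()` assigns a discretized normal charge distribution
#' with mean `scale * sqrt(n)` -- the familiar square-root-of-mass scaling of
#' native electrospray charging; the default `scale` puts 14+ on the 17-mer
#' and 3+ on the monomer. `fixed_charge_model(z)` pins every state to one
#' charge (useful for closed-form tests).
#'
#' @param scale Mean charge of the monomer-equivalent unit (charge per
#'   sqrt(n)).
#' @param rel_sd Relative standard deviation of the charge distribution.
#' @param z_window Number of charge states kept either side of the mean.
#' @return A function `n -> data.frame(z, weight)` with weights summing to 1.
#' @export
default_charge_model <- function(scale = 3.4, rel_sd = 0.08, z_window = 4L) {
  force(scale); force(rel_sd); force(z_window)
  function(n) {
    mu <- scale * sqrt(n)
    sd <- max(0.4, rel_sd * mu)
    z <- max(1L, round(mu) - z_window):(round(mu) + z_window)
    w <- stats::dnorm(z, mu, sd)
    data.frame(z = z, weight = w / sum(w))
  }
}

#' @rdname default_charge_model
#' @param z Charge to pin every state to.
#' @export
fixed_charge_model <- function(z) {
  force(z)
  function(n) data.frame(z = z, weight = 1)
}

#' Generate a native profile mass spectrum
#'
#' Emits one Gaussian peak per populated (state, charge) pair at
#' `mz_of(n * M, z)`, with optional additive baseline noise. Monoisotopic
#' monomer mass is used for states n <= 8 (isotopically resolvable) and the
#' average mass for n >= 9 (unresolved envelopes).
#'
#' @param abundance Named numeric vector: state n -> relative abundance.
#'   Zero/empty abundances give a flat (noise-only) spectrum.
#' @param charge_model Function `n -> data.frame(z, weight)`; see
#'   [default_charge_model()].
#' @param spec Peptide specification providing the monomer masses.
#' @param mz_range Length-2 numeric, spectrum limits in Th.
#' @param dmz Grid spacing in Th.
#' @param peak_width Gaussian sigma in Th.
#' @param noise_sd Additive baseline noise sigma (intensity units).
#' @param seed Optional RNG seed (only the noise is random).
#' @return An `ms_spectrum`: data.frame with columns `mz`, `intensity`.
#' @export
gen_native_spectrum <- function(abundance, charge_model = default_charge_model(),
                                spec = liraglutide(), mz_range = c(2000, 5000),
                                dmz = 0.25, peak_width = 1.5, noise_sd = 0,
                                seed = NULL) {
  stopifnot(length(mz_range) == 2L, all(mz_range > 0), mz_range[1] < mz_range[2])
  if (dmz <= 0 || peak_width <= 0) stop("dmz and peak_width must be > 0")
  if (!is.null(seed)) set.seed(seed)
  mz <- seq(mz_range[1], mz_range[2], by = dmz)
  intensity <- numeric(length(mz))
  m_mono <- monomer_mass(spec, "monoisotopic")
  m_avg <- monomer_mass(spec, "average")
  states <- as.integer(names(abundance))
  if (length(abundance) && is.null(names(abundance)))
    stop("abundance must be named by oligomer state")
  for (k in seq_along(abundance)) {
    a <- abundance[[k]]
    if (a <= 0) next
    n <- states[k]
    mass <- n * if (n <= 8) m_mono else m_avg
    cs <- charge_model(n)
    for (r in seq_len(nrow(cs))) {
      center <- mz_of(mass, cs$z[r])
      if (center < mz_range[1] - 5 * peak_width ||
          center > mz_range[2] + 5 * peak_width) next
      intensity <- intensity +
        a * cs$weight[r] * exp(-(mz - center)^2 / (2 * peak_width^2))
    }
  }
  if (noise_sd > 0)
    intensity <- pmax(0, intensity + stats::rnorm(length(mz), 0, noise_sd))
  structure(data.frame(mz = mz, intensity = intensity),
            class = c("ms_spectrum", "data.frame"))
}

#' Single-ion trace generation parameters
#'
#' @param k_cal Calibration constant: expected cumulative-intensity slope per
#'   unit charge (intensity units / s / charge). Must be > 0.
#' @param sigma_rel Relative slope noise (per-trace multiplicative Gaussian,
#'   plus per-point jitter of the same scale). The default reflects the
#'   sub-single-charge precision of Orbitrap-based single-ion measurements.
#' @param dt Sampling interval in seconds.
#' @param t_max Longest trace duration in seconds.
#' @param min_frac Surviving traces last between `min_frac * t_max` and
#'   `t_max` (uniform).
#' @param p_death Probability an ion dies early; its duration is then further
#'   scaled by Uniform(0.1, 0.5).
#' @return List of class `trace_params`.
#' @export
trace_params <- function(k_cal = 1, sigma_rel = 0.003, dt = 0.05, t_max = 2,
                         min_frac = 0.5, p_death = 0.05) {
  if (k_cal <= 0) stop("k_cal must be > 0")
  if (sigma_rel < 0) stop("sigma_rel must be >= 0")
  if (dt <= 0 || t_max <= 3 * dt) stop("invalid sampling interval / duration")
  structure(list(k_cal = k_cal, sigma_rel = sigma_rel, dt = dt, t_max = t_max,
                 min_frac = min_frac, p_death = p_death),
            class = "trace_params")
}

#' Generate single-ion cumulative-intensity traces
#'
#' Each ion yields a cumulative intensity series whose expected slope is
#' `k_cal * z` -- the physical basis of slope-based (STORI) charge
#' assignment. The true state and charge are recorded for recovery tests;
#' m/z is attached from the average monomer mass.
#'
#' @param population Data frame with columns `n`, `z`, `count` (one row per
#'   (state, charge) cell, `count` ions each).
#' @param params A [trace_params()].
#' @param spec Peptide specification for the monomer mass.
#' @param seed Optional RNG seed.
#' @return List with `traces` (long data.frame: ion_id, t,
#'   cumulative_intensity, mz, true_z, true_n) and `truth` (one row per ion).
#' @export
gen_ion_traces <- function(population, params = trace_params(),
                           spec = liraglutide(), seed = NULL) {
  stopifnot(is.data.frame(population),
            all(c("n", "z", "count") %in% names(population)))
  if (any(population$count < 1)) stop("counts must be >= 1")
  if (any(population$z < 1)) stop("charges must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m_avg <- monomer_mass(spec, "average")
  ions <- population[rep(seq_len(nrow(population)), population$count),
                     c("n", "z")]
  n_ion <- nrow(ions)
  ions$ion_id <- seq_len(n_ion)
  ions$mz <- mz_of(ions$n * m_avg, ions$z)

  dur <- stats::runif(n_ion, params$min_frac * params$t_max, params$t_max)
  died <- stats::runif(n_ion) < params$p_death
  dur[died] <- dur[died] * stats::runif(sum(died), 0.1, 0.5)
  dur <- pmax(dur, 3 * params$dt)
  slope <- params$k_cal * ions$z *
    (1 + params$sigma_rel * stats::rnorm(n_ion))

  pieces <- vector("list", n_ion)
  for (i in seq_len(n_ion)) {
    t <- seq(params$dt, dur[i], by = params$dt)
    y <- slope[i] * t
    if (params$sigma_rel > 0)
      y <- y * (1 + params$sigma_rel * stats::rnorm(length(t)))
    pieces[[i]] <- data.frame(ion_id = i, t = t, cumulative_intensity = y)
  }
  traces <- do.call(rbind, pieces)
  traces$mz <- ions$mz[traces$ion_id]
  traces$true_z <- ions$z[traces$ion_id]
  traces$true_n <- ions$n[traces$ion_id]
  rownames(traces) <- NULL
  truth <- data.frame(ion_id = ions$ion_id, n = ions$n, z = ions$z,
                      mz = ions$mz, duration = dur)
  list(traces = traces, truth = truth)
}

# Region definitions for the high-mass single-ion populations.
.DMT_REGIONS <- list(I = 9:19, II = 25:32, III = 37:48, IV = 54:62)

#' Preset single-ion populations for the high-mass region
#'
#' Builds deterministic (state, charge) populations emulating the four
#' disjoint oligomer clusters seen in direct-mass measurements after long
#' incubation: Region I (n = 9-19), II (25-32), III (37-48), IV (54-62).
#' Region I is bimodal (n = 12 and 16) at 25 degrees C and unimodal with
#' n = 16 dominant at 37 and 50 degrees C; higher temperature shifts the
#' outer regions up. Charges scale with state across the 8+ to 75+ window,
#' bounded below by the smallest detectable charge and above by the Rayleigh
#' charging limit of the largest species.
#'
#' Cell counts are expected counts rounded, so the population structure (all
#' four regions occupied, charge endpoints present) does not depend on a
#' random draw; only the trace noise added later is stochastic.
#'
#' @param temperature One of `"25"`, `"37"`, `"50"` (degrees C).
#' @param n_ions Approximate total number of ions.
#' @param z_sd Charge spread (standard deviation, charges).
#' @param z_range Charge bounds.
#' @return Data frame with columns `n`, `z`, `count` suitable for
#'   [gen_ion_traces()].
#' @export
dmt_population_preset <- function(temperature = c("37", "25", "50"),
                                  n_ions = 10000, z_sd = 1.2,
                                  z_range = c(8L, 75L)) {
  temperature <- match.arg(as.character(temperature), c("37", "25", "50"))
  reg <- .DMT_REGIONS
  shape <- function(states, means, sds, mix, unif) {
    w <- rep(unif / length(states), length(states))
    for (k in seq_along(means))
      w <- w + mix[k] * stats::dnorm(states, means[k], sds[k])
    w / sum(w)
  }
  cfg <- switch(temperature,
    "25" = list(wr = c(0.60, 0.18, 0.13, 0.09),
                I = shape(reg$I, c(12, 16), c(1.2, 1.2), c(0.45, 0.40), 0.15),
                II = shape(reg$II, 28, 2, 0.8, 0.2),
                III = shape(reg$III, 42, 2.5, 0.8, 0.2),
                IV = shape(reg$IV, 57, 2, 0.8, 0.2)),
    "37" = list(wr = c(0.50, 0.20, 0.18, 0.12),
                I = shape(reg$I, 16, 2, 0.85, 0.15),
                II = shape(reg$II, 29, 2, 0.8, 0.2),
                III = shape(reg$III, 43, 2.5, 0.8, 0.2),
                IV = shape(reg$IV, 58, 2, 0.8, 0.2)),
    "50" = list(wr = c(0.48, 0.20, 0.18, 0.14),
                I = shape(reg$I, 16, 2.5, 0.85, 0.15),
                II = shape(reg$II, 30, 2, 0.8, 0.2),
                III = shape(reg$III, 44, 2.5, 0.8, 0.2),
                IV = shape(reg$IV, 59, 2, 0.8, 0.2))
  )
  mean_z <- function(n) z_range[1] +
    (z_range[2] - z_range[1]) * (n - 9) / (62 - 9)
  rows <- list()
  for (r in seq_along(reg)) {
    states <- reg[[r]]
    wn <- cfg[[r + 1L]] * cfg$wr[r]
    for (k in seq_along(states)) {
      n <- states[k]
      z <- z_range[1]:z_range[2]
      # discretized normal with mass outside the window folded onto the bounds
      pz <- stats::pnorm(z + 0.5, mean_z(n), z_sd) -
        stats::pnorm(z - 0.5, mean_z(n), z_sd)
      pz[1] <- pz[1] + stats::pnorm(z_range[1] - 0.5, mean_z(n), z_sd)
      pz[length(pz)] <- pz[length(pz)] +
        stats::pnorm(z_range[2] + 0.5, mean_z(n), z_sd, lower.tail = FALSE)
      count <- round(n_ions * wn[k] * pz)
      keep <- count > 0
      if (any(keep))
        rows[[length(rows) + 1L]] <-
          data.frame(n = n, z = z[keep], count = count[keep])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fragment detection-probability profiles
#'
#' Per-class Bernoulli detection probabilities for the theoretical c/z
#' ladder, split by ion type and by whether the fragment contains the lipid
#' conjugate. The two presets encode the qualitative monomer-vs-oligomer
#' contrast: in the oligomeric form, release of C-terminal z-ions and of
#' conjugate-containing fragments is strongly suppressed (the conjugation
#' site is buried and the C-terminus restrained), while plain c-ions become
#' slightly more likely (higher precursor charges fragment more
#' efficiently).
#'
#' @param preset `"monomer"` or `"oligomer"`.
#' @param sigma_ppm Mass-error scale (ppm) applied to observed fragments.
#' @return List of class `fragment_profile` with elements `p_c_plain`,
#'   `p_c_conj`, `p_z_plain`, `p_z_conj`, `sigma_ppm`.
#' @export
fragment_profile <- function(preset = c("monomer", "oligomer"),
                             sigma_ppm = 5) {
  preset <- match.arg(preset)
  if (sigma_ppm < 0) stop("sigma_ppm must be >= 0")
  p <- switch(preset,
    monomer  = list(p_c_plain = 0.284, p_c_conj = 0.600,
                    p_z_plain = 0.600, p_z_conj = 0.600),
    oligomer = list(p_c_plain = 0.942, p_c_conj = 0.282,
                    p_z_plain = 0.100, p_z_conj = 0.047)
  )
  structure(c(p, list(sigma_ppm = sigma_ppm, preset = preset)),
            class = "fragment_profile")
}

#' Sample observed fragment masses from a detection profile
#'
#' Bernoulli-samples every fragment of the theoretical ladder with its
#' class probability and perturbs each detected mass by Normal(0, sigma_ppm).
#'
#' @param profile A [fragment_profile()].
#' @param ladder Theoretical ladder from [theoretical_ladder()].
#' @param seed Optional RNG seed.
#' @return Numeric vector of observed neutral masses (Da), with the sampled
#'   ladder rows attached as attribute `"fragments"`.
#' @export
gen_fragment_observations <- function(profile, ladder, seed = NULL) {
  stopifnot(inherits(profile, "fragment_profile"), nrow(ladder) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  p <- ifelse(ladder$type == "c",
              ifelse(ladder$contains_conjugate, profile$p_c_conj,
                     profile$p_c_plain),
              ifelse(ladder$contains_conjugate, profile$p_z_conj,
                     profile$p_z_plain))
  hit <- stats::runif(nrow(ladder)) < p
  obs <- ladder$mass[hit] *
    (1 + stats::rnorm(sum(hit), 0, profile$sigma_ppm * 1e-6))
  attr(obs, "fragments") <- ladder[hit, , drop = FALSE]
  obs
}
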