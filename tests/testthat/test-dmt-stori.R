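test_that("slope fitting recovers exact lines and matches closed-form OLS", {
  t <- seq(0.1, 2, 0.1)
  f <- fit_stori_slope(t, 5 * t)
  expect_equal(f$slope, 5, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$duration, 2)

  set.seed(31)
  y <- 3 * t + rnorm(length(t), 0, 0.2)
  f2 <- fit_stori_slope(t, y)
  # algebraic oracle: cov/var form
  expect_equal(f2$slope, sum((t - mean(t)) * (y - mean(y))) /
                 sum((t - mean(t))^2), tolerance = 1e-12)
  expect_equal(f2$r2, cor(t, y)^2, tolerance = 1e-10)

  expect_error(fit_stori_slope(c(1, 2), c(1, 2)), "too short")
})

test_that("charge assignment is exact at zero noise for z in 1..100", {
  p <- trace_params(sigma_rel = 0, p_death = 0)
  pop <- data.frame(n = 1, z = 1:100, count = 3)
  tr <- gen_ion_traces(pop, p, seed = 5)
  rec <- assign_charge(fit_stori_slopes(tr$traces), k_cal = 1, min_ions = 1)
  expect_true(all(!is.na(rec$z_assigned)))
  expect_equal(rec$z_assigned, rec$true_z)
})

test_that("quality filters reject poor traces with named reasons", {
  tr <- data.frame(ion_id = rep(1:2, c(2, 10)),
                   t = c(0.1, 0.2, seq(0.1, 1, 0.1)),
                   cumulative_intensity = c(1, 2, seq(0.1, 1, 0.1) * 7),
                   mz = 3000)
  rec <- assign_charge(fit_stori_slopes(tr), min_ions = 1)
  expect_equal(rec$reject_reason[rec$ion_id == 1], "too_short")
  expect_equal(rec$z_assigned[rec$ion_id == 2], 7L)
  expect_error(assign_charge(rec, bin_size = 0), "bin_size")
})

test_that("sparse charge bins are discarded by the min-ion filter", {
  p <- trace_params(sigma_rel = 0, p_death = 0)
  pop <- data.frame(n = 1, z = c(10, 11), count = c(5, 1))
  tr <- gen_ion_traces(pop, p, seed = 6)
  rec <- assign_charge(fit_stori_slopes(tr$traces), min_ions = 3)
  expect_equal(sum(rec$z_assigned == 10, na.rm = TRUE), 5)
  expect_equal(rec$reject_reason[rec$true_z == 11], "sparse_bin")
})

test_that("assigned charges span the true extremes on the preset population", {
  pop <- dmt_population_preset("37", n_ions = 4000)
  tr <- gen_ion_traces(pop, trace_params(), seed = 17)
  rec <- assign_charge(fit_stori_slopes(tr$traces))
  expect_equal(min(rec$z_assigned, na.rm = TRUE), 8)
  expect_equal(max(rec$z_assigned, na.rm = TRUE), 75)
})

test_that("exact-assignment fraction tracks a Monte-Carlo oracle within 2%", {
  z <- 40
  sigma <- 0.008
  p <- trace_params(sigma_rel = sigma, p_death = 0)
  tr <- gen_ion_traces(data.frame(n = 20, z = z, count = 400), p, seed = 77)
  rec <- assign_charge(fit_stori_slopes(tr$traces), min_ions = 1)
  frac <- mean(rec$z_assigned == z, na.rm = TRUE)
  # oracle: 10x repetitions of rounding a normal draw; the trace model adds
  # per-point jitter on top of the per-trace slope offset, so simulate both
  set.seed(99)
  m <- 30  # representative samples per trace
  raw <- rnorm(4000, 0, sigma) + rnorm(4000, 0, sigma / sqrt(m))
  oracle_frac <- mean(abs(z * raw) < 0.5)
  expect_lt(abs(frac - oracle_frac), 0.02 + 3 * sqrt(0.25 / 400))
})

test_that("mass and state computation inverts the generator exactly", {
  m_avg <- monomer_mass(liraglutide(), "average")
  rec <- data.frame(mz = mz_of(16 * m_avg, 12), z_assigned = 12L)
  out <- ion_mass_and_state(rec, m_avg)
  expect_equal(out$n_state, 16L)
  expect_equal(out$mass, 16 * m_avg, tolerance = 1e-9)

  # n = 62 sits inside the reported 100-250 kDa window
  rec62 <- ion_mass_and_state(
    data.frame(mz = mz_of(62 * m_avg, 70), z_assigned = 70L), m_avg)
  expect_equal(rec62$n_state, 62L)
  expect_gt(rec62$mass, 100e3); expect_lt(rec62$mass, 250e3)

  # round trip over all noiseless preset ions
  pop <- dmt_population_preset("37", n_ions = 1500)
  tr <- gen_ion_traces(pop, trace_params(sigma_rel = 0, p_death = 0),
                       seed = 2)
  rec <- assign_charge(fit_stori_slopes(tr$traces), min_ions = 1)
  out <- ion_mass_and_state(rec, m_avg)
  expect_equal(out$n_state, out$true_n)
})

test_that("round-trip state recovery is >= 99% at the default slope noise", {
  pop <- dmt_population_preset("37", n_ions = 3000)
  tr <- gen_ion_traces(pop, trace_params(p_death = 0), seed = 3)
  rec <- ion_mass_and_state(assign_charge(fit_stori_slopes(tr$traces)),
                            monomer_mass(liraglutide(), "average"))
  ok <- !is.na(rec$z_assigned)
  expect_gte(mean(rec$n_state[ok] == rec$true_n[ok], na.rm = TRUE), 0.99)
})

test_that("region segmentation matches the run-length oracle", {
  expect_equal(segment_state_regions(c(1, 2, 2, 3))$state_lo, 1)
  expect_equal(segment_state_regions(c(1, 2, 2, 3))$state_hi, 3)

  occ <- c(9:19, 25:32, 37:48, 54:62)
  seg <- segment_state_regions(rep(occ, 2), min_gap = 3)
  expect_equal(nrow(seg), 4)
  expect_equal(seg$state_lo, c(9, 25, 37, 54))
  expect_equal(seg$state_hi, c(19, 32, 48, 62))
  expect_equal(seg$region, c("I", "II", "III", "IV"))

  set.seed(41)
  for (rep in 1:20) {
    states <- sort(sample(1:60, sample(5:30, 1)))
    gap <- sample(1:5, 1)
    seg <- segment_state_regions(states, min_gap = gap)
    oracle <- oracle_segments(states, gap)
    expect_equal(nrow(seg), length(oracle))
    expect_equal(seg$state_lo, vapply(oracle, `[`, numeric(1), 1))
    expect_equal(seg$state_hi, vapply(oracle, `[`, numeric(1), 2))
  }
})

test_that("segmentation is idempotent and scale-invariant; empty input empty", {
  counts <- table(c(9:19, 25:32))
  a <- segment_state_regions(counts)
  b <- segment_state_regions(counts * 100)
  expect_equal(a[, c("state_lo", "state_hi")], b[, c("state_lo", "state_hi")])
  expect_equal(nrow(segment_state_regions(integer(0))), 0)
})

test_that("direct mass histogram conserves records and finds modal states", {
  m_avg <- monomer_mass(liraglutide(), "average")
  rec <- data.frame(mz = mz_of(16 * m_avg, 12), z_assigned = 12L)
  out <- ion_mass_and_state(rec, m_avg)
  h <- direct_mass_histogram(out)
  expect_equal(sum(h$histogram$count), 1)
  expect_equal(h$regions$modal_n, 16L)
  expect_error(direct_mass_histogram(out, mass_bin = -1), "mass_bin")

  pop <- dmt_population_preset("37", n_ions = 3000)
  tr <- gen_ion_traces(pop, trace_params(), seed = 4)
  res <- dmt_pipeline(tr$traces)
  expect_equal(sum(res$histogram$count),
               sum(!is.na(res$records$mass)))
  expect_equal(res$regions$modal_n[1], 16L)
})
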