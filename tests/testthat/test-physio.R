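test_that("relative heart rate per section: constants and coverage flags", {
  course <- tiny_course()
  ref <- lay_out_reference(course)
  prof <- athlete_profile(hr_peak = 195)
  tr <- track_on_reference(ref, speed = 2, hr = 195)
  sp <- virtual_splits(map_to_course(tr, ref), course)
  hp <- hr_percent_by_section(tr, sp, prof)
  expect_equal(hp$pct_hr_peak, rep(100, 3), tolerance = 1e-9)
  tr$hr <- 97.5
  hp <- hr_percent_by_section(tr, sp, prof)
  expect_equal(hp$pct_hr_peak, rep(50, 3), tolerance = 1e-9)
  expect_true(all(!hp$hr_flagged))
  # sparse heart rate trips the coverage flag
  tr$hr[seq(1, nrow(tr), by = 2)] <- NA
  hp <- hr_percent_by_section(tr, sp, prof)
  expect_true(all(hp$hr_flagged))
  tr$hr <- NA_real_
  expect_warning(hr_percent_by_section(tr, sp, prof), "no heart-rate")
})

test_that("section heart-rate means match the first-order kinetics solution", {
  cfg <- synth_config("HIT", course = demo_course(n_laps = 1),
                      gnss_sigma = 0, seed = 4)
  ses <- simulate_session(cfg)
  prof <- athlete_profile(hr_peak = 195)
  sp <- virtual_splits(map_to_course(ses$track, ses$reference), cfg$course)
  hp <- hr_percent_by_section(ses$track, sp, prof)
  # oracle: closed-form mean of H* + (H0-H*) e^(-t/tau) over each true window
  truth <- ses$truth$splits
  hr_t <- ses$truth$hr
  h_at <- approxfun(hr_t$time, hr_t$hr)
  for (i in seq_len(nrow(truth))) {
    tgt <- cfg$hr_targets[[truth$terrain[i]]]
    t0 <- truth$entry_time[i]; t1 <- truth$exit_time[i]
    h0 <- h_at(t0)
    dtau <- (t1 - t0) / cfg$tau
    mean_closed <- tgt + (h0 - tgt) * (1 - exp(-dtau)) / dtau
    expect_lt(abs(hp$hr_mean[i] - mean_closed), 1.0)
  }
})

test_that("heart-rate summaries are invariant to time reparameterisation", {
  course <- tiny_course()
  ref <- lay_out_reference(course)
  prof <- athlete_profile(hr_peak = 200)
  tr <- track_on_reference(ref, speed = 2, hr = NA)
  tr$hr <- 150 + 10 * sin(tr$time / 20)
  sp <- virtual_splits(map_to_course(tr, ref), course)
  h1 <- hr_percent_by_section(tr, sp, prof)$pct_hr_peak
  # uniformly dilate the clock: same path sampled twice as densely in time
  tr2 <- tr; tr2$time <- tr$time * 2
  class(tr2) <- class(tr)
  sp2 <- sp
  sp2$entry_time <- sp$entry_time * 2
  sp2$exit_time <- sp$exit_time * 2
  sp2$duration <- sp$duration * 2
  h2 <- hr_percent_by_section(tr2, sp2, prof)$pct_hr_peak
  expect_equal(h1, h2, tolerance = 1e-9)
})

test_that("paired t test matches the textbook formula and handles degeneracy", {
  a <- c(61.2, 59.8, 60.5, 62.1, 58.9, 61.7)
  b <- c(49.9, 51.2, 48.7, 50.4, 49.1, 50.8)
  got <- compare_paired(a, b)
  want <- oracle_paired_t(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  expect_equal(got$df, want$df)
  expect_equal(got$mean_diff, mean(a - b))
  # constant shift: zero within-pair variance is degenerate, not an error
  dg <- compare_paired(b + 2, b)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$t))
  expect_equal(dg$mean_diff, 2)
  expect_error(compare_paired(1:3, 1:4), "equal lengths")
})

test_that("independent (Welch) t test matches the textbook formula", {
  got <- compare_independent(c(3, 4, 5), c(5, 6, 7))
  want <- oracle_welch_t(c(3, 4, 5), c(5, 6, 7))
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$df, want$df, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  # identical groups: t exactly 0
  expect_equal(compare_independent(c(3, 4, 5), c(3, 4, 5))$t, 0)
  # equal n and equal variance: Welch and pooled forms coincide
  a <- c(2, 4, 6, 8); b <- c(3, 5, 7, 9)
  expect_equal(compare_independent(a, b)$t,
               compare_independent(a, b, var_equal = TRUE)$t,
               tolerance = 1e-6)
  dg <- compare_independent(c(1, 1), c(2, 2))
  expect_true(dg$degenerate)
})

test_that("both tests agree with their closed forms on random draws", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    a <- rnorm(n, 50, 5); b <- rnorm(n, 48, 5)
    gp <- compare_paired(a, b); wp <- oracle_paired_t(a, b)
    expect_equal(gp$t, wp$t, tolerance = 1e-9)
    expect_equal(gp$p, wp$p, tolerance = 1e-9)
    m <- sample(3:12, 1)
    c2 <- rnorm(m, 52, 8)
    gi <- compare_independent(a, c2); wi <- oracle_welch_t(a, c2)
    expect_equal(gi$t, wi$t, tolerance = 1e-9)
    expect_equal(gi$p, wi$p, tolerance = 1e-9)
  }
})

test_that("paired test detects a 10 cycles/min rate difference reliably", {
  # Monte-Carlo power check: true diff 10, sigma 2, n = 12 -> p < 0.03
  set.seed(11)
  hits <- replicate(200, {
    a <- rnorm(12, 60, 2); b <- a - 10 + rnorm(12, 0, 2)
    compare_paired(a, b)$p < 0.03
  })
  expect_gte(mean(hits), 0.95)
})

test_that("terrain summary assembles all components and degrades gracefully", {
  cfg <- synth_config("HIT", course = demo_course(n_laps = 1),
                      gnss_sigma = 0, seed = 6)
  ses <- simulate_session(cfg)
  prof <- athlete_profile(hr_peak = 195, body_mass = 67.5,
                          equipment_mass = 4.2)
  params <- power_params(prof$mass_total, 0.036)
  sp <- virtual_splits(map_to_course(ses$track, ses$reference), cfg$course)
  sp <- power_by_section(sp, params)
  sp <- hr_percent_by_section(ses$track, sp, prof)
  cyc <- assign_cycle_length(
    cycles_from_plants(detect_pole_plants(ses$imu)), sp)
  st <- section_cycle_stats(cyc)
  sm <- build_summary(sp, cycle_stats = st,
                      vmax = c(uphill = 4.0, flat = 6.2),
                      pmax = c(uphill = 342, flat = 252), intensity = "HIT")
  expect_equal(sm$terrain, c("uphill", "flat", "downhill", "overall"))
  expect_equal(sum(sm$time_share_pct[1:3]), 100, tolerance = 1e-9)
  filled <- sm[sm$terrain %in% c("uphill", "flat"), ]
  expect_true(all(!is.na(unlist(filled[-1]))))
  # no power/cycles downhill: columns absent there, speed still present
  down <- sm[sm$terrain == "downhill", ]
  expect_true(is.na(down$power_W))
  expect_false(is.na(down$mean_speed))
  # without components the columns stay NA and are noted
  bare <- build_summary(sp[, !(names(sp) %in% c("P_g", "P_f", "P_d", "P_tot",
                                                "hr_mean", "pct_hr_peak",
                                                "hr_coverage", "hr_flagged"))])
  expect_true(all(is.na(bare$power_W)))
  expect_true("no cycle statistics" %in% attr(bare, "notes"))
})
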