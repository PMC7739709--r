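ref_params <- power_params(mass_total = 71.7, mu_s = 0.036, rho = 1.29,
                           drag_area = 0.338)

test_that("power decomposition matches the closed-form components", {
  # hand evaluation: a = atan(0.08); m g = 703.377; v = 4
  a <- atan(0.08)
  expect_g <- 71.7 * 9.81 * sin(a) * 4        # 224.35 W
  expect_f <- 71.7 * 9.81 * cos(a) * 0.036 * 4  # 100.97 W
  expect_d <- 0.5 * 1.29 * 4^3 * 0.338          # 13.95 W
  pb <- power_breakdown(4.0, 8, ref_params)
  expect_equal(pb$P_g, expect_g, tolerance = 1e-12)
  expect_equal(pb$P_f, expect_f, tolerance = 1e-12)
  expect_equal(pb$P_d, expect_d, tolerance = 1e-12)
  expect_equal(pb$P_tot, expect_g + expect_f + expect_d)
  expect_equal(unname(round(pb$shares)), c(66, 30, 4))

  # v = 0 is legal and gives zero power
  z <- power_breakdown(0, 8, ref_params)
  expect_equal(c(z$P_g, z$P_f, z$P_d, z$P_tot), rep(0, 4))

  # level ground, no drag: P_tot = m g mu v exactly
  p0 <- power_params(70, 0.04, drag_area = 1e-12)
  pb0 <- power_breakdown(3, 0, p0)
  expect_equal(pb0$P_tot, 70 * 9.81 * 0.04 * 3, tolerance = 1e-6)
})

test_that("power model obeys additivity, scaling and sign properties", {
  set.seed(42)
  for (i in 1:25) {
    v <- runif(1, 0, 8); g <- runif(1, -16, 16); m <- runif(1, 50, 90)
    p1 <- power_params(m, 0.036)
    p2 <- power_params(2 * m, 0.036)
    b1 <- power_breakdown(v, g, p1)
    b2 <- power_breakdown(v, g, p2)
    expect_identical(b1$P_tot, b1$P_g + b1$P_f + b1$P_d)
    # P_g, P_f linear in mass; P_d mass-independent
    expect_equal(b2$P_g, 2 * b1$P_g, tolerance = 1e-12)
    expect_equal(b2$P_f, 2 * b1$P_f, tolerance = 1e-12)
    expect_equal(b2$P_d, b1$P_d)
    # P_d cubic in v
    if (v > 0)
      expect_equal(power_breakdown(2 * v, g, p1)$P_d / b1$P_d, 8,
                   tolerance = 1e-9)
    # signs
    if (v > 0) {
      expect_true(b1$P_f >= 0 && b1$P_d >= 0)
      if (g < 0) expect_lt(b1$P_g, 0)
      if (g > 0) expect_gt(b1$P_g, 0)
    }
  }
})

test_that("glide-test friction inversion matches the energy balance", {
  # (5.5^2 - 4^2) / (2 * 9.81 * 20) = 0.036315
  expect_equal(estimate_friction(5.5, 4.0, 20),
               (5.5^2 - 4^2) / (2 * 9.81 * 20), tolerance = 1e-12)
  expect_equal(estimate_friction(3, 3, 20), 0)
  expect_warning(mu <- estimate_friction(4, 4, 20, grade = 2), "negative")
  expect_lt(mu, 0)
  expect_error(estimate_friction(4, 5, 20), "exceeds")
  expect_error(estimate_friction(5, 4, 0), "distance")
})

test_that("glide simulation round-trips the friction coefficient", {
  # drag off: inversion is exact up to float error
  for (mu in c(0.02, 0.036, 0.05)) {
    gl <- simulate_glide(mu, 5.5, 20)
    expect_false(gl$stopped)
    expect_equal(estimate_friction(gl$v_in, gl$v_out, gl$distance), mu,
                 tolerance = 1e-3)
  }
  # frozen forward value: v_out = sqrt(5.5^2 - 2*9.81*0.036*20) = 4.0154
  expect_equal(simulate_glide(0.036, 5.5, 20)$v_out,
               sqrt(5.5^2 - 2 * 9.81 * 0.036 * 20), tolerance = 1e-9)
  # zero friction on the flat with no drag: exit = entry
  expect_equal(simulate_glide(0, 5, 20)$v_out, 5)
  # skier stopping inside the zone is flagged with the stop distance
  st <- simulate_glide(0.2, 2, 20)
  expect_true(st$stopped)
  expect_equal(st$v_out, 0)
  expect_lt(st$distance, 20)
})

test_that("drag-on glide matches an independent ODE oracle, bias accounted", {
  # independent fine-step RK2 integration of dv/dx = -(g C + k v^2) / v
  mu <- 0.036
  g <- 9.81
  k <- ref_params$rho * ref_params$drag_area / (2 * ref_params$mass_total)
  rhs <- function(v) -(g * mu + k * v^2) / v
  v <- 5.5; x <- 0; h <- 1e-3; drag_work <- 0
  while (x < 20) {
    vm <- v + rhs(v) * h / 2
    drag_work <- drag_work + ref_params$mass_total * k * vm^2 * h
    v <- v + rhs(vm) * h
    x <- x + h
  }
  gl <- simulate_glide(mu, 5.5, 20, params = ref_params)
  expect_equal(gl$v_out, v, tolerance = 1e-5)
  # the drag-blind inversion overestimates mu by exactly the drag work
  # spread over the zone: mu_hat - mu = W_drag / (m g d)  (~7e-3 at the
  # poling-posture drag area; small only for a tucked posture)
  mu_hat <- estimate_friction(gl$v_in, gl$v_out, gl$distance)
  bias <- drag_work / (ref_params$mass_total * g * 20)
  expect_equal(mu_hat - mu, bias, tolerance = 1e-3)
  expect_gt(mu_hat, mu)
  expect_lt(mu_hat - mu, 0.01)
})

test_that("friction estimates combine by arithmetic mean", {
  expect_equal(combine_friction(c(0.039, 0.033)), 0.036)
  expect_equal(combine_friction(0.05), 0.05)
  expect_equal(combine_friction(rep(0.041, 7)), 0.041)
  expect_error(combine_friction(numeric(0)), "no friction")
})

test_that("vmax picks the best trial and percent_of_max scales", {
  v <- vmax_from_splits(20, c(5.0, 5.2))
  expect_equal(v$v_max, 4.0)
  expect_equal(v$best_time, 5.0)
  expect_equal(vmax_from_splits(20, 3.2258)$v_max, 6.2, tolerance = 1e-3)
  expect_equal(vmax_from_splits(15, 5)$v_max, 3)
  expect_error(vmax_from_splits(20, numeric(0)), "trial")
  expect_error(vmax_from_splits(0, 5), "zone_length")

  expect_equal(percent_of_max(4, 4), 100)
  expect_equal(percent_of_max(2, 4), 50)
  expect_equal(percent_of_max(0, 3), 0)
  expect_error(percent_of_max(1, 0), "max_value")
})

test_that("per-section power rows respect terrain drag areas and downhill", {
  course <- tiny_course()
  ref <- lay_out_reference(course)
  sp <- virtual_splits(map_to_course(track_on_reference(ref, 2), ref), course)
  sp <- power_by_section(sp, ref_params,
                         drag_by_terrain = c(uphill = 0.338, flat = 0.336))
  expect_true(all(!is.na(sp$P_tot[sp$terrain != "downhill"])))
  expect_true(all(is.na(sp$P_tot[sp$terrain == "downhill"])))
  pb_u <- power_breakdown(sp$mean_speed[1], course$grade[1], ref_params)
  expect_equal(sp$P_tot[1], pb_u$P_tot, tolerance = 1e-9)
  p_flat <- ref_params; p_flat$drag_area <- 0.336
  pb_f <- power_breakdown(sp$mean_speed[2], 0, p_flat)
  expect_equal(sp$P_tot[2], pb_f$P_tot, tolerance = 1e-9)
})
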