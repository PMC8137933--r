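test_that("protocol validation enforces physical parameters", {
  p <- smd_protocol()
  expect_equal(p$spring_constant, 1000)
  expect_equal(p$pull_velocity, 1)
  expect_equal(p$max_duration, 50)
  expect_equal(p$n_replicas, 5)
  expect_error(smd_protocol(spring_constant = -1), "positive")
  expect_error(smd_protocol(max_duration = 0.001, time_step = 0.01),
               "max_duration")
})

test_that("the spring force identity holds exactly along every trace", {
  pot <- membrane_potential(300)
  proto <- smd_protocol(seed = 2L)
  tr <- run_steered(pot, proto, seed = 5)
  expect_identical(tr$forces, proto$spring_constant * tr$extensions)
  expect_true(all(diff(tr$times) > 0))
  # doubling the spring constant doubles the force at fixed extension
  tr2 <- cppforge:::new_force_trace(tr$times, 2 * proto$spring_constant *
                                      tr$extensions, tr$extensions)
  expect_equal(tr2$forces, 2 * tr$forces)
})

test_that("every run terminates by exit or at the duration cap", {
  proto <- smd_protocol()
  tr <- run_steered(membrane_potential(100), proto, seed = 3)
  expect_lte(max(tr$times), proto$max_duration)
  expect_lt(max(tr$times), proto$max_duration)  # crossed and exited early

  flat <- run_steered(flat_potential(), smd_protocol(max_duration = 2),
                      seed = 3)
  expect_equal(length(flat$times), 200)  # no exit event: runs to the cap
})

test_that("the integrator refuses an unstable time step", {
  expect_error(run_steered(membrane_potential(2000),
                           smd_protocol(time_step = 0.5), seed = 1),
               "stability bound")
})

test_that("flat-potential pulling settles at friction x velocity", {
  proto <- smd_protocol(max_duration = 50)
  means <- vapply(1:6, function(s) {
    tr <- run_steered(flat_potential(), proto, seed = s)
    mean(tr$forces[tr$times > proto$max_duration / 2])
  }, 0)
  target <- proto$friction * proto$pull_velocity
  expect_lt(abs(mean(means) - target) / target, 0.05)
})

test_that("zero pull velocity gives zero mean force at equilibrium", {
  proto <- smd_protocol(pull_velocity = 0, max_duration = 30)
  means <- vapply(1:6, function(s) {
    tr <- run_steered(flat_potential(), proto, seed = 10 + s)
    mean(tr$forces[tr$times > 15])
  }, 0)
  # fluctuation scale is sqrt(kT k) ~ 50; the mean must vanish within SE
  expect_lt(abs(mean(means)), 15)
})

test_that("mean maximum force grows with barrier height (paired seeds)", {
  proto <- smd_protocol()
  mean_max <- function(B) {
    mean(vapply(1:8, function(r) {
      max_steering_force(run_steered(membrane_potential(B), proto,
                                     seed = 500 + r),
                         smooth_window = 101L)
    }, 0))
  }
  m <- vapply(c(800, 1300, 1800), mean_max, 0)
  expect_true(all(diff(m) > 0))
})

test_that("replica sets derive distinct per-replica seeds", {
  pot <- sequence_to_potential(pep_md())
  rs <- steered_replicas(pot, smd_protocol(n_replicas = 3L, seed = 8L))
  expect_length(rs$max_forces, 3)
  expect_gt(stats::sd(rs$max_forces), 0)
  rs2 <- steered_replicas(pot, smd_protocol(n_replicas = 3L, seed = 8L))
  expect_identical(rs$max_forces, rs2$max_forces)
})

test_that("maximum steering force reads raw or smoothed maxima", {
  tr <- cppforge:::new_force_trace(0:2, c(0, 5, 10), c(0, 5, 10) / 1000)
  expect_equal(max_steering_force(tr), 10)
  tr <- cppforge:::new_force_trace(0:2, c(7, 7, 7), rep(7, 3) / 1000)
  expect_equal(max_steering_force(tr), 7)
  tr <- cppforge:::new_force_trace(0:3, c(0, 12, 3, 9), rep(0, 4))
  expect_equal(max_steering_force(tr), 12)
  # centered 3-sample mean: interior values (5, 8); the max is 8
  expect_equal(max_steering_force(tr, smooth_window = 3L), 8)
  expect_error(max_steering_force(tr, smooth_window = 2L), "odd")
  expect_error(cppforge:::new_force_trace(numeric(0), numeric(0),
                                          numeric(0)), "empty")
})

test_that("force traces round-trip through the xvg dialect", {
  f <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("@ title \"x\"", "# comment", "0 0", "1 10", "2 5"), f)
  tr <- read_force_trace(f)
  expect_equal(tr$times, c(0, 1, 2))
  expect_equal(tr$forces, c(0, 10, 5))

  # extension back-computed from a supplied spring constant
  tr <- read_force_trace(f, spring_constant = 1000)
  expect_equal(tr$extensions, c(0, 10, 5) / 1000)

  writeLines(c("0 0", "2 1", "1 5"), f)
  expect_error(read_force_trace(f), "non-monotone")
  writeLines(c("0 0", "1 abc"), f)
  expect_error(read_force_trace(f), "line 2")

  proto <- smd_protocol(max_duration = 1)
  tr <- run_steered(flat_potential(), proto, seed = 4)
  out <- withr::local_tempfile(fileext = ".xvg")
  write_force_trace(tr, out)
  hdr <- readLines(out)
  expect_true(any(grepl("spring_constant = 1000", hdr)))
  expect_true(any(grepl("seed = 4", hdr)))
  back <- read_force_trace(out)
  expect_equal(back$times, tr$times, tolerance = 1e-6)
  expect_equal(back$forces, tr$forces, tolerance = 1e-8)
  expect_equal(back$extensions, tr$extensions, tolerance = 1e-8)
  expect_equal(back$seed, 4L)
})
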