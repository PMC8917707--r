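test_that("zero-noise sleep is exactly the gravity baseline", {
  res <- simulate_motion("sleep", quiet_cfg(),
                         motion_template("sleep", duration_s = 10))
  rec <- res$recording
  expect_equal(nrow(rec), 100)
  expect_true(all(rec$x == 0))
  expect_true(all(rec$y == 1.0))
  expect_true(all(rec$z == 0))
})

test_that("tagged interval spans duration x sample rate", {
  res <- simulate_motion("enter", sim_config(seed = 3))
  tag <- res$tags
  rate <- attr(res$recording, "sample_rate_hz")
  expect_equal((tag$end - tag$start) * rate, 40)
})

test_that("exit envelope is the exact time reversal of the enter envelope", {
  env_in <- motion_envelope("enter", 4, 10)
  env_out <- motion_envelope("exit", 4, 10)
  expect_identical(max(abs(env_out - rev(env_in))), 0)
})

test_that("unknown labels and invalid configs are rejected", {
  expect_error(simulate_motion("dance"), "unknown motion label")
  expect_error(sim_config(sample_rate_hz = 0), "sample_rate_hz")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(motion_template("sleep", amplitude_g = 0.3), "sleep")
})

test_that("session bookkeeping: tag count, ordering and total length", {
  plan <- data.frame(label = c("net_down", "enter", "sleep", "exit", "net_up"))
  sess <- simulate_session(plan, sim_config(seed = 5), gap_s = 60)
  expect_equal(nrow(sess$tags), 5)
  expect_true(all(diff(sess$tags$start) > 0))
  expect_true(all(sess$tags$end[-5] <= sess$tags$start[-1]))
  durations <- c(3, 4, 60, 4, 4)
  expect_equal(nrow(sess$recording), (sum(durations) + 4 * 60) * 10,
               tolerance = 1 / 10)
})

test_that("the study protocol of 14 repetitions x 5 motions yields 70 tags", {
  plan <- data.frame(label = rep(motion_labels(), times = 14))
  sess <- simulate_session(plan, sim_config(seed = 11), gap_s = 1)
  expect_equal(nrow(sess$tags), 70)
})

test_that("identical plan, config and seed give bit-identical recordings", {
  plan <- data.frame(label = c("enter", "sleep", "exit"))
  a <- simulate_session(plan, sim_config(seed = 8), gap_s = 2)
  b <- simulate_session(plan, sim_config(seed = 8), gap_s = 2)
  expect_identical(a$recording, b$recording)
  expect_identical(a$tags, b$tags)
  c <- simulate_session(plan, sim_config(seed = 9), gap_s = 2)
  expect_false(identical(a$recording, c$recording))
})

test_that("long sleep noise converges to the configured noise sd", {
  cfg <- sim_config(noise_sd = 0.02, seed = 21)
  res <- simulate_motion("sleep", cfg, motion_template("sleep", duration_s = 600))
  n <- nrow(res$recording)
  se <- cfg$noise_sd / sqrt(2 * (n - 1))  # sd of a sample sd, normal data
  for (ax in c("x", "y", "z"))
    expect_lt(abs(sd(res$recording[[ax]]) - cfg$noise_sd), 3 * se)
})

test_that("doubling subject_scale exactly doubles enter/exit peak amplitude", {
  for (lab in c("enter", "exit")) {
    a <- simulate_motion(lab, quiet_cfg(seed = 13))$recording
    b <- simulate_motion(lab, quiet_cfg(seed = 13, subject_scale = 2))$recording
    base <- cbind(a$x, a$y - 1, a$z)
    base2 <- cbind(b$x, b$y - 1, b$z)
    expect_equal(max(abs(base2)), 2 * max(abs(base)))
  }
})

test_that("energy ordering: sleep < enter ~ exit < net_down ~ net_up", {
  cfg <- quiet_cfg(seed = 17)
  ms <- vapply(motion_labels(), function(lab) {
    vals <- vapply(1:20, function(i) {
      cfg$seed <- i
      rec <- simulate_motion(lab, cfg)$recording
      mean(rec$x^2 + (rec$y - 1)^2 + rec$z^2)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_lt(ms[["sleep"]], ms[["enter"]])
  expect_lt(ms[["enter"]], ms[["net_down"]])
  expect_lt(ms[["exit"]], ms[["net_up"]])
  expect_lt(abs(log(ms[["enter"]] / ms[["exit"]])), log(1.5))
  expect_lt(abs(log(ms[["net_down"]] / ms[["net_up"]])), log(1.5))
})

test_that("children assigned net handling motions trigger the configured policy", {
  plan <- data.frame(label = c("net_down", "sleep"),
                     subject_class = c("child", "child"))
  expect_warning(simulate_session(plan, sim_config(seed = 1), gap_s = 1),
                 "children perform only")
  expect_error(simulate_session(plan, sim_config(seed = 1), gap_s = 1,
                                on_child_violation = "error"),
               "children perform only")
})

test_that("simulate_study restricts children to enter/sleep/exit", {
  sess <- small_study(seed = 2)
  child_tags <- sess$tags[sess$tags$subject_class == "child", ]
  expect_true(all(child_tags$label %in% child_labels()))
  adult_tags <- sess$tags[sess$tags$subject_class == "adult", ]
  expect_setequal(unique(adult_tags$label), motion_labels())
})
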