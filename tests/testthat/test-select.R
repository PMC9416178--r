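test_that("length principle arithmetic matches the apnea worked examples", {
  # breath-hold intervals: threshold 2*fmin*dt exceeds the observed count
  expect_equal(length_threshold(16.5226), 1.65226)
  expect_false(length_principle(1, 16.5226))
  expect_equal(length_threshold(15.8621), 1.58621)
  expect_false(length_principle(1, 15.8621))
  expect_equal(length_threshold(15.2011), 1.52011)
  expect_false(length_principle(1, 15.2011))
  expect_false(length_principle(0, 16.5226))
  expect_false(length_principle(0, 100))
  expect_true(length_principle(30, 60))   # 6 < 30
  expect_error(length_threshold(0), "positive")
})

test_that("amplitude principle uses the mean absolute difference", {
  expect_false(amplitude_principle(numeric(0), threshold = 0.1))
  expect_true(amplitude_principle(c(0.5, -0.5), threshold = 0.1))
  expect_false(amplitude_principle(c(0.01, -0.01), threshold = 0.1))
  D <- difference(data.frame(time = 1:3, value = c(0, 0.5, 0),
                             kind = c("min", "max", "min"), index = 1:3,
                             stringsAsFactors = FALSE))
  expect_true(amplitude_principle(D, threshold = 0.1))
  expect_error(amplitude_principle(c(1), threshold = -1), "positive")
})

test_that("tag selection prefers chest and flags apnea when both fail", {
  both <- data.frame(epc = c("A", "B"), body_part = c("chest", "abdomen"),
                     passes = c(TRUE, TRUE), stringsAsFactors = FALSE)
  expect_equal(assess_subject(both), list(selected = "A", apnea = FALSE))
  chest_fails <- transform(both, passes = c(FALSE, TRUE))
  expect_equal(assess_subject(chest_fails), list(selected = "B", apnea = FALSE))
  none <- transform(both, passes = c(FALSE, FALSE))
  v <- assess_subject(none)
  expect_true(v$apnea)
  expect_true(is.na(v$selected))
})

test_that("accuracy reproduces the published rate pairs", {
  expect_equal(rate_accuracy(0.25, 0.25), 100)
  expect_equal(round(rate_accuracy(0.388803, 0.3889), 2), 99.98)
  expect_equal(round(rate_accuracy(0.403683, 0.3670), 2), 90.00)
  expect_equal(round(rate_accuracy(0.4073239, 0.4043), 2), 99.25)
  expect_lt(rate_accuracy(0.9, 0.3), 0)   # gross error goes negative
  expect_error(rate_accuracy(0.3, 0), "positive")
})

test_that("monitoring selects an informative tag per subject with high accuracy", {
  for (seed in c(21, 22)) {
    sc <- breathing_scenario(3, noise_sigma = 0.05, ambiguity_prob = 0.05,
                             seed = seed)
    sim <- simulate_streams(sc, 120)
    rep <- monitor_streams(sim$streams)
    expect_equal(nrow(rep$subjects), 3)
    expect_false(any(rep$subjects$apnea))
    for (i in seq_len(3)) {
      s <- rep$subjects[i, ]
      truth <- sim$truth$rate[sim$truth$epc == s$selected]
      expect_gte(rate_accuracy(s$rate, truth), 95)
    }
  }
})

test_that("monitoring errors on an unmapped EPC, naming it", {
  sim <- simulate_streams(breathing_scenario(1, seed = 2), 30)
  empty_map <- data.frame(epc = character(), subject_id = integer(),
                          body_part = character(), stringsAsFactors = FALSE)
  expect_error(monitor_streams(sim$streams, empty_map),
               paste0("unmapped tag.*", names(sim$streams)[1]))
})

test_that("a one-sided breather is monitored through the abdomen tag", {
  s <- subject_spec(1, chest = list(R0 = 1.0, A = 0, rate = 0.25),
                    abdomen = list(R0 = 1.05, A = 0.0025, rate = 0.25))
  sim <- simulate_streams(breathing_scenario(list(s), noise_sigma = 0.005,
                                             ambiguity_prob = 0, seed = 31), 120)
  rep <- monitor_streams(sim$streams)
  expect_false(rep$subjects$apnea)
  expect_equal(rep$tags$body_part[rep$tags$epc == rep$subjects$selected], "abdomen")
})

test_that("sliding-window apnea screening flags holds and spares breathers", {
  hold <- subject_spec(1, apnea_intervals = list(c(20, 40)))
  sim_hold <- simulate_streams(breathing_scenario(list(hold), seed = 41), 60)
  res <- detect_apnea(sim_hold$streams)
  expect_true(res$apnea)
  expect_gte(res$t_flag, 10)
  expect_lte(res$t_flag, 40)
  breather <- subject_spec(1)
  sim_ok <- simulate_streams(breathing_scenario(list(breather), seed = 41), 60)
  expect_false(detect_apnea(sim_ok$streams)$apnea)
})
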