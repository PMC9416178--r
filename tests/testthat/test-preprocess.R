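test_that("disambiguation hand-traced cases", {
  expect_equal(disambiguate(c(1, 1, 1)), c(1, 1, 1))              # no jump
  expect_equal(disambiguate(c(1.0, 1.0 + pi)), c(1.0, 1.0))       # subtract pi
  expect_equal(disambiguate(c(4.0, 4.0 - pi)), c(4.0, 4.0))       # add pi
  expect_equal(disambiguate(numeric(0)), numeric(0))
  expect_error(disambiguate(c(1, 2), delta = 0), "\\(0, pi\\)")
  expect_error(disambiguate(c(1, 2), delta = 4), "\\(0, pi\\)")
})

test_that("disambiguation compares against the running corrected value", {
  # after correcting sample 2, sample 3 (back at truth) must not misfire
  truth <- c(1.0, 1.0, 1.0, 1.0)
  flipped <- c(1.0, 1.0 + pi, 1.0, 1.0 + pi)
  expect_equal(disambiguate(flipped), truth)
})

test_that("unwrapping hand-traced cases and accumulation", {
  expect_equal(unwrap_phase(c(0.1, 0.2, 0.3)), c(0.1, 0.2, 0.3))
  expect_equal(unwrap_phase(c(6.2, 0.05), delta = 1), c(6.2, 0.05 + 2 * pi))
  expect_equal(unwrap_phase(c(0.1, 6.25), delta = 1), c(0.1, 6.25 - 2 * pi))
  # a steady climb through two full cycles accumulates +4*pi of offset
  cont <- seq(5, 5 + 4 * pi, by = 0.5)
  expect_equal(unwrap_phase(cont %% (2 * pi), delta = 1), cont)
  expect_equal(unwrap_phase(numeric(0)), numeric(0))
})

test_that("unwrap agrees with the cumulative-correction oracle on smooth signals", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- seq(0, 60, by = 0.05)
    cont <- 3 + 2.5 * sin(2 * pi * 0.08 * t) + cumsum(rnorm(length(t), 0, 0.01))
    wrapped <- cont %% (2 * pi)
    u <- unwrap_phase(wrapped, delta = 1)
    o <- unwrap_oracle(wrapped)
    off <- (u - o) / (2 * pi)
    expect_equal(off, rep(round(off[1]), length(off)), tolerance = 1e-9)
  }
})

test_that("disambiguate and unwrap are idempotent and length-preserving", {
  set.seed(7)
  wrapped <- (2 + 1.5 * sin(seq(0, 20, by = 0.04))) %% (2 * pi)
  flips <- runif(length(wrapped)) < 0.1
  flips[1] <- FALSE
  x <- (wrapped + flips * pi) %% (2 * pi)
  d1 <- disambiguate(x)
  expect_length(d1, length(x))
  expect_equal(disambiguate(d1), d1)
  u1 <- unwrap_phase(d1)
  expect_length(u1, length(x))
  expect_equal(unwrap_phase(u1), u1)
})

test_that("injected pi-ambiguities are recovered on a smooth quantized truth", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- seq(0, 60, by = 0.04)
    cont <- 4.0 + 0.2 * sin(2 * pi * 0.25 * t)          # smooth truth phase
    truth_q <- quantize_phase(cont)$phase
    flips <- runif(length(t)) < 0.1
    flips[1] <- FALSE                                    # anchor the reference
    observed <- quantize_phase(cont + flips * pi)$phase
    rec <- disambiguate(observed)
    frac_ok <- mean(abs(rec - truth_q) <= phase_resolution() + 1e-12)
    expect_gte(frac_ok, 0.99)
  }
})

test_that("sampling rate is intervals over spanned seconds", {
  expect_equal(estimate_fs(c(0, 1000)), 1)
  expect_equal(estimate_fs(c(0, 500, 1000)), 2)
  expect_equal(estimate_fs(seq(0, 9971, length.out = 232)), 231 / 9.971)
  expect_error(estimate_fs(1000), "at least 2")
  expect_error(estimate_fs(c(0, 0, 100)), "strictly increasing")
})

test_that("uniform resampling reproduces uniform input and exact ramps", {
  t <- seq(0, 10, by = 0.1)
  y <- 2 * t + 1
  cs <- resample_uniform(t, y, Fs = 10)
  expect_equal(cs$t, t)
  expect_equal(cs$phase, y)
  # linear interpolation of a linear function is exact at any rate
  tj <- sort(runif(200, 0, 10))
  cs2 <- resample_uniform(c(0, tj, 10), 3 * c(0, tj, 10) - 2, Fs = 7)
  expect_equal(cs2$phase, 3 * cs2$t - 2)
  expect_equal(diff(cs2$t), rep(1 / 7, length(cs2$t) - 1))
})

test_that("jittered sine resampling error is second order in the gap", {
  set.seed(11)
  fr <- 0.3
  gaps <- 0.04 * (1 + runif(1500, -0.2, 0.2))
  t <- cumsum(c(0, gaps))
  cs <- resample_uniform(t, sin(2 * pi * fr * t))
  truth <- sin(2 * pi * fr * cs$t)               # dense analytic oracle
  bound <- (2 * pi * fr * max(diff(t)))^2        # curvature-term bound
  expect_lt(max(abs(cs$phase - truth)), bound)
  expect_error(resample_uniform(c(0, 0, 1), 1:3), "strictly increasing")
})

test_that("clean_stream composes the steps and keeps the EPC", {
  sim <- simulate_streams(one_tag_scenario(noise = 0.01, ambiguity = 0.05, seed = 4), 30)
  cs <- clean_stream(sim$streams[[1]])
  expect_s3_class(cs, "clean_stream")
  expect_equal(cs$epc, names(sim$streams)[1])
  expect_equal(diff(cs$t), rep(1 / cs$Fs, length(cs$t) - 1))
  # no pi- or 2*pi-sized jumps survive cleaning
  expect_true(all(abs(diff(cs$phase)) < 1))
})
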