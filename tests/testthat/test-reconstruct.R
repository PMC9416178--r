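test_that("extremum detection handles peaks, ramps and plateaus", {
  ex <- detect_extrema(c(0, 1, 0), 0:2)
  expect_equal(nrow(ex), 1)
  expect_equal(ex$kind, "max")
  expect_equal(ex$index, 2)
  expect_equal(nrow(detect_extrema(1:10)), 0)          # monotone ramp
  expect_equal(nrow(detect_extrema(c(1, 2))), 0)       # too short
  # plateau contributes its first sample
  exp_ <- detect_extrema(c(0, 2, 2, 2, 0, -1, -1, 0), 1:8)
  expect_equal(exp_$index, c(2L, 6L))
  expect_equal(exp_$kind, c("max", "min"))
})

test_that("a sampled sine yields alternating extrema, one pair per period", {
  t <- seq(0, 12 - 0.05, by = 0.05)                     # 3 periods at 0.25 Hz
  ex <- detect_extrema(sin(2 * pi * 0.25 * t), t)
  expect_equal(sum(ex$kind == "max"), 3)
  expect_equal(sum(ex$kind == "min"), 3)
  expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
})

test_that("amplitude filter keeps large swings and drops small ones", {
  full <- data.frame(time = 1:4, value = c(2, -2, 2, -2),
                     kind = c("max", "min", "max", "min"),
                     index = 1:4, stringsAsFactors = FALSE)
  # threshold = 0.5 * (2 - (-2)) = 2; every swing is 4 >= 2
  expect_equal(filter_extrema(full), full)
  # an interloping small maximum (swing 1.5 < 2 from the last kept minimum)
  withsmall <- data.frame(time = c(1, 2, 2.5, 3, 4),
                          value = c(2, -2, -0.5, 2, -2),
                          kind = c("max", "min", "max", "max", "min"),
                          index = 1:5, stringsAsFactors = FALSE)
  out <- filter_extrema(withsmall)
  expect_false(-0.5 %in% out$value)
  expect_equal(out$value, c(2, -2, 2, -2))
  expect_equal(nrow(filter_extrema(full[0, ])), 0)
  expect_error(filter_extrema(full, alpha = 0), "alpha")
})

test_that("amplitude filter is a no-op when all gaps clear the threshold", {
  set.seed(3)
  v <- rep(c(5, -5), 10) + rnorm(20, 0, 0.1)
  ex <- data.frame(time = 1:20, value = v,
                   kind = rep(c("max", "min"), 10), index = 1:20,
                   stringsAsFactors = FALSE)
  expect_equal(filter_extrema(ex, alpha = 0.5), ex)
})

test_that("differencing and alternation enforcement follow the decision rule", {
  e1 <- data.frame(time = 1:3, value = c(2, -2, 2),
                   kind = c("max", "min", "max"), index = 1:3,
                   stringsAsFactors = FALSE)
  D1 <- difference(e1)
  expect_equal(D1$d, c(-4, 4))
  expect_equal(D1$L, 2)
  expect_equal(enforce_alternation(D1)$d, c(-4, 4))    # already alternating
  # same-sign pair: drop the shared middle extremum
  e2 <- data.frame(time = 1:3, value = c(0, 3, 5),
                   kind = c("min", "max", "max"), index = 1:3,
                   stringsAsFactors = FALSE)
  D2 <- enforce_alternation(difference(e2))
  expect_equal(D2$d, 5)
  expect_equal(D2$extrema$value, c(0, 5))
  # single extremum: empty difference sequence is valid
  expect_equal(difference(e1[1, ])$L, 0)
})

test_that("alternation invariant holds for random extremum sequences", {
  for (seed in 1:25) {
    D <- enforce_alternation(difference(random_extrema(sample(2:40, 1), seed)))
    if (D$L >= 2) {
      expect_true(all(sign(D$d[-1]) * sign(D$d[-D$L]) == -1),
                  label = sprintf("seed %d", seed))
    }
    expect_equal(D$d, diff(D$extrema$value))
  }
})

test_that("spline passes through every knot and degenerates to a line", {
  two <- data.frame(time = c(0, 4), value = c(1, 3),
                    kind = c("min", "max"), index = 1:2, stringsAsFactors = FALSE)
  wf <- spline_waveform(two, Fs_out = 4)
  expect_equal(wf$y, 1 + 0.5 * wf$t)                   # straight line
  t_k <- c(1, 3, 5, 7, 9)
  knots <- data.frame(time = t_k, value = sin(t_k),
                      kind = rep(c("max", "min"), length.out = 5),
                      index = 1:5, stringsAsFactors = FALSE)
  f <- stats::splinefun(knots$time, knots$value, method = "natural")
  expect_equal(f(t_k), sin(t_k))
  expect_error(spline_waveform(two[1, ]), "at least 2")
})

test_that("spline through the true extrema of a sine tracks the sine", {
  fr <- 0.25
  t_ext <- seq(1, 29, by = 2)                           # extrema of sin(2*pi*0.25*t)
  knots <- data.frame(time = t_ext, value = sin(2 * pi * fr * t_ext),
                      kind = rep(c("max", "min"), length.out = length(t_ext)),
                      index = seq_along(t_ext), stringsAsFactors = FALSE)
  wf <- spline_waveform(knots, Fs_out = 10)
  expect_gt(cor(wf$y, sin(2 * pi * fr * wf$t)), 0.95)
})

test_that("reconstructed breath count matches the true rate", {
  for (seed in 1:5) {
    fr <- c(0.2, 0.25, 0.3, 0.33, 0.22)[seed]
    dur <- 60
    sim <- simulate_streams(one_tag_scenario(rate = fr, noise = 0.05,
                                             ambiguity = 0.05, seed = seed), dur)
    cs <- clean_stream(sim$streams[[1]])
    rec <- reconstruct_waveform(cs, signal = bandpass(remove_dc(cs$phase), Fs = cs$Fs))
    n_peaks <- sum(rec$extrema$kind == "max")
    expect_lte(abs(n_peaks - fr * dur), 1.5, label = sprintf("fr = %.2f", fr))
  }
})
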