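test_that("noiseless staircases are called exactly", {
  x <- c(rep(200, 100), rep(100, 100), rep(0, 100))
  call <- detect_steps(trace("t1", x))
  expect_equal(call$quality, "clean")
  expect_equal(call$k, 2L)
  expect_equal(call$changepoints, c(100L, 200L))
  expect_equal(call$levels, c(200, 100, 0))
})

test_that("flat traces are discarded, not called", {
  call <- detect_steps(trace("flat", rep(0, 50)))
  expect_equal(call$quality, "discarded")
  expect_true(is.na(call$k))
  expect_match(call$reason, "no steps")
})

test_that("upward or sub-threshold level changes discard the trace", {
  up <- detect_steps(trace("up", c(rep(0, 50), rep(100, 50), rep(0, 50))))
  expect_equal(up$quality, "discarded")
  small <- detect_steps(trace("small", c(rep(30, 100), rep(0, 100))),
                        min_step = 50)
  expect_equal(small$quality, "discarded")
  # a trace that never bleaches to baseline is discarded too
  high <- detect_steps(trace("high", c(rep(200, 100), rep(100, 100))))
  expect_equal(high$quality, "discarded")
  expect_match(high$reason, "baseline")
})

test_that("detector is deterministic and >= 95% accurate at SNR 10", {
  st <- make_traces(trace_spec(n_traces = 400, n = 2, p = 0.8, unit = 100,
                               noise_sd = 10, seed = 81))
  calls <- lapply(st$traces, detect_steps)
  calls2 <- lapply(st$traces, detect_steps)
  expect_identical(calls, calls2)
  got <- vapply(calls, function(c_) if (is.na(c_$k)) -1L else c_$k, 1L)
  clean <- got > 0
  acc <- mean(got[clean] == st$truth$k[clean])
  expect_gte(acc, 0.95)
  # dark complexes (k = 0) must not produce clean calls
  expect_true(all(got[st$truth$k == 0] == -1L))
})

test_that("step distributions aggregate clean calls and keep discards", {
  mk_call <- function(k) {
    kk <- if (is.na(k)) 0L else k
    structure(
      list(id = "x", k = k, changepoints = seq_len(kk),
           levels = seq(100 * kk, 0, by = -100),
           quality = if (is.na(k)) "discarded" else "clean",
           reason = NA_character_, sigma = 1), class = "step_call")
  }
  calls <- list(mk_call(1L), mk_call(2L), mk_call(2L), mk_call(NA_integer_))
  d <- step_distribution(calls)
  expect_equal(unname(d$counts), c(1L, 2L))
  expect_equal(d$discarded, 1L)
  expect_equal(d$total, 4L)
  expect_equal(sum(100 * d$counts / sum(d$counts)), 100)
  expect_error(step_distribution(list(mk_call(NA_integer_))), "discarded")
})

test_that("intensity ratio is 2 for noiseless fixtures and scale-free", {
  st <- make_traces(trace_spec(n_traces = 60, n = 2, p = 0.8, noise_sd = 0,
                               seed = 83))
  # drop the discretization artifact of two bleach events landing on the
  # same frame (those collapse to a single double-height step)
  distinct <- vapply(strsplit(st$truth$steps, ","), function(s)
    !anyDuplicated(s), TRUE)
  st$traces <- st$traces[distinct]
  calls <- lapply(st$traces, detect_steps)
  expect_equal(intensity_ratio(calls), 2, tolerance = 1e-9)
  # rescaling all intensities leaves the ratio unchanged
  scaled <- lapply(st$traces, function(tr)
    trace(tr$id, tr$intensity * 3.7, tr$frame))
  calls_s <- lapply(scaled, function(tr) detect_steps(tr, min_step = 50))
  expect_equal(intensity_ratio(calls_s), 2, tolerance = 1e-9)
  expect_error(intensity_ratio(calls[1]), "one-step")
})
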