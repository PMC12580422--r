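test_that("resampling maps traces of any length onto the 33-point grid", {
  # constant trace
  cv <- resample_trace(strain_trace(rep(5, 5), "torsion", "a"))
  expect_length(cv$values, 33)
  expect_equal(cv$values, rep(5, 33))
  expect_equal(cv$grid, (0:32) / 32)

  # identity on matching grid
  set.seed(1)
  v33 <- rnorm(33)
  expect_equal(resample_trace(strain_trace(v33, "gls", "a"))$values, v33,
               tolerance = 1e-12)

  # linear ramp of length 50 stays a ramp and matches the oracle
  ramp <- seq(0, 9.8, length.out = 50)
  out <- resample_trace(strain_trace(ramp, "rotation_apical", "a"))
  expect_equal(out$values, seq(0, 9.8, length.out = 33), tolerance = 1e-12)
  expect_lt(max(abs(out$values - interp_oracle(ramp))), 1e-12)
})

test_that("resampling matches the interpolation oracle on random traces", {
  set.seed(7)
  for (n in c(2, 3, 17, 33, 50, 121)) {
    v <- rnorm(n, sd = 10)
    out <- resample_trace(strain_trace(v, "torsion", "x"))$values
    expect_lt(max(abs(out - interp_oracle(v))), 1e-12)
    # endpoints preserved exactly, no overshoot
    expect_identical(out[1], v[1])
    expect_identical(out[33], v[n])
    expect_gte(min(out), min(v))
    expect_lte(max(out), max(v))
    # idempotent once on the grid
    out2 <- resample_trace(strain_trace(out, "torsion", "x"))$values
    expect_equal(out2, out, tolerance = 1e-12)
  }
})

test_that("invalid traces are rejected", {
  expect_error(strain_trace(5, "gls"), "at least 2")
  expect_error(strain_trace(c(1, NA), "gls"), "non-finite")
  expect_error(strain_trace(c(1, Inf), "gls"), "non-finite")
  expect_error(strain_trace(c(1, 2), "nonsense"))
  expect_error(normalized_curve(rep(1, 20), "gls"), "exactly 33")
})

test_that("torsion is the apical-minus-basal rotation difference", {
  set.seed(2)
  a <- normalized_curve(rnorm(33), "rotation_apical", "s1")
  b <- normalized_curve(rnorm(33), "rotation_basal", "s1")
  tw <- compute_torsion(a, b)
  expect_identical(tw$modality, "torsion")
  expect_equal(tw$values, a$values - b$values)

  # self-difference and constant difference
  a0 <- normalized_curve(b$values, "rotation_apical", "s1")
  expect_equal(compute_torsion(a0, b)$values, rep(0, 33))
  ca <- normalized_curve(rep(2, 33), "rotation_apical")
  cb <- normalized_curve(rep(-1, 33), "rotation_basal")
  expect_equal(compute_torsion(ca, cb)$values, rep(3, 33))

  # antisymmetry under swapping roles
  a2 <- normalized_curve(b$values, "rotation_apical")
  b2 <- normalized_curve(a$values, "rotation_basal")
  expect_equal(compute_torsion(a, b)$values,
               -compute_torsion(a2, b2)$values)

  expect_error(compute_torsion(b, a), "modalities")
  expect_error(compute_torsion(a, a), "modalities")
})

test_that("curve summaries find the signed peak and its timing", {
  tg <- cycle_grid(33)
  tor <- normalized_curve(sin(pi * tg), "torsion")
  s <- summarize_curve(tor)
  expect_equal(s$peak_value, 1)
  expect_equal(s$time_to_peak, 0.5)

  gls <- normalized_curve(-20 * sin(pi * tg), "gls")
  s <- summarize_curve(gls)
  expect_equal(s$peak_value, -20)
  expect_equal(s$time_to_peak, 0.5)

  # brute-force scan agreement on random curves, both conventions
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(33)
    s_tor <- summarize_curve(normalized_curve(v, "torsion"))
    expect_equal(s_tor$peak_value, max(v))
    expect_equal(s_tor$time_to_peak, tg[which.max(v)])
    s_gls <- summarize_curve(normalized_curve(v, "rv_free_wall"))
    expect_equal(s_gls$peak_value, min(v))
    expect_equal(s_gls$time_to_peak, tg[which.min(v)])
  }

  # ties resolved to the earliest time
  flat <- normalized_curve(c(0, rep(1, 32)), "torsion")
  expect_equal(summarize_curve(flat)$time_to_peak, tg[2])
})

test_that("trace files round-trip through the readers and writers", {
  tmp <- withr::local_tempdir()
  # long-format trace file with two subjects, ragged lengths
  long <- rbind(
    data.frame(subject_id = "s1", modality = "gls", frame_index = 0:40,
               value = -18 * sin(pi * (0:40) / 40)),
    data.frame(subject_id = "s2", modality = "torsion", frame_index = 0:24,
               value = 22 * sin(pi * (0:24) / 24)^2))
  p <- file.path(tmp, "traces.csv")
  write.csv(long, p, row.names = FALSE)
  traces <- read_traces(p)
  expect_length(traces, 2)
  expect_setequal(vapply(traces, function(x) x$modality, ""),
                  c("gls", "torsion"))
  expect_length(traces[[1]]$values, 41)

  # non-contiguous frame index is rejected
  bad <- long[-3, ]
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_traces(p), "contiguous")

  # normalized curves round-trip exactly
  curves <- lapply(traces, resample_trace)
  pc <- file.path(tmp, "curves.csv")
  write_curves(curves, pc)
  back <- read_curves(pc)
  expect_length(back, 2)
  ord <- match(vapply(curves, function(x) x$subject_id, ""),
               vapply(back, function(x) x$subject_id, ""))
  for (i in seq_along(curves)) {
    expect_equal(back[[ord[i]]]$values, curves[[i]]$values,
                 tolerance = 1e-9)
    expect_equal(back[[ord[i]]]$grid, curves[[i]]$grid, tolerance = 1e-7)
  }
})
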