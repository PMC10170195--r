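test_that("dark times are the empty-frame gaps between events", {
  expect_equal(extract_dark_times(c(10L, 20L), 0.1), 0.9)
  expect_equal(extract_dark_times(c(3L, 4L, 5L), 0.1), numeric(0))
  expect_equal(extract_dark_times(c(5L, 4L, 3L, 5L), 0.1), numeric(0))
  expect_equal(extract_dark_times(c(0L, 2L, 10L), 0.5), c(0.5, 3.5))
  expect_warning(out <- extract_dark_times(integer(0), 0.1), "no event")
  expect_equal(out, numeric(0))
})

test_that("dark times of a simulated single site recover the kinetic
           mean", {
  # long acquisition: negligible window truncation; rate 0.01/s -> 100 s
  acq <- acquisition_params(n_frames = 1.5e6, frame_time = 0.1)
  ev <- simulate_binding_timeseries(1, acq, default_kin, seed = 12)
  dt <- extract_dark_times(unlist(event_frames(ev, 1)), 0.1)
  expect_gt(length(dt), 1e3)
  expect_lt(abs(mean(dt) - 100) / 100, 3 / sqrt(length(dt)))
})

test_that("dark-time fit agrees with the sample-mean MLE on exponential
           data", {
  set.seed(7)
  draws <- stats::rexp(1e4, rate = 1 / 83.3)
  fit <- fit_dark_time(draws)
  expect_equal(fit$method, "cdf_fit")
  expect_lt(abs(fit$tau_d - mean(draws)) / mean(draws), 0.05)
  expect_lt(abs(fit$tau_d - 83.3) / 83.3, 0.05)
})

test_that("dark-time fit degenerate and scaling behaviour", {
  expect_equal(fit_dark_time(50)$tau_d, 50)        # single gap
  expect_equal(fit_dark_time(rep(7, 20))$tau_d, 7) # all-identical gaps
  set.seed(8)
  d <- stats::rexp(500, 1 / 10)
  expect_equal(fit_dark_time(3 * d)$tau_d, 3 * fit_dark_time(d)$tau_d,
               tolerance = 1e-6)
  expect_error(fit_dark_time(numeric(0)), "zero gaps")
  expect_error(fit_dark_time(c(1, -1)), "> 0")
})

test_that("the qPAINT index is the reciprocal dark time", {
  expect_equal(qpaint_index(100), 0.01)
  expect_equal(qpaint_index(83.3), 0.012, tolerance = 1e-3)
  expect_equal(1 / qpaint_index(37.5), 37.5)
  expect_error(qpaint_index(0), "tau_d")
})

test_that("calibration on a pure single-site population recovers the
           inverse mean dark time", {
  set.seed(15)
  # per-cluster indexes concentrated around one peak
  q <- 1 / vapply(1:400, function(i) {
    mean(stats::rexp(120, 1 / 83.3))
  }, 0)
  cal <- calibrate_qpaint(q)
  expect_equal(cal$method, "multi_gauss")
  expect_lt(abs(cal$q_i1 - 1 / 83.3) / (1 / 83.3), 0.05)
  expect_gt(cal$counting_precision, 0)
})

test_that("calibration resolves a 1/2/3-site mixture with rank-ordered
           peak weights", {
  set.seed(16)
  n_per <- c(240, 120, 40)  # 60/30/10%
  q <- unlist(lapply(1:3, function(k) {
    1 / vapply(seq_len(n_per[k]), function(i) {
      mean(stats::rexp(150, k / 83.3))
    }, 0)
  }))
  cal <- calibrate_qpaint(q)
  expect_lt(abs(cal$q_i1 - 1 / 83.3) / (1 / 83.3), 0.10)
  w <- cal$peaks$amplitude[1:3] * cal$peaks$sigma[1:3]  # ~ peak masses
  expect_true(w[1] > w[2] && w[2] > w[3])
})

test_that("calibration rejects an undersized cluster population", {
  expect_error(calibrate_qpaint(stats::rexp(10, 100)), "eligible")
})

test_that("copy numbers follow the calibrated index ratio", {
  cal <- qpaint_calibration(q_i1 = 0.01)
  expect_equal(count_proteins(0.01, cal)$n_proteins, 1L)
  # tau_off 25 s at a 0.01/s single-site rate: 1 / (0.01 * 25) = 4
  expect_equal(count_proteins(qpaint_index(25), cal)$n_proteins, 4L)
  expect_equal(count_proteins(0.05, cal)$n_proteins, 5L)
  expect_equal(count_proteins(0.015, cal)$n_proteins, 2L)  # half rounds up
  expect_equal(count_proteins(0.001, cal)$n_proteins, 1L)  # floor at 1
  expect_equal(count_proteins(0.025, cal)$raw_ratio, 2.5)
})

test_that("qPAINT indexes are additive over merged independent sites", {
  acq <- acquisition_params(n_frames = 60000)
  q_single <- c(); q_merged <- c()
  ev <- simulate_binding_timeseries(160, acq, default_kin, seed = 44)
  fr <- event_frames(ev, 160)
  for (i in seq_len(80)) {
    a <- fr[[2 * i - 1]]; b <- fr[[2 * i]]
    qa <- qpaint_index(fit_dark_time(extract_dark_times(a, 0.1)))
    qb <- qpaint_index(fit_dark_time(extract_dark_times(b, 0.1)))
    qm <- qpaint_index(fit_dark_time(extract_dark_times(
      sort(unique(c(a, b))), 0.1)))
    q_single <- c(q_single, qa + qb)
    q_merged <- c(q_merged, qm)
  }
  expect_lt(abs(mean(q_merged) - mean(q_single)) / mean(q_single), 0.05)
})

test_that("planted copy numbers are recovered end to end", {
  # calibration from a monomer-dominated 1-3 site mixture under
  # identical conditions
  set.seed(9)
  mix <- sample(1:3, 300, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  ev <- simulate_binding_timeseries(sum(mix), default_acq, default_kin,
                                    seed = 31)
  fr <- event_frames(ev, sum(mix))
  idx <- split(seq_len(sum(mix)), rep(seq_along(mix), mix))
  qcal <- vapply(idx, function(ix) {
    dt <- extract_dark_times(sort(unique(unlist(fr[ix]))), 0.1)
    if (length(dt) < 2) return(NA_real_)
    qpaint_index(fit_dark_time(dt))
  }, 0)
  cal <- calibrate_qpaint(qcal[!is.na(qcal)])

  recover <- function(n_true, reps = 50L) {
    ev <- simulate_binding_timeseries(n_true * reps, default_acq,
                                      default_kin, seed = 100 + n_true)
    fr <- event_frames(ev, n_true * reps)
    grp <- split(seq_len(n_true * reps), rep(seq_len(reps), each = n_true))
    vapply(grp, function(ix) {
      dt <- extract_dark_times(sort(unique(unlist(fr[ix]))), 0.1)
      count_proteins(qpaint_index(fit_dark_time(dt)), cal)$n_proteins
    }, 0L)
  }
  for (n_true in c(1L, 2L, 4L, 6L)) {
    expect_gte(mean(abs(recover(n_true) - n_true) <= 1), 0.8)
  }
  # beyond ~6 sites per cluster the count saturates (simultaneous bright
  # events hide gaps); the mean still tracks the planted number
  nhat12 <- recover(12L)
  expect_lt(abs(mean(nhat12) - 12) / 12, 0.20)
})

test_that("longer acquisitions tighten the dark-time estimate", {
  spreads <- vapply(c(5000L, 15000L, 45000L), function(nf) {
    acq <- acquisition_params(n_frames = nf)
    ev <- simulate_binding_timeseries(200, acq, default_kin,
                                      seed = 500 + nf)
    fr <- event_frames(ev, 200)
    taus <- vapply(fr, function(f) {
      dt <- suppressWarnings(extract_dark_times(f, 0.1))
      if (length(dt) < 2) return(NA_real_)
      fit_dark_time(dt)$tau_d
    }, 0)
    # robust spread: per-site tau_d is heavy-tailed at few gaps
    stats::IQR(taus, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(spreads) < 0))
})
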