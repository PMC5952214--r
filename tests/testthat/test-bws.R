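ref_summaries <- function(basal = c(4.0, 4.2, 4.4),
                          event = c(4.5, 4.5, 4.5), n_fish = 13) {
  tibble::tibble(
    experiment = "sim", tank = "1", day = seq_along(basal),
    n_fish = as.integer(n_fish),
    basal_mean = basal, basal_sd = 0.1, event_se = event
  )
}

test_that("reference sub-models are means and sds over reference days", {
  ref <- build_reference(ref_summaries())
  expect_equal(ref$basal_mean, 4.2)
  expect_equal(ref$basal_sd, 0.2, tolerance = 1e-12)
  expect_equal(ref$event_mean, 4.5)
  expect_equal(ref$event_sd, 0)
  expect_equal(ref$ratio_mean, mean(c(4.0, 4.2, 4.4) / 4.5),
               tolerance = 1e-12)  # ~0.933
  expect_equal(ref$n_reference_days, 3)
  expect_null(ref$one_fish_warning)

  expect_error(build_reference(ref_summaries()[1, ]), ">= 2")
  mixed <- ref_summaries()
  mixed$n_fish <- c(13L, 13L, 25L)
  expect_error(build_reference(mixed), "conditional on fish count")
  zero <- ref_summaries(event = c(4.5, 0, 4.5))
  expect_error(build_reference(zero), "ratio undefined")
})

test_that("one-fish references carry a structured warning", {
  ref <- build_reference(ref_summaries(basal = c(0.6, 1.8, 0.9),
                                       event = c(2.8, 2.6, 2.3),
                                       n_fish = 1))
  expect_false(is.null(ref$one_fish_warning))
  expect_equal(ref$one_fish_warning$observed_basal_cv,
               cv(c(0.6, 1.8, 0.9)), tolerance = 1e-9)
})

test_that("error signals and the two-sided k*sd alarm rule", {
  ref <- build_reference(ref_summaries())

  # observation at the reference means: zero errors, no alarms
  at_mean <- tibble::tibble(day = 9L, basal_mean = ref$basal_mean,
                            event_se = 4.5)
  es <- compute_error_signals(ref, at_mean)
  expect_equal(es$e_basal, 0)
  expect_false(es$any_alarm)

  # basal 3.0 against 4.2 +/- 0.2 at k = 2: |-1.2| > 0.4, alarm
  low <- tibble::tibble(day = 10L, basal_mean = 3.0, event_se = 4.5)
  es2 <- compute_error_signals(ref, low)
  expect_equal(es2$e_basal, -1.2)
  expect_true(es2$alarm_basal)
  expect_true(es2$any_alarm)

  # symmetry: the mirrored deviation alarms identically
  high <- tibble::tibble(day = 11L, basal_mean = 4.2 + 1.2, event_se = 4.5)
  es3 <- compute_error_signals(ref, high)
  expect_equal(es3$alarm_basal, es2$alarm_basal)

  # zero-sd channel: equality is quiet, any deviation alarms
  es4 <- compute_error_signals(ref, tibble::tibble(day = 1L,
                                                   basal_mean = 4.2,
                                                   event_se = 4.5))
  expect_false(es4$alarm_event)
  es5 <- compute_error_signals(ref, tibble::tibble(day = 1L,
                                                   basal_mean = 4.2,
                                                   event_se = 4.5 + 1e-6))
  expect_true(es5$alarm_event)
})

test_that("growing a deviation never clears an alarm (monotonicity)", {
  ref <- build_reference(ref_summaries(basal = c(4.0, 4.1, 4.2, 4.3),
                                       event = c(4.4, 4.6, 4.5, 4.5)))
  deviations <- seq(0, 2, by = 0.1)
  fired <- FALSE
  for (d in deviations) {
    es <- compute_error_signals(ref, tibble::tibble(
      day = 1L, basal_mean = ref$basal_mean + d, event_se = ref$event_mean
    ))
    if (fired) expect_true(es$alarm_basal)
    fired <- fired || es$alarm_basal
  }
  expect_true(fired)
})

test_that("monitoring a stream flags shifted days from onset onwards", {
  ref <- build_reference(ref_summaries(basal = c(4.0, 4.1, 4.2, 4.3, 4.4),
                                       event = c(4.4, 4.6, 4.5, 4.7, 4.3)))
  # empty stream: empty output
  empty <- monitor_stream(ref, ref_summaries()[0, ])
  expect_equal(nrow(empty), 0)

  # constructed -3 sd basal shift from day 10 of a 20-day stream
  stream <- tibble::tibble(
    day = 1:20,
    basal_mean = c(rep(ref$basal_mean, 9),
                   rep(ref$basal_mean - 3 * ref$basal_sd, 11)),
    event_se = rep(ref$event_mean, 20)
  )
  out <- monitor_stream(ref, stream)
  expect_equal(nrow(out), 20)
  expect_false(any(out$alarm_basal[1:9]))
  expect_true(all(out$alarm_basal[10:20]))
  expect_equal(out$any_alarm,
               out$alarm_basal | out$alarm_event | out$alarm_ratio)

  # the integration stub logs and passes rows through
  expect_message(monitor_stream(ref, stream[1, ],
                                integration_hook = log_integration_stub),
                 "any_alarm")
})
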