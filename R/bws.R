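# Biological warning system: reference sub-models built from a healthy
# system's SE record, error signals for newly observed days, and a two-sided
# k*sd alarm rule. Three monitored channels: basal SE, event (response) SE,
# and their ratio.

#' Build a healthy-system reference
#'
#' The three reference sub-models, each a mean +/- sd over the reference
#' days of a healthy system at a fixed fish count: (i) basal SE, from the
#' daily basal means; (ii) event SE, from the daily response values;
#' (iii) the basal/event ratio (`basal_mean / event_se` — dimensionless,
#' direction fixed by convention and recorded here).
#'
#' References are conditional on fish count: SE depends strongly on group
#' size, so mixing counts is refused. A reference built from a one-fish
#' system is permitted but tagged with a warning field: replicate SE values
#' of single fish disperse enormously (CVs up to ~60%), so such systems make
#' poor sensors and should be avoided.
#'
#' @param summaries daily summaries of the healthy system
#'   ([summarise_daily()]), >= 2 rows, all with the same `n_fish`.
#' @param k_tolerance alarm band half-width in sd multiples (default 2).
#' @return A `bws_reference`: list with `basal_mean`, `basal_sd`,
#'   `event_mean`, `event_sd`, `ratio_mean`, `ratio_sd`, `k_tolerance`,
#'   `n_reference_days`, `n_fish`, `one_fish_warning`.
#' @export
build_reference <- function(summaries, k_tolerance = 2) {
  if (nrow(summaries) < 2) {
    stop("need >= 2 reference tank-days", call. = FALSE)
  }
  nf <- unique(summaries$n_fish)
  if (length(nf) != 1) {
    stop("mixed `n_fish` in reference data: the reference is conditional ",
         "on fish count (", paste(nf, collapse = ", "), ")", call. = FALSE)
  }
  if (any(summaries$event_se == 0)) {
    stop("event SE of 0 in reference data: ratio undefined", call. = FALSE)
  }
  ratio <- summaries$basal_mean / summaries$event_se
  ref <- list(
    basal_mean = mean(summaries$basal_mean),
    basal_sd = stats::sd(summaries$basal_mean),
    event_mean = mean(summaries$event_se),
    event_sd = stats::sd(summaries$event_se),
    ratio_mean = mean(ratio),
    ratio_sd = stats::sd(ratio),
    k_tolerance = k_tolerance,
    n_reference_days = nrow(summaries),
    n_fish = nf,
    one_fish_warning = if (nf == 1L) {
      list(
        note = paste("reference built from a one-fish system: replicate SE",
                     "dispersion is very large (CV up to ~60%); avoid",
                     "one-fish sensors"),
        observed_basal_cv = 100 * stats::sd(summaries$basal_mean) /
          mean(summaries$basal_mean)
      )
    } else {
      NULL
    }
  )
  class(ref) <- "bws_reference"
  ref
}

#' @export
print.bws_reference <- function(x, ...) {
  cat(sprintf(
    "<bws_reference> %d fish, %d days | basal %.3f+/-%.3f  event %.3f+/-%.3f  ratio %.3f+/-%.3f  (k = %g)\n",
    x$n_fish, x$n_reference_days, x$basal_mean, x$basal_sd,
    x$event_mean, x$event_sd, x$ratio_mean, x$ratio_sd, x$k_tolerance
  ))
  if (!is.null(x$one_fish_warning)) {
    cat("  WARNING: ", x$one_fish_warning$note, "\n", sep = "")
  }
  invisible(x)
}

#' Error signals and alarms for one observed day
#'
#' The error signal of each channel is `observed - reference mean`; the
#' channel alarms when `|error| > k_tolerance * channel sd` (two-sided — a
#' deviation alarms regardless of sign). A channel with zero reference sd
#' alarms on any non-zero deviation.
#'
#' @param ref a [build_reference()] object.
#' @param observed a one-row daily summary (`basal_mean`, `event_se`).
#' @return A one-row tibble: `day` (if present in `observed`), `e_basal`,
#'   `e_event`, `e_ratio`, `alarm_basal`, `alarm_event`, `alarm_ratio`,
#'   `any_alarm`.
#' @export
compute_error_signals <- function(ref, observed) {
  stopifnot(inherits(ref, "bws_reference"))
  if (nrow(observed) != 1) stop("`observed` must be one day", call. = FALSE)
  if (observed$event_se == 0) stop("observed event SE is 0", call. = FALSE)
  k <- ref$k_tolerance
  e_basal <- observed$basal_mean - ref$basal_mean
  e_event <- observed$event_se - ref$event_mean
  e_ratio <- observed$basal_mean / observed$event_se - ref$ratio_mean
  tibble::tibble(
    day = if ("day" %in% names(observed)) observed$day else NA_integer_,
    e_basal = e_basal, e_event = e_event, e_ratio = e_ratio,
    alarm_basal = abs(e_basal) > k * ref$basal_sd,
    alarm_event = abs(e_event) > k * ref$event_sd,
    alarm_ratio = abs(e_ratio) > k * ref$ratio_sd,
    any_alarm = abs(e_basal) > k * ref$basal_sd |
      abs(e_event) > k * ref$event_sd |
      abs(e_ratio) > k * ref$ratio_sd
  )
}

#' Monitor a stream of daily summaries
#'
#' Applies [compute_error_signals()] day by day, in order. The resulting
#' error signals are the model's outputs; integration into higher-order
#' knowledge models is out of scope here, so `integration_hook` is a stub
#' contract: a function called once per day with that day's error-signal
#' row, default [log_integration_stub()] which only logs.
#'
#' @param ref a [build_reference()] object.
#' @param summaries time-ordered daily summaries.
#' @param integration_hook function(row) called per day; `NULL` disables.
#' @return A tibble with one error-signal row per day (empty for an empty
#'   stream).
#' @export
monitor_stream <- function(ref, summaries, integration_hook = NULL) {
  if (nrow(summaries) == 0) {
    return(compute_error_signals(ref, NULL_summary())[0, ])
  }
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    row <- compute_error_signals(ref, summaries[i, ])
    if (!is.null(integration_hook)) integration_hook(row)
    row
  })
  dplyr::bind_rows(rows)
}

# a syntactically valid empty observation used to type the empty stream
NULL_summary <- function() {
  tibble::tibble(day = 1L, basal_mean = 1, event_se = 1)
}

#' Model-integration stub
#'
#' Placeholder for the downstream "model integration" stage that would
#' combine error signals with other farm knowledge: it only logs the day
#' and its alarm state to `stderr`.
#'
#' @param row a one-row error-signal tibble.
#' @return `row`, invisibly.
#' @export
log_integration_stub <- function(row) {
  message(sprintf("[bws] day %s: any_alarm = %s",
                  format(row$day), format(row$any_alarm)))
  invisible(row)
}
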