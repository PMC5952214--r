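# Aggregation of per-clip SE values into daily summaries and
# coefficient-of-variation tables. Conventions: sample (n-1) standard
# deviation everywhere; basal and event states are never merged.

#' Assemble clip records
#'
#' One row per analysis clip: the observation unit behind the daily SE
#' tables. A complete tank-day holds exactly three basal clips and one event
#' clip.
#'
#' @param experiment experiment label (e.g. `"A"`, `"B"`).
#' @param tank tank identifier.
#' @param day day number.
#' @param n_fish fish count in the tank.
#' @param clip_type `"basal1"`, `"basal2"`, `"basal3"` or `"event"`.
#' @param se the clip's combined Shannon entropy.
#' @return A tibble of class `clip_records`.
#' @export
clip_records <- function(experiment, tank, day, n_fish, clip_type, se) {
  out <- tibble::tibble(
    experiment = as.character(experiment), tank = as.character(tank),
    day = as.integer(day), n_fish = as.integer(n_fish),
    clip_type = as.character(clip_type), se = as.numeric(se)
  )
  if (any(out$se < 0, na.rm = TRUE)) stop("`se` must be >= 0", call. = FALSE)
  bad <- !grepl("^(basal[0-9]+|event)$", out$clip_type)
  if (any(bad)) {
    stop("invalid clip_type: ", paste(unique(out$clip_type[bad]),
                                      collapse = ", "), call. = FALSE)
  }
  class(out) <- c("clip_records", class(out))
  out
}

is_basal <- function(clip_type) grepl("^basal", clip_type)

#' Daily summary of one tank-day
#'
#' Reduces the clips of a single tank-day to `basal_mean` +/- `basal_sd`
#' (sample sd over the `n_basal` basal clips) and the event SE — one row of
#' the daily-evolution table.
#'
#' @param records clip records for exactly one tank-day.
#' @param n_basal expected number of basal clips (default 3).
#' @return A one-row tibble: `experiment`, `tank`, `day`, `n_fish`,
#'   `basal_mean`, `basal_sd`, `event_se`.
#' @export
daily_summary <- function(records, n_basal = 3) {
  key <- unique(records[, c("experiment", "tank", "day", "n_fish")])
  if (nrow(key) != 1) {
    stop("`records` must cover exactly one tank-day", call. = FALSE)
  }
  basal <- records$se[is_basal(records$clip_type)]
  event <- records$se[records$clip_type == "event"]
  missing <- c(
    if (length(basal) != n_basal) {
      sprintf("%d basal clip(s) (expected %d)", length(basal), n_basal)
    },
    if (length(event) != 1) sprintf("%d event clip(s) (expected 1)",
                                    length(event))
  )
  if (length(missing)) {
    stop(sprintf("incomplete tank-day (tank %s, day %d): %s",
                 key$tank, key$day, paste(missing, collapse = "; ")),
         call. = FALSE)
  }
  tibble::tibble(
    experiment = key$experiment, tank = key$tank, day = key$day,
    n_fish = key$n_fish,
    basal_mean = mean(basal), basal_sd = stats::sd(basal),
    event_se = event
  )
}

#' Daily summaries for a whole record set
#'
#' Applies [daily_summary()] to every (experiment, tank, day) group.
#'
#' @inheritParams daily_summary
#' @return A tibble with one row per tank-day.
#' @export
summarise_daily <- function(records, n_basal = 3) {
  dplyr::bind_rows(lapply(
    split(records,
          interaction(records$experiment, records$tank, records$day,
                      records$n_fish, drop = TRUE)),
    daily_summary, n_basal = n_basal
  ))
}

#' Coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation: the
#' dispersion measure used to compare replicate SE values across group
#' sizes.
#'
#' @param values at least two numbers with non-zero mean.
#' @return CV in percent.
#' @examples
#' cv(c(4, 6))  # 28.28
#' @export
cv <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  if (abs(m) < 1e-12) stop("zero mean: CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Pooled coefficient of variation from per-group mean and sd
#'
#' Reconstructs the CV over all individual measurements when only each
#' group's mean, sample sd and size are available (e.g. daily mean +/- sd of
#' 3 replicate clips): the pooled sum of squares is
#' `sum((k-1) sd^2 + k (mean - grand)^2)`.
#'
#' @param means,sds per-group means and sample sds.
#' @param k measurements per group (default 3 replicate clips).
#' @return CV in percent over the `k * length(means)` underlying values.
#' @export
pooled_cv <- function(means, sds, k = 3) {
  stopifnot(length(means) == length(sds), length(means) >= 1, k >= 2)
  total <- k * length(means)
  grand <- mean(means)
  if (abs(grand) < 1e-12) stop("zero mean: CV undefined", call. = FALSE)
  ss <- sum((k - 1) * sds^2 + k * (means - grand)^2)
  100 * sqrt(ss / (total - 1)) / grand
}

#' CV-by-fish-number table
#'
#' The replicate-dispersion table: for each fish count, the CV of SE values
#' under one of two bases — `"all_measurements"` pools every individual clip
#' SE of the requested state across tanks, days and experiments;
#' `"daily_averages"` pools the per-tank-day basal means (or, for the
#' response state, the single daily event values).
#'
#' @param records a [clip_records()] tibble.
#' @param basis `"all_measurements"` or `"daily_averages"`.
#' @param state `"basal"` or `"response"`.
#' @param n_basal basal clips per day (for the daily-averages basis).
#' @return A tibble with columns `n_fish`, `basis`, `state`, `cv_percent`,
#'   `n_values`, `flagged` (`TRUE` when a group had < 2 values; its CV is
#'   `NA`, never silently dropped).
#' @export
cv_table <- function(records, basis = c("all_measurements", "daily_averages"),
                     state = c("basal", "response"), n_basal = 3) {
  basis <- match.arg(basis)
  state <- match.arg(state)
  if (nrow(records) == 0) stop("no records", call. = FALSE)

  values_by_n <- if (basis == "all_measurements") {
    keep <- if (state == "basal") is_basal(records$clip_type) else
      records$clip_type == "event"
    split(records$se[keep], records$n_fish[keep])
  } else {
    daily <- summarise_daily(records, n_basal = n_basal)
    v <- if (state == "basal") daily$basal_mean else daily$event_se
    split(v, daily$n_fish)
  }

  rows <- lapply(names(values_by_n), function(nm) {
    v <- values_by_n[[nm]]
    ok <- length(v) >= 2
    tibble::tibble(
      n_fish = as.integer(nm), basis = basis, state = state,
      cv_percent = if (ok) cv(v) else NA_real_,
      n_values = length(v), flagged = !ok
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$n_fish), ]
}
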