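# End-to-end pipeline over a simulated multi-tank study, plus loaders for
# external data sheets and the published daily-SE reference table.

#' Deterministic per-recording seed
#'
#' Derives a distinct, reproducible sub-seed for each (experiment, tank,
#' day, fish count) recording from one master seed, kept within 32-bit
#' integer range.
#'
#' @param seed master seed (small integer).
#' @param experiment,tank,day,n_fish recording identifiers.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, experiment, tank, day, n_fish) {
  exp_i <- sum(utf8ToInt(as.character(experiment)))
  x <- (as.numeric(seed) * 1000003 + exp_i * 10007 +
          as.numeric(tank) * 101 + as.numeric(day) * 131 +
          as.numeric(n_fish) * 17) %% 2147483647
  as.integer(x)
}

#' Study designs of the two reference experiments
#'
#' `experiment_design_A()`: two tanks recorded for 5 days at each of 50, 25,
#' 13 and 1 fish (the decreasing-numbers experiment).
#' `experiment_design_B()`: tank 1 holds a single (different) fish each of
#' 5 days while tank 2 grows from 1 to 5 fish (the increasing-numbers
#' experiment).
#'
#' @param days recording days per fish count (A) / total days (B).
#' @return A design tibble: `experiment`, `tank`, `day`, `n_fish`.
#' @export
experiment_design_A <- function(days = 5) {
  expand_design("A", tanks = 1:2, days = days, n_fish = c(50, 25, 13, 1))
}

#' @rdname experiment_design_A
#' @export
experiment_design_B <- function(days = 5) {
  d1 <- tibble::tibble(experiment = "B", tank = "1", day = seq_len(days),
                       n_fish = 1L)
  d2 <- tibble::tibble(experiment = "B", tank = "2", day = seq_len(days),
                       n_fish = seq_len(days))
  dplyr::bind_rows(d1, d2)
}

#' @rdname experiment_design_A
#' @param experiment experiment label.
#' @param tanks tank identifiers.
#' @param n_fish fish counts, one 5-day block each.
#' @export
expand_design <- function(experiment, tanks, days, n_fish) {
  g <- expand.grid(tank = tanks, day = seq_len(days), n_fish = n_fish,
                   stringsAsFactors = FALSE)
  tibble::tibble(experiment = experiment, tank = as.character(g$tank),
                 day = as.integer(g$day), n_fish = as.integer(g$n_fish))
}

#' Run the full analysis pipeline on a simulated study
#'
#' For every row of `design`, simulates one recording (shoal + disturbance),
#' cuts it into three basal clips and one event clip, computes each clip's
#' Shannon entropy, and then aggregates: daily summaries (daily-evolution
#' table shape), CV-by-fish-number tables under both bases, and power-law
#' fits of SE versus fish number for the basal and response states.
#'
#' Every recording gets its own seed via [derive_seed()], so the whole
#' bundle is a pure function of (design, settings, seed). When `out_dir` is
#' given, all tables are written as dot-decimal CSV together with a JSON
#' file of the resolved configuration and seed.
#'
#' @param design a design tibble (see [experiment_design_A()]).
#' @param seed master seed.
#' @param sim_args named list of [sim_config()] overrides applied to every
#'   recording (e.g. shorter `recording_duration` for quick runs).
#' @param n_basal basal clips per recording.
#' @param entropy_args named list passed to [clip_entropy()].
#' @param fit_mode observation unit for the fits: `"clips"` (every clip SE
#'   is a point) or `"daily_means"` (basal daily means / daily event
#'   values).
#' @param out_dir optional output directory.
#' @return A list: `records`, `summaries`, `cv_all_basal`,
#'   `cv_daily_basal`, `cv_all_response`, `fit_basal`, `fit_response`,
#'   `config`.
#' @export
run_pipeline <- function(design, seed = 1,
                         sim_args = list(),
                         n_basal = 3,
                         entropy_args = list(),
                         fit_mode = c("clips", "daily_means"),
                         out_dir = NULL) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(all(c("experiment", "tank", "day", "n_fish") %in% names(design)))

  rec_list <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    cfg <- do.call(sim_config, c(
      list(n_fish = row$n_fish,
           seed = derive_seed(seed, row$experiment, row$tank, row$day,
                              row$n_fish)),
      sim_args
    ))
    cfg_event <- cfg
    if (is.na(cfg_event$event_time)) {
      # default protocol: event after the basal window block
      cfg_event$event_time <- n_basal * cfg$clip_duration
      validate_sim_config(cfg_event)
    }
    clips <- tryCatch(
      make_clipset(cfg_event, n_basal = n_basal),
      error = function(e) {
        stop(sprintf("stage simulate (experiment %s, tank %s, day %d): %s",
                     row$experiment, row$tank, row$day,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    se <- vapply(clips, function(cl) {
      do.call(clip_entropy, c(list(cl$trajectory), entropy_args))$H_combined
    }, 0)
    clip_records(row$experiment, row$tank, row$day, row$n_fish,
                 vapply(clips, `[[`, "", "clip_type"), se)
  })
  records <- dplyr::bind_rows(rec_list)

  summaries <- summarise_daily(records, n_basal = n_basal)
  cv_all_basal <- cv_table(records, "all_measurements", "basal", n_basal)
  cv_daily_basal <- cv_table(records, "daily_averages", "basal", n_basal)
  cv_all_response <- cv_table(records, "all_measurements", "response",
                              n_basal)

  fit_for <- function(state) {
    if (fit_mode == "clips") {
      keep <- if (state == "basal") is_basal(records$clip_type) else
        records$clip_type == "event"
      fit_power(records$n_fish[keep], records$se[keep], seed = seed,
                mode = "clips")
    } else {
      v <- if (state == "basal") summaries$basal_mean else summaries$event_se
      fit_power(summaries$n_fish, v, seed = seed, mode = "daily_means")
    }
  }
  if (length(unique(records$n_fish)) >= 3) {
    fit_basal <- fit_for("basal")
    fit_response <- fit_for("response")
  } else {
    message("fewer than 3 distinct fish counts: skipping the power fits")
    fit_basal <- NULL
    fit_response <- NULL
  }

  bundle <- list(
    records = records, summaries = summaries,
    cv_all_basal = cv_all_basal, cv_daily_basal = cv_daily_basal,
    cv_all_response = cv_all_response,
    fit_basal = fit_basal, fit_response = fit_response,
    config = list(seed = seed, sim_args = sim_args, n_basal = n_basal,
                  entropy_args = entropy_args, fit_mode = fit_mode)
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "clip_records.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "daily_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(dplyr::bind_rows(cv_all_basal, cv_daily_basal,
                                      cv_all_response),
                     file.path(out_dir, "cv_tables.csv"), row.names = FALSE)
    fit_row <- function(f, state) {
      if (is.null(f)) return(NULL)
      tibble::tibble(state = state, a = f$coefficients["a"],
                     b = f$coefficients["b"], c = f$coefficients["c"],
                     sse = f$sse, r2 = f$r2, adj_r2 = f$adj_r2,
                     rmse = f$rmse, n_points = f$n_points, mode = f$mode)
    }
    fits <- dplyr::bind_rows(fit_row(fit_basal, "basal"),
                             fit_row(fit_response, "response"))
    if (nrow(fits)) {
      utils::write.csv(fits, file.path(out_dir, "power_fits.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(bundle$config,
                         file.path(out_dir, "pipeline_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

# decimal-comma tolerant numeric parsing; errors name the first bad row
parse_decimal <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(gsub(",", ".", trimws(as.character(x)))))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad)) {
    stop(sprintf("%s: column '%s', row %d: cannot parse '%s' as a number",
                 path, col, bad[1], x[bad[1]]), call. = FALSE)
  }
  v
}

#' Load external data sheets
#'
#' Reads trajectory sheets (columns `frame`, `x`, `y`, optional `clip`
#' grouping) or per-clip SE sheets (tank/day/fish-count/clip-type/SE) in a
#' layout described by a column mapping, so adapting to a differently-named
#' sheet is a configuration change. Decimal commas are tolerated.
#'
#' @param path CSV file.
#' @param sheet_kind `"trajectories"`, `"se_values_A"` or `"se_values_B"`.
#' @param mapping named list giving the file's column names for the
#'   canonical fields (`tank`, `day`, `n_fish`, `clip_type`, `se`, and for
#'   trajectories `frame`, `x`, `y`, optional `clip`).
#' @return For trajectories, a list of [trajectory_series()]; for SE sheets,
#'   a [clip_records()] tibble with the experiment label set.
#' @export
load_supplementary <- function(path,
                               sheet_kind = c("trajectories", "se_values_A",
                                              "se_values_B"),
                               mapping = NULL) {
  sheet_kind <- match.arg(sheet_kind)
  d <- utils::read.csv(path, colClasses = "character")
  if (nrow(d) == 0) stop(path, ": empty file", call. = FALSE)

  if (sheet_kind == "trajectories") {
    map <- utils::modifyList(list(frame = "frame", x = "x", y = "y",
                                  clip = "clip"), mapping %||% list())
    need <- unlist(map[c("frame", "x", "y")])
    if (!all(need %in% names(d))) {
      stop(path, ": layout mismatch, missing column(s) ",
           paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
    }
    grp <- if (map$clip %in% names(d)) d[[map$clip]] else "1"
    lapply(split(d, grp), function(g) {
      trajectory_series(parse_decimal(g[[map$frame]], map$frame, path),
                        parse_decimal(g[[map$x]], map$x, path),
                        parse_decimal(g[[map$y]], map$y, path),
                        source = "file")
    })
  } else {
    map <- utils::modifyList(list(tank = "tank", day = "day",
                                  n_fish = "n_fish", clip_type = "clip_type",
                                  se = "se"), mapping %||% list())
    need <- unlist(map)
    if (!all(need %in% names(d))) {
      stop(path, ": layout mismatch, missing column(s) ",
           paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
    }
    clip_records(
      experiment = if (sheet_kind == "se_values_A") "A" else "B",
      tank = d[[map$tank]],
      day = parse_decimal(d[[map$day]], map$day, path),
      n_fish = parse_decimal(d[[map$n_fish]], map$n_fish, path),
      clip_type = d[[map$clip_type]],
      se = parse_decimal(d[[map$se]], map$se, path)
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published daily Shannon-entropy table (decreasing-numbers experiment)
#'
#' The daily SE summaries of the published two-tank seabass study this
#' package's methods reproduce: for each of 50, 25, 13 and 1 fish, five days
#' per tank of basal mean +/- sd (over 3 clips) and the event-response SE.
#' Ships as plain CSV under `inst/extdata`.
#'
#' @return A tibble: `n_fish`, `tank`, `day`, `basal_mean`, `basal_sd`,
#'   `event_se`.
#' @export
published_daily_se <- function() {
  path <- system.file("extdata", "experimentA_daily_se.csv",
                      package = "shoalSE", mustWork = TRUE)
  d <- utils::read.csv(path)
  tibble::tibble(
    experiment = "A", n_fish = as.integer(d$n_fish),
    tank = as.character(d$tank), day = as.integer(d$day),
    basal_mean = d$basal_mean, basal_sd = d$basal_sd, event_se = d$event_se
  )
}
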