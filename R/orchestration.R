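#' Load a run configuration
#'
#' Configurations are plain nested key-value structures: an R list, or a
#' path to a YAML file with the same shape. Missing fields fall back to
#' defaults; `threshold` must be >= 1 and `age_cap` in \[1, 100\].
#'
#' @param config A list or a path to a YAML file.
#' @return A named list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(threshold = 1000L, age_cap = 100L, seed = 1L,
                   by_sex = FALSE, allow_remission_pairs = FALSE,
                   out_dir = "results")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (config$threshold < 1) stop("threshold must be >= 1", call. = FALSE)
  if (config$age_cap < 1 || config$age_cap > 100) {
    stop("age_cap must lie in [1, 100]", call. = FALSE)
  }
  config
}

hazard_from_config <- function(cfg) {
  build <- function(x) {
    if (!is.null(x$type) && x$type == "gompertz") {
      hazard_gompertz(x$b, x$theta)
    } else if (!is.null(x$type) && x$type == "constant") {
      hazard_constant(x$p)
    } else stop("hazard type must be 'constant' or 'gompertz'",
                call. = FALSE)
  }
  mh <- build(cfg$mortality_healthy)
  mi <- if (!is.null(cfg$ill_multiplier)) {
    hazard_scaled(mh, cfg$ill_multiplier)
  } else build(cfg$mortality_ill)
  hazard_spec(illness = build(cfg$illness), mortality_healthy = mh,
              mortality_ill = mi)
}

ensure_out_dir <- function(path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) {
      stop("cannot create output directory: ", path, call. = FALSE)
    }
  }
  probe <- file.path(path, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", path,
                        call. = FALSE)
  unlink(probe)
  invisible(path)
}

write_manifest <- function(out_dir, kind, config, outputs) {
  manifest <- list(
    kind = kind,
    package = "mltcburden",
    version = as.character(utils::packageVersion("mltcburden")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config[setdiff(names(config), "out_dir")],
    outputs = outputs
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(kind, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a synthetic study: panel, snapshot and ground truth
#'
#' Generates a person-month panel and a cross-sectional prevalence
#' snapshot under the configured hazards, writes both as CSV together
#' with the analytic ground-truth burden metrics and a machine-readable
#' run manifest (inputs, seed, versions). Identical configuration yields
#' byte-identical outputs.
#'
#' @param config List or YAML path; recognized fields: `n_persons`,
#'   `observation_months`, `seed`, `start_age = list(from, to)`,
#'   `hazards` (see Details), `initial_illness` (`"model"` to seed
#'   prevalent cases at the model-implied prevalence, `"none"`),
#'   `include_sex`, `snapshot = list(n_persons, marginals, excess)`,
#'   `out_dir`.
#' @details The `hazards` block has sub-blocks `illness`,
#'   `mortality_healthy` (each `type: constant, p:` or `type: gompertz,
#'   b:, theta:`) and either `mortality_ill` or `ill_multiplier`. When
#'   `hazards` is absent, [default_study_hazards()] is used.
#' @return Invisibly, a list of written file paths.
#' @export
run_simulate <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$n_persons)) config$n_persons <- 100000L
  if (is.null(config$observation_months)) config$observation_months <- 12L
  if (is.null(config$start_age)) config$start_age <- list(from = 0L, to = 99L)
  if (is.null(config$initial_illness)) config$initial_illness <- "model"
  ensure_out_dir(config$out_dir)

  hazards <- if (is.null(config$hazards)) default_study_hazards()
             else hazard_from_config(config$hazards)
  init_ill <- if (identical(config$initial_illness, "model")) {
    model_illness_prevalence(hazards)
  } else NULL
  cc <- cohort_config(
    n_persons = config$n_persons,
    start_age_distribution = uniform_ages(config$start_age$from,
                                          config$start_age$to),
    observation_months = config$observation_months,
    random_seed = config$seed,
    initial_illness_prob = init_ill,
    include_sex = isTRUE(config$include_sex)
  )
  panel <- generate_panel(cc, hazards)
  truth <- analytic_metrics(hazards)

  paths <- list(panel = file.path(config$out_dir, "panel.csv"),
                ground_truth = file.path(config$out_dir, "ground_truth.csv"))
  write_panel(panel, paths$panel)
  utils::write.csv(as.data.frame(truth), paths$ground_truth,
                   row.names = FALSE)

  if (!is.null(config$snapshot)) {
    sc <- config$snapshot
    snap <- generate_prevalence_snapshot(
      n_persons = sc$n_persons,
      marginals = unlist(sc$marginals),
      excess = sc$excess,
      random_seed = config$seed + 1L
    )
    paths$snapshot <- file.path(config$out_dir, "snapshot.csv")
    write_snapshot(snap, paths$snapshot)
  }
  write_manifest(config$out_dir, "simulate", config, paths)
  message("simulate: wrote ", length(paths), " files to ", config$out_dir,
          " (seed ", config$seed, ")")
  invisible(paths)
}

burden_for_panel <- function(panel, label, stratum, threshold,
                             allow_remission) {
  counts <- tally_transitions(panel)
  remitted <- sum(counts$remission)
  if (remitted > 0 && !allow_remission) {
    return(list(metrics = NULL,
                status = data.frame(
                  combination_label = label, sex_stratum = stratum,
                  status = "remission_present",
                  detail = sprintf("%d ill->healthy moves excluded", remitted))))
  }
  elig <- check_eligibility(counts, threshold)
  if (!elig$eligible) {
    failing <- paste(elig$table$transition[!elig$table$pass], collapse = "; ")
    return(list(metrics = NULL,
                status = data.frame(
                  combination_label = label, sex_stratum = stratum,
                  status = "ineligible", detail = failing)))
  }
  matrices <- annualize(estimate_monthly_matrices(counts))
  bm <- compute_burden(matrices, counts, threshold = threshold)
  row <- cbind(data.frame(combination_label = label, sex_stratum = stratum),
               as.data.frame(bm))
  list(metrics = row,
       status = data.frame(combination_label = label, sex_stratum = stratum,
                           status = "ok", detail = ""))
}

#' Estimate burden metrics for every eligible condition pair
#'
#' Reads a person-month panel, applies the illness definition for each
#' requested condition pair (or uses the panel's own `state` column when
#' it has one), tallies transitions, applies the eligibility filter, and
#' writes one burden-metrics row per eligible pair (per sex stratum when
#' requested), plus an eligibility/exclusion log and a manifest. Pairs
#' with remission moves are skipped with a report unless
#' `allow_remission_pairs` is set.
#'
#' @param config List or YAML path; fields: `panel` (path), `pairs`
#'   (list of length-2 character vectors; optional for state panels),
#'   `threshold`, `age_cap` (panel rows above the cap are dropped),
#'   `by_sex`, `allow_remission_pairs`, `out_dir`.
#' @return Invisibly, a list with the metrics and status tables.
#' @export
run_burden <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$panel)) stop("config$panel (path) is required",
                                  call. = FALSE)
  ensure_out_dir(config$out_dir)
  panel <- read_panel(config$panel)
  if (config$age_cap < 100L) {
    panel <- panel[panel$age_years <= config$age_cap, ]
  }
  has_state <- "state" %in% names(panel)
  jobs <- if (!is.null(config$pairs)) {
    lapply(config$pairs, function(p) {
      list(label = paste(unlist(p), collapse = "+"), pair = unlist(p))
    })
  } else if (has_state) {
    list(list(label = "illness", pair = NULL))
  } else {
    stop("config$pairs is required for panels without a state column",
         call. = FALSE)
  }
  strata <- if (isTRUE(config$by_sex) && "sex" %in% names(panel)) {
    sort(unique(panel$sex))
  } else "all"

  metrics <- list(); status <- list()
  for (job in jobs) {
    jp <- if (is.null(job$pair)) panel
          else apply_illness_definition(panel, job$pair)
    for (sx in strata) {
      sp <- if (identical(sx, "all")) jp else jp[jp$sex == sx, ]
      res <- burden_for_panel(sp, job$label, sx, config$threshold,
                              isTRUE(config$allow_remission_pairs))
      if (!is.null(res$metrics)) metrics[[length(metrics) + 1L]] <- res$metrics
      status[[length(status) + 1L]] <- res$status
    }
  }
  metrics_tab <- if (length(metrics)) do.call(rbind, metrics) else
    data.frame(combination_label = character(), sex_stratum = character(),
               lifetime_risk = numeric(), median_onset_age = integer(),
               years_lived_with = numeric(), years_of_life_lost = numeric(),
               age_at_death = numeric(), community_years_lived = numeric(),
               community_years_lost = numeric())
  status_tab <- do.call(rbind, status)
  paths <- list(metrics = file.path(config$out_dir, "burden_metrics.csv"),
                status = file.path(config$out_dir, "burden_status.csv"))
  utils::write.csv(metrics_tab, paths$metrics, row.names = FALSE)
  utils::write.csv(status_tab, paths$status, row.names = FALSE)
  write_manifest(config$out_dir, "burden", config, paths)
  for (i in seq_len(nrow(status_tab))) {
    message(sprintf("burden [%s/%s]: %s %s",
                    status_tab$combination_label[i],
                    status_tab$sex_stratum[i], status_tab$status[i],
                    status_tab$detail[i]))
  }
  invisible(list(metrics = metrics_tab, status = status_tab, paths = paths))
}

#' Cross-sectional prevalence analytics over a snapshot
#'
#' Reads a prevalence snapshot and writes three tables: per-condition
#' point prevalence (overall and, when requested, by sex), the
#' observed-minus-expected excess for the configured condition pairs, and
#' the condition-count distribution by age band, sex and index-condition
#' status. Percentage columns are rounded to one decimal, half away from
#' zero.
#'
#' @param config List or YAML path; fields: `snapshot` (path), `pairs`,
#'   `index_condition` (default `"diabetes"`), `by_sex`, `out_dir`.
#' @return Invisibly, a list with the three tables.
#' @export
run_prevalence <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$snapshot)) stop("config$snapshot (path) is required",
                                     call. = FALSE)
  if (is.null(config$index_condition)) config$index_condition <- "diabetes"
  ensure_out_dir(config$out_dir)
  snap <- read_snapshot(config$snapshot)
  conds <- snapshot_conditions(snap)
  if (!is.null(config$pairs)) {
    unknown <- setdiff(unique(unlist(config$pairs)), conds)
    if (length(unknown)) {
      stop("unknown condition label(s) in pair list: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  strata <- if (isTRUE(config$by_sex)) c(NA, sort(unique(snap$sex))) else NA
  prev <- do.call(rbind, lapply(conds, function(cn) {
    do.call(rbind, lapply(strata, function(sx) {
      s <- if (is.na(sx)) NULL else sx
      p <- point_prevalence(snap, cn, sex = s)
      data.frame(condition = cn, sex_stratum = ifelse(is.na(sx), "all", sx),
                 prevalence = p,
                 prevalence_pct = round_half_away(100 * p))
    }))
  }))
  pairs <- if (!is.null(config$pairs)) {
    lapply(config$pairs, unlist)
  } else NULL
  excess <- excess_prevalence_table(snap, pairs,
                                    index_condition = config$index_condition)
  excess$observed_pct <- round_half_away(100 * excess$observed)
  excess$expected_pct <- round_half_away(100 * excess$expected)
  excess$excess_pct <- round_half_away(100 * excess$excess)
  counts <- mltc_count_distribution(snap,
                                    index_condition = config$index_condition)
  counts$proportion_pct <- round_half_away(100 * counts$proportion)
  paths <- list(prevalence = file.path(config$out_dir, "prevalence.csv"),
                excess = file.path(config$out_dir, "excess_prevalence.csv"),
                counts = file.path(config$out_dir, "mltc_counts.csv"))
  utils::write.csv(prev, paths$prevalence, row.names = FALSE)
  utils::write.csv(excess, paths$excess, row.names = FALSE)
  utils::write.csv(counts, paths$counts, row.names = FALSE)
  write_manifest(config$out_dir, "prevalence", config, paths)
  message("prevalence: wrote 3 tables to ", config$out_dir)
  invisible(list(prevalence = prev, excess = excess, counts = counts,
                 paths = paths))
}
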