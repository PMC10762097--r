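# Reading/writing trial tables as delimited text and the configurable
# pipeline runner tying the stages together.

CANONICAL_COLUMNS <- c("participant", "trial_id", "condition", "choice_type",
                       "d_a", "mu", "gamma_a", "gamma_b", "max_benefit",
                       "d_b", "accept")

#' Write trial tables to CSV
#'
#' @param trials Trial table (long format, canonical headers).
#' @param path Output file.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate trial tables
#'
#' Reads a delimited text file of per-trial behavioral data, optionally
#' renaming source headers to the canonical names and recoding condition
#' labels. Rows violating the range rules (cost in \[0, 20\], reciprocity
#' in \[0, 25\], 0-100 ratings in scale) are quarantined, not silently
#' kept; the ingestion report is attached as the `"report"` attribute.
#'
#' @param path CSV file.
#' @param column_map Named character vector mapping canonical names to
#'   source headers, e.g. `c(d_a = "cost", d_b = "repayment")`. `NULL`
#'   assumes canonical headers.
#' @param condition_recode Named character vector mapping source condition
#'   labels to `"repayment_impossible"` / `"repayment_possible"`.
#' @return Validated data frame; `attr(x, "report")` lists the columns
#'   found, rows read and rows quarantined; `attr(x, "quarantined")` holds
#'   the dropped rows.
#' @export
read_trials <- function(path, column_map = NULL, condition_recode = NULL) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop_input(sprintf("mapped column '%s' (-> %s) missing from %s",
                           src, canon, path))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  needed <- c("participant", "condition", "d_a")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop_input("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(condition_recode)) {
    hit <- raw$condition %in% names(condition_recode)
    raw$condition[hit] <- unname(condition_recode[raw$condition[hit]])
  }
  if (is.null(raw$gamma_a)) raw$gamma_a <- 20
  if (is.null(raw$gamma_b)) raw$gamma_b <- 25
  if (is.null(raw$mu)) raw$mu <- 1
  if (is.null(raw$max_benefit)) {
    raw$max_benefit <- min(max(raw$d_a * raw$mu), MAX_PAIN_REDUCTION)
  }

  bad <- !raw$condition %in% c("repayment_impossible", "repayment_possible") |
    !is.finite(raw$d_a) | raw$d_a < 0 | raw$d_a > 20
  if (!is.null(raw$d_b)) {
    bad <- bad | (!is.na(raw$d_b) & (raw$d_b < 0 | raw$d_b > raw$gamma_b))
  }
  for (rc in grep("^rating_", names(raw), value = TRUE)) {
    hi <- if (rc == "rating_belief") 25 else 100
    bad <- bad | (!is.na(raw[[rc]]) & (raw[[rc]] < 0 | raw[[rc]] > hi))
  }
  out <- raw[!bad, , drop = FALSE]
  attr(out, "quarantined") <- raw[bad, , drop = FALSE]
  attr(out, "report") <- list(path = path, rows_read = nrow(raw),
                              rows_kept = nrow(out),
                              rows_quarantined = sum(bad),
                              columns = names(raw))
  out
}

#' Run a configured multi-stage analysis
#'
#' Executes the requested stages in order -- `simulate`, `fit`, `compare`,
#' `recover`, `linkage`, `neural` -- writing CSV/JSON outputs and a
#' manifest (seed, config, package version) to `out_dir`. Stage
#' dependencies are checked before anything runs: `fit`, `compare` and
#' `linkage` need trial data from either the `simulate` stage or a
#' configured `data` file.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Recognized fields: `seed`, `out_dir`, `stages` (character
#'   vector), `simulate` (`n`, `study`), `data` (`path`, optional
#'   `column_map`, `condition_recode`), `fit` (`models`), `recover` (`n`,
#'   `model`), `neural` (`n`, `v`, `snr`).
#' @return The run directory, invisibly; outputs and `manifest.json` are
#'   inside.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop_input("config needs `out_dir`")
  stages <- config$stages %||% c("simulate", "fit")
  known <- c("simulate", "fit", "compare", "recover", "linkage", "neural")
  if (any(!stages %in% known)) {
    stop_input("unknown stage(s): ",
               paste(setdiff(stages, known), collapse = ", "))
  }
  needs_data <- intersect(stages, c("fit", "compare", "linkage"))
  if (length(needs_data) > 0 && !"simulate" %in% stages &&
      is.null(config$data$path)) {
    stop_input(sprintf("stage '%s' needs trial data: add the 'simulate' stage or config$data$path",
                       needs_data[1]))
  }
  if (!is.null(config$data$path) && !file.exists(config$data$path)) {
    stop_input(sprintf("configured data file not found: %s", config$data$path))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  trials <- NULL
  if ("simulate" %in% stages) {
    sim <- config$simulate %||% list()
    co <- simulate_cohort(sim$n %||% 20, study = sim$study %||% "2a",
                          seed = seed)
    trials <- co$trials
    write_trials(trials, file.path(out_dir, "trials.csv"))
  } else if (!is.null(config$data$path)) {
    trials <- read_trials(config$data$path,
                          column_map = unlist(config$data$column_map),
                          condition_recode = unlist(config$data$condition_recode))
  }

  fits_by_model <- NULL
  if ("fit" %in% stages) {
    models <- config$fit$models %||% "1.1"
    fits_by_model <- lapply(models, function(m) {
      fit_cohort(trials, build_model(m), seed = seed)
    })
    names(fits_by_model) <- models
    fit_rows <- do.call(rbind, lapply(names(fits_by_model), function(m) {
      do.call(rbind, lapply(fits_by_model[[m]], function(f) {
        cbind(data.frame(participant = f$participant, model = m,
                         objective = f$objective, aic = f$aic,
                         converged = f$converged),
              as.data.frame(as.list(f$par)))
      }))
    }))
    utils::write.csv(fit_rows, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
  }

  if ("compare" %in% stages) {
    if (is.null(fits_by_model) || length(fits_by_model) < 2) {
      stop_input("stage 'compare' needs stage 'fit' with at least 2 models")
    }
    utils::write.csv(compare_models(fits_by_model),
                     file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
  }

  if ("recover" %in% stages) {
    rc <- config$recover %||% list()
    model <- build_model(rc$model %||% "1.1")
    pop <- sample_population(rc$n %||% 20, seed = seed,
                             decision = model$decision)
    rep <- parameter_recovery(model, pop, make_design(rc$study %||% "2a",
                                                      seed = seed),
                              seed = seed)
    utils::write.csv(rep$per_parameter,
                     file.path(out_dir, "recovery.csv"), row.names = FALSE)
  }

  if ("linkage" %in% stages) {
    utils::write.csv(linkage_battery(trials),
                     file.path(out_dir, "linkage.csv"), row.names = FALSE)
  }

  if ("neural" %in% stages) {
    nc <- config$neural %||% list()
    res <- run_neural_cohort(nc$n %||% 20, v = nc$v %||% NEURAL_V_DEFAULT,
                             snr = nc$snr %||% NEURAL_SNR_DEFAULT,
                             seed = seed)
    utils::write.csv(res$participants,
                     file.path(out_dir, "neural.csv"), row.names = FALSE)
  }

  manifest <- list(
    seed = seed, stages = stages, config = config,
    package_version = as.character(utils::packageVersion("indebtr")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
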