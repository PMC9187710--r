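#' Write / read trial tables (JSON lines)
#'
#' One JSON record per trial with arrays for the click and state-change
#' times; times in seconds, 0 = stimulus onset.  Reading validates the
#' schema and reports the offending record on failure.
#'
#' @param trials a \code{dc_trials} list.
#' @param path output file.
#' @return \code{write_trials}: the path, invisibly.  \code{read_trials}:
#'   a \code{dc_trials} list.
#' @export
write_trials <- function(trials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in trials) {
    rec <- unclass(tr)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  req <- c("trial_id", "duration", "left_clicks", "right_clicks",
           "state_changes", "initial_state", "final_state")
  out <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
      stop("malformed trial record at line ", i, ": ",
           conditionMessage(e)))
    miss <- setdiff(req, names(rec))
    if (length(miss))
      stop("trial record at line ", i, " missing field(s): ",
           paste(miss, collapse = ", "))
    num_arr <- function(x) if (is.null(x)) numeric(0) else
      sort(as.numeric(x))
    for (f in c("left_clicks", "right_clicks", "state_changes"))
      rec[[f]] <- num_arr(rec[[f]])
    if (any(rec$left_clicks < 0 | rec$left_clicks > rec$duration) ||
        any(rec$right_clicks < 0 | rec$right_clicks > rec$duration))
      stop("trial record at line ", i,
           ": click times outside [0, duration]")
    rec$choice <- if (is.null(rec$choice)) NA_integer_ else
      as.integer(rec$choice)
    rec$hit <- if (is.null(rec$hit)) NA else as.logical(rec$hit)
    if (is.null(rec$movement)) rec$movement <- rec$duration + 0.3
    structure(rec[c(req, "movement", "choice", "hit")],
              class = "dc_trial")
  })
  structure(out, class = "dc_trials")
}

#' Write / read spike tables (long CSV)
#'
#' Columns \code{unit_id}, \code{trial_id}, \code{spike_time} (seconds,
#' stimulus-aligned); rows are sorted on read.
#'
#' @param spikes long-format spike data.frame.
#' @param path file path.
#' @return \code{write_spikes}: the path, invisibly;
#'   \code{read_spikes}: the sorted data.frame.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.csv(spikes[, c("unit_id", "trial_id", "spike_time")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path)
  need <- c("unit_id", "trial_id", "spike_time")
  if (!all(need %in% names(df)))
    stop("spike table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) && any(df$trial_id < 0))
    stop("negative trial reference in spike table")
  df[order(df$unit_id, df$trial_id, df$spike_time), need,
     drop = FALSE]
}

#' Read a pipeline configuration (YAML)
#'
#' Blocks \code{task:}, \code{agent:}, \code{neurons:}, \code{seed:};
#' missing entries fall back to package defaults.
#'
#' @param path YAML file.
#' @return A list with \code{task} (\code{dc_task}), \code{theta}
#'   (\code{dc_params}), \code{n_trials}, \code{n_units}, \code{seed}.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  task <- do.call(task_params, as.list(cfg$task))
  theta <- do.call(model_params, as.list(cfg$agent))
  list(task = task, theta = theta,
       n_trials = cfg$neurons$n_trials %||% 1000,
       n_units = cfg$neurons$n_units %||% 10,
       seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on synthetic data
#'
#' Chains the stages end to end: simulate a dataset, fit the
#' accumulation model to the agent's choices, compute behavioral curves,
#' classify units and compute choice-AUC timecourses, build evidence
#' tuning maps with their rank-1 decompositions (per unit and
#' population), detect model-predicted and generative state changes, and
#' compute state-change triggered responses.  Writes trial/spike tables,
#' per-curve CSVs, and a JSON manifest with the seed and per-file
#' checksums into \code{outdir}.
#'
#' @param n_trials,n_units dataset size.
#' @param task,theta generative settings.
#' @param seed master seed (all stage streams derive from it).
#' @param outdir output directory (created); NULL skips writing.
#' @param fit_model refit the accumulation model (TRUE) or reuse the
#'   generative parameters (FALSE, faster).
#' @return A list with the dataset, fitted parameters, behavioral
#'   curves, classification, tuning results, events and STR results.
#' @export
run_pipeline <- function(n_trials = 1000, n_units = 10,
                         task = task_params(), theta = model_params(),
                         seed = 1, outdir = NULL, fit_model = FALSE) {
  ds <- generate_dataset(n_trials, n_units, task, theta, seed = seed)
  theta_hat <- if (fit_model) {
    fit_parameters(ds$trials, seed = derive_seed(seed, "fit"))$theta_hat
  } else theta
  psy <- psychometric(ds$trials, theta_hat, task = task)
  chron <- chronometric(ds$trials)
  rc <- reverse_correlation(ds$trials, task)
  cls <- classify_cells(ds$spikes, ds$trials)
  rates <- compute_rates(ds$spikes, ds$trials)
  t_edges <- seq(0, 2, by = 0.025)
  pcm <- posterior_coarse_mass(ds$trials, theta_hat, t_edges)
  tcol <- which(rates$centers > t_edges[1] &
                  rates$centers < t_edges[length(t_edges)])
  sel <- cls$unit_id[cls$selective]
  maps <- list(); r1 <- list()
  for (u in sel) {
    ui <- match(u, rates$units)
    z <- zscore_rates(rates$rate[, , ui], rates$mask)
    jt <- build_joint(z[, tcol], rates$mask[, tcol], pcm)
    maps[[as.character(u)]] <- tuning_map(jt)
    pref <- cls$preferred[cls$unit_id == u]
    r1[[as.character(u)]] <- rank1(maps[[as.character(u)]],
                                   preferred = pref)
  }
  pop <- if (length(maps) > 0)
    population_map(maps, cls$preferred[match(as.integer(names(maps)),
                                             cls$unit_id)]) else NULL
  events <- detect_changes(ds$trials, theta_hat)
  str_model <- tryCatch(
    compute_str(rates, ds$trials,
                events[events$source == "model", ], cls,
                seed = derive_seed(seed, "str")),
    error = function(e) NULL)
  out <- list(dataset = ds, theta_hat = theta_hat, psychometric = psy,
              chronometric = chron, reverse_correlation = rc,
              classification = cls, rates = rates, maps = maps,
              rank1 = r1, population = pop, events = events,
              str = str_model, seed = seed)
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

write_pipeline <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  w <- function(obj, name, writer) {
    p <- file.path(outdir, name)
    writer(obj, p)
    files[[name]] <<- unname(tools::md5sum(p))
    p
  }
  w(out$dataset$trials, "trials.jsonl", write_trials)
  w(out$dataset$spikes, "spikes.csv", write_spikes)
  wcsv <- function(obj, p) utils::write.csv(obj, p, row.names = FALSE)
  w(out$psychometric, "psychometric.csv", wcsv)
  w(out$chronometric, "chronometric.csv", wcsv)
  w(out$reverse_correlation, "reverse_correlation.csv", wcsv)
  w(out$classification, "classification.csv", wcsv)
  w(out$events, "events.csv", wcsv)
  theta_file <- file.path(outdir, "theta.json")
  jsonlite::write_json(unclass(out$theta_hat), theta_file,
                       auto_unbox = TRUE, digits = NA)
  files[["theta.json"]] <- unname(tools::md5sum(theta_file))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("dynclicks")),
                   seed = out$seed, files = as.list(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
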