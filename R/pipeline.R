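#' Write a session bundle as delimited text tables
#'
#' Serializes a session as `trials.tsv`, `spikes.tsv`, `neurons.tsv` (and
#' `latents.tsv` when simulated ground truth is present), plus the generating
#' configuration as parseable text (`config.txt`, via [dput()]). All times
#' are milliseconds with stimulus onset at 0.
#'
#' @param session A `"bl_session"`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(session$trials, "trials.tsv")
  wt(session$spikes, "spikes.tsv")
  wt(session$neurons, "neurons.tsv")
  if (!is.null(session$latents)) wt(session$latents, "latents.tsv")
  dput(list(window = session$window, config = unclass(session$config)),
       file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#'
#' @param dir Directory containing the tables.
#' @return A `"bl_session"`.
#' @export
read_session <- function(dir) {
  rt <- function(name) {
    utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  meta <- dget(file.path(dir, "config.txt"))
  cfg <- meta$config
  if (!is.null(cfg)) class(cfg) <- "bl_sim_config"
  lat_path <- file.path(dir, "latents.tsv")
  structure(
    list(
      trials = rt("trials.tsv"),
      spikes = rt("spikes.tsv"),
      neurons = rt("neurons.tsv"),
      latents = if (file.exists(lat_path)) rt("latents.tsv") else NULL,
      window = meta$window,
      config = cfg
    ),
    class = "bl_session"
  )
}

#' Validate the tables of a written session directory
#'
#' Schema and invariant checks: files present and readable, spike foreign
#' keys (`trial_id`, `neuron_id`) resolve, spike times lie within the
#' recording window, and reaction times are strictly positive. Failures are
#' reported, not thrown.
#'
#' @param dir Session directory.
#' @return Data frame with `check`, `pass`, `detail` (row numbers or counts
#'   for failures).
#' @export
validate_tables <- function(dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail
    )
  }
  read_ok <- function(name) {
    tryCatch(
      utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE),
      error = function(e) NULL
    )
  }
  trials <- read_ok("trials.tsv")
  spikes <- read_ok("spikes.tsv")
  neurons <- read_ok("neurons.tsv")
  add("trials.tsv readable", !is.null(trials))
  add("spikes.tsv readable", !is.null(spikes))
  add("neurons.tsv readable", !is.null(neurons))
  if (is.null(trials) || is.null(spikes) || is.null(neurons)) {
    return(do.call(rbind, checks))
  }
  orphan_t <- which(!spikes$trial_id %in% trials$trial_id)
  add("spike trial_id resolves", length(orphan_t) == 0,
      paste(utils::head(orphan_t, 10), collapse = ","))
  orphan_n <- which(!spikes$neuron_id %in% neurons$neuron_id)
  add("spike neuron_id resolves", length(orphan_n) == 0,
      paste(utils::head(orphan_n, 10), collapse = ","))
  meta_path <- file.path(dir, "config.txt")
  if (file.exists(meta_path)) {
    win <- dget(meta_path)$window
    upper <- max(win[2], trials$saccade_onset + 200, na.rm = TRUE)
    bad_t <- which(spikes$spike_time < win[1] | spikes$spike_time > upper)
    add("spike times within window", length(bad_t) == 0,
        paste(utils::head(bad_t, 10), collapse = ","))
  }
  bad_rt <- which(!(trials$reaction_time > 0))
  add("reaction times positive", length(bad_rt) == 0,
      paste(utils::head(bad_rt, 10), collapse = ","))
  do.call(rbind, checks)
}

#' Run the analysis pipeline on a simulated session
#'
#' Orchestrates simulate -> feature extraction -> correlation battery ->
#' mixed model into one reproducible, seeded run, writing every table under
#' `out_dir` along with a machine-readable report. Stage subsets are allowed
#' (later stages require the earlier ones in the same call or on disk).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param stages Character subset of
#'   `c("simulate", "features", "correlate", "glmm")`, in pipeline order.
#' @return The run report (list), invisibly: per-feature mean/median rho and
#'   population tests, GLMM coefficient table and AIC (when fitted), and
#'   stage provenance.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "features", "correlate",
                                    "glmm")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, area = config$area_profile,
                 stages = stages)
  session <- NULL
  features <- NULL
  if ("simulate" %in% stages) {
    session <- generate_session(config)
    write_session(session, out_dir)
  }
  if ("features" %in% stages) {
    if (is.null(session)) session <- read_session(out_dir)
    features <- session_features(session)
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("correlate" %in% stages) {
    if (is.null(features)) {
      features <- utils::read.table(file.path(out_dir, "features.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
    }
    recs <- do.call(rbind, lapply(c("latency", "strength", "prestim"),
                                  function(f) correlation_records(features, f)))
    utils::write.table(recs, file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$correlations <- lapply(split(recs, recs$feature), function(d) {
      pt <- population_tests(d)
      list(mean_rho = mean(d$rho, na.rm = TRUE),
           median_rho = stats::median(d$rho, na.rm = TRUE),
           n = sum(!is.na(d$rho)),
           signed_rank = pt$pooled)
    })
  }
  if ("glmm" %in% stages) {
    if (is.null(features)) {
      features <- utils::read.table(file.path(out_dir, "features.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
    }
    report$glmm <- list()
    for (pol in unique(features$polarity)) {
      d <- features[features$polarity == pol & features$detected &
                      features$latency_included, , drop = FALSE]
      md <- data.frame(rt = d$reaction_time, latency = d$latency,
                       strength = d$strength, contrast = d$contrast,
                       neuron = d$neuron_id)
      if (nrow(md) >= 10 && length(unique(md$neuron)) >= 2) {
        fit <- fit_gamma_glmm(md)
        utils::write.table(
          fit$coefficients,
          file.path(out_dir, paste0("glmm_fit_", pol, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
        report$glmm[[pol]] <- list(coefficients = fit$coefficients,
                                   AIC = fit$AIC, sigma_u = fit$sigma_u,
                                   shape = fit$shape)
      }
    }
  }
  dput(report, file.path(out_dir, "report.txt"))
  invisible(report)
}
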