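#' Run configuration
#'
#' Plain-JSON run description for the end-to-end pipelines. For the ephys
#' study the manifest pairs each animal's Phase I and Phase II sessions; for
#' the behavior study it points at a cohort table CSV.
#'
#' @param manifest data frame; for ephys: columns `animal_id`, `genotype`,
#'   `phase` (`"I"`/`"II"`), `session`, `file`; for behavior: unused.
#' @param cohort_file path to a cohort CSV (behavior study).
#' @param params named list of stage-parameter overrides (defaults come from
#'   the stage functions).
#' @param seed integer seed used for every stochastic stage.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(manifest = NULL, cohort_file = NULL, params = list(),
                       seed = 1L, out_dir = ".") {
  structure(list(manifest = manifest, cohort_file = cohort_file,
                 params = params, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for `write_run_config`).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(manifest = x$manifest, cohort_file = x$cohort_file,
             params = if (is.null(x$params)) list() else x$params,
             seed = if (is.null(x$seed)) 1L else x$seed,
             out_dir = if (is.null(x$out_dir)) "." else x$out_dir)
}

param_or <- function(params, name, default) {
  if (!is.null(params[[name]])) params[[name]] else default
}

provenance <- function(config, stage) {
  list(stage = stage, seed = config$seed, params = config$params,
       package = "epiphys",
       version = as.character(utils::packageVersion("epiphys")),
       r_version = R.version.string)
}

#' End-to-end electrophysiology study
#'
#' Reproduces the two-phase within-animal design: for every manifest entry
#' the recording is loaded, wake/sleep segmented from the EMG, interictal
#' spikes detected and artifact-screened, and per-state rates computed; then
#' across animals the report assembles (i) the mixed repeated-measures ANOVA
#' on wake spike rates (genotype x phase), (ii) the wake-vs-sleep paired t
#' test on Phase I rates in mutants, and (iii) the theta-band amplitude
#' change between phases with bootstrap CI and sign-flip permutation p.
#' Animals missing a phase are excluded with a warning. All outputs carry a
#' provenance block (parameters, seed, package version) and rerunning the
#' same config reproduces them exactly.
#'
#' @param config a [run_config()] with an ephys manifest.
#' @return the report list, invisibly written to
#'   `file.path(config$out_dir, "ephys_report.json")` plus per-animal rate
#'   CSVs.
#' @export
run_ephys_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  man <- config$manifest
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(provenance = provenance(config, "run_ephys_study"))
  if (is.null(man) || nrow(man) == 0) {
    report$error <- "empty manifest: nothing to analyze"
    jsonlite::write_json(report, file.path(config$out_dir, "ephys_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(report))
  }
  p <- config$params
  rates <- list(); spectra <- list()
  for (i in seq_len(nrow(man))) {
    rec <- read_recording(man$file[i])
    states <- segment_states(rec,
                             emg_window_s = param_or(p, "emg_window_s", 1),
                             quiet_ratio = param_or(p, "quiet_ratio", 0.5),
                             min_bout_s = param_or(p, "min_bout_s", 10))
    ev <- detect_spikes(rec,
                        threshold_mV = param_or(p, "threshold_mV", 1.0),
                        refractory_s = param_or(p, "refractory_s", 0.2))
    ev <- reject_artifacts(ev, rec,
                           sync_window_s = param_or(p, "sync_window_s", 0.01),
                           sync_min_channels = param_or(p, "sync_min_channels", 2),
                           amp_cap_mV = param_or(p, "amp_cap_mV", 10))
    rb <- spike_rate_by_state(ev, states)
    rates[[i]] <- data.frame(animal_id = man$animal_id[i],
                             genotype = man$genotype[i], phase = man$phase[i],
                             session = man$session[i],
                             wake_rate = rb$wake_rate, sleep_rate = rb$sleep_rate,
                             wake_time_s = rb$wake_time_s,
                             sleep_time_s = rb$sleep_time_s,
                             stringsAsFactors = FALSE)
    win <- analysis_window(rec, minutes = param_or(p, "window_minutes", 10))
    spec <- morlet_amplitude(win$channels$hlfp, win$fs,
                             freqs = log_freqs(param_or(p, "n_freqs", 50)),
                             n_cycles = param_or(p, "n_cycles", 6))
    key <- paste(man$animal_id[i], man$phase[i], sep = "|")
    spectra[[key]] <- c(spectra[[key]], list(spec))
  }
  rates <- do.call(rbind, rates)
  utils::write.csv(rates, file.path(config$out_dir, "spike_rates.csv"),
                   row.names = FALSE)

  # keep only animals with both phases
  ids <- unique(rates$animal_id)
  phases_of <- function(id) unique(rates$phase[rates$animal_id == id])
  paired <- ids[vapply(ids, function(id) all(c("I", "II") %in% phases_of(id)),
                       logical(1))]
  dropped <- setdiff(ids, paired)
  if (length(dropped))
    warning("excluding unpaired animal(s): ", paste(dropped, collapse = ", "))
  rates <- rates[rates$animal_id %in% paired, ]
  report$n_animals <- length(paired)

  # session-mean wake rate per animal x phase -> mixed RM ANOVA
  agg <- stats::aggregate(wake_rate ~ animal_id + genotype + phase, rates, mean)
  ct <- cohort_table(data.frame(animal_id = agg$animal_id,
                                genotype = agg$genotype, cre = "+", tmx = "-",
                                endpoint = "wake_rate", value = agg$wake_rate,
                                within = agg$phase, stringsAsFactors = FALSE))
  if (length(unique(agg$genotype)) >= 2 && length(paired) >= 4)
    report$mixed_rm_anova_wake <- mixed_rm_anova(ct, "wake_rate")

  # Phase I wake vs sleep paired t in mutants
  mut <- rates[rates$genotype != "+/+" & rates$phase == "I", ]
  if (nrow(mut)) {
    ws <- stats::aggregate(cbind(wake_rate, sleep_rate) ~ animal_id, mut, mean)
    ws <- ws[stats::complete.cases(ws), ]
    if (nrow(ws) >= 2)
      report$paired_t_wake_sleep_mutants <-
        group_compare(ws$wake_rate, ws$sleep_rate, "paired_t",
                      comparison = "wake vs sleep rate, mutants, Phase I")
  }

  # theta amplitude change across phases
  split_phase <- function(ph) {
    keys <- names(spectra)[endsWith(names(spectra), paste0("|", ph))]
    out <- spectra[keys]
    names(out) <- sub("\\|.*$", "", keys)
    out[names(out) %in% paired]
  }
  p1 <- split_phase("I"); p2 <- split_phase("II")
  if (length(intersect(names(p1), names(p2))) >= 2) {
    chg <- normalized_amplitude_change(p1, p2)
    chg <- bootstrap_ci(chg, n_boot = param_or(p, "n_boot", 2000),
                        seed = config$seed)
    perm <- band_permutation_test(chg, band = band_defs()$theta,
                                  n_shuffles = param_or(p, "n_shuffles", 5000),
                                  seed = config$seed)
    report$theta_change <- list(freqs_hz = chg$freqs_hz,
                                grand_mean = chg$grand_mean,
                                ci_low = chg$ci_low, ci_high = chg$ci_high,
                                permutation = perm)
    utils::write.csv(data.frame(freq_hz = chg$freqs_hz,
                                grand_mean = chg$grand_mean,
                                ci_low = chg$ci_low, ci_high = chg$ci_high),
                     file.path(config$out_dir, "theta_change.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(config$out_dir, "ephys_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}

#' End-to-end behavioral study
#'
#' Runs the per-endpoint statistical battery on a cohort table: type-III
#' two-factor ANOVA (Cre x genotype) with Bonferroni pairwise comparisons and
#' Cohen's d per Cre level, plus a MANOVA over the three seizure-stage
#' latencies when all are present. Degenerate single-genotype tables get a
#' main-effect-only report.
#'
#' @param config a [run_config()] with `cohort_file` set.
#' @return the report list, also written to
#'   `file.path(config$out_dir, "behavior_report.json")` and a flat CSV of
#'   statistics.
#' @export
run_behavior_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- read_cohort_table(config$cohort_file)
  report <- list(provenance = provenance(config, "run_behavior_study"))
  endpoints <- unique(ct$endpoint)
  all_stats <- list()
  for (ep in endpoints) {
    sub <- ct[ct$endpoint == ep, ]
    res <- NULL
    if (length(unique(sub$cre)) >= 2 && length(unique(sub$genotype)) >= 2) {
      res <- two_factor_anova(ct, ep)
      pw <- bonferroni_pairwise(ct, ep)
      all_stats[[paste0(ep, "_pairwise")]] <- pw
      for (cl in unique(sub$cre)) {
        gt <- setdiff(unique(sub$genotype), "+/+")
        for (g in gt) {
          a <- sub$value[sub$cre == cl & sub$genotype == "+/+"]
          b <- sub$value[sub$cre == cl & sub$genotype == g]
          if (length(a) >= 2 && length(b) >= 2)
            res <- rbind(res, stat_row("cohens_d",
                                       sprintf("cre %s: +/+ vs %s", cl, g),
                                       statistic = cohens_d(a, b)))
        }
      }
    } else if (length(unique(sub$genotype)) >= 2) {
      groups <- split(sub$value, sub$genotype)
      res <- group_compare(groups[[1]], groups[[2]], "unpaired_t",
                           comparison = paste(names(groups)[1:2], collapse = " vs "))
      res$note <- "single-factor degenerate design: unpaired t reported"
    } else {
      res <- stat_row("none", ep, NA,
                      note = "single group: no between-group test possible")
    }
    all_stats[[ep]] <- res
  }
  if (all(c("clonus", "tc", "the") %in% endpoints) &&
      length(unique(ct$cre)) >= 2 && length(unique(ct$genotype)) >= 2)
    all_stats$manova_seizure_stages <- manova_pillai(ct)
  report$stats <- all_stats
  flat <- do.call(rbind, lapply(names(all_stats), function(nm) {
    df <- all_stats[[nm]]
    if (!"p_adj" %in% names(df)) df$p_adj <- NA_real_
    cbind(analysis = nm, df[, c("test", "comparison", "statistic", "df1",
                                "df2", "p", "p_adj", "effect_size", "note")])
  }))
  utils::write.csv(flat, file.path(config$out_dir, "behavior_stats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "behavior_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    out[[key]] <- if (i + 1 <= length(args)) args[i + 1] else NA
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic recording), `segment`
#' (recording -> BED-like state intervals), `iis` (recording + states ->
#' event CSV and rates), `theta` (manifest -> grand-mean change, CI and
#' permutation p as JSON), `stats` (cohort CSV -> statistics), `run-ephys`
#' and `run-behavior` (config JSON -> full report). Invoke from a shell as
#' `Rscript -e 'epiphys::epiphys_cli()' <subcommand> --key value ...`.
#'
#' @param args character vector (default: command-line arguments).
#' @return invisibly, the subcommand's result.
#' @export
epiphys_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: epiphys <simulate|segment|iis|theta|stats|run-ephys|run-behavior> [--key value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- cli_args_to_list(args[-1])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  switch(cmd,
    simulate = {
      prm <- sim_recording_params(
        duration_s = num(opt$duration_s, 600), fs = num(opt$fs, 2000),
        spike_rate_wake = num(opt$spike_rate_wake, 0.5),
        spike_rate_sleep = num(opt$spike_rate_sleep, 9),
        sleep_fraction = num(opt$sleep_fraction, 0.3),
        seed = num(opt$seed, 1))
      sim <- simulate_recording(prm)
      write_recording(sim$recording, opt$out)
      write_state_intervals(sim$true_states, paste0(opt$out, ".states.bed"))
      message("wrote ", opt$out, " (+ sidecar, + true states)")
      invisible(sim)
    },
    segment = {
      rec <- read_recording(opt$`in`)
      st <- segment_states(rec, emg_window_s = num(opt$emg_window_s, 1),
                           quiet_ratio = num(opt$quiet_ratio, 0.5),
                           min_bout_s = num(opt$min_bout_s, 10))
      write_state_intervals(st, opt$out)
      invisible(st)
    },
    iis = {
      rec <- read_recording(opt$`in`)
      st <- read_state_intervals(opt$states)
      ev <- detect_spikes(rec, threshold_mV = num(opt$threshold_mV, 1),
                          refractory_s = num(opt$refractory_s, 0.2))
      ev <- reject_artifacts(ev, rec)
      write_spike_events(ev, opt$out, states = st)
      rb <- spike_rate_by_state(ev, st)
      cat(jsonlite::toJSON(unclass(rb), auto_unbox = TRUE, digits = NA), "\n")
      invisible(rb)
    },
    theta = {
      man <- utils::read.csv(opt$manifest, stringsAsFactors = FALSE)
      cfg <- run_config(manifest = man, seed = num(opt$seed, 1),
                        out_dir = if (is.null(opt$out_dir)) "." else opt$out_dir)
      invisible(run_ephys_study(cfg))
    },
    stats = {
      cfg <- run_config(cohort_file = opt$cohort, seed = num(opt$seed, 1),
                        out_dir = if (is.null(opt$out_dir)) "." else opt$out_dir)
      invisible(run_behavior_study(cfg))
    },
    `run-ephys` = invisible(run_ephys_study(read_run_config(opt$config))),
    `run-behavior` = invisible(run_behavior_study(read_run_config(opt$config))),
    stop("unknown subcommand: ", cmd)
  )
}
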