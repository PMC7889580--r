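# End-to-end pipeline: chains synth -> decode -> run -> metrics / maps /
# ephys / classify and writes a report directory (tidy CSVs, figures, and a
# machine-readable summary). All randomness flows from the named seeds in
# the configuration.

.pipeline_defaults <- function() {
  list(preset = "expert-session", seed = 1L, n_trials = 30L,
       baseline_s = 600, n_splits = 40L, n_repeats = 20L,
       figures = TRUE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stage chain and writes CSV outputs, figures and
#' a machine-readable `summary.json` to a report directory. Two presets are
#' provided: `"expert-session"` (agent session, trial engine, behavioral
#' and entropy metrics, maps, tuning, population classifier) and
#' `"chance-replay"` (spontaneous baseline through calibration and the
#' trial engine; the summary's `hits_per_min` is the chance-rate estimate).
#'
#' @param config a list or the path to a YAML file; recognized fields are
#'   `preset`, `seed`, `n_trials`, `baseline_s`, `n_splits`, `n_repeats`,
#'   `figures`.
#' @param out_dir report directory (created if needed).
#' @return The summary list, invisibly; files are written to `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("report_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  summary <- list(preset = cfg$preset, seed = seed)

  if (cfg$preset == "chance-replay") {
    pr <- .stage("synth", {
      generate_region_pair(gen_config(duration_s = cfg$baseline_s,
                                      seed = seed))
    })
    params <- .stage("decode", {
      calibrate(pr$r1, pr$r2, min_baseline_s = min(600, cfg$baseline_s))
    })
    rate <- .stage("run", estimate_chance_rate(pr$r1, pr$r2, params))
    ses <- attr(rate, "session")
    utils::write.csv(ses$trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    summary$hits_per_min <- as.numeric(rate)
    summary$n_trials <- nrow(ses$trials)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(summary))
  }

  # expert-session (default): full chain
  gen <- gen_config(duration_s = cfg$baseline_s, seed = seed)
  base <- .stage("synth", generate_region_pair(gen))
  agent <- agent_config(init = "expert", exploit_jitter_sd = 0.05)
  ag <- .stage("synth", {
    generate_agent_session(gen, agent, n_trials = cfg$n_trials, seed = seed)
  })
  params <- .stage("decode", {
    calibrate(base$r1, base$r2, min_baseline_s = min(600, cfg$baseline_s))
  })
  ses <- .stage("run", run_session(ag, params))
  utils::write.csv(ses$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)

  metrics <- .stage("metrics", {
    hr <- hit_rate_curve(ses$trials, window_min = 1,
                         session_frames = ses$n_frames,
                         frame_rate = ses$frame_rate)
    ent <- spectral_entropy(ag$r1)
    list(hit_rate = hr, entropy = ent,
         r1_r2_correlation = pairwise_correlation(ag$r1, ag$r2),
         hits_per_min = sum(ses$trials$outcome == "hit") /
           (ses$n_frames / ses$frame_rate / 60))
  })
  utils::write.csv(metrics$hit_rate, file.path(out_dir, "hit_rate.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(metrics$entropy),
                   file.path(out_dir, "entropy.csv"), row.names = FALSE)

  maps <- .stage("maps", {
    masks <- default_region_masks(gen$movie_shape)
    # task-locked component in the higher visual areas (strongest in AM)
    # and, more weakly, V1; driven by the agent's pattern emissions
    task_sig <- as.numeric(ag$mode != "background") * gen$amp_sd
    traces <- list(R1 = ag$r1$values, R2 = ag$r2$values,
                   AM = task_sig, PM = 0.8 * task_sig, RL = 0.8 * task_sig,
                   V1 = 0.4 * task_sig)
    movie <- generate_movie(gen, traces, masks[names(traces)])
    movie$region_masks <- masks
    on <- ag$mode != "background"   # task engagement
    amap <- activation_map(movie, on, !on)
    ratio <- region_ratio(amap, masks[c("AM", "PM", "RL")], masks$V1)
    smap <- seed_correlation_map(movie, "R1")
    list(activation = amap, seed_r1 = smap, hva_v1_ratio = ratio)
  })
  utils::write.csv(maps$activation$values,
                   file.path(out_dir, "activation_map.csv"),
                   row.names = FALSE)

  ephys <- .stage("ephys", {
    pop <- generate_population_spikes(spiking_config(), ses$cursor,
                                      condition = "task", seed = seed)
    tc <- tuning_curve(pop[[1]], ses$cursor)
    list(pop = pop, tuning = tc, units = unit_table(pop))
  })
  utils::write.csv(ephys$units, file.path(out_dir, "units.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ephys$tuning),
                   file.path(out_dir, "tuning.csv"), row.names = FALSE)

  cls <- .stage("classify", {
    ds <- classifier_dataset(ses$cursor, ephys$pop, classes = "position")
    n_splits <- min(cfg$n_splits, floor(dim(ds$responses)[1] / 2))
    train_eval(ds$responses, ds$labels,
               classifier_spec(n_splits = n_splits,
                               n_repeats = cfg$n_repeats, seed = seed))
  })
  utils::write.csv(
    data.frame(time_ms = cls$time_ms, accuracy = cls$accuracy),
    file.path(out_dir, "accuracy.csv"), row.names = FALSE)

  if (isTRUE(cfg$figures)) {
    grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 9)
    graphics::par(mfrow = c(3, 2))
    graphics::plot(metrics$hit_rate$time_min, metrics$hit_rate$hits_per_min,
                   type = "s", xlab = "time (min)", ylab = "hits/min",
                   main = "hit rate")
    graphics::plot(metrics$entropy$time_s / 60, metrics$entropy$se,
                   type = "l", xlab = "time (min)", ylab = "SE (bits)",
                   main = "spectral entropy")
    plot(maps$activation)
    plot(maps$seed_r1)
    plot(ephys$tuning)
    plot(cls)
    grDevices::dev.off()
  }

  summary$hits_per_min <- metrics$hits_per_min
  summary$n_trials <- nrow(ses$trials)
  summary$n_hits <- sum(ses$trials$outcome == "hit")
  summary$r1_r2_correlation <- metrics$r1_r2_correlation
  summary$mean_entropy_bits <- mean(metrics$entropy$se)
  summary$hva_v1_ratio <- maps$hva_v1_ratio
  summary$classifier_accuracy <- cls$overall
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
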