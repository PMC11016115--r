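#' Default pipeline configuration
#'
#' The full study conditions as a nested list: 8 subjects x 2 tasks x
#' 180 trials, the gradual 0.2 degree/trial rotation up to 20 degrees,
#' the default learner and EEG parameters, Morlet settings, the
#' conventional dB baselines, and the four decoding analyses the design
#' motivates. Every random stage derives its stream deterministically
#' from the top-level `seed`.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    design = list(n_subjects = 8L),
    learner = list(
      A = list(visual = 0.95, memory = 0.90),
      B = list(visual = 0.25, memory = 0.15),
      motor_noise_sd = 2, x1 = 0,
      rt_mean = list(visual = 0.30, memory = 0.40),
      rt_sd = 0.05, mt_mean = 0.30,
      inject_outliers = TRUE, n_outliers = 2L),
    eeg = list(
      enabled = TRUE,
      channels = eegParams()$channels,
      fs = 500, bg_exponent = 1, bg_rms = 10,
      trial_period = 8, pad = 3,
      effects = list(
        list(name = "feedback_delta_parietal", band = c(1, 4),
             channels = c("P3", "Pz", "P4"), align = "feedback",
             window = c(0, 1), db_diff = 3),
        list(name = "premove_beta_central", band = c(13, 30),
             channels = c("C3", "Fz"), align = "move_onset",
             window = c(-1, 0), db_diff = -3))),
    analysis = list(
      wavelet_mode = "cycles", n_cycles = 3,
      channels = c("Fz", "C3", "P3", "Pz", "P4"),
      baseline_reach = c(-1.5, -1.0),
      baseline_feedback = c(-0.1, 0)),
    decoding = list(
      n_perm = 1000L, mode = "max", svm_cost = 1,
      analyses = list(
        list(name = "feedback_delta_parietal", band = "delta",
             electrodes = c("P3", "Pz", "P4"), alignment = "feedback",
             window = c(0, 1)),
        list(name = "feedback_delta_c3", band = "delta",
             electrodes = "C3", alignment = "feedback",
             window = c(0, 1)),
        list(name = "reach_beta_c3", band = "beta", electrodes = "C3",
             alignment = "move_onset", window = c(-1, 0)),
        list(name = "reach_beta_fz", band = "beta", electrodes = "Fz",
             alignment = "move_onset", window = c(-1, 0)))),
    stats = list(d_convention = "dz"))
}

# recursively reject keys absent from the reference configuration
.checkConfigKeys <- function(cfg, ref, path = "") {
  if (!is.list(cfg) || is.null(names(cfg)) || !is.list(ref)) return()
  if (is.null(names(ref))) return()   # list-of-entries (effects, analyses)
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg))
    if (nm %in% names(ref))
      .checkConfigKeys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
}

#' Read and validate a pipeline configuration file
#'
#' YAML file with the [defaultPipelineConfig()] hierarchy; missing keys
#' take their defaults, unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  ref <- defaultPipelineConfig()
  .checkConfigKeys(user, ref)
  utils::modifyList(ref, user)
}

.learnerFromConfig <- function(lc) {
  learnerParams(
    A = unlist(lc$A), B = unlist(lc$B),
    motorNoiseSd = lc$motor_noise_sd, x1 = lc$x1,
    rtMean = unlist(lc$rt_mean), rtSd = lc$rt_sd, mtMean = lc$mt_mean)
}

.eegFromConfig <- function(ec) {
  effects <- lapply(ec$effects, function(ef)
    list(name = ef$name, band = as.numeric(ef$band),
         channels = ef$channels, align = ef$align,
         window = as.numeric(ef$window), dbDiff = ef$db_diff))
  eegParams(channels = ec$channels, fs = ec$fs,
            bgExponent = ec$bg_exponent, bgRms = ec$bg_rms,
            effects = effects, trialPeriod = ec$trial_period,
            pad = ec$pad)
}

.baselineFor <- function(alignment, ac) {
  if (alignment == "feedback") ac$baseline_feedback else ac$baseline_reach
}

#' Run the full analysis pipeline
#'
#' generate -> kinematics -> state-space fits -> behavioral statistics ->
#' EEG time-frequency -> decoding, writing every table plus a
#' human-readable report and a manifest to `outDir`. Identical
#' configurations produce identical artifact contents. EEG recordings
#' are generated, analyzed and discarded one subject x task at a time to
#' bound memory; set `writeEEG = TRUE` to also store them in the binary
#' dialect.
#'
#' @param config configuration list ([defaultPipelineConfig()] or
#'   [readPipelineConfig()]).
#' @param outDir artifact directory (created).
#' @param writeEEG also write the raw EEG recordings (default FALSE).
#' @param quiet suppress progress messages (default FALSE).
#' @return invisibly, a list with the key result objects and `outDir`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        writeEEG = FALSE, quiet = FALSE) {
  .checkConfigKeys(config, defaultPipelineConfig())
  config <- utils::modifyList(defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[rotadapt] ", sprintf(...))
  stageFail <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  t0 <- Sys.time()

  # --- generate -----------------------------------------------------
  say("design + behavior (n_subjects = %d)", config$design$n_subjects)
  schedule <- buildRotationSchedule()
  design <- stageFail("design",
    makeDesign(config$design$n_subjects, seed = config$seed,
               schedule = schedule))
  learner <- .learnerFromConfig(config$learner)
  behavior <- stageFail("behavior",
    simulateBehavior(design, learner, seed = config$seed,
                     injectOutliers = config$learner$inject_outliers,
                     nOutliers = config$learner$n_outliers))
  writeDataset(behavior, dir = outDir)

  # --- kinematics ---------------------------------------------------
  say("kinematics (%d trials)", nrow(behavior$trials))
  kin <- stageFail("kinematics",
    computeKinematics(behavior$trials, behavior$trajectories))
  .writeTableExact(kin, file.path(outDir, "kinematics.csv"))

  # --- state-space fits + block metrics -----------------------------
  say("state-space fits")
  adaptTrials <- schedule$trial[schedule$phase == "adaptation"]
  keys <- unique(kin[, c("subject", "task")])
  fitRows <- list(); blockRows <- list(); subjRows <- list()
  for (i in seq_len(nrow(keys))) {
    s <- keys$subject[i]; tk <- keys$task[i]
    sub <- kin[kin$subject == s & kin$task == tk, ]
    sub <- sub[order(sub$trial), ]
    ad <- sub[match(adaptTrials, sub$trial), ]
    fit <- stageFail(sprintf("fit subject %d %s", s, tk),
      estimateStateSpace(ad$hand_angle_deg,
                         schedule$rotation_deg[adaptTrials],
                         excluded = ad$excluded))
    fitRows[[i]] <- data.frame(subject = s, task = tk, A_hat = fit@A,
                               B_hat = fit@B, R2 = fit@R2,
                               n_pairs = fit@nPairs)
    met <- stageFail(sprintf("metrics subject %d %s", s, tk),
      adaptationMetrics(sub, schedule))
    blockRows[[i]] <- cbind(subject = s, task = tk, met$blocks)
    subjRows[[i]] <- data.frame(subject = s, task = tk,
                                baseline_sd_deg = met$baseline_sd_deg,
                                aftereffect_deg = met$aftereffect_deg)
  }
  fits <- do.call(rbind, fitRows)
  blocks <- do.call(rbind, blockRows)
  subj <- do.call(rbind, subjRows)
  .writeTableExact(fits, file.path(outDir, "statespace_fits.csv"))
  .writeTableExact(blocks, file.path(outDir, "block_summary.csv"))
  .writeTableExact(subj, file.path(outDir, "subject_summary.csv"))

  # --- behavioral statistics ----------------------------------------
  say("behavioral statistics")
  adat <- blocks[blocks$phase == "adaptation", ]
  adat$ablock <- adat$block - 1L
  rdat <- blocks[blocks$phase %in% c("baseline", "adaptation"), ]
  anova <- rbind(
    cbind(measure = "mean_hand_angle",
          rmAnovaTwoWay(adat, "mean_hand_angle_deg", "subject", "task",
                        "ablock")),
    cbind(measure = "mean_abs_error",
          rmAnovaTwoWay(adat, "mean_abs_error_deg", "subject", "task",
                        "ablock")),
    cbind(measure = "rt",
          rmAnovaTwoWay(rdat, "mean_rt_s", "subject", "task", "block")),
    cbind(measure = "mt",
          rmAnovaTwoWay(rdat, "mean_mt_s", "subject", "task", "block")))
  dconv <- config$stats$d_convention
  pairWide <- function(df, col) {
    v <- df[df$task == "visual", ]; m <- df[df$task == "memory", ]
    v <- v[order(v$subject), ]; m <- m[order(m$subject), ]
    list(v = v[[col]], m = m[[col]])
  }
  paired <- do.call(rbind, lapply(
    list(c("retention_rate", "A_hat"), c("adaptation_rate", "B_hat"),
         c("baseline_sd", "baseline_sd_deg"),
         c("aftereffect", "aftereffect_deg")),
    function(z) {
      src <- if (z[2] %in% names(fits)) fits else subj
      p <- pairWide(src, z[2])
      cbind(measure = z[1], pairedTTest(p$v, p$m, convention = dconv))
    }))
  .writeTableExact(anova, file.path(outDir, "stats_anova.csv"))
  .writeTableExact(paired, file.path(outDir, "stats_paired.csv"))

  # --- EEG time-frequency -------------------------------------------
  bandTable <- NULL
  decRes <- list()
  if (isTRUE(config$eeg$enabled)) {
    eegP <- .eegFromConfig(config$eeg)
    ac <- config$analysis
    alignments <- unique(vapply(config$decoding$analyses,
                                function(a) a$alignment, ""))
    bandRows <- list()
    for (i in seq_len(nrow(keys))) {
      s <- keys$subject[i]; tk <- keys$task[i]
      say("EEG subject %d %s", s, tk)
      sub <- behavior$trials[behavior$trials$subject == s &
                             behavior$trials$task == tk, ]
      rec <- stageFail(sprintf("eeg subject %d %s", s, tk), {
        r <- simulateEEGRecording(sub, eegP, seed = config$seed)
        if (writeEEG) writeEEGRecording(r, file.path(outDir, "eeg"))
        removeArtifacts(preprocessRaw(r))
      })
      for (al in alignments) {
        ep <- epochByEvent(rec, al, channels = ac$channels)
        tf <- morletTFR(ep, mode = ac$wavelet_mode,
                        nCycles = ac$n_cycles)
        tf <- dbNormalize(tf, .baselineFor(al, ac))
        bandRows[[length(bandRows) + 1L]] <- bandAverage(tf)
      }
      rm(rec)
    }
    bandTable <- do.call(rbind, bandRows)
    .writeTableExact(bandTable, file.path(outDir, "bandpower.csv"))

    # --- decoding ----------------------------------------------------
    for (an in config$decoding$analyses) {
      say("decoding %s", an$name)
      ds <- stageFail(paste("decoding", an$name),
        assembleFeatures(bandTable, an$band, an$electrodes,
                         an$alignment, an$window))
      res <- decodeTaskType(ds, nPerm = config$decoding$n_perm,
                            seed = config$seed,
                            mode = config$decoding$mode,
                            C = config$decoding$svm_cost)
      decRes[[an$name]] <- res
      .writeTableExact(decodingTable(res),
                       file.path(outDir,
                                 sprintf("decoding_%s.csv", an$name)))
      .writeTableExact(
        data.frame(null_accuracy = if (res@mode == "max") res@nullStat
                   else as.vector(res@null)),
        file.path(outDir, sprintf("decoding_%s_null.csv", an$name)))
    }
  }

  # --- report + manifest --------------------------------------------
  report <- c(
    "# rotadapt pipeline report", "",
    sprintf("- subjects: %d, trials per task: %d, total records: %d",
            config$design$n_subjects, max(design$trial), nrow(design)),
    sprintf("- excluded trials: %d of %d (%s)", sum(kin$excluded),
            nrow(kin), paste0(names(table(kin$exclude_reason[kin$excluded])),
                              ": ",
                              table(kin$exclude_reason[kin$excluded]),
                              collapse = ", ")),
    "",
    "## State-space fits (mean over subjects)", "",
    sprintf("- %s: A = %.3f, B = %.3f, R2 = %.3f", .TASKS,
            tapply(fits$A_hat, fits$task, mean)[.TASKS],
            tapply(fits$B_hat, fits$task, mean)[.TASKS],
            tapply(fits$R2, fits$task, mean)[.TASKS]),
    "",
    "## Paired t tests (visual - memory)", "",
    sprintf("- %s: t(%d) = %.3f, p = %.4f, d = %.3f", paired$measure,
            paired$df, paired$t, paired$p, paired$d),
    "",
    "## rmANOVA", "",
    sprintf("- %s, %s: F(%d,%d) = %.3f, p = %.4f, pes = %.3f",
            anova$measure, anova$effect, anova$df1, anova$df2, anova$F,
            anova$p, anova$partial_eta_sq))
  if (length(decRes)) {
    report <- c(report, "", "## Decoding", "")
    for (nm in names(decRes)) {
      r <- decRes[[nm]]
      sig <- which(r@significant)
      report <- c(report, sprintf(
        "- %s: %s (chance %.3f, threshold %.3f, %d permutations)", nm,
        if (length(sig)) paste0("significant at ",
                                paste(round(r@times[sig] * 1000),
                                      collapse = ", "), " ms")
        else "no significant decoding windows", r@chance[1],
        r@threshold[1], r@nPerm))
    }
  }
  writeLines(report, file.path(outDir, "report.md"))

  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  manifest <- c(
    sprintf("config_md5: %s", unname(tools::md5sum(cfgPath))),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("rotadapt"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("elapsed_s: %.1f",
            as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(manifest, file.path(outDir, "manifest.txt"))
  say("done in %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(outDir = outDir, trials = behavior$trials,
                 kinematics = kin, fits = fits, blocks = blocks,
                 subjects = subj, anova = anova, paired = paired,
                 bandPower = bandTable, decoding = decRes))
}
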