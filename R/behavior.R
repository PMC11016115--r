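# angle helpers: directions are measured from the +y axis (the centerline),
# counterclockwise positive, in degrees. A counterclockwise rotation takes
# +y toward -x in screen coordinates (x right, y away from the body).
unitVec <- function(angleDeg) {
  a <- angleDeg * pi / 180
  c(-sin(a), cos(a))
}

angleCCW <- function(x, y) atan2(-x, y) * 180 / pi

# minimum-jerk position profile: fraction of amplitude covered at
# normalized time tau in [0, 1]
minJerkS <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# normalized time at which the min-jerk reach covers fraction `frac`
minJerkTimeToFraction <- function(frac) {
  stats::uniroot(function(tau) minJerkS(tau) - frac, c(0, 1),
                 tol = 1e-10)$root
}

rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Simulate reaching behavior for a full design
#'
#' Drives each subject x task series with the state-space learner
#' ([simulateStateSpace()]; motor noise enters the executed hand angle and
#' hence the error the learner experiences), draws trial timing, and
#' renders each reach as a minimum-jerk trajectory sampled on the 60 Hz
#' cursor grid.
#'
#' Per trial, time runs from the trial start: the target appears after a
#' uniform 1.5--2 s hold; in the visually-guided task the go signal is the
#' target onset, while in the memory-guided task the target is flashed for
#' 0.2 s and the go signal follows 2 s later. Movement starts at
#' go + RT (truncated-normal per task) and lasts `mtMean` seconds; cursor
#' feedback occurs when the hand crosses the 80 mm feedback radius. The
#' reach direction is the target direction minus the trial's hand angle
#' (compensatory-positive sign convention shared with the analyzers).
#'
#' Optionally injects large hand-angle outliers (default two per full
#' dataset, mirroring the scale at which the exclusion rule operates) at
#' random non-adjacent trial slots.
#'
#' @param design design table from [makeDesign()].
#' @param learner parameters from [learnerParams()].
#' @param seed integer seed; all draws derive from it deterministically.
#' @param injectOutliers logical, inject hand-angle outliers
#'   (default TRUE).
#' @param nOutliers number of injected outliers (default 2).
#' @param outlierMagnitude absolute size of an injected deviation in
#'   degrees (default 40).
#' @return list with `trials` (the design plus `hand_angle_true_deg`,
#'   `rt_true_s`, `mt_s`, `t_target_on_s`, `t_go_s`, `t_move_onset_s`,
#'   `t_feedback_s`, `outlier_injected`) and `trajectories` (data.frame:
#'   `subject`, `task`, `trial`, `t_s`, `x_mm`, `y_mm` at 60 Hz).
#' @export
simulateBehavior <- function(design, learner = learnerParams(), seed = 1,
                             injectOutliers = TRUE, nOutliers = 2,
                             outlierMagnitude = 40) {
  stopifnot(inherits(learner, "learnerParams"))
  fsTraj <- 60
  tau80 <- minJerkTimeToFraction(80 / learner$reachAmplitude)
  trials <- design[order(design$subject, design$task, design$trial), ,
                   drop = FALSE]
  rownames(trials) <- NULL
  keys <- unique(trials[, c("subject", "task")])
  nT <- max(trials$trial)

  # learner state and timing draws per subject x task
  trials$hand_angle_true_deg <- NA_real_
  trials$rt_true_s <- NA_real_
  for (k in seq_len(nrow(keys))) {
    s <- keys$subject[k]; tk <- keys$task[k]
    idx <- which(trials$subject == s & trials$task == tk)
    if (length(idx) != nT) stop("design is not complete for subject ", s)
    rot <- trials$rotation_deg[idx]
    trials$hand_angle_true_deg[idx] <- simulateStateSpace(
      rot, A = learner$A[[tk]], B = learner$B[[tk]], x1 = learner$x1,
      noiseSd = learner$motorNoiseSd,
      seed = deriveSeed(seed, paste("learner", s, tk)))
    set.seed(deriveSeed(seed, paste("timing", s, tk)))
    trials$rt_true_s[idx] <- rtruncnorm0(length(idx),
                                         learner$rtMean[[tk]],
                                         learner$rtSd)
  }

  trials$outlier_injected <- FALSE
  if (injectOutliers && nOutliers > 0) {
    set.seed(deriveSeed(seed, "outliers"))
    repeat {
      slots <- sample(nrow(trials), nOutliers)
      ok <- TRUE
      if (nOutliers > 1L) {
        st <- trials[slots, c("subject", "task", "trial")]
        for (i in seq_len(nOutliers - 1L)) for (j in (i + 1L):nOutliers) {
          same <- st$subject[i] == st$subject[j] && st$task[i] == st$task[j]
          if (same && abs(st$trial[i] - st$trial[j]) < 5L) ok <- FALSE
        }
      }
      if (ok) break
    }
    signs <- sample(c(-1, 1), nOutliers, replace = TRUE)
    trials$hand_angle_true_deg[slots] <-
      trials$hand_angle_true_deg[slots] + signs * outlierMagnitude
    trials$outlier_injected[slots] <- TRUE
  }

  set.seed(deriveSeed(seed, "targeton"))
  trials$t_target_on_s <- runif(nrow(trials), 1.5, 2.0)
  trials$t_go_s <- trials$t_target_on_s +
    ifelse(trials$task == "memory", 2.2, 0)   # 0.2 s flash + 2 s delay
  trials$t_move_onset_s <- trials$t_go_s + trials$rt_true_s
  trials$mt_s <- learner$mtMean
  trials$t_feedback_s <- trials$t_move_onset_s + tau80 * trials$mt_s

  # render trajectories on the 60 Hz grid
  D <- learner$reachAmplitude
  trajList <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tOn <- trials$t_move_onset_s[i]
    mt <- trials$mt_s[i]
    tEnd <- tOn + mt + 0.25
    tGrid <- seq(0, tEnd, by = 1 / fsTraj)
    dirDeg <- trials$target_angle_deg[i] - trials$hand_angle_true_deg[i]
    u <- unitVec(dirDeg)
    sProf <- D * minJerkS((tGrid - tOn) / mt)
    trajList[[i]] <- data.frame(
      subject = trials$subject[i], task = trials$task[i],
      trial = trials$trial[i], t_s = tGrid,
      x_mm = u[1] * sProf, y_mm = u[2] * sProf)
  }
  trajectories <- as.data.frame(data.table::rbindlist(trajList))
  list(trials = trials, trajectories = trajectories)
}
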