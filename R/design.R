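#' Build the experiment design table
#'
#' One row per trial slot: `nSubjects` subjects x 2 tasks (visually- and
#' memory-guided) x 180 trials divided into 6 blocks of 30 (baseline,
#' 4 adaptation blocks, washout). Target angles are drawn i.i.d. uniform
#' on [-10, 10] degrees about the centerline; the rotation column comes
#' from [buildRotationSchedule()].
#'
#' @param nSubjects number of subjects (default 8).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param schedule rotation schedule (default [buildRotationSchedule()]).
#' @return data.frame with columns `subject`, `task`, `block` (1..6),
#'   `phase`, `trial_in_block` (1..30), `trial` (1..180),
#'   `target_angle_deg`, `rotation_deg`.
#' @export
#' @examples
#' d <- makeDesign(8, seed = 1)
#' nrow(d)  # 2880
makeDesign <- function(nSubjects = 8, seed = 1,
                       schedule = buildRotationSchedule()) {
  if (nSubjects < 1) stop("nSubjects must be >= 1")
  nTrials <- nrow(schedule)
  perBlock <- 30L
  if (nTrials %% perBlock != 0L)
    stop("schedule length must be a multiple of the 30-trial block size")
  set.seed(deriveSeed(seed, "design"))
  grid <- expand.grid(trial = seq_len(nTrials), task = .TASKS,
                      subject = seq_len(nSubjects),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject", "task", "trial")]
  grid$block <- (grid$trial - 1L) %/% perBlock + 1L
  grid$phase <- schedule$phase[grid$trial]
  grid$trial_in_block <- (grid$trial - 1L) %% perBlock + 1L
  grid$target_angle_deg <- runif(nrow(grid), -10, 10)
  grid$rotation_deg <- schedule$rotation_deg[grid$trial]
  grid[, c("subject", "task", "block", "phase", "trial_in_block", "trial",
           "target_angle_deg", "rotation_deg")]
}

#' Learner and movement parameters for the behavior generator
#'
#' Generative parameters of the state-space learner and of the reach
#' itself, per task. Defaults encode the study conditions: higher
#' retention and adaptation rates and shorter reaction times in the
#' visually-guided task, motor noise of 2 degrees, 100 mm minimum-jerk
#' reaches of 0.3 s.
#'
#' @param A named retention rates per task, in [0, 1].
#' @param B named adaptation rates per task, in [0, 1].
#' @param motorNoiseSd motor noise SD in degrees (>= 0).
#' @param x1 initial internal state in degrees.
#' @param rtMean named mean reaction time per task (s); the memory-guided
#'   mean must not be below the visually-guided mean.
#' @param rtSd reaction-time SD (s); draws are truncated at 0.
#' @param mtMean movement duration (s) of the minimum-jerk reach.
#' @param reachAmplitude reach amplitude in mm (>= 80 mm so the cursor
#'   crosses the 8 cm feedback radius).
#' @return a validated list of class `"learnerParams"`.
#' @export
learnerParams <- function(A = c(visual = 0.95, memory = 0.90),
                          B = c(visual = 0.25, memory = 0.15),
                          motorNoiseSd = 2, x1 = 0,
                          rtMean = c(visual = 0.30, memory = 0.40),
                          rtSd = 0.05, mtMean = 0.30,
                          reachAmplitude = 100) {
  for (nm in c("A", "B", "rtMean")) {
    v <- get(nm)
    if (!all(.TASKS %in% names(v)))
      stop(nm, " must be named with tasks ",
           paste(.TASKS, collapse = ", "))
  }
  if (any(A < 0 | A > 1) || any(B < 0 | B > 1))
    stop("A and B must lie in [0, 1]")
  if (motorNoiseSd < 0) stop("motorNoiseSd must be >= 0")
  if (rtMean["memory"] < rtMean["visual"])
    stop("rtMean: the memory-guided mean must be >= the visually-guided mean")
  if (mtMean <= 0 || rtSd < 0) stop("mtMean must be > 0 and rtSd >= 0")
  if (reachAmplitude < 80)
    stop("reachAmplitude must be >= 80 mm (the feedback radius)")
  structure(list(A = A[.TASKS], B = B[.TASKS], motorNoiseSd = motorNoiseSd,
                 x1 = x1, rtMean = rtMean[.TASKS], rtSd = rtSd,
                 mtMean = mtMean, reachAmplitude = reachAmplitude),
            class = "learnerParams")
}
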