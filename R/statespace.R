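#' Build the gradual rotation schedule
#'
#' Cursor rotation per trial for one task: zero during baseline, a gradual
#' counterclockwise ramp during adaptation that grows by `increment`
#' degrees per adaptation trial up to `ceiling`, and zero again during
#' washout. With the defaults the ramp is 0.2 * (t - 1) degrees on the
#' t-th adaptation trial, so it first reaches the 20 degree ceiling on
#' adaptation trial 101 and stays there for the remaining 19 trials.
#'
#' @param nBaseline,nAdapt,nWashout trial counts per phase
#'   (defaults 30, 120, 30).
#' @param increment ramp increment in degrees per adaptation trial
#'   (default 0.2).
#' @param ceiling maximum rotation in degrees (default 20).
#' @return data.frame with columns `trial` (1-based overall index),
#'   `phase` (`"baseline"`, `"adaptation"`, `"washout"`) and
#'   `rotation_deg` (counterclockwise positive).
#' @export
#' @examples
#' sched <- buildRotationSchedule()
#' which(sched$rotation_deg == 20)[1] - 30   # adaptation trial 101
buildRotationSchedule <- function(nBaseline = 30, nAdapt = 120,
                                  nWashout = 30, increment = 0.2,
                                  ceiling = 20) {
  if (any(c(nBaseline, nAdapt, nWashout) < 0))
    stop("phase lengths must be non-negative")
  if (increment < 0 || ceiling < 0)
    stop("increment and ceiling must be non-negative")
  phase <- rep(c("baseline", "adaptation", "washout"),
               times = c(nBaseline, nAdapt, nWashout))
  r <- c(rep(0, nBaseline),
         pmin(increment * (seq_len(nAdapt) - 1), ceiling),
         rep(0, nWashout))
  data.frame(trial = seq_along(r), phase = phase, rotation_deg = r)
}

#' Forward-simulate the single-rate state-space learner
#'
#' Iterates the trial-by-trial model: the reaching error is
#' `e_t = r_t - x_t` (rotation minus compensatory hand angle) and the next
#' state is `x_{t+1} = A * x_t + B * e_t` plus motor noise. The state is
#' identified with the observed hand angle, signed positive in the
#' compensatory (counter-rotation) direction.
#'
#' Under a constant rotation `r` the noiseless fixed point is
#' `B * r / (1 - A + B)`.
#'
#' @param rotation numeric, rotation schedule in degrees (one value per
#'   trial; a `buildRotationSchedule()` data.frame is also accepted).
#' @param A retention rate (0 <= A).
#' @param B adaptation rate.
#' @param x1 initial state in degrees (default 0).
#' @param noiseSd motor noise SD in degrees (default 0).
#' @param seed optional integer seed for the noise draws.
#' @return numeric vector of hand angles, one per trial.
#' @export
#' @examples
#' x <- simulateStateSpace(rep(20, 500), A = 0.9, B = 0.3)
#' tail(x, 1)  # ~ 0.3 * 20 / (1 - 0.9 + 0.3) = 15
simulateStateSpace <- function(rotation, A, B, x1 = 0, noiseSd = 0,
                               seed = NULL) {
  if (is.data.frame(rotation)) rotation <- rotation$rotation_deg
  if (A < 0) stop("A must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  n <- length(rotation)
  if (n == 0L) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noiseSd > 0) rnorm(n, 0, noiseSd) else numeric(n)
  x <- numeric(n)
  x[1] <- x1
  for (t in seq_len(n - 1L)) {
    e <- rotation[t] - x[t]
    x[t + 1L] <- A * x[t] + B * e + eps[t + 1L]
  }
  x
}

#' Estimate retention and adaptation rates by regression
#'
#' Least-squares fit of the state-space model to an observed hand-angle
#' series over the adaptation trials: the hand angle at trial t+1 is
#' regressed on the hand angle x_t and the reaching error
#' `e_t = r_t - x_t` with no intercept (the model's own form). The
#' coefficient of x_t is the retention rate A, the coefficient of e_t the
#' adaptation rate B. R2 is the ordinary coefficient of determination of
#' the one-step-ahead predictions.
#'
#' Excluded trials are dropped pairwise: a pair (t, t+1) enters the fit
#' only when both trials are usable.
#'
#' @param handAngles numeric, observed hand angles over the adaptation
#'   trials (degrees, compensatory-positive).
#' @param rotation numeric, rotation per adaptation trial (degrees), same
#'   length; a schedule data.frame restricted to adaptation is accepted.
#' @param excluded logical, trials to drop (default none).
#' @param intercept logical, add an intercept term (default FALSE;
#'   sensitivity switch).
#' @return a [StateSpaceFit-class] object.
#' @export
#' @examples
#' r <- pmin(0.2 * (0:119), 20)
#' x <- simulateStateSpace(r, A = 0.9, B = 0.3)
#' estimateStateSpace(x, r)
estimateStateSpace <- function(handAngles, rotation, excluded = NULL,
                               intercept = FALSE) {
  if (is.data.frame(rotation)) rotation <- rotation$rotation_deg
  n <- length(handAngles)
  if (length(rotation) != n)
    stop("handAngles and rotation must have equal length")
  usable <- is.finite(handAngles)
  if (!is.null(excluded)) usable <- usable & !excluded
  keep <- which(usable[-n] & usable[-1])   # pairs (t, t+1) both usable
  if (length(keep) < 3L)
    stop("need at least 3 usable adaptation trial pairs")
  xt <- handAngles[keep]
  et <- rotation[keep] - xt
  y <- handAngles[keep + 1L]
  X <- cbind(x = xt, e = et)
  if (intercept) X <- cbind(X, `(Intercept)` = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("unidentifiable: rank-deficient regressor matrix ",
         "(e.g. constant-zero hand angles)")
  beta <- qr.coef(qrX, y)
  pred <- drop(X %*% beta)
  res <- y - pred
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
  new("StateSpaceFit",
      A = unname(beta["x"]), B = unname(beta["e"]),
      intercept = if (intercept) unname(beta["(Intercept)"]) else NA_real_,
      R2 = r2, predicted = pred, residuals = res,
      nPairs = length(keep))
}

#' Block-level behavioral summary of one subject x task series
#'
#' Computes, over non-excluded trials only: the mean hand angle and mean
#' absolute reaching error (|r_t - x_t|, the angle between cursor and
#' target) for each of the four adaptation blocks; the SD of baseline
#' hand angles; the aftereffect (mean washout hand angle); and mean
#' reaction and movement times for the baseline and adaptation blocks.
#'
#' @param kin data.frame with columns `trial`, `block`, `phase`,
#'   `hand_angle_deg`, `rt_s`, `mt_s`, `excluded` for one subject and task
#'   (as produced by [computeKinematics()] merged with the design).
#' @param schedule rotation schedule data.frame ([buildRotationSchedule()]).
#' @return list with `blocks` (data.frame: block, phase,
#'   mean_hand_angle_deg, mean_abs_error_deg, mean_rt_s, mean_mt_s),
#'   `baseline_sd_deg` and `aftereffect_deg`.
#' @export
adaptationMetrics <- function(kin, schedule) {
  need <- c("trial", "block", "phase", "hand_angle_deg", "rt_s", "mt_s",
            "excluded")
  if (!all(need %in% names(kin)))
    stop("kin is missing columns: ",
         paste(setdiff(need, names(kin)), collapse = ", "))
  kin <- kin[order(kin$trial), , drop = FALSE]
  kin$rotation_deg <- schedule$rotation_deg[match(kin$trial, schedule$trial)]
  use <- kin[!kin$excluded, , drop = FALSE]
  if (nrow(use) == 0L) stop("no usable trials after exclusions")
  blk <- split(use, use$block)
  if (any(!vapply(blk, nrow, 0L)))
    NULL
  rows <- lapply(blk, function(b) data.frame(
    block = b$block[1], phase = b$phase[1],
    mean_hand_angle_deg = mean(b$hand_angle_deg),
    mean_abs_error_deg = mean(abs(b$rotation_deg - b$hand_angle_deg)),
    mean_rt_s = mean(b$rt_s, na.rm = TRUE),
    mean_mt_s = mean(b$mt_s, na.rm = TRUE)))
  blocks <- do.call(rbind, rows)
  rownames(blocks) <- NULL
  base <- use[use$phase == "baseline", ]
  wash <- use[use$phase == "washout", ]
  if (nrow(base) == 0L || nrow(wash) == 0L)
    stop("a phase is empty after exclusions")
  list(blocks = blocks,
       baseline_sd_deg = sd(base$hand_angle_deg),
       aftereffect_deg = mean(wash$hand_angle_deg))
}
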