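#' Paired t test with Cohen's d
#'
#' Two-sided paired t test (via [stats::t.test()]) with an effect size.
#' The default convention is d_z = mean(x - y) / SD(x - y); the
#' alternative `"average_sd"` divides the mean difference by the average
#' of the two condition SDs. A zero difference variance with a nonzero
#' mean difference (infinite t) is reported as an error rather than a
#' silent value.
#'
#' @param x,y paired numeric vectors (same subjects, same order).
#' @param convention `"dz"` (default) or `"average_sd"`.
#' @return data.frame: `t`, `df`, `p`, `d`, `convention`.
#' @export
#' @examples
#' pairedTTest(c(1, 2, 3), c(2, 4, 6))
pairedTTest <- function(x, y, convention = c("dz", "average_sd")) {
  convention <- match.arg(convention)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) != 0)
      stop("zero difference variance with nonzero mean: t is infinite")
    return(data.frame(t = 0, df = length(x) - 1L, p = 1, d = 0,
                      convention = convention))
  }
  tt <- t.test(x, y, paired = TRUE)
  dval <- switch(convention,
    dz = mean(d) / sd(d),
    average_sd = mean(d) / ((sd(x) + sd(y)) / 2))
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = dval, convention = convention)
}

#' Two-way repeated-measures ANOVA with partial eta squared
#'
#' Classical within-subject decomposition for a complete balanced
#' subject x factor1 x factor2 table, fitted with [stats::aov()] using
#' subject-by-effect error strata
#' (`value ~ f1 * f2 + Error(subject / (f1 * f2))`). Each effect is
#' tested against its own stratum (F = MS_effect / MS_error, no
#' sphericity correction, so the degrees of freedom are the integer
#' textbook values: (a-1, (a-1)(n-1)) for a main effect and
#' ((a-1)(b-1), (a-1)(b-1)(n-1)) for the interaction). The effect size
#' is partial eta squared, SS_effect / (SS_effect + SS_error).
#'
#' @param data data.frame in long form.
#' @param value,subject,factor1,factor2 column names in `data`.
#' @return data.frame with one row per effect (factor1, factor2,
#'   interaction): `effect`, `df1`, `df2`, `SS`, `SS_error`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
#' @examples
#' d <- expand.grid(subject = 1:8, task = c("v", "m"), block = 1:4)
#' d$y <- rnorm(nrow(d))
#' rmAnovaTwoWay(d, "y", "subject", "task", "block")
rmAnovaTwoWay <- function(data, value, subject, factor1, factor2) {
  for (col in c(value, subject, factor1, factor2))
    if (!col %in% names(data)) stop("column '", col, "' not in data")
  df <- data.frame(y = data[[value]],
                   s = factor(data[[subject]]),
                   f1 = factor(data[[factor1]]),
                   f2 = factor(data[[factor2]]))
  if (anyNA(df)) stop("missing values in the design")
  if (any(table(df$s, df$f1, df$f2) != 1L))
    stop("design must be complete and balanced: exactly one observation ",
         "per subject x factor cell")
  fit <- aov(y ~ f1 * f2 + Error(s / (f1 * f2)), data = df)
  sm <- summary(fit)
  # pull (SS, df) for an effect and its error line from the right stratum
  stratum <- function(name) {
    hit <- sm[[paste0("Error: ", name)]]
    if (is.null(hit)) stop("aov stratum '", name, "' not found")
    as.data.frame(hit[[1]])
  }
  pick <- function(strat, term) {
    tab <- stratum(strat)
    rn <- trimws(rownames(tab))
    eff <- tab[match(term, rn), ]
    err <- tab[match("Residuals", rn), ]
    if (anyNA(eff$Df) || anyNA(err$Df))
      stop("could not extract effect '", term, "' from stratum ", strat)
    data.frame(df1 = eff$Df, df2 = err$Df, SS = eff$`Sum Sq`,
               SS_error = err$`Sum Sq`)
  }
  rows <- rbind(cbind(effect = factor1, pick("s:f1", "f1")),
                cbind(effect = factor2, pick("s:f2", "f2")),
                cbind(effect = paste0(factor1, ":", factor2),
                      pick("s:f1:f2", "f1:f2")))
  # clamp sums of squares that are pure floating-point residue (e.g. data
  # carrying subject offsets only), so such effects report F = 0, p = 1
  tol <- 1e-12 * sum((df$y - mean(df$y))^2)
  rows$SS[rows$SS <= tol] <- 0
  rows$SS_error[rows$SS_error <= tol] <- 0
  rows$F <- ifelse(rows$SS == 0, 0,
                   (rows$SS / rows$df1) / (rows$SS_error / rows$df2))
  rows$p <- pf(rows$F, rows$df1, rows$df2, lower.tail = FALSE)
  rows$partial_eta_sq <- ifelse(rows$SS + rows$SS_error > 0,
                                rows$SS / (rows$SS + rows$SS_error), 0)
  rownames(rows) <- NULL
  rows
}
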