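# Lifetime smoking index: status + duration + intensity + cessation folded
# into one non-negative score with exponential half-life decay.

#' Duration of smoking and time since cessation
#'
#' Derives the two exposure times that enter the lifetime smoking index from
#' a smoking-history table. Never smokers get duration 0 and an undefined
#' (NA) time since cessation; current smokers have not ceased, so their time
#' since cessation is 0.
#'
#' @param histories data.frame with columns `status` (one of `"never"`,
#'   `"former"`, `"current"`), `age_init`, `age_cess`, `age_assess` (years;
#'   `NA` where not applicable).
#' @param onMissing what to do when an age required for the given status is
#'   missing: `"error"` (default) stops naming the offending field and rows;
#'   `"exclude"` returns `NA` for those rows and attaches the excluded row
#'   indices as attribute `"excluded"`.
#' @return data.frame with columns `dur` (smoking duration, years) and `tsc`
#'   (time since cessation, years).
#' @examples
#' h <- data.frame(status = c("former", "never", "current"),
#'                 age_init = c(20, NA, 30), age_cess = c(35, NA, NA),
#'                 age_assess = c(52, 60, 50))
#' deriveExposureTimes(h)   # dur 15/0/20, tsc 17/NA/0
#' @export
deriveExposureTimes <- function(histories, onMissing = c("error", "exclude")) {
  onMissing <- match.arg(onMissing)
  stopifnot(is.data.frame(histories),
            all(c("status", "age_init", "age_cess", "age_assess") %in%
                  names(histories)))
  status <- as.character(histories$status)
  bad_status <- setdiff(unique(status), c("never", "former", "current"))
  if (length(bad_status) > 0)
    stop("unknown smoking status: ", paste(bad_status, collapse = ", "))

  need <- function(field, rows) {
    miss <- rows & is.na(histories[[field]])
    if (any(miss)) {
      if (onMissing == "error")
        stop(sprintf("missing %s for %d %s smoker(s) (rows %s)",
                     field, sum(miss), status[which(miss)[1]],
                     paste(head(which(miss), 5), collapse = ", ")),
             call. = FALSE)
    }
    miss
  }

  former <- status == "former"
  current <- status == "current"
  excl <- need("age_init", former | current) |
    need("age_cess", former) |
    need("age_assess", former | current)

  dur <- tsc <- rep(NA_real_, length(status))
  dur[status == "never"] <- 0
  ok_cur <- current & !excl
  dur[ok_cur] <- histories$age_assess[ok_cur] - histories$age_init[ok_cur]
  tsc[ok_cur] <- 0
  ok_for <- former & !excl
  dur[ok_for] <- histories$age_cess[ok_for] - histories$age_init[ok_for]
  tsc[ok_for] <- histories$age_assess[ok_for] - histories$age_cess[ok_for]

  neg <- which(dur < 0 | tsc < 0)
  if (length(neg) > 0)
    stop("inconsistent ages (negative duration or time since cessation) ",
         "in rows ", paste(head(neg, 5), collapse = ", "))

  out <- data.frame(dur = dur, tsc = tsc)
  if (onMissing == "exclude") attr(out, "excluded") <- which(excl)
  out
}

#' Lifetime smoking index
#'
#' Combines duration of smoking (`dur`), time since cessation (`tsc`) and
#' cigarettes per day (`cpd`) into a dimensionless exposure score
#'
#' \deqn{(1 - 0.5^{dur/\tau})\; 0.5^{tsc/\tau}\; \ln(cpd + 1)}
#'
#' where the half-life \eqn{\tau} (years) captures the exponentially
#' decaying effect of past smoking on current health risk. The score is 0
#' for never smokers, increases in duration and intensity, decays with time
#' since cessation, and is bounded above by \eqn{\ln(cpd+1)}.
#'
#' @param dur smoking duration in years (0 for never smokers).
#' @param tsc time since cessation in years (0 for current smokers; ignored
#'   when `dur = 0`, where the score is 0 regardless).
#' @param cpd cigarettes smoked per day.
#' @param tau half-life in years; must be positive.
#' @return numeric vector of non-negative index values.
#' @examples
#' ## a standard-deviation-sized exposure: 20 a day for 15 years, quit 17
#' ## years ago
#' lifetimeSmokingIndex(15, 17, 20, tau = 18)   # 0.694
#' lifetimeSmokingIndex(13, 22, 60, tau = 18)   # 0.694
#' @export
lifetimeSmokingIndex <- function(dur, tsc, cpd, tau = 18) {
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("half-life tau must be a positive number")
  tsc <- ifelse(dur == 0 & is.na(tsc), 0, tsc)
  if (any(dur < 0, na.rm = TRUE) || any(tsc < 0, na.rm = TRUE) ||
      any(cpd < 0, na.rm = TRUE))
    stop("dur, tsc and cpd must be non-negative")
  (1 - 0.5^(dur / tau)) * 0.5^(tsc / tau) * log(cpd + 1)
}

#' Score a smoking-history table
#'
#' Convenience wrapper: derives exposure times with [deriveExposureTimes()]
#' and evaluates [lifetimeSmokingIndex()]. Never smokers (and ever smokers
#' with `cpd = 0`) score exactly 0.
#'
#' @inheritParams deriveExposureTimes
#' @param tau half-life in years.
#' @return numeric vector of scores (with `NA` for rows excluded under
#'   `onMissing = "exclude"`).
#' @export
smokingIndex <- function(histories, tau = 18,
                         onMissing = c("error", "exclude")) {
  et <- deriveExposureTimes(histories, onMissing = onMissing)
  cpd <- histories$cpd
  cpd[histories$status == "never" | is.na(cpd)] <- 0
  out <- lifetimeSmokingIndex(et$dur, et$tsc, cpd, tau)
  attr(out, "excluded") <- attr(et, "excluded")
  out
}

#' Calibrate the half-life of the lifetime smoking index
#'
#' Scans a grid of candidate half-life values; for each, the cohort is
#' scored and a single-predictor model of the health outcome on the score is
#' fitted. The half-life maximising the model log-likelihood is returned
#' (ties broken towards the smaller value). The default criterion is
#' logistic regression on a binary outcome; a proportional-hazards
#' criterion on a time-to-event outcome is available with `model = "cox"`.
#'
#' Former smokers with a missing cessation age cannot be scored and are
#' excluded with a message reporting the count.
#'
#' @param histories smoking-history data.frame (see
#'   [deriveExposureTimes()]), with a `cpd` column.
#' @param outcome for `model = "logistic"`, a 0/1 vector aligned with
#'   `histories`; for `model = "cox"`, a data.frame with columns `time` and
#'   `status`.
#' @param grid strictly increasing vector of candidate half-lives (years).
#' @param model fit criterion, `"logistic"` (default) or `"cox"`.
#' @return list of class `"halfLifeFit"` with elements `tau_star` (chosen
#'   half-life), `fit` (per-candidate table: `tau`, `logLik`, `deviance`,
#'   `coef`, `pval`), `n_used`, `n_excluded`, and `flat` (`TRUE` when the
#'   outcome carries no detectable smoking signal, in which case a warning
#'   is also raised).
#' @examples
#' sim <- simulateCohort(cohortConfig(n = 2000, seed = 1))
#' fit <- calibrateHalfLife(sim$histories, sim$outcome$outcome,
#'                          grid = c(10, 18, 26))
#' fit$tau_star
#' @export
calibrateHalfLife <- function(histories, outcome, grid = seq(2, 40, by = 2),
                              model = c("logistic", "cox")) {
  model <- match.arg(model)
  if (length(grid) < 1 || any(diff(grid) <= 0) || any(grid <= 0))
    stop("grid must be a strictly increasing vector of positive half-lives")

  et <- deriveExposureTimes(histories, onMissing = "exclude")
  excl <- attr(et, "excluded")
  keep <- setdiff(seq_len(nrow(histories)), excl)
  if (length(excl) > 0)
    message(length(excl),
            " participant(s) excluded: required age fields missing")
  h <- histories[keep, , drop = FALSE]
  et <- et[keep, , drop = FALSE]
  cpd <- h$cpd
  cpd[h$status == "never" | is.na(cpd)] <- 0

  if (model == "logistic") {
    y <- outcome[keep]
    if (length(y) != nrow(h)) stop("outcome not aligned with histories")
    if (sum(y == 1) == 0 || sum(y == 0) == 0)
      stop("calibration impossible: outcome has no events (or no non-events)")
  } else {
    surv <- outcome[keep, , drop = FALSE]
    if (!all(c("time", "status") %in% names(surv)))
      stop("cox calibration needs an outcome data.frame with time and status")
    if (sum(surv$status == 1) == 0)
      stop("calibration impossible: outcome has no events")
  }
  if (all(h$status == "never") || all(cpd == 0))
    stop("calibration impossible: no exposure variance (no ever smokers)")

  fit <- data.frame(tau = grid, logLik = NA_real_, deviance = NA_real_,
                    coef = NA_real_, pval = NA_real_)
  for (i in seq_along(grid)) {
    idx <- lifetimeSmokingIndex(et$dur, et$tsc, cpd, grid[i])
    if (sd(idx) == 0) stop("calibration impossible: no exposure variance")
    if (model == "logistic") {
      m <- glm(y ~ idx, family = binomial())
      fit$logLik[i] <- as.numeric(logLik(m))
      fit$deviance[i] <- deviance(m)
      fit$coef[i] <- coef(m)[["idx"]]
      fit$pval[i] <- summary(m)$coefficients["idx", 4]
    } else {
      m <- survival::coxph(survival::Surv(surv$time, surv$status) ~ idx)
      fit$logLik[i] <- m$loglik[2]
      fit$deviance[i] <- -2 * m$loglik[2]
      fit$coef[i] <- coef(m)[["idx"]]
      fit$pval[i] <- summary(m)$coefficients["idx", 5]
    }
  }

  best <- which.max(fit$logLik)   # first maximum = smallest tau on ties
  # no-signal check: likelihood-ratio of the score at the best tau
  flat <- FALSE
  if (model == "logistic") {
    null_ll <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
    lr <- 2 * (fit$logLik[best] - null_ll)
    if (!is.finite(lr) || lr < qchisq(0.95, 1)) flat <- TRUE
  } else if (fit$pval[best] > 0.05) flat <- TRUE
  if (flat)
    warning("flat fit profile: outcome shows no association with the ",
            "smoking index; returned tau is arbitrary")

  structure(list(tau_star = grid[best], fit = fit, model = model,
                 n_used = nrow(h), n_excluded = length(excl), flat = flat),
            class = "halfLifeFit")
}

#' @export
print.halfLifeFit <- function(x, ...) {
  cat(sprintf("Half-life calibration (%s criterion, %d candidates)\n",
              x$model, nrow(x$fit)))
  cat(sprintf("  chosen tau = %g years%s\n", x$tau_star,
              if (x$flat) "  [flat profile: not identified]" else ""))
  cat(sprintf("  participants used: %d (excluded: %d)\n",
              x$n_used, x$n_excluded))
  invisible(x)
}
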