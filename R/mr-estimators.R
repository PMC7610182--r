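# Two-sample MR estimators. Throughout, gamma (g) is the SNP-exposure
# effect and Gamma (G) the allele-aligned SNP-outcome effect; weights are
# inverse outcome-variance unless a method specifies otherwise.

.unpack <- function(data) {
  stopifnot(is(data, "HarmonisedDataset"))
  list(g = exposureBeta(data), sg = exposureSE(data),
       G = outcomeBeta(data), sG = outcomeSE(data))
}

#' Wald ratio: single-variant causal estimate
#'
#' The ratio estimate `Gamma/gamma` with, by default, the first-order delta
#' standard error `se(Gamma)/|gamma|`. The second-order delta option adds
#' the exposure-uncertainty inflation term
#' `Gamma^2 * se(gamma)^2 / gamma^4`.
#'
#' @param gamma_hat,sigma_gamma SNP-exposure effect and standard error.
#' @param Gamma_hat,sigma_Gamma SNP-outcome effect and standard error.
#' @param second_order use the second-order delta standard error.
#' @return an [MREstimate-class] with method `"Wald"`.
#' @examples
#' estimate(waldRatio(0.1, 0.01, 0.05, 0.05))  # 0.5
#' @export
waldRatio <- function(gamma_hat, sigma_gamma, Gamma_hat, sigma_Gamma,
                      second_order = FALSE) {
  if (gamma_hat == 0)
    stop("undefined ratio: SNP-exposure effect is zero")
  beta <- Gamma_hat / gamma_hat
  v <- sigma_Gamma^2 / gamma_hat^2
  if (second_order)
    v <- v + Gamma_hat^2 * sigma_gamma^2 / gamma_hat^4
  .mk_estimate("Wald", beta, sqrt(v), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects through the origin, weights `1/se(Gamma)^2` — equivalently the
#' inverse-variance-weighted meta-analysis of the per-variant Wald ratios.
#' Under the default multiplicative random-effects model the standard error
#' is scaled by `max(1, sqrt(Q/(J-1)))`, so heterogeneity can widen but
#' never narrow the interval; p-values come from a t distribution with
#' `J - 1` degrees of freedom. A single variant delegates to [waldRatio()].
#'
#' @param data a [HarmonisedDataset-class].
#' @param robust `"multiplicative"` (random-effects, default) or `"fixed"`.
#' @return an [MREstimate-class]; `details` carries the heterogeneity
#'   statistic `Q` and the residual scale factor `phi`.
#' @export
mrIVW <- function(data, robust = c("multiplicative", "fixed")) {
  robust <- match.arg(robust)
  d <- .unpack(data)
  J <- length(d$g)
  if (J < 1) stop("no variants")
  if (J == 1)
    return(waldRatio(d$g, d$sg, d$G, d$sG))
  w <- 1 / d$sG^2
  beta <- sum(w * d$g * d$G) / sum(w * d$g^2)
  Q <- sum(w * (d$G - beta * d$g)^2)
  phi <- if (robust == "multiplicative") max(1, sqrt(Q / (J - 1))) else 1
  se <- sqrt(1 / sum(w * d$g^2)) * phi
  .mk_estimate("IVW", beta, se, J, df = J - 1,
               details = list(Q = Q, phi = phi, robust = robust))
}

# weighted simple linear regression, closed form; x-weights w
.wls <- function(x, y, w) {
  sw <- sum(w); xm <- sum(w * x) / sw; ym <- sum(w * y) / sw
  sxx <- sum(w * (x - xm)^2)
  slope <- sum(w * (x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       var_slope = 1 / sxx,
       var_intercept = 1 / sw + xm^2 / sxx,
       rss = sum(w * res^2))
}

#' MR-Egger regression
#'
#' Weighted regression of the aligned SNP-outcome effects on SNP-exposure
#' effects *with* an intercept, weights `1/se(Gamma)^2`. The slope is the
#' causal estimate (consistent under the InSIDE assumption even with
#' directional pleiotropy); the intercept estimates the average directional
#' pleiotropic effect, and its test is the usual screen for directional
#' pleiotropy. Variants are first put in canonical orientation
#' (SNP-exposure effects non-negative, flipping each (gamma, Gamma) pair
#' jointly). Multiplicative random-effects scaling and `J - 2` t degrees of
#' freedom as in [mrIVW()].
#'
#' @inheritParams mrIVW
#' @return an [MREstimate-class] with method `"Egger"`; `details` carries
#'   `intercept`, `intercept_se`, `intercept_pval`, `Q` and `phi`.
#' @export
mrEgger <- function(data, robust = c("multiplicative", "fixed")) {
  robust <- match.arg(robust)
  d <- .unpack(data)
  J <- length(d$g)
  if (J < 3) stop("insufficient instruments: MR-Egger needs at least 3")
  flip <- sign(d$g); flip[flip == 0] <- 1
  g <- d$g * flip; G <- d$G * flip
  w <- 1 / d$sG^2
  f <- .wls(g, G, w)
  phi <- if (robust == "multiplicative") max(1, sqrt(f$rss / (J - 2))) else 1
  se_slope <- sqrt(f$var_slope) * phi
  se_int <- sqrt(f$var_intercept) * phi
  int_p <- 2 * pt(abs(f$intercept / se_int), J - 2, lower.tail = FALSE)
  .mk_estimate("Egger", f$slope, se_slope, J, df = J - 2,
               details = list(intercept = f$intercept,
                              intercept_se = se_int,
                              intercept_pval = int_p,
                              Q = f$rss, phi = phi, robust = robust))
}

#' I2_GX: regression-dilution diagnostic for MR-Egger
#'
#' Quantifies how much measurement error in the SNP-exposure effects
#' attenuates the MR-Egger slope (violation of the no-measurement-error,
#' NOME, assumption). Computed as `max(0, (Q_GX - (J-1))/Q_GX)` where
#' `Q_GX` is the heterogeneity of the SNP-exposure effects about their
#' inverse-variance-weighted mean. Values near 1 indicate negligible
#' dilution; low values (< 0.9 by convention) call for SIMEX correction.
#'
#' @param gamma_hat SNP-exposure effects, or a [HarmonisedDataset-class].
#' @param sigma_gamma their standard errors (ignored when a dataset is
#'   given).
#' @return a value in `[0, 1]`.
#' @export
i2GX <- function(gamma_hat, sigma_gamma = NULL) {
  if (is(gamma_hat, "HarmonisedDataset")) {
    sigma_gamma <- exposureSE(gamma_hat)
    gamma_hat <- exposureBeta(gamma_hat)
  }
  J <- length(gamma_hat)
  if (J < 2) stop("I2_GX needs at least 2 variants")
  # orientation-invariant: use magnitudes, as Egger does
  g <- abs(gamma_hat)
  w <- 1 / sigma_gamma^2
  gbar <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gbar)^2)
  if (Q <= 0) return(0)
  max(0, min(1, (Q - (J - 1)) / Q))
}

#' Mean F statistic: instrument strength
#'
#' Mean over variants of `(gamma/se(gamma))^2`, the standard indicator of
#' instrument strength; values well above 10 indicate weak-instrument bias
#' is unlikely to be material.
#'
#' @inheritParams i2GX
#' @return a single number.
#' @export
meanF <- function(gamma_hat, sigma_gamma = NULL) {
  if (is(gamma_hat, "HarmonisedDataset")) {
    sigma_gamma <- exposureSE(gamma_hat)
    gamma_hat <- exposureBeta(gamma_hat)
  }
  if (length(gamma_hat) < 1) stop("no variants")
  mean(gamma_hat^2 / sigma_gamma^2)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((Gamma - beta * gamma)^2 / se(Gamma)^2)` about a given causal
#' estimate, referred to a chi-square distribution with `J - 1` degrees of
#' freedom. Large Q indicates the per-variant ratios disagree more than
#' sampling error allows — heterogeneity from pleiotropy or invalid
#' instruments.
#'
#' @param data a [HarmonisedDataset-class].
#' @param beta the causal estimate about which residuals are taken
#'   (default: the IVW estimate).
#' @return list with `Q`, `df`, `pval`.
#' @export
cochranQ <- function(data, beta = NULL) {
  d <- .unpack(data)
  J <- length(d$g)
  if (J < 2) stop("Cochran's Q needs at least 2 variants")
  if (is.null(beta)) beta <- estimate(mrIVW(data))
  Q <- sum((d$G - beta * d$g)^2 / d$sG^2)
  list(Q = Q, df = J - 1, pval = pchisq(Q, J - 1, lower.tail = FALSE))
}

# ---- weighted median -------------------------------------------------

# weighted median of x given positive weights: the point where the
# cumulative standardised weight (less half of each point's own mass)
# crosses one half, linearly interpolated between adjacent order statistics
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(x[1])
  n <- length(x)
  if (cum[n] <= 0.5) return(x[n])
  i <- max(which(cum < 0.5))
  x[i] + (x[i + 1] - x[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

#' Weighted median estimate
#'
#' The inverse-variance weighted median of the per-variant Wald ratios:
#' consistent as long as at least half of the total weight comes from valid
#' instruments, making it robust to a minority of pleiotropic variants.
#' The standard error comes from a parametric bootstrap that redraws
#' (gamma, Gamma) from their reported standard errors.
#'
#' @param data a [HarmonisedDataset-class].
#' @param n_boot bootstrap replicates for the standard error (default
#'   1000). `n_boot = 0` skips the bootstrap (point estimate only,
#'   `se = NA`).
#' @param seed RNG seed for the bootstrap (required when `n_boot > 0`).
#' @return an [MREstimate-class] with method `"Weighted median"`.
#' @export
mrWeightedMedian <- function(data, n_boot = 1000, seed = NULL) {
  d <- .unpack(data)
  J <- length(d$g)
  if (J < 3) stop("insufficient instruments: weighted median needs >= 3")
  ratio <- d$G / d$g
  w <- (d$g / d$sG)^2       # first-order inverse variance of the ratio
  beta <- .weighted_median(ratio, w)
  se <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) stop("bootstrap requires a seed")
    boots <- .with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        gb <- rnorm(J, d$g, d$sg)
        Gb <- rnorm(J, d$G, d$sG)
        ok <- gb != 0
        .weighted_median(Gb[ok] / gb[ok], (gb[ok] / d$sG[ok])^2)
      }, numeric(1))
    })
    se <- sd(boots)
  }
  .mk_estimate("Weighted median", beta, if (is.na(se)) 0 else se, J,
               details = list(n_boot = n_boot)) -> est
  if (is.na(se)) { est@se <- NA_real_; est@ciLow <- est@ciHigh <- NA_real_
    est@pval <- NA_real_ }
  est
}

# ---- weighted mode ---------------------------------------------------

# weighted normal-kernel density over a grid including the data points
.weighted_mode_point <- function(ratio, w, bw) {
  w <- w / sum(w)
  grid <- sort(unique(c(ratio,
                        seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw,
                            length.out = 512))))
  dens <- vapply(grid, function(x) sum(w * dnorm(x, ratio, bw)), numeric(1))
  grid[which.max(dens)]
}

.silverman_bw <- function(x, factor = 1) {
  s <- min(sd(x), mad(x))
  if (s == 0) s <- sd(x)
  if (s == 0) s <- .Machine$double.eps
  factor * 0.9 * s * length(x)^(-1 / 5)   # modified Silverman rule
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance-weighted, normal-kernel-smoothed
#' density of the per-variant Wald ratios: consistent when the largest
#' group of variants sharing the same ratio are valid instruments (the
#' "plurality valid" / zero-modal-pleiotropy assumption). Bandwidth is a
#' modified Silverman rule on the ratios, scaled by `bandwidth_factor`.
#' Standard error by parametric bootstrap, as in [mrWeightedMedian()].
#'
#' @inheritParams mrWeightedMedian
#' @param bandwidth_factor multiplier on the modified Silverman bandwidth
#'   (default 1).
#' @return an [MREstimate-class] with method `"Weighted mode"`.
#' @export
mrWeightedMode <- function(data, bandwidth_factor = 1, n_boot = 1000,
                           seed = NULL) {
  d <- .unpack(data)
  J <- length(d$g)
  if (J < 3) stop("insufficient instruments: weighted mode needs >= 3")
  ratio <- d$G / d$g
  w <- (d$g / d$sG)^2
  bw <- .silverman_bw(ratio, bandwidth_factor)
  beta <- .weighted_mode_point(ratio, w, bw)
  se <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) stop("bootstrap requires a seed")
    boots <- .with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        gb <- rnorm(J, d$g, d$sg)
        Gb <- rnorm(J, d$G, d$sG)
        ok <- gb != 0
        rb <- Gb[ok] / gb[ok]
        .weighted_mode_point(rb, (gb[ok] / d$sG[ok])^2,
                             .silverman_bw(rb, bandwidth_factor))
      }, numeric(1))
    })
    se <- sd(boots)
  }
  est <- .mk_estimate("Weighted mode", beta, if (is.na(se)) 0 else se, J,
                      details = list(bw = bw, n_boot = n_boot))
  if (is.na(se)) { est@se <- NA_real_; est@ciLow <- est@ciHigh <- NA_real_
    est@pval <- NA_real_ }
  est
}

# ---- RAPS ------------------------------------------------------------

#' Robust adjusted profile score (RAPS) estimate
#'
#' Profiles out the true SNP-exposure effects and estimates the causal
#' effect from the standardised residuals
#' `t_j(beta) = (Gamma_j - beta * gamma_j) / sqrt(se(Gamma_j)^2 +
#' beta^2 se(gamma_j)^2)`, which properly accounts for measurement error in
#' the SNP-exposure effects (no NOME assumption, no weak-instrument
#' attenuation). The simple loss minimises `sum(t_j^2)`; the Huber loss
#' (tuning constant 1.345) downweights outlying residuals. With
#' `overdispersion = TRUE` a systematic-pleiotropy variance component
#' `tau2` is estimated jointly by matching `sum(psi(t) t)` to its standard
#' normal expectation. Standard errors come from the M-estimation sandwich.
#'
#' @param data a [HarmonisedDataset-class].
#' @param overdispersion estimate a pleiotropy variance component.
#' @param loss `"simple"` or `"huber"`.
#' @param tuning Huber tuning constant (default 1.345).
#' @return an [MREstimate-class] with method `"RAPS"`; `details` carries
#'   `tau2` and the optimiser trace.
#' @export
mrRAPS <- function(data, overdispersion = FALSE,
                   loss = c("simple", "huber"), tuning = 1.345) {
  loss <- match.arg(loss)
  d <- .unpack(data)
  J <- length(d$g)
  if (J < 3) stop("insufficient instruments: RAPS needs >= 3")

  rho <- switch(loss,
    simple = function(t) t^2 / 2,
    huber = function(t) ifelse(abs(t) <= tuning, t^2 / 2,
                               tuning * abs(t) - tuning^2 / 2))
  psi <- switch(loss,
    simple = function(t) t,
    huber = function(t) pmax(-tuning, pmin(tuning, t)))
  # E[psi(t) t] under t ~ N(0,1): 1 for the simple loss, delta < 1 for Huber
  delta <- if (loss == "simple") 1 else {
    2 * (pnorm(tuning) - 0.5) - 2 * tuning * dnorm(tuning) +
      2 * tuning^2 * pnorm(-tuning)
    # = E[t^2; |t|<c] + c E[|t|; |t|>=c]
  }

  tres <- function(beta, tau2)
    (d$G - beta * d$g) / sqrt(d$sG^2 + beta^2 * d$sg^2 + tau2)
  obj <- function(beta, tau2) sum(rho(tres(beta, tau2)))

  ratios <- d$G / d$g
  span <- range(ratios[is.finite(ratios)])
  pad <- max(1, diff(span))
  lo <- span[1] - pad; hi <- span[2] + pad

  # the profile loss need not be unimodal over a wide interval (a
  # near-zero gamma-hat throws a ratio far out), so bracket the global
  # minimum on a coarse grid before refining
  argmin <- function(tau2) {
    grid <- seq(lo, hi, length.out = 257)
    vals <- vapply(grid, obj, numeric(1), tau2 = tau2)
    i <- which.min(vals)
    optimize(obj, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
             tau2 = tau2, tol = 1e-12)$minimum
  }

  trace <- character()
  tau2 <- 0
  beta <- argmin(0)
  if (overdispersion) {
    for (it in seq_len(100)) {
      gfun <- function(t2) sum(psi(tres(beta, t2)) * tres(beta, t2)) -
        J * delta
      tau2_new <- if (gfun(0) <= 0) 0 else {
        upper <- max(d$sG^2) * 100 + 1
        if (gfun(upper) > 0) upper else uniroot(gfun, c(0, upper),
                                                tol = 1e-14)$root
      }
      beta_new <- argmin(tau2_new)
      trace <- c(trace, sprintf("iter %d: beta = %.8g tau2 = %.3g", it,
                                beta_new, tau2_new))
      if (abs(beta_new - beta) < 1e-10 &&
          abs(tau2_new - tau2) < 1e-12 * (1 + tau2)) {
        beta <- beta_new; tau2 <- tau2_new; break
      }
      beta <- beta_new; tau2 <- tau2_new
      if (it == 100)
        stop(paste(c("RAPS did not converge; trace:", tail(trace, 5)),
                   collapse = "\n"))
    }
  }
  if (abs(beta - lo) < 1e-8 || abs(beta - hi) < 1e-8)
    stop(paste("RAPS did not converge: solution at search boundary;",
               sprintf("beta = %g in [%g, %g]", beta, lo, hi)))

  # sandwich variance for the beta estimating equation at (beta, tau2)
  score <- function(b) sum(psi(tres(b, tau2)) * .dt_dbeta(b, tau2, d))
  eps <- 1e-6 * (1 + abs(beta))
  A <- (score(beta + eps) - score(beta - eps)) / (2 * eps)
  u <- psi(tres(beta, tau2)) * .dt_dbeta(beta, tau2, d)
  B <- sum(u^2)
  se <- sqrt(B / A^2)
  .mk_estimate("RAPS", beta, se, J,
               details = list(tau2 = tau2, loss = loss,
                              overdispersion = overdispersion,
                              trace = trace))
}

.dt_dbeta <- function(beta, tau2, d) {
  v <- d$sG^2 + beta^2 * d$sg^2 + tau2
  (-d$g * v - (d$G - beta * d$g) * beta * d$sg^2) / v^1.5
}

# ---- SIMEX-corrected Egger -------------------------------------------

#' SIMEX measurement-error correction for MR-Egger
#'
#' Simulation-extrapolation on the *unweighted* Egger regression, the
#' standard remedy when I2_GX indicates material regression dilution. For
#' each lambda in `lambda_grid` the SNP-exposure effects are perturbed with
#' additional noise of variance `lambda * se(gamma)^2`, the unweighted
#' Egger slope is averaged over `n_boot` replicates, and a quadratic in
#' lambda is extrapolated back to lambda = -1 (zero measurement error).
#' The standard error extrapolates the replicate-mean squared standard
#' errors the same way.
#'
#' @param data a [HarmonisedDataset-class].
#' @param lambda_grid noise-inflation grid (default `seq(0, 2, 0.25)`).
#' @param n_boot replicates per lambda (default 1000).
#' @param seed RNG seed (required).
#' @return an [MREstimate-class] with method `"Egger-SIMEX"`; `details`
#'   carries the per-lambda mean slopes, the naive (lambda = 0) estimate
#'   and, if the extrapolation was degenerate, `degenerate = TRUE` (the
#'   uncorrected estimate is then returned with a warning).
#' @export
mrSIMEXEgger <- function(data, lambda_grid = seq(0, 2, by = 0.25),
                         n_boot = 1000, seed = NULL) {
  d <- .unpack(data)
  J <- length(d$g)
  if (J < 3) stop("insufficient instruments: MR-Egger needs at least 3")
  if (is.null(seed)) stop("SIMEX requires a seed")
  if (n_boot < 1) stop("SIMEX needs at least one replicate per lambda")
  flip <- sign(d$g); flip[flip == 0] <- 1
  g <- d$g * flip; G <- d$G * flip; sg <- d$sg
  short_grid <- length(unique(lambda_grid)) < 3

  # unweighted OLS slope/intercept, vectorised over replicate columns
  ols_cols <- function(X, y) {
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2, xm)
    sxx <- colSums(Xc^2)
    slope <- colSums(Xc * y) / sxx
    res2 <- colSums((matrix(y, nrow(X), ncol(X)) -
                       sweep(Xc, 2, slope, `*`) -
                       matrix(ym, nrow(X), ncol(X)))^2)
    s2 <- res2 / (nrow(X) - 2)
    list(slope = slope, var_slope = s2 / sxx)
  }

  res <- .with_seed(seed, {
    lapply(lambda_grid, function(lam) {
      if (lam == 0) {
        f <- ols_cols(matrix(g, ncol = 1), G)
        list(slope = f$slope, var = f$var_slope)
      } else {
        E <- matrix(rnorm(J * n_boot), J, n_boot)
        X <- g + sqrt(lam) * sg * E
        f <- ols_cols(X, G)
        list(slope = mean(f$slope), var = mean(f$var_slope))
      }
    })
  })
  s_lam <- vapply(res, `[[`, numeric(1), "slope")
  v_lam <- vapply(res, `[[`, numeric(1), "var")
  naive <- s_lam[which(lambda_grid == 0)[1]]
  if (length(naive) == 0) naive <- s_lam[1]

  if (short_grid) {
    # fewer than 3 noise levels cannot support the quadratic extrapolant:
    # report the estimate at the observed noise level
    f <- ols_cols(matrix(g, ncol = 1), G)
    return(.mk_estimate("Egger-SIMEX", f$slope, sqrt(f$var_slope), J,
                        df = J - 2,
                        details = list(degenerate = FALSE,
                                       extrapolated = FALSE,
                                       naive = f$slope,
                                       lambda = lambda_grid,
                                       slopes = s_lam)))
  }

  quad_extrap <- function(y) {
    if (length(unique(lambda_grid)) < 3) return(NA_real_)
    co <- tryCatch(coef(stats::lm(y ~ lambda_grid + I(lambda_grid^2))),
                   error = function(e) rep(NA_real_, 3))
    if (anyNA(co)) return(NA_real_)
    unname(co[1] - co[2] + co[3])    # evaluated at lambda = -1
  }
  beta <- quad_extrap(s_lam)
  v <- quad_extrap(v_lam)
  if (!is.finite(beta) || !is.finite(v) || v <= 0) {
    warning("degenerate SIMEX extrapolation; returning uncorrected ",
            "unweighted Egger estimate")
    f <- ols_cols(matrix(g, ncol = 1), G)
    return(.mk_estimate("Egger-SIMEX", f$slope, sqrt(f$var_slope), J,
                        df = J - 2,
                        details = list(degenerate = TRUE, naive = naive,
                                       lambda = lambda_grid,
                                       slopes = s_lam)))
  }
  .mk_estimate("Egger-SIMEX", beta, sqrt(v), J, df = J - 2,
               details = list(degenerate = FALSE, naive = naive,
                              lambda = lambda_grid, slopes = s_lam))
}

# ---- Steiger ---------------------------------------------------------

#' Steiger directionality filtering
#'
#' For each variant, compares the variance it explains in the exposure,
#' `r2_X = 2 gamma^2 eaf (1 - eaf)` (standardised-trait approximation; for
#' binary traits this is the liability-linear approximation on the log-odds
#' scale), with the analogous `r2_Y` in the outcome. A variant supports the
#' exposure-to-outcome direction when `r2_X > r2_Y`. Exact ties are flagged
#' indeterminate and retained. The overall call combines the per-variant
#' majority with a z-test comparing the two multi-variant correlations
#' (Fisher transformed, using the study sample sizes).
#'
#' @param data a [HarmonisedDataset-class]; variants with missing exposure
#'   allele frequency are excluded from filtering (retained, flagged `NA`).
#' @param exposure_n,outcome_n study sample sizes.
#' @return list with `flags` (per-variant data.frame: `snp`, `r2_exposure`,
#'   `r2_outcome`, `correct_direction`, `indeterminate`), `filtered` (a
#'   [HarmonisedDataset-class] keeping correct-direction plus indeterminate
#'   and unassessable variants; wrong-direction variants move to the drop
#'   log), and `overall` (`direction`, `z`, `pval`, `share_correct`).
#' @export
steigerFilter <- function(data, exposure_n, outcome_n) {
  s <- harmonisedTable(data)
  eaf <- ifelse(is.na(s$eaf_exposure), s$eaf_outcome, s$eaf_exposure)
  r2x <- 2 * s$gamma_hat^2 * eaf * (1 - eaf)
  r2y <- 2 * s$Gamma_hat^2 * eaf * (1 - eaf)
  correct <- ifelse(is.na(eaf), NA, r2x > r2y)
  indet <- !is.na(eaf) & r2x == r2y
  n_na <- sum(is.na(eaf))
  if (n_na > 0)
    message(n_na, " variant(s) excluded from Steiger filtering: ",
            "missing allele frequency")

  flags <- data.frame(snp = s$snp, r2_exposure = r2x, r2_outcome = r2y,
                      correct_direction = correct, indeterminate = indet,
                      stringsAsFactors = FALSE)
  keep <- is.na(correct) | correct | indet
  dropped <- data.frame(snp = s$snp[!keep],
                        reason = rep("steiger_wrong_direction", sum(!keep)),
                        stringsAsFactors = FALSE)
  filtered <- new("HarmonisedDataset",
                  snps = s[keep, , drop = FALSE],
                  drops = rbind(droppedSnps(data), dropped),
                  meta = c(data@meta, list(steiger = TRUE)))

  ok <- !is.na(eaf)
  rx <- sqrt(min(0.999, sum(r2x[ok])))
  ry <- sqrt(min(0.999, sum(r2y[ok])))
  z <- (atanh(rx) - atanh(ry)) /
    sqrt(1 / (exposure_n - 3) + 1 / (outcome_n - 3))
  overall <- list(
    direction = if (mean(correct[ok] | indet[ok]) >= 0.5 && z > 0)
      "exposure->outcome" else if (z < 0 && mean(!correct[ok], na.rm = TRUE)
                                   > 0.5) "outcome->exposure" else
        "indeterminate",
    z = z, pval = 2 * pnorm(abs(z), lower.tail = FALSE),
    share_correct = mean(correct[ok] | indet[ok]))
  list(flags = flags, filtered = filtered, overall = overall)
}

# ---- battery ---------------------------------------------------------

#' Default settings for [runMR()]
#'
#' @param i2_trigger when I2_GX falls below this, the Egger estimate is
#'   SIMEX-corrected (default 0.9).
#' @param n_boot bootstrap replicates for median/mode standard errors and
#'   SIMEX (default 1000).
#' @param seed RNG seed for all stochastic components (mandatory).
#' @param bandwidth_factor weighted-mode bandwidth multiplier.
#' @param lambda_grid SIMEX noise grid.
#' @param robust `"multiplicative"` or `"fixed"` heterogeneity model.
#' @param raps_overdispersion,raps_loss RAPS settings.
#' @param second_order_wald second-order delta SE for single-variant input.
#' @param exclude_snps variants to remove before analysis (sensitivity
#'   analyses, e.g. excluding a gene region's variants by id).
#' @return a list of settings.
#' @export
mrConfig <- function(i2_trigger = 0.9, n_boot = 1000, seed = 1,
                     bandwidth_factor = 1,
                     lambda_grid = seq(0, 2, by = 0.25),
                     robust = "multiplicative",
                     raps_overdispersion = FALSE, raps_loss = "simple",
                     second_order_wald = FALSE, exclude_snps = NULL) {
  stopifnot(i2_trigger >= 0, i2_trigger <= 1, n_boot >= 0)
  if (is.null(seed)) stop("seed is mandatory")
  list(i2_trigger = i2_trigger, n_boot = n_boot, seed = seed,
       bandwidth_factor = bandwidth_factor, lambda_grid = lambda_grid,
       robust = robust, raps_overdispersion = raps_overdispersion,
       raps_loss = raps_loss, second_order_wald = second_order_wald,
       exclude_snps = exclude_snps)
}

#' Run the full estimator battery with diagnostics
#'
#' Applies the five estimators (IVW as the main analysis; Egger, weighted
#' median, weighted mode and RAPS as sensitivity analyses) plus
#' diagnostics to a harmonised dataset. When I2_GX falls below
#' `config$i2_trigger` the Egger row is supplemented with a SIMEX-corrected
#' row. A single-variant dataset yields only the Wald ratio. A method that
#' errors contributes an annotation row instead of aborting the rest.
#' Binary outcomes are additionally reported as odds ratios with
#' `exp(beta +/- 1.96 se)` intervals.
#'
#' @param data a [HarmonisedDataset-class].
#' @param outcome_type `"binary"` (effects are log odds ratios) or
#'   `"continuous"`.
#' @param config settings from [mrConfig()].
#' @return list of class `"mr_result"`: `estimates` (one row per method:
#'   `method`, `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, plus
#'   `or`, `or_ci_low`, `or_ci_high` for binary outcomes, and `note` for
#'   failed methods), `diagnostics` (Cochran's Q, Egger intercept, I2_GX,
#'   mean F), and `objects` (the underlying [MREstimate-class] objects).
#' @export
runMR <- function(data, outcome_type = c("binary", "continuous"),
                  config = mrConfig()) {
  outcome_type <- match.arg(outcome_type)
  if (!is.null(config$exclude_snps)) {
    s <- harmonisedTable(data)
    drop_idx <- s$snp %in% config$exclude_snps
    data <- new("HarmonisedDataset",
                snps = s[!drop_idx, , drop = FALSE],
                drops = rbind(droppedSnps(data),
                              data.frame(snp = s$snp[drop_idx],
                                         reason = "excluded_by_config")),
                meta = data@meta)
  }
  J <- nSnp(data)
  if (J == 0) stop("no variants to analyse")

  ests <- list(); notes <- list()
  add <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (is.character(r)) notes[[name]] <<- r else ests[[name]] <<- r
  }

  if (J == 1) {
    d <- .unpack(data)
    add("Wald", waldRatio(d$g, d$sg, d$G, d$sG,
                          second_order = config$second_order_wald))
    diagnostics <- list(mean_f = meanF(data))
  } else {
    add("IVW", mrIVW(data, robust = config$robust))
    egger <- tryCatch(mrEgger(data, robust = config$robust),
                      error = function(e) conditionMessage(e))
    i2 <- tryCatch(i2GX(data), error = function(e) NA_real_)
    if (is.character(egger)) notes[["Egger"]] <- egger else {
      ests[["Egger"]] <- egger
      if (is.finite(i2) && i2 < config$i2_trigger && config$n_boot > 0)
        add("Egger-SIMEX",
            mrSIMEXEgger(data, lambda_grid = config$lambda_grid,
                         n_boot = config$n_boot, seed = config$seed))
    }
    add("Weighted median",
        mrWeightedMedian(data, n_boot = config$n_boot, seed = config$seed))
    add("Weighted mode",
        mrWeightedMode(data, bandwidth_factor = config$bandwidth_factor,
                       n_boot = config$n_boot, seed = config$seed))
    add("RAPS", mrRAPS(data, overdispersion = config$raps_overdispersion,
                       loss = config$raps_loss))

    ivw_beta <- if (!is.null(ests$IVW)) estimate(ests$IVW) else NULL
    diagnostics <- list(
      cochran_q = tryCatch(cochranQ(data, ivw_beta),
                           error = function(e) NULL),
      egger_intercept = if (!is.null(ests$Egger))
        ests$Egger@details[c("intercept", "intercept_se",
                             "intercept_pval")],
      i2_gx = i2,
      mean_f = meanF(data))
  }

  rows <- lapply(names(ests), function(nm) {
    e <- ests[[nm]]
    r <- data.frame(method = mrMethod(e), n_snp = nSnp(e),
                    beta = estimate(e), se = stdError(e),
                    ci_low = e@ciLow, ci_high = e@ciHigh,
                    pval = pValue(e), note = "", stringsAsFactors = FALSE)
    if (outcome_type == "binary") {
      or <- asOddsRatio(e)
      r$or <- or[["or"]]; r$or_ci_low <- or[["ci_low"]]
      r$or_ci_high <- or[["ci_high"]]
    }
    r
  })
  for (nm in names(notes)) {
    r <- data.frame(method = nm, n_snp = J, beta = NA_real_, se = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                    note = notes[[nm]], stringsAsFactors = FALSE)
    if (outcome_type == "binary")
      r$or <- r$or_ci_low <- r$or_ci_high <- NA_real_
    rows <- c(rows, list(r))
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, diagnostics = diagnostics,
                 objects = ests, outcome_type = outcome_type,
                 dataset = data),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat("Two-sample MR results (", x$outcome_type, " outcome, ",
      nSnp(x$dataset), " variants)\n", sep = "")
  est <- x$estimates
  num <- vapply(est, is.numeric, logical(1))
  est[num] <- lapply(est[num], signif, digits = 3)
  print(est, row.names = FALSE)
  dg <- x$diagnostics
  if (!is.null(dg$cochran_q))
    cat(sprintf("Cochran Q = %.3g (df %d, p = %.3g)\n", dg$cochran_q$Q,
                dg$cochran_q$df, dg$cochran_q$pval))
  if (!is.null(dg$i2_gx) && is.finite(dg$i2_gx))
    cat(sprintf("I2_GX = %.3f   mean F = %.1f\n", dg$i2_gx, dg$mean_f))
  invisible(x)
}
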