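# Seeded generators for synthetic GWAS summary statistics and smoking
# cohorts with known ground truth.

#' Configuration for the summary-statistic generator
#'
#' Defines the generative model behind [simulateSummaryStats()]. Each
#' variant j gets a true SNP-exposure effect `gamma_j` (half-normal with
#' scale `gamma_scale`, i.e. instruments oriented to the exposure-increasing
#' allele), a direct pleiotropic effect `alpha_j` on the outcome, and a true
#' SNP-outcome effect `Gamma_j = theta * gamma_j + alpha_j`. Estimates are
#' drawn with the standard GWAS sampling approximation
#' `se = 1/sqrt(2 n eaf (1-eaf))` on the standardised scale, so the default
#' exposure sample size (462,690) and effect scale give a mean F statistic
#' around 40 — a well-powered but realistically noisy instrument.
#'
#' Pleiotropy regimes: `"none"` (`alpha = 0`), `"balanced"`
#' (`alpha ~ N(0, alpha_sd)`, InSIDE holds), `"directional"`
#' (`alpha ~ N(alpha_mean, alpha_sd)` for a fraction `pleiotropy_frac` of
#' variants, InSIDE holds), `"inside_violating"` (directional with
#' correlation `inside_rho` between `gamma` and `alpha`).
#'
#' @param n_snp number of instruments (>= 1).
#' @param theta true causal effect of exposure on outcome.
#' @param pleiotropy regime, see above.
#' @param alpha_mean,alpha_sd mean and sd of the direct effects (used per
#'   regime).
#' @param pleiotropy_frac fraction of variants carrying direct effects
#'   (regimes other than `"none"`).
#' @param inside_rho correlation between `gamma` and `alpha` under
#'   `"inside_violating"`.
#' @param gamma_scale spread of the true exposure effects:
#'   `gamma = |N(gamma_mean, gamma_scale)|`.
#' @param gamma_mean location of the effect-size distribution. The default
#'   0 gives a half-normal (a full spectrum of effect sizes down to zero);
#'   a value several times `gamma_scale` emulates a clumped genome-wide
#'   significant instrument — effects bounded away from zero but tightly
#'   clustered, the regime in which the Egger regression-dilution
#'   diagnostic I2_GX is low.
#' @param eaf_range uniform range of effect-allele frequencies.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param palindromic_frac fraction of variants given A/T or C/G alleles.
#' @param swap_frac fraction of outcome records with swapped allele labels
#'   (effect reported for the other allele).
#' @param strand_flip_frac fraction of outcome records reported on the
#'   opposite strand (complemented allele labels).
#' @param seed RNG seed (mandatory).
#' @return validated config list of class `"sim_config"`.
#' @export
simulationConfig <- function(n_snp = 100, theta = 0,
                             pleiotropy = c("none", "balanced",
                                            "directional",
                                            "inside_violating"),
                             alpha_mean = 1e-3, alpha_sd = 1e-3,
                             pleiotropy_frac = 1, inside_rho = 0.5,
                             gamma_scale = 0.0146, gamma_mean = 0,
                             eaf_range = c(0.1, 0.9),
                             n_exposure = 462690, n_outcome = 150064,
                             palindromic_frac = 0.15, swap_frac = 0.3,
                             strand_flip_frac = 0.05, seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  if (is.null(seed)) stop("seed is mandatory")
  if (n_snp < 1) stop("n_snp must be >= 1")
  if (any(eaf_range <= 0) || any(eaf_range >= 1) || diff(eaf_range) < 0)
    stop("eaf_range must lie strictly inside (0, 1)")
  for (f in c(pleiotropy_frac, palindromic_frac, swap_frac,
              strand_flip_frac))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]")
  structure(list(n_snp = as.integer(n_snp), theta = theta,
                 pleiotropy = pleiotropy, alpha_mean = alpha_mean,
                 alpha_sd = alpha_sd, pleiotropy_frac = pleiotropy_frac,
                 inside_rho = inside_rho, gamma_scale = gamma_scale,
                 gamma_mean = gamma_mean,
                 eaf_range = eaf_range, n_exposure = n_exposure,
                 n_outcome = n_outcome,
                 palindromic_frac = palindromic_frac,
                 swap_frac = swap_frac,
                 strand_flip_frac = strand_flip_frac, seed = seed),
            class = "sim_config")
}

.ALLELE_PAIRS <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))

#' Simulate a two-sample MR dataset with known ground truth
#'
#' Draws true per-variant effects under the configured pleiotropy regime
#' and emits exposure and outcome summary-statistic tables shaped exactly
#' like [readSummaryStats()] output (so they round-trip through
#' [writeSummaryStats()]/[readSummaryStats()] losslessly), plus a truth
#' table holding every latent quantity. Configurable fractions of outcome
#' records have swapped allele labels or strand-complemented labels — and a
#' fraction of variants are palindromic — so harmonisation is genuinely
#' exercised. Identical config and seed give byte-identical output.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `exposure`, `outcome` (summary-stat data.frames),
#'   `truth` (per-variant: `snp`, `gamma`, `alpha`, `Gamma`, flags
#'   `palindromic`, `swapped`, `strand_flipped`) and `config`.
#' @export
simulateSummaryStats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    J <- cfg$n_snp
    eaf <- runif(J, cfg$eaf_range[1], cfg$eaf_range[2])
    gamma <- abs(rnorm(J, cfg$gamma_mean, cfg$gamma_scale))

    carrier <- rep(FALSE, J)
    alpha <- numeric(J)
    if (cfg$pleiotropy != "none") {
      carrier <- runif(J) < cfg$pleiotropy_frac
      z <- rnorm(J)
      if (cfg$pleiotropy == "inside_violating") {
        gs <- as.numeric(scale(gamma))
        z <- cfg$inside_rho * gs + sqrt(1 - cfg$inside_rho^2) * z
      }
      mu <- if (cfg$pleiotropy == "balanced") 0 else cfg$alpha_mean
      alpha <- ifelse(carrier, mu + cfg$alpha_sd * z, 0)
    }
    Gamma <- cfg$theta * gamma + alpha

    se_x <- 1 / sqrt(2 * cfg$n_exposure * eaf * (1 - eaf))
    se_y <- 1 / sqrt(2 * cfg$n_outcome * eaf * (1 - eaf))
    gamma_hat <- rnorm(J, gamma, se_x)
    Gamma_hat <- rnorm(J, Gamma, se_y)

    palin <- runif(J) < cfg$palindromic_frac
    pair <- lapply(seq_len(J), function(j) {
      if (palin[j]) {
        p <- if (runif(1) < 0.5) c("A", "T") else c("C", "G")
      } else p <- .ALLELE_PAIRS[[sample.int(4, 1)]]
      if (runif(1) < 0.5) p else rev(p)
    })
    ea <- vapply(pair, `[`, character(1), 1)
    oa <- vapply(pair, `[`, character(1), 2)

    mk_pval <- function(b, se) pmax(2 * pnorm(-abs(b) / se), 1e-300)
    chrom <- as.character(rep_len(1:22, J))
    pos <- 1e6 + 2e7 * (seq_len(J) - 1) %/% 22 + 13 * seq_len(J)

    exposure <- data.frame(snp = sprintf("rs%04d", seq_len(J)),
                           chrom = chrom, pos = pos, ea = ea, oa = oa,
                           eaf = eaf, beta = gamma_hat, se = se_x,
                           pval = mk_pval(gamma_hat, se_x),
                           n = cfg$n_exposure, stringsAsFactors = FALSE)

    # outcome study, allele-aligned first, then label noise
    o_ea <- ea; o_oa <- oa; o_beta <- Gamma_hat; o_eaf <- eaf
    swapped <- runif(J) < cfg$swap_frac
    o_ea[swapped] <- oa[swapped]; o_oa[swapped] <- ea[swapped]
    o_beta[swapped] <- -o_beta[swapped]
    o_eaf[swapped] <- 1 - o_eaf[swapped]
    flipped <- runif(J) < cfg$strand_flip_frac
    # palindromic + opposite strand is indistinguishable from a label swap
    pf <- flipped & palin
    o_beta[pf] <- -o_beta[pf]; o_eaf[pf] <- 1 - o_eaf[pf]
    nf <- flipped & !palin
    o_ea[nf] <- unname(.COMPLEMENT[o_ea[nf]])
    o_oa[nf] <- unname(.COMPLEMENT[o_oa[nf]])

    outcome <- data.frame(snp = exposure$snp, chrom = chrom, pos = pos,
                          ea = o_ea, oa = o_oa, eaf = o_eaf,
                          beta = o_beta, se = se_y,
                          pval = mk_pval(o_beta, se_y),
                          n = cfg$n_outcome, stringsAsFactors = FALSE)

    truth <- data.frame(snp = exposure$snp, gamma = gamma, alpha = alpha,
                        Gamma = Gamma, eaf = eaf, palindromic = palin,
                        swapped = swapped, strand_flipped = flipped,
                        stringsAsFactors = FALSE)
    attr(truth, "theta") <- cfg$theta
    list(exposure = exposure, outcome = outcome, truth = truth,
         config = cfg)
  })
}

#' Assemble the truth-aligned harmonised dataset of a simulation
#'
#' Bypasses allele bookkeeping and pairs the simulated estimates with their
#' true orientation — the reference dataset for estimator validation (the
#' alternative route, `harmoniseData(sim$exposure, sim$outcome)`, must
#' agree on every variant it retains).
#'
#' @param sim output of [simulateSummaryStats()].
#' @return a [HarmonisedDataset-class] with all variants.
#' @export
truthDataset <- function(sim) {
  e <- sim$exposure
  # undo the label noise using the recorded truth flags (a palindromic
  # strand flip manifests as one more sign change, possibly on top of a
  # label swap)
  sign_fix <- ifelse(xor(sim$truth$swapped,
                         sim$truth$strand_flipped & sim$truth$palindromic),
                     -1, 1)
  harmonisedDataset(gamma_hat = e$beta, gamma_se = e$se,
                    Gamma_hat = sim$outcome$beta * sign_fix,
                    Gamma_se = sim$outcome$se,
                    snp = e$snp, ea = e$ea, oa = e$oa,
                    eaf_exposure = e$eaf, eaf_outcome = e$eaf)
}

#' Configuration for the cohort generator
#'
#' Defines the generative model behind [simulateCohort()]: smoking status
#' drawn with the UK-Biobank-like mix (default 53.9% never / 35.6% former /
#' 10.5% current, the exact proportions behind the rounded 54/36/11 split),
#' assessment ages normal around 56.7 (sd 8) clamped to 40-69, initiation
#' ages around 17 (sd 3), log-normal cigarettes-per-day clamped to the
#' plausibility window 1-150, and a binary outcome drawn from a logistic
#' model on the true lifetime smoking index at `tau_true`. The default
#' outcome model (intercept -2.2, slope 1) is all-cause-mortality-like:
#' about 10% baseline risk and an odds ratio near 2 per index standard
#' deviation.
#'
#' @param n number of participants.
#' @param status_mix probabilities for never/former/current (re-normalised
#'   if they do not sum exactly to 1).
#' @param cpd_meanlog,cpd_sdlog log-normal parameters for cigarettes/day.
#' @param age_assess_mean,age_assess_sd,age_assess_range assessment age.
#' @param age_init_mean,age_init_sd initiation age (clamped to 10 and one
#'   year before assessment).
#' @param tau_true half-life used to generate the outcome (years).
#' @param outcome_model list with `intercept` and `slope` (logit scale, per
#'   index unit).
#' @param seed RNG seed (mandatory).
#' @return validated config list of class `"cohort_config"`.
#' @export
cohortConfig <- function(n = 20000,
                         status_mix = c(never = 249318, former = 164649,
                                        current = 48723) / 462690,
                         cpd_meanlog = log(15), cpd_sdlog = 0.45,
                         age_assess_mean = 56.7, age_assess_sd = 8,
                         age_assess_range = c(40, 69),
                         age_init_mean = 17, age_init_sd = 3,
                         tau_true = 18,
                         outcome_model = list(intercept = -2.2, slope = 1),
                         seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  if (length(status_mix) != 3 || any(status_mix < 0))
    stop("status_mix must be 3 non-negative proportions")
  if (abs(sum(status_mix) - 1) > 0.02)
    stop("status_mix proportions must sum to ~1")
  status_mix <- status_mix / sum(status_mix)
  if (tau_true <= 0) stop("tau_true must be positive")
  structure(list(n = as.integer(n), status_mix = status_mix,
                 cpd_meanlog = cpd_meanlog, cpd_sdlog = cpd_sdlog,
                 age_assess_mean = age_assess_mean,
                 age_assess_sd = age_assess_sd,
                 age_assess_range = age_assess_range,
                 age_init_mean = age_init_mean,
                 age_init_sd = age_init_sd,
                 tau_true = tau_true, outcome_model = outcome_model,
                 seed = seed),
            class = "cohort_config")
}

#' Simulate a smoking-history cohort with a linked binary outcome
#'
#' Per participant: smoking status, cigarettes per day within the 1-150
#' plausibility window for ever smokers, coherent initiation/cessation/
#' assessment ages (never smokers have all smoking fields missing; current
#' smokers have no cessation age), and a binary outcome drawn from the
#' configured logistic model on the participant's true lifetime smoking
#' index at `tau_true`. Identical config and seed give byte-identical
#' output.
#'
#' @param cfg a [cohortConfig()].
#' @return list with `histories` (columns `id`, `status`, `cpd`,
#'   `age_init`, `age_cess`, `age_assess`), `outcome` (columns `id`,
#'   `outcome`), and `truth` (the config parameters, the per-participant
#'   true index, and the realised outcome prevalence).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n
    status <- sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = cfg$status_mix)
    ever <- status != "never"

    age_assess <- round(pmin(pmax(rnorm(n, cfg$age_assess_mean,
                                        cfg$age_assess_sd),
                                  cfg$age_assess_range[1]),
                             cfg$age_assess_range[2]))
    age_init <- rep(NA_real_, n)
    age_init[ever] <- round(pmin(pmax(rnorm(sum(ever), cfg$age_init_mean,
                                            cfg$age_init_sd), 10),
                                 age_assess[ever] - 1))
    age_cess <- rep(NA_real_, n)
    former <- status == "former"
    age_cess[former] <- floor(runif(sum(former), age_init[former],
                                    age_assess[former] + 1))
    age_cess[former] <- pmin(age_cess[former], age_assess[former])

    cpd <- rep(NA_real_, n)
    cpd[ever] <- pmin(pmax(round(exp(rnorm(sum(ever), cfg$cpd_meanlog,
                                           cfg$cpd_sdlog))), 1), 150)

    histories <- data.frame(id = sprintf("id%06d", seq_len(n)),
                            status = status, cpd = cpd,
                            age_init = age_init, age_cess = age_cess,
                            age_assess = age_assess,
                            stringsAsFactors = FALSE)
    index <- smokingIndex(histories, tau = cfg$tau_true)
    p <- plogis(cfg$outcome_model$intercept +
                  cfg$outcome_model$slope * index)
    y <- rbinom(n, 1, p)
    list(histories = histories,
         outcome = data.frame(id = histories$id, outcome = y,
                              stringsAsFactors = FALSE),
         truth = list(tau_true = cfg$tau_true,
                      outcome_model = cfg$outcome_model,
                      index = index, prevalence = mean(y),
                      config = cfg))
  })
}

#' Read and write cohort smoking-history tables
#'
#' The cohort TSV layout has columns `id`, `status`, `cpd`, `age_init`,
#' `age_cess`, `age_assess`, with missing values as empty fields.
#'
#' @param path file path.
#' @return `readCohort()`: the validated data.frame; `writeCohort()`:
#'   `path` invisibly.
#' @export
readCohort <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  need <- c("id", "status", "cpd", "age_init", "age_cess", "age_assess")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("cohort file lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$status), c("never", "former", "current"))
  if (length(bad) > 0)
    stop("unknown smoking status in cohort file: ",
         paste(bad, collapse = ", "))
  x
}

#' @rdname readCohort
#' @param x cohort data.frame.
#' @export
writeCohort <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
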