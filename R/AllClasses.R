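# S4 containers for the MR workflow. Columns use the two-sample MR
# convention: gamma (SNP-exposure) and Gamma (SNP-outcome) effects.

.HARM_COLS <- c("snp", "ea", "oa", "gamma_hat", "gamma_se",
                "Gamma_hat", "Gamma_se", "eaf_exposure", "eaf_outcome",
                "palindromic", "flipped", "proxied")

#' InstrumentSet: genome-wide significant, mutually independent variants
#'
#' Holds the variants retained by [selectInstruments()] together with a
#' provenance log describing every filtering decision (significance
#' threshold, clumping distance and LD rule, and whether LD information was
#' available or distance-only pruning was applied).
#'
#' @slot records data.frame of retained summary-statistic records (columns
#'   as returned by [readSummaryStats()]).
#' @slot log character vector, one entry per filtering event.
#' @seealso [selectInstruments()] and the accessors `instrumentRecords()`,
#'   `provenanceLog()`
#' @exportClass InstrumentSet
setClass("InstrumentSet",
         representation(records = "data.frame", log = "character"))

setValidity("InstrumentSet", function(object) {
  need <- c("snp", "pval")
  miss <- setdiff(need, names(object@records))
  if (length(miss) > 0 && nrow(object@records) > 0)
    return(paste("records lack columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@records$snp))
    return("duplicated SNP identifiers in an instrument set")
  TRUE
})

#' HarmonisedDataset: allele-aligned exposure/outcome effect pairs
#'
#' The central analysis container: one row per retained variant with the
#' SNP-exposure estimate (`gamma_hat`, `gamma_se`), the SNP-outcome estimate
#' aligned to the same effect allele (`Gamma_hat`, `Gamma_se`), effect-allele
#' frequencies in both studies, and harmonisation flags (`palindromic`,
#' `flipped`, `proxied`). Variants that could not be harmonised are kept in
#' `drops` with a reason, so that retained + dropped always accounts for
#' every input variant.
#'
#' @slot snps data.frame with the columns listed above.
#' @slot drops data.frame with columns `snp`, `reason`.
#' @slot meta list of provenance (thresholds used, counts).
#' @seealso [harmoniseData()], [harmonisedDataset()], [runMR()]
#' @exportClass HarmonisedDataset
setClass("HarmonisedDataset",
         representation(snps = "data.frame", drops = "data.frame",
                        meta = "list"))

setValidity("HarmonisedDataset", function(object) {
  s <- object@snps
  miss <- setdiff(.HARM_COLS, names(s))
  if (length(miss) > 0)
    return(paste("snps lack columns:", paste(miss, collapse = ", ")))
  if (nrow(s) > 0) {
    if (any(!is.finite(s$gamma_hat)) || any(!is.finite(s$Gamma_hat)))
      return("non-finite effect estimates")
    if (any(s$gamma_se < 0) || any(s$Gamma_se <= 0))
      return("outcome standard errors must be strictly positive and exposure standard errors non-negative")
    eafs <- c(s$eaf_exposure, s$eaf_outcome)
    if (any(eafs < 0 | eafs > 1, na.rm = TRUE))
      return("allele frequencies outside [0, 1]")
    if (anyDuplicated(s$snp))
      return("duplicated SNP identifiers")
  }
  if (nrow(object@drops) > 0) {
    if (!all(c("snp", "reason") %in% names(object@drops)))
      return("drops must have columns snp, reason")
    if (any(object@drops$snp %in% s$snp))
      return("a dropped SNP also appears among retained SNPs")
  }
  TRUE
})

#' Construct a HarmonisedDataset directly from effect vectors
#'
#' Convenience constructor used by the simulators and by analyses that start
#' from already-aligned effects (e.g. the output of another harmonisation
#' tool). All vectors are recycled-checked to a common length.
#'
#' @param gamma_hat,gamma_se SNP-exposure effects and standard errors.
#' @param Gamma_hat,Gamma_se SNP-outcome effects and standard errors, aligned
#'   to the same effect allele as the exposure.
#' @param snp variant identifiers (default `snp_1 ... snp_J`).
#' @param ea,oa effect/other alleles (defaults `"A"`/`"G"`, i.e. assumed
#'   pre-aligned and non-palindromic).
#' @param eaf_exposure,eaf_outcome effect-allele frequencies (may be `NA`).
#' @return A [HarmonisedDataset-class] with an empty drop log.
#' @examples
#' d <- harmonisedDataset(gamma_hat = c(0.1, 0.2), gamma_se = c(0.01, 0.01),
#'                        Gamma_hat = c(0.05, 0.10), Gamma_se = c(0.02, 0.02))
#' mrIVW(d)
#' @export
harmonisedDataset <- function(gamma_hat, gamma_se, Gamma_hat, Gamma_se,
                              snp = paste0("snp_", seq_along(gamma_hat)),
                              ea = "A", oa = "G",
                              eaf_exposure = NA_real_,
                              eaf_outcome = NA_real_) {
  J <- length(gamma_hat)
  snps <- data.frame(
    snp = as.character(snp),
    ea = rep_len(as.character(ea), J), oa = rep_len(as.character(oa), J),
    gamma_hat = as.numeric(gamma_hat),
    gamma_se = rep_len(as.numeric(gamma_se), J),
    Gamma_hat = as.numeric(Gamma_hat),
    Gamma_se = rep_len(as.numeric(Gamma_se), J),
    eaf_exposure = rep_len(as.numeric(eaf_exposure), J),
    eaf_outcome = rep_len(as.numeric(eaf_outcome), J),
    palindromic = FALSE, flipped = FALSE, proxied = FALSE,
    stringsAsFactors = FALSE)
  new("HarmonisedDataset", snps = snps,
      drops = data.frame(snp = character(), reason = character(),
                         stringsAsFactors = FALSE),
      meta = list(constructed = "direct"))
}

#' MREstimate: one method's causal estimate with uncertainty
#'
#' @slot method estimator label, one of `"Wald"`, `"IVW"`, `"Egger"`,
#'   `"Egger-SIMEX"`, `"Weighted median"`, `"Weighted mode"`, `"RAPS"`.
#' @slot beta causal effect on the outcome scale (log odds ratio for binary
#'   outcomes).
#' @slot se standard error of `beta`.
#' @slot ciLow,ciHigh 95% confidence limits.
#' @slot pval two-sided p-value.
#' @slot nSnp number of variants used.
#' @slot details method-specific extras (e.g. Egger intercept and its
#'   standard error/p-value, heterogeneity scale factor, SIMEX lambda fit).
#' @seealso [mrIVW()], [mrEgger()], [asOddsRatio()]
#' @exportClass MREstimate
setClass("MREstimate",
         representation(method = "character", beta = "numeric",
                        se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        pval = "numeric", nSnp = "integer", details = "list"))

setValidity("MREstimate", function(object) {
  if (length(object@beta) != 1 || !is.finite(object@beta))
    return("beta must be a single finite number")
  if (object@se < 0) return("se must be non-negative")
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      (object@ciLow > object@beta || object@ciHigh < object@beta))
    return("confidence interval must bracket the point estimate")
  if (is.finite(object@pval) && (object@pval < 0 || object@pval > 1))
    return("pval outside [0, 1]")
  TRUE
})

# internal constructor: CI from t (df > 0) or normal quantiles
.mk_estimate <- function(method, beta, se, nSnp, df = NA_real_,
                         details = list(), level = 0.95) {
  q <- if (is.finite(df) && df > 0) qt(1 - (1 - level) / 2, df)
       else qnorm(1 - (1 - level) / 2)
  pval <- if (se > 0) {
    if (is.finite(df) && df > 0) 2 * pt(abs(beta / se), df, lower.tail = FALSE)
    else 2 * pnorm(abs(beta / se), lower.tail = FALSE)
  } else NA_real_
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - q * se, ciHigh = beta + q * se,
      pval = pval, nSnp = as.integer(nSnp),
      details = c(details, list(df = df)))
}
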