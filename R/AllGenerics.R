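# Accessor generics and show() methods.

#' Number of variants behind an object
#'
#' @param object a [HarmonisedDataset-class], [InstrumentSet-class] or
#'   [MREstimate-class].
#' @return integer count of variants.
#' @export
setGeneric("nSnp", function(object) standardGeneric("nSnp"))

#' Variant identifiers
#'
#' @param object a [HarmonisedDataset-class] or [InstrumentSet-class].
#' @return character vector of retained variant ids.
#' @export
setGeneric("snpIds", function(object) standardGeneric("snpIds"))

#' Per-variant effects of a harmonised dataset
#'
#' `exposureBeta()`/`exposureSE()` return the SNP-exposure estimates
#' (gamma-hat and its standard error); `outcomeBeta()`/`outcomeSE()` the
#' allele-aligned SNP-outcome estimates (Gamma-hat). `harmonisedTable()`
#' returns the full per-variant data.frame and `droppedSnps()` the drop
#' log (`snp`, `reason`).
#'
#' @param object a [HarmonisedDataset-class].
#' @return numeric vector (effects/standard errors) or data.frame.
#' @name harmonised-accessors
#' @export
setGeneric("exposureBeta", function(object) standardGeneric("exposureBeta"))

#' @rdname harmonised-accessors
#' @export
setGeneric("exposureSE", function(object) standardGeneric("exposureSE"))

#' @rdname harmonised-accessors
#' @export
setGeneric("outcomeBeta", function(object) standardGeneric("outcomeBeta"))

#' @rdname harmonised-accessors
#' @export
setGeneric("outcomeSE", function(object) standardGeneric("outcomeSE"))

#' @rdname harmonised-accessors
#' @export
setGeneric("droppedSnps", function(object) standardGeneric("droppedSnps"))

#' @rdname harmonised-accessors
#' @export
setGeneric("harmonisedTable",
           function(object) standardGeneric("harmonisedTable"))

#' Contents of an instrument set
#'
#' `instrumentRecords()` returns the retained summary-statistic records;
#' `provenanceLog()` the filtering log.
#'
#' @param object an [InstrumentSet-class].
#' @return data.frame or character vector.
#' @name instrument-accessors
#' @export
setGeneric("instrumentRecords",
           function(object) standardGeneric("instrumentRecords"))

#' @rdname instrument-accessors
#' @export
setGeneric("provenanceLog",
           function(object) standardGeneric("provenanceLog"))

#' Components of an MR estimate
#'
#' `estimate()` is the causal point estimate (log odds ratio for binary
#' outcomes), `stdError()` its standard error, `confInt()` the 95%
#' confidence limits, `pValue()` the two-sided p-value and `mrMethod()`
#' the estimator label.
#'
#' @param object an [MREstimate-class].
#' @return numeric scalar/length-2 vector, or character for `mrMethod()`.
#' @name estimate-accessors
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))

#' @rdname estimate-accessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))

#' @rdname estimate-accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))

#' @rdname estimate-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname estimate-accessors
#' @export
setGeneric("mrMethod", function(object) standardGeneric("mrMethod"))

#' @rdname nSnp
#' @export
setMethod("nSnp", "HarmonisedDataset", function(object) nrow(object@snps))
#' @rdname nSnp
#' @export
setMethod("nSnp", "InstrumentSet", function(object) nrow(object@records))
#' @rdname nSnp
#' @export
setMethod("nSnp", "MREstimate", function(object) object@nSnp)

#' @rdname snpIds
#' @export
setMethod("snpIds", "HarmonisedDataset", function(object) object@snps$snp)
#' @rdname snpIds
#' @export
setMethod("snpIds", "InstrumentSet", function(object) object@records$snp)

#' @rdname harmonised-accessors
#' @export
setMethod("exposureBeta", "HarmonisedDataset",
          function(object) object@snps$gamma_hat)
#' @rdname harmonised-accessors
#' @export
setMethod("exposureSE", "HarmonisedDataset",
          function(object) object@snps$gamma_se)
#' @rdname harmonised-accessors
#' @export
setMethod("outcomeBeta", "HarmonisedDataset",
          function(object) object@snps$Gamma_hat)
#' @rdname harmonised-accessors
#' @export
setMethod("outcomeSE", "HarmonisedDataset",
          function(object) object@snps$Gamma_se)
#' @rdname harmonised-accessors
#' @export
setMethod("droppedSnps", "HarmonisedDataset", function(object) object@drops)
#' @rdname harmonised-accessors
#' @export
setMethod("harmonisedTable", "HarmonisedDataset",
          function(object) object@snps)

#' @rdname instrument-accessors
#' @export
setMethod("instrumentRecords", "InstrumentSet",
          function(object) object@records)
#' @rdname instrument-accessors
#' @export
setMethod("provenanceLog", "InstrumentSet", function(object) object@log)

#' @rdname estimate-accessors
#' @export
setMethod("estimate", "MREstimate", function(object) object@beta)
#' @rdname estimate-accessors
#' @export
setMethod("stdError", "MREstimate", function(object) object@se)
#' @rdname estimate-accessors
#' @export
setMethod("confInt", "MREstimate",
          function(object) c(object@ciLow, object@ciHigh))
#' @rdname estimate-accessors
#' @export
setMethod("pValue", "MREstimate", function(object) object@pval)
#' @rdname estimate-accessors
#' @export
setMethod("mrMethod", "MREstimate", function(object) object@method)

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet with", nrow(object@records), "variants\n")
  if (nrow(object@records) > 0) {
    cat("  p-value range:",
        format(range(object@records$pval), digits = 3), "\n")
  }
  cat("  provenance entries:", length(object@log), "\n")
})

setMethod("show", "HarmonisedDataset", function(object) {
  s <- object@snps
  cat("HarmonisedDataset:", nrow(s), "variants retained,",
      nrow(object@drops), "dropped\n")
  if (nrow(s) > 0) {
    cat(sprintf("  flipped: %d  palindromic kept: %d  proxied: %d\n",
                sum(s$flipped), sum(s$palindromic), sum(s$proxied)))
    cat("  mean F statistic:", format(meanF(object), digits = 4), "\n")
  }
  if (nrow(object@drops) > 0) {
    tab <- table(object@drops$reason)
    cat("  drop reasons:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s estimate (%d SNPs)\n", object@method, object@nSnp))
  cat(sprintf("  beta = %.4f  se = %.4f  95%% CI [%.4f, %.4f]  p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pval))
  if (!is.null(object@details$intercept))
    cat(sprintf("  intercept = %.4g (se %.3g, p = %.3g)\n",
                object@details$intercept, object@details$intercept_se,
                object@details$intercept_pval))
  invisible(object)
})

#' Express a binary-outcome estimate as an odds ratio
#'
#' Exponentiates the log odds ratio and its confidence limits. The interval
#' uses `exp(beta +/- 1.96 se)`, the conventional presentation for MR
#' result tables.
#'
#' @param object an [MREstimate-class] for a binary outcome.
#' @return named numeric vector `or`, `ci_low`, `ci_high`.
#' @export
asOddsRatio <- function(object) {
  stopifnot(is(object, "MREstimate"))
  c(or = exp(object@beta),
    ci_low = exp(object@beta - 1.96 * object@se),
    ci_high = exp(object@beta + 1.96 * object@se))
}
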