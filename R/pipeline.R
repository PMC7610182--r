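# Bi-directional MR pipeline orchestration: instrument selection ->
# harmonisation -> estimators -> diagnostics, with results tables, drop
# logs and a reproducibility manifest.

#' Configure a bi-directional MR analysis
#'
#' @param exposure,outcome paths to summary-statistic TSVs, or data.frames
#'   already shaped like [readSummaryStats()] output. In the forward
#'   direction `exposure` is instrumented against `outcome`; `"reverse"`
#'   swaps the roles.
#' @param exposure_type,outcome_type `"continuous"` or `"binary"` — decides
#'   whether results are presented as odds ratios when the trait is the MR
#'   outcome.
#' @param direction `"forward"`, `"reverse"` or `"both"`.
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @param distance_kb,r2_threshold clumping parameters (defaults 10,000 kb,
#'   0.001).
#' @param maf_limit palindromic alignment limit (default 0.3).
#' @param r2_min minimum proxy LD (default 0.8).
#' @param ld,proxies optional LD table and proxy table (see
#'   [selectInstruments()], [substituteProxies()]).
#' @param steiger apply Steiger directionality filtering before estimation
#'   (needs sample-size columns; default FALSE).
#' @param mr settings from [mrConfig()]; its seed drives every stochastic
#'   component.
#' @param exclude_snps variant ids removed after instrument selection
#'   (sensitivity analyses of the leave-a-region-out kind).
#' @param column_map passed to [readSummaryStats()] when paths are given.
#' @return validated config of class `"analysis_config"`.
#' @export
analysisConfig <- function(exposure, outcome,
                           exposure_type = c("continuous", "binary"),
                           outcome_type = c("binary", "continuous"),
                           direction = c("both", "forward", "reverse"),
                           p_threshold = 5e-8, distance_kb = 10000,
                           r2_threshold = 0.001, maf_limit = 0.3,
                           r2_min = 0.8, ld = NULL, proxies = NULL,
                           steiger = FALSE, mr = mrConfig(),
                           exclude_snps = NULL, column_map = list()) {
  exposure_type <- match.arg(exposure_type)
  outcome_type <- match.arg(outcome_type)
  direction <- match.arg(direction)
  stopifnot(p_threshold > 0, p_threshold < 1, maf_limit >= 0,
            maf_limit <= 0.5, r2_min >= 0, r2_min <= 1)
  if (is.null(mr$seed)) stop("mr config must carry a seed")
  structure(list(exposure = exposure, outcome = outcome,
                 exposure_type = exposure_type,
                 outcome_type = outcome_type, direction = direction,
                 p_threshold = p_threshold, distance_kb = distance_kb,
                 r2_threshold = r2_threshold, maf_limit = maf_limit,
                 r2_min = r2_min, ld = ld, proxies = proxies,
                 steiger = steiger, mr = mr, exclude_snps = exclude_snps,
                 column_map = column_map),
            class = "analysis_config")
}

.load_stats <- function(x, column_map) {
  if (is.data.frame(x)) return(x)
  readSummaryStats(x, column_map = column_map)
}

# one direction: select instruments in `exp_stats`, harmonise against
# `out_stats`, run the battery
.run_direction <- function(exp_stats, out_stats, out_type, cfg, label) {
  log <- c(sprintf("[%s] instrument selection", label))
  instruments <- selectInstruments(exp_stats,
                                   p_threshold = cfg$p_threshold,
                                   ld = cfg$ld,
                                   distance_kb = cfg$distance_kb,
                                   r2_threshold = cfg$r2_threshold)
  log <- c(log, provenanceLog(instruments))
  recs <- instrumentRecords(instruments)
  if (nrow(recs) == 0)
    return(list(label = label, error = "no instruments at threshold",
                log = log))
  harm <- harmoniseData(recs, out_stats, maf_limit = cfg$maf_limit,
                        proxies = cfg$proxies, r2_min = cfg$r2_min)
  log <- c(log, sprintf("[%s] harmonised: %d retained, %d dropped", label,
                        nSnp(harm), nrow(droppedSnps(harm))))
  steiger_overall <- NULL
  if (cfg$steiger) {
    ne <- suppressWarnings(max(exp_stats$n, na.rm = TRUE))
    no <- suppressWarnings(max(out_stats$n, na.rm = TRUE))
    if (is.finite(ne) && is.finite(no)) {
      st <- steigerFilter(harm, ne, no)
      harm <- st$filtered
      steiger_overall <- st$overall
      log <- c(log, sprintf("[%s] Steiger: %d retained, direction %s",
                            label, nSnp(harm), st$overall$direction))
    } else log <- c(log, sprintf(
      "[%s] Steiger skipped: sample sizes unavailable", label))
  }
  if (nSnp(harm) == 0)
    return(list(label = label, error = "no variants after harmonisation",
                log = log))
  mr_cfg <- cfg$mr
  mr_cfg$exclude_snps <- unique(c(mr_cfg$exclude_snps, cfg$exclude_snps))
  res <- runMR(harm, outcome_type = out_type, config = mr_cfg)
  list(label = label, instruments = instruments, harmonised = harm,
       result = res, steiger = steiger_overall, log = log)
}

.render_table <- function(est, out_type) {
  if (out_type == "binary" && "or" %in% names(est)) {
    txt <- sprintf("%-16s %5d  OR %s (95%% CI %s-%s)  p = %s",
                   est$method, est$n_snp, signif(est$or, 3),
                   signif(est$or_ci_low, 3), signif(est$or_ci_high, 3),
                   signif(est$pval, 2))
  } else {
    txt <- sprintf("%-16s %5d  beta %s (95%% CI %s-%s)  p = %s",
                   est$method, est$n_snp, signif(est$beta, 3),
                   signif(est$ci_low, 3), signif(est$ci_high, 3),
                   signif(est$pval, 2))
  }
  txt
}

#' Run the bi-directional MR pipeline
#'
#' Executes instrument selection, harmonisation, optional Steiger
#' filtering, the five-estimator battery and diagnostics for the requested
#' direction(s), and — when `out_dir` is given — writes per-direction
#' results TSVs, diagnostics TSVs, drop logs, a plain-text log, a rendered
#' text table, and a JSON run manifest (input checksums, thresholds, seeds
#' and package version) from which every number in the report can be
#' regenerated. A stage failure in one direction is recorded in the
#' manifest and does not discard the other direction's results.
#'
#' @param cfg an [analysisConfig()].
#' @param out_dir optional output directory (created if needed).
#' @return list of class `"mr_pipeline"` with one element per direction
#'   (`forward`: exposure -> outcome; `reverse`: outcome -> exposure), plus
#'   `manifest`.
#' @export
runPipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  exp_stats <- .load_stats(cfg$exposure, cfg$column_map)
  out_stats <- .load_stats(cfg$outcome, cfg$column_map)

  directions <- switch(cfg$direction, both = c("forward", "reverse"),
                       forward = "forward", reverse = "reverse")
  runs <- list()
  for (dir in directions) {
    runs[[dir]] <- if (dir == "forward")
      .run_direction(exp_stats, out_stats, cfg$outcome_type, cfg,
                     "forward")
    else
      .run_direction(out_stats, exp_stats, cfg$exposure_type, cfg,
                     "reverse")
  }

  file_digest <- function(x) {
    if (is.data.frame(x)) {
      tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
      write.table(x, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
      unname(tools::md5sum(tmp))
    } else unname(tools::md5sum(x))
  }
  manifest <- list(
    package = "smokemr",
    version = as.character(packageVersion("smokemr")),
    inputs = list(exposure_md5 = file_digest(cfg$exposure),
                  outcome_md5 = file_digest(cfg$outcome)),
    settings = cfg[c("exposure_type", "outcome_type", "direction",
                     "p_threshold", "distance_kb", "r2_threshold",
                     "maf_limit", "r2_min", "steiger", "exclude_snps")],
    mr = cfg$mr[c("i2_trigger", "n_boot", "seed", "bandwidth_factor",
                  "robust", "raps_overdispersion", "raps_loss")],
    errors = Filter(Negate(is.null),
                    lapply(runs, function(r) r$error)))

  out <- structure(c(runs, list(manifest = manifest)),
                   class = "mr_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- character()
    for (dir in names(runs)) {
      r <- runs[[dir]]
      writeLines(r$log, file.path(out_dir, paste0(dir, "_log.txt")))
      if (!is.null(r$error)) next
      est <- r$result$estimates
      write.table(est, file.path(out_dir, paste0(dir, "_results.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      dg <- r$result$diagnostics
      diag_df <- data.frame(
        statistic = c("cochran_q", "q_df", "q_pval", "egger_intercept",
                      "egger_intercept_se", "egger_intercept_pval",
                      "i2_gx", "mean_f"),
        value = c(if (is.null(dg$cochran_q)) c(NA, NA, NA) else
                    unlist(dg$cochran_q),
                  if (is.null(dg$egger_intercept)) c(NA, NA, NA) else
                    unlist(dg$egger_intercept),
                  if (is.null(dg$i2_gx)) NA else dg$i2_gx,
                  dg$mean_f))
      write.table(diag_df,
                  file.path(out_dir, paste0(dir, "_diagnostics.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(droppedSnps(r$harmonised),
                  file.path(out_dir, paste0(dir, "_drops.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report <- c(report, paste0("== ", dir, " =="),
                  .render_table(est, r$result$outcome_type), "")
    }
    writeLines(report, file.path(out_dir, "report.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  out
}

#' @export
print.mr_pipeline <- function(x, ...) {
  for (dir in setdiff(names(x), "manifest")) {
    cat("==", dir, "==\n")
    r <- x[[dir]]
    if (!is.null(r$error)) cat("  failed:", r$error, "\n")
    else print(r$result)
  }
  invisible(x)
}
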