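# GWAS summary statistics: ingestion, instrument selection, allele
# harmonisation and proxy substitution.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Default column-name dialects for GWAS summary statistics
#'
#' Candidate header names tried, in order, for each standardised field.
#' Override any entry through the `column_map` argument of
#' [readSummaryStats()].
#'
#' @return named list of character vectors.
#' @export
defaultColumnMap <- function() {
  list(snp   = c("SNP", "snp", "rsid", "RSID", "MarkerName", "variant_id"),
       chrom = c("CHR", "chr", "chrom", "chromosome", "CHROM"),
       pos   = c("BP", "bp", "POS", "pos", "position", "base_pair_location"),
       ea    = c("EA", "ea", "A1", "effect_allele", "ALT"),
       oa    = c("OA", "oa", "A2", "other_allele", "REF"),
       eaf   = c("EAF", "eaf", "FRQ", "af", "effect_allele_frequency", "MAF"),
       beta  = c("BETA", "beta", "b", "Effect", "effect"),
       or    = c("OR", "or", "odds_ratio"),
       se    = c("SE", "se", "StdErr", "standard_error"),
       pval  = c("P", "p", "PVAL", "pval", "p_value", "P-value", "pvalue"),
       n     = c("N", "n", "samplesize", "sample_size"))
}

.resolve_column <- function(header, candidates) {
  hit <- match(tolower(candidates), tolower(header))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Read GWAS summary statistics
#'
#' Reads a tab- (or whitespace-) separated association table with a header
#' row and returns validated, standardised records. Column-name dialects
#' are resolved through a candidate map (`A1`/`A2` vs `EA`/`OA`, `OR` vs
#' `BETA`, ...); when only an odds-ratio column is present, effects are
#' log-transformed onto the beta scale. Malformed rows (non-positive
#' standard error, p-value outside (0, 1], invalid alleles, non-finite
#' effect) are rejected, and the rejections are attached as attribute
#' `"rejections"` — a data.frame with the 1-based file line number and a
#' reason for each.
#'
#' @param path file path (TSV with header; empty fields are missing).
#' @param column_map named list overriding entries of [defaultColumnMap()].
#' @param sep field separator; default tab, use `""` for any whitespace.
#' @return data.frame with columns `snp`, `chrom`, `pos`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `pval`, `n` (optional fields `NA` when absent),
#'   with attribute `"rejections"`.
#' @export
readSummaryStats <- function(path, column_map = list(), sep = "\t") {
  raw <- read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE,
                    na.strings = c("NA", "", "."))
  if (ncol(raw) == 1 && sep == "\t")   # whitespace-separated fallback
    raw <- read.table(path, header = TRUE, sep = "", quote = "",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE,
                      na.strings = c("NA", "", "."))
  cmap <- modifyList(defaultColumnMap(), column_map)
  idx <- lapply(cmap, .resolve_column, header = names(raw))

  mandatory <- c("snp", "ea", "oa", "se", "pval")
  for (f in mandatory)
    if (is.na(idx[[f]]))
      stop(sprintf("missing mandatory column '%s'; candidates tried: %s",
                   f, paste(cmap[[f]], collapse = ", ")), call. = FALSE)
  if (is.na(idx$beta) && is.na(idx$or))
    stop("missing effect column; candidates tried: ",
         paste(c(cmap$beta, cmap$or), collapse = ", "), call. = FALSE)

  grab <- function(f, as = as.numeric) {
    if (is.na(idx[[f]])) rep(NA, nrow(raw)) else as(raw[[idx[[f]]]])
  }
  out <- data.frame(
    snp = grab("snp", as.character),
    chrom = grab("chrom", as.character),
    pos = grab("pos"),
    ea = toupper(grab("ea", as.character)),
    oa = toupper(grab("oa", as.character)),
    eaf = grab("eaf"),
    beta = if (!is.na(idx$beta)) as.numeric(raw[[idx$beta]]) else NA_real_,
    se = grab("se"),
    pval = grab("pval"),
    n = grab("n"),
    stringsAsFactors = FALSE)

  or_used <- is.na(idx$beta)
  if (or_used) {
    or_val <- as.numeric(raw[[idx$or]])
    out$beta <- ifelse(is.finite(or_val) & or_val > 0, log(or_val), NA_real_)
  }

  line_no <- seq_len(nrow(out)) + 1L    # header is line 1
  reasons <- character(nrow(out))
  flag <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reasons[cond & reasons == ""] <<- why
  }
  flag(is.na(out$snp), "missing SNP id")
  flag(!(out$ea %in% names(.COMPLEMENT)), "invalid effect allele")
  flag(!(out$oa %in% names(.COMPLEMENT)), "invalid other allele")
  flag(out$ea == out$oa, "effect and other allele identical")
  flag(!is.finite(out$beta),
       if (or_used) "invalid odds ratio" else "non-finite beta")
  flag(!is.finite(out$se) | out$se <= 0, "standard error not positive")
  flag(!is.finite(out$pval) | out$pval <= 0 | out$pval > 1,
       "p-value outside (0, 1]")
  flag(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1),
       "allele frequency outside [0, 1]")

  bad <- reasons != ""
  rejections <- data.frame(line = line_no[bad], snp = out$snp[bad],
                           reason = reasons[bad], stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Write summary statistics in the package's standard TSV layout
#'
#' @param x data.frame shaped as returned by [readSummaryStats()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Select independent genome-wide significant instruments
#'
#' Filters to records with `pval < p_threshold` and applies greedy clumping:
#' records are visited in ascending p-value order, and a variant is retained
#' unless it lies within `distance_kb` of an already-retained variant on the
#' same chromosome *and* is in linkage disequilibrium with it at
#' `r2 >= r2_threshold`. LD is looked up in `ld`, a user-supplied pairwise
#' table (`snp1`, `snp2`, `r2`); when no LD information is available for a
#' nearby pair — or no table is supplied at all — the distance rule alone
#' decides (conservative), and the provenance log flags the pruning as
#' approximate.
#'
#' @param stats data.frame of summary statistics ([readSummaryStats()]).
#' @param p_threshold significance threshold (default genome-wide, 5e-8).
#' @param ld optional pairwise LD data.frame with columns `snp1`, `snp2`,
#'   `r2` (order-insensitive).
#' @param distance_kb clumping window in kilobases (default 10,000).
#' @param r2_threshold LD independence threshold (default 0.001).
#' @return an [InstrumentSet-class].
#' @export
selectInstruments <- function(stats, p_threshold = 5e-8, ld = NULL,
                              distance_kb = 10000, r2_threshold = 0.001) {
  log <- sprintf("significance filter p < %g: %d of %d records pass",
                 p_threshold, sum(stats$pval < p_threshold), nrow(stats))
  sig <- stats[stats$pval < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    log <- c(log, "empty instrument set")
    return(new("InstrumentSet", records = sig, log = log))
  }

  have_pos <- !anyNA(sig$chrom) && !anyNA(sig$pos)
  if (!have_pos) {
    log <- c(log, "WARNING: chromosome/position unavailable; clumping skipped")
    ord <- order(sig$pval, sig$snp)
    return(new("InstrumentSet", records = sig[ord, , drop = FALSE],
               log = log))
  }
  if (is.null(ld))
    log <- c(log, paste("WARNING: no LD table supplied; distance-only",
                        "pruning applied (approximate clumping)"))

  ld_key <- if (!is.null(ld))
    setNames(ld$r2, paste(pmin(ld$snp1, ld$snp2), pmax(ld$snp1, ld$snp2)))
  lookup_r2 <- function(a, b) {
    if (is.null(ld)) return(NA_real_)
    r <- ld_key[paste(min(a, b), max(a, b))]
    if (is.na(r)) NA_real_ else unname(r)
  }

  sig <- sig[order(sig$pval, sig$snp), , drop = FALSE]
  keep <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    conflict <- FALSE
    for (j in which(keep)) {
      if (sig$chrom[i] != sig$chrom[j]) next
      if (abs(sig$pos[i] - sig$pos[j]) > distance_kb * 1000) next
      r2 <- lookup_r2(sig$snp[i], sig$snp[j])
      if (is.na(r2)) {       # unknown LD: distance rule alone decides
        conflict <- TRUE
        log <- c(log, sprintf(
          "%s pruned: within %g kb of %s, LD unknown (approximate rule)",
          sig$snp[i], distance_kb, sig$snp[j]))
      } else if (r2 >= r2_threshold) {
        conflict <- TRUE
        log <- c(log, sprintf("%s pruned: within %g kb of %s, r2 = %g",
                              sig$snp[i], distance_kb, sig$snp[j], r2))
      }
      if (conflict) break
    }
    keep[i] <- !conflict
  }
  log <- c(log, sprintf("clumping retained %d of %d significant records",
                        sum(keep), nrow(sig)))
  recs <- sig[keep, , drop = FALSE]
  rownames(recs) <- NULL
  new("InstrumentSet", records = recs, log = log)
}

#' Is a variant palindromic?
#'
#' A variant is palindromic when its two alleles are strand complements of
#' each other ({A,T} or {C,G}), so strand orientation cannot be resolved
#' from the allele labels alone.
#'
#' @param ea,oa effect and other allele (character vectors).
#' @return logical vector.
#' @examples
#' isPalindromic(c("A", "A", "C"), c("T", "G", "G"))  # TRUE FALSE TRUE
#' @export
isPalindromic <- function(ea, oa) {
  ea <- toupper(ea); oa <- toupper(oa)
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Substitute proxy variants for instruments absent from the outcome study
#'
#' For each missing target variant, the best available proxy with
#' `r2 >= r2_min` is taken from the outcome records and relabelled as the
#' target, with the user-supplied allele mapping applied so that downstream
#' harmonisation sees the target's alleles. Linkage information is never
#' computed here: `proxy_table` is user-supplied.
#'
#' @param missing_snps character vector of target variants absent from the
#'   outcome study.
#' @param outcome outcome summary statistics data.frame.
#' @param proxy_table data.frame with columns `target_snp`, `proxy_snp`,
#'   `r2`, `target_ea`, `target_oa`, `proxy_ea`, `proxy_oa` (the proxy
#'   allele carried with the target's effect allele, and the counterpart).
#' @param r2_min minimum LD between target and proxy (default 0.8).
#' @return list with `records` (relabelled outcome rows, flagged
#'   `proxied = TRUE` and carrying `proxy_for`), `dropped` (targets with no
#'   adequate proxy) and `log`.
#' @export
substituteProxies <- function(missing_snps, outcome, proxy_table,
                              r2_min = 0.8) {
  need <- c("target_snp", "proxy_snp", "r2", "target_ea", "target_oa",
            "proxy_ea", "proxy_oa")
  if (!is.data.frame(proxy_table) || !all(need %in% names(proxy_table)))
    stop("malformed proxy table: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(proxy_table$r2) | proxy_table$r2 < 0 |
            proxy_table$r2 > 1))
    stop("malformed proxy table: r2 outside [0, 1]", call. = FALSE)

  subs <- list(); dropped <- character(); log <- character()
  for (target in missing_snps) {
    cand <- proxy_table[proxy_table$target_snp == target &
                          proxy_table$r2 >= r2_min &
                          proxy_table$proxy_snp %in% outcome$snp, ,
                        drop = FALSE]
    if (nrow(cand) == 0) {
      dropped <- c(dropped, target)
      log <- c(log, sprintf("%s: no proxy at r2 >= %g available", target,
                            r2_min))
      next
    }
    best <- cand[which.max(cand$r2), , drop = FALSE]
    rec <- outcome[outcome$snp == best$proxy_snp, , drop = FALSE][1, ]
    # orient the proxy record so its effect allele is the one tagging the
    # target's effect allele, then relabel with the target's alleles
    if (toupper(rec$ea) == toupper(best$proxy_oa) &&
        toupper(rec$oa) == toupper(best$proxy_ea)) {
      rec$beta <- -rec$beta
      if (!is.na(rec$eaf)) rec$eaf <- 1 - rec$eaf
    } else if (!(toupper(rec$ea) == toupper(best$proxy_ea) &&
                   toupper(rec$oa) == toupper(best$proxy_oa))) {
      dropped <- c(dropped, target)
      log <- c(log, sprintf(
        "%s: proxy %s alleles do not match the proxy table", target,
        best$proxy_snp))
      next
    }
    rec$proxy_for <- target
    rec$proxy_r2 <- best$r2
    rec$snp <- target
    rec$ea <- toupper(best$target_ea)
    rec$oa <- toupper(best$target_oa)
    subs[[target]] <- rec
    log <- c(log, sprintf("%s: substituted proxy %s (r2 = %g)", target,
                          best$proxy_snp, best$r2))
  }
  records <- if (length(subs) > 0) do.call(rbind, subs) else
    outcome[0, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, dropped = dropped, log = log)
}

# Align one outcome record to the exposure's allele orientation.
# Returns list(action = "ok"|"flip"|"drop", strand = TRUE/FALSE, reason).
.align_alleles <- function(exp_ea, exp_oa, out_ea, out_oa,
                           eaf_exp, eaf_out, maf_limit) {
  if (isPalindromic(exp_ea, exp_oa)) {
    if (!setequal(c(out_ea, out_oa), c(exp_ea, exp_oa)))
      return(list(action = "drop", reason = "allele_mismatch"))
    if (is.na(eaf_exp) || is.na(eaf_out))
      return(list(action = "drop", reason = "palindromic_missing_eaf"))
    if (min(eaf_exp, 1 - eaf_exp) >= maf_limit ||
        min(eaf_out, 1 - eaf_out) >= maf_limit)
      return(list(action = "drop", reason = "palindromic_maf"))
    # label-level swap first, then strand resolution by frequency agreement
    eaf_aligned <- if (out_ea == exp_ea) eaf_out else 1 - eaf_out
    flip_label <- out_ea != exp_ea
    flip_freq <- (eaf_exp < 0.5) != (eaf_aligned < 0.5)
    flips <- xor(flip_label, flip_freq)
    list(action = if (flips) "flip" else "ok", strand = flip_freq)
  } else {
    if (out_ea == exp_ea && out_oa == exp_oa)
      return(list(action = "ok", strand = FALSE))
    if (out_ea == exp_oa && out_oa == exp_ea)
      return(list(action = "flip", strand = FALSE))
    c_ea <- unname(.COMPLEMENT[out_ea]); c_oa <- unname(.COMPLEMENT[out_oa])
    if (identical(c_ea, exp_ea) && identical(c_oa, exp_oa))
      return(list(action = "ok", strand = TRUE))
    if (identical(c_ea, exp_oa) && identical(c_oa, exp_ea))
      return(list(action = "flip", strand = TRUE))
    list(action = "drop", reason = "allele_mismatch")
  }
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the outcome study's per-variant effects to the exposure study's
#' effect alleles, producing the per-SNP (gamma, Gamma) pairs that the MR
#' estimators consume. For each shared variant: swapped allele labels flip
#' the outcome effect sign (and reflect the allele frequency); alleles
#' differing by strand complement are complemented and then aligned;
#' palindromic variants are resolved by allele-frequency agreement, and only
#' when the minor allele frequency is below `maf_limit` in both studies —
#' otherwise they are dropped with a reason, as are variants with
#' irreconcilable allele sets. Exposure variants absent from the outcome can
#' be rescued through [substituteProxies()] by supplying `proxies`.
#' Dropped variants are never silently discarded: they appear in the drop
#' log, so retained + dropped equals the input count.
#'
#' @param exposure,outcome summary-statistic data.frames
#'   ([readSummaryStats()]); `exposure` is typically
#'   `instrumentRecords(selectInstruments(...))`.
#' @param maf_limit palindromic variants are only alignable when the minor
#'   allele frequency is below this in both studies (default 0.3).
#' @param proxies optional proxy table (see [substituteProxies()]).
#' @param r2_min minimum proxy LD (default 0.8).
#' @return a [HarmonisedDataset-class].
#' @export
harmoniseData <- function(exposure, outcome, maf_limit = 0.3,
                          proxies = NULL, r2_min = 0.8) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  outcome$proxy_for <- NA_character_
  outcome$proxy_r2 <- NA_real_

  missing <- setdiff(exposure$snp, outcome$snp)
  proxy_log <- character()
  if (length(missing) > 0 && !is.null(proxies)) {
    sub <- substituteProxies(missing, outcome, proxies, r2_min = r2_min)
    if (nrow(sub$records) > 0)
      outcome <- rbind(outcome, sub$records[names(outcome)])
    proxy_log <- sub$log
  }

  rows <- vector("list", nrow(exposure))
  drops <- list()
  for (i in seq_len(nrow(exposure))) {
    e <- exposure[i, ]
    o <- outcome[outcome$snp == e$snp, , drop = FALSE]
    if (nrow(o) == 0) {
      drops[[length(drops) + 1L]] <-
        data.frame(snp = e$snp, reason = "absent_in_outcome")
      next
    }
    o <- o[1, ]
    al <- .align_alleles(e$ea, e$oa, o$ea, o$oa, e$eaf, o$eaf, maf_limit)
    if (al$action == "drop") {
      drops[[length(drops) + 1L]] <-
        data.frame(snp = e$snp, reason = al$reason)
      next
    }
    flip <- al$action == "flip"
    rows[[i]] <- data.frame(
      snp = e$snp, ea = e$ea, oa = e$oa,
      gamma_hat = e$beta, gamma_se = e$se,
      Gamma_hat = if (flip) -o$beta else o$beta,
      Gamma_se = o$se,
      eaf_exposure = e$eaf,
      eaf_outcome = if (flip && !is.na(o$eaf)) 1 - o$eaf else o$eaf,
      palindromic = isPalindromic(e$ea, e$oa),
      flipped = flip,
      proxied = !is.na(o$proxy_for),
      stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(snps))
    snps <- harmonisedDataset(numeric(), numeric(), numeric(),
                              numeric())@snps
  drops <- if (length(drops) > 0) do.call(rbind, drops) else
    data.frame(snp = character(), reason = character())
  rownames(snps) <- rownames(drops) <- NULL
  new("HarmonisedDataset", snps = snps, drops = drops,
      meta = list(maf_limit = maf_limit, n_input = nrow(exposure),
                  proxy_log = proxy_log))
}
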