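# Summary-statistic ingestion, instrument selection, harmonisation.

test_that("summary statistics are read, dialects resolved, bad rows logged", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
                   BP = c(1e6, 2e6, 3e6), A1 = c("A", "C", "T"),
                   A2 = c("G", "T", "C"), FRQ = c(0.2, 0.3, 0.4),
                   BETA = c(0.1, -0.05, 0.02), SE = c(0.01, 0.02, 0.01),
                   P = c(1e-10, 1e-5, 0.5), N = 1e5)
  path <- write_tsv(df, tempfile(fileext = ".tsv"))
  x <- readSummaryStats(path)
  expect_equal(nrow(x), 3)
  expect_equal(x$snp, c("rs1", "rs2", "rs3"))
  expect_equal(x$beta, df$BETA)
  expect_equal(nrow(attr(x, "rejections")), 0)

  # odds-ratio dialect is log-transformed
  df_or <- data.frame(rsid = "rs9", effect_allele = "A",
                      other_allele = "G", OR = 1.105, SE = 0.02,
                      pval = 1e-9)
  y <- readSummaryStats(write_tsv(df_or, tempfile(fileext = ".tsv")))
  expect_equal(y$beta, log(1.105), tolerance = 1e-12)

  # malformed rows are rejected with their file line number
  df$SE[2] <- 0
  df$P[3] <- 0
  z <- readSummaryStats(write_tsv(df, tempfile(fileext = ".tsv")))
  expect_equal(nrow(z), 1)
  rej <- attr(z, "rejections")
  expect_equal(rej$line, c(3L, 4L))
  expect_match(rej$reason[1], "standard error")
  expect_match(rej$reason[2], "p-value")

  # missing mandatory column names the candidates tried
  df_bad <- df[, setdiff(names(df), "SE")]
  expect_error(readSummaryStats(write_tsv(df_bad,
                                          tempfile(fileext = ".tsv"))),
               "StdErr")

  # whitespace-separated files are accepted
  p2 <- tempfile()
  writeLines(c("SNP EA OA BETA SE P",
               "rs1 A G 0.1 0.01 1e-9"), p2)
  w <- readSummaryStats(p2, sep = "")
  expect_equal(w$beta, 0.1)
})

test_that("palindromic variants are exactly the strand-ambiguous pairs", {
  expect_equal(isPalindromic(c("A", "T", "C", "G", "A", "a"),
                             c("T", "A", "G", "C", "G", "t")),
               c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("instrument selection applies the significance threshold and greedy clumping", {
  s <- mk_stats(c("rs1", "rs2", "rs3"), "A", "G",
                beta = 0.1, se = 0.01,
                pval = c(1e-9, 6e-8, 1e-7),
                chrom = c("1", "5", "9"), pos = c(1e6, 1e6, 1e6))
  got <- selectInstruments(s)
  expect_equal(snpIds(got), "rs1")

  # close pair in LD: only the stronger survives
  ld <- data.frame(snp1 = "rsA", snp2 = "rsB", r2 = 0.5)
  s2 <- mk_stats(c("rsA", "rsB"), "A", "G", beta = 0.1, se = 0.01,
                 pval = c(1e-10, 1e-9), chrom = "2",
                 pos = c(1e6, 1e6 + 5000 * 1000))
  expect_equal(snpIds(selectInstruments(s2, ld = ld)), "rsA")
  # same distance on different chromosomes: both kept
  s3 <- s2; s3$chrom <- c("2", "3")
  expect_equal(sort(snpIds(selectInstruments(s3, ld = ld))),
               c("rsA", "rsB"))
  # close pair but below the LD threshold: independent, both kept
  ld_lo <- data.frame(snp1 = "rsA", snp2 = "rsB", r2 = 0.0005)
  expect_equal(sort(snpIds(selectInstruments(s2, ld = ld_lo))),
               c("rsA", "rsB"))
  # without any LD information the distance rule alone prunes, with notice
  no_ld <- selectInstruments(s2)
  expect_equal(snpIds(no_ld), "rsA")
  expect_true(any(grepl("approximate", provenanceLog(no_ld))))

  # an empty set is allowed
  none <- selectInstruments(mk_stats("rs1", "A", "G", 0.1, 0.01, 1e-4))
  expect_equal(nSnp(none), 0)
})

test_that("harmonisation aligns, flips, complements and drops correctly", {
  exp <- mk_stats(paste0("rs", 1:6),
                  ea = c("A", "A", "A", "C", "A", "A"),
                  oa = c("G", "G", "T", "G", "G", "G"),
                  beta = 0.1, se = 0.01, pval = 1e-10,
                  eaf = c(0.2, 0.2, 0.10, 0.45, 0.2, 0.2))
  out <- mk_stats(paste0("rs", 1:6),
                  ea = c("A", "G", "A", "C", "T", "A"),
                  oa = c("G", "A", "T", "G", "C", "C"),
                  beta = c(0.05, -0.05, 0.05, 0.05, 0.05, 0.05),
                  se = 0.02, pval = 0.01,
                  eaf = c(0.2, 0.8, 0.88, 0.45, 0.2, 0.2))
  h <- harmoniseData(exp, out)
  tab <- harmonisedTable(h)

  # rs1 already aligned; rs2 label-swapped: double negation restores +0.05
  expect_equal(tab$Gamma_hat[tab$snp == "rs1"], 0.05)
  expect_equal(tab$Gamma_hat[tab$snp == "rs2"], 0.05)
  expect_true(tab$flipped[tab$snp == "rs2"])
  # rs3 palindromic with discordant frequencies: flipped to the other strand
  expect_equal(tab$Gamma_hat[tab$snp == "rs3"], -0.05)
  expect_equal(tab$eaf_outcome[tab$snp == "rs3"], 0.12)
  # rs4 palindromic with MAF >= 0.3: unresolvable, dropped
  drops <- droppedSnps(h)
  expect_equal(drops$reason[drops$snp == "rs4"], "palindromic_maf")
  # rs5 strand-complemented labels (T/C vs A/G): aligned without sign flip
  expect_equal(tab$Gamma_hat[tab$snp == "rs5"], 0.05)
  expect_false(tab$flipped[tab$snp == "rs5"])
  # rs6 irreconcilable allele sets
  expect_equal(drops$reason[drops$snp == "rs6"], "allele_mismatch")

  # every input variant is accounted for
  expect_equal(nSnp(h) + nrow(drops), nrow(exp))

  # idempotence: re-harmonising the aligned outcome changes nothing
  out2 <- out
  for (i in seq_len(nrow(tab))) {
    j <- which(out2$snp == tab$snp[i])
    out2$ea[j] <- tab$ea[i]; out2$oa[j] <- tab$oa[i]
    out2$beta[j] <- tab$Gamma_hat[i]; out2$eaf[j] <- tab$eaf_outcome[i]
  }
  h2 <- harmoniseData(exp[exp$snp %in% tab$snp, ], out2)
  tab2 <- harmonisedTable(h2)
  expect_equal(tab2$Gamma_hat, tab$Gamma_hat)
  expect_false(any(tab2$flipped))
})

test_that("relabelling both studies consistently leaves harmonised effects unchanged", {
  set.seed(77)
  exp <- mk_stats(paste0("rs", 1:8), ea = "A", oa = "G",
                  beta = rnorm(8, 0.1, 0.02), se = 0.01, pval = 1e-10,
                  eaf = runif(8, 0.1, 0.9))
  out <- mk_stats(paste0("rs", 1:8), ea = "A", oa = "G",
                  beta = rnorm(8, 0.05, 0.02), se = 0.02, pval = 0.01,
                  eaf = runif(8, 0.1, 0.9))
  base <- harmonisedTable(harmoniseData(exp, out))

  relabel <- function(x) {
    x$ea <- "G"; x$oa <- "A"; x$beta <- -x$beta; x$eaf <- 1 - x$eaf
    x
  }
  swapped <- harmonisedTable(harmoniseData(relabel(exp), relabel(out)))
  # gamma/Gamma pairs are identical up to a joint sign convention
  expect_equal(swapped$Gamma_hat / swapped$gamma_hat,
               base$Gamma_hat / base$gamma_hat, tolerance = 1e-12)
  expect_equal(abs(swapped$gamma_hat), abs(base$gamma_hat))
})

test_that("proxy substitution picks the best adequate proxy and maps alleles", {
  exp <- mk_stats(c("rs1", "rs2", "rs3"), "A", "G", beta = 0.1,
                  se = 0.01, pval = 1e-10, eaf = 0.2)
  # outcome lacks rs1 and rs2 entirely, rs3 present
  out <- mk_stats(c("px1", "px2", "px_weak", "rs3"),
                  ea = c("T", "T", "A", "A"), oa = c("C", "C", "G", "G"),
                  beta = c(0.04, -0.04, 0.02, 0.05), se = 0.02,
                  pval = 0.01, eaf = c(0.25, 0.75, 0.2, 0.2))
  proxies <- data.frame(
    target_snp = c("rs1", "rs1", "rs2"),
    proxy_snp = c("px1", "px2", "px_weak"),
    r2 = c(0.85, 0.92, 0.6),
    target_ea = "A", target_oa = "G",
    proxy_ea = c("T", "C", "A"), proxy_oa = c("C", "T", "G"),
    stringsAsFactors = FALSE)

  h <- harmoniseData(exp, out, proxies = proxies)
  tab <- harmonisedTable(h)
  # rs1 rescued through the stronger proxy px2 (r2 0.92), whose record is
  # reported for the counterpart allele, so the effect flips to +0.04
  expect_true(tab$proxied[tab$snp == "rs1"])
  expect_equal(tab$Gamma_hat[tab$snp == "rs1"], 0.04)
  # rs2's only proxy is below the LD floor: dropped
  expect_equal(droppedSnps(h)$reason[droppedSnps(h)$snp == "rs2"],
               "absent_in_outcome")
  expect_false("rs2" %in% tab$snp)
  expect_equal(nSnp(h) + nrow(droppedSnps(h)), 3)

  expect_error(substituteProxies("rs1", out, proxies[, 1:3]),
               "malformed proxy table")
})
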