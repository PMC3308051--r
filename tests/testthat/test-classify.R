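test_that("variable sites require two pooled reads for the second allele", {
  ref <- c(t1 = strrep("G", 60))
  mk <- function(c1, c2) {
    aln <- list()
    add <- function(base, n, acc) {
      for (i in seq_len(n)) {
        aln[[length(aln) + 1L]] <<- data.table(
          read_id = paste0(acc, base, i), target = "t1", pos = 30L,
          seq = base, accession = acc, strand = "+")
      }
    }
    for (b in names(c1)) add(b, c1[[b]], "Ld")
    for (b in names(c2)) add(b, c2[[b]], "Td")
    build_pileup(rbindlist(aln), ref)
  }
  s1 <- call_variable_sites(mk(list(A = 5, G = 6), list(G = 9)))
  expect_equal(nrow(s1), 1L)
  expect_true(s1$ivs1); expect_false(s1$ivs2)
  expect_setequal(c(s1$a1, s1$a2), c("A", "G"))

  expect_equal(nrow(call_variable_sites(mk(list(A = 1, G = 12), list(G = 1)))), 0L)
  expect_equal(nrow(call_variable_sites(mk(list(G = 10), list(G = 10)))), 0L)
})

test_that("the MDC filter uses the 99th percentile of single-copy targets", {
  summ <- data.table(target = sprintf("g%03d", 1:100),
                     mdc_combined = as.numeric(1:100))
  flt <- mdc_target_filter(summ, summ$target)
  expect_equal(flt$cutoff, 99.01)
  expect_equal(flt$excluded, c("g100"))

  cfg <- classifier_config(mdc_cutoff_override = 61)
  summ2 <- data.table(target = c("a", "b", "c"),
                      mdc_combined = c(60, 61, 80))
  flt2 <- mdc_target_filter(summ2, "a", cfg)
  expect_setequal(flt2$excluded, c("b", "c"))  # >= 61 is inclusive

  # nothing at or above the cutoff: empty exclusion set
  flt3 <- mdc_target_filter(summ2, "c", classifier_config(mdc_cutoff_override = 100))
  expect_equal(length(flt3$excluded), 0L)
  expect_error(mdc_target_filter(summ, character(0)), "empty")
})

test_that("log2 variant ratios are antisymmetric with guarded zeros", {
  expect_equal(log2_variant_ratio(8, 2), 2)
  expect_equal(log2_variant_ratio(5, 5), 0)
  expect_equal(log2_variant_ratio(2, 8), -2)
  expect_error(log2_variant_ratio(0, 5), "at least one read")
})

test_that("ratio threshold calibration scans the merged observed values", {
  true_r <- c(0.1, 0.4, 0.5, 0.8, 1.0)
  false_r <- c(4.0, 4.2, 5.0)
  expect_equal(calibrate_ratio_thresholds(true_r, false_r, 0.05), 1.0)
  expect_equal(calibrate_ratio_thresholds(true_r, numeric(0)), 1.0)

  # brute-force oracle over every candidate threshold
  set.seed(10)
  tr <- round(rnorm(10, 1, 1), 2)
  fa <- round(rnorm(10, 3, 1), 2)
  rate <- 0.25
  cand <- sort(unique(c(tr, fa)))
  feasible <- vapply(cand, function(u) {
    nt <- sum(tr <= u); nf <- sum(fa <= u)
    (nt + nf) > 0 && nf / (nt + nf) <= rate
  }, TRUE)
  expect_equal(calibrate_ratio_thresholds(tr, fa, rate), max(cand[feasible]))

  expect_warning(u <- calibrate_ratio_thresholds(5, c(1, 1, 1), 0.05),
                 "minimum observed")
  expect_equal(u, 1)
})

test_that("sites classify into GSS, SNP and filtered with reasons", {
  cfg <- classifier_config()
  # SNP: IVS in Ld, Td monomorphic G at depth 15
  s <- classify_sites(make_site(list(A = 6, G = 7), list(G = 15), ref = "G"), cfg)
  expect_equal(s$label, "SNP")
  expect_equal(s$lineage, "Ld")
  expect_equal(s$ancestral, "G")
  expect_equal(s$derived, "A")

  # GSS: both accessions carry both variants
  g <- classify_sites(make_site(list(C = 5, T = 6), list(C = 7, T = 4),
                                ref = "C"), cfg)
  expect_equal(g$label, "GSS")

  # monomorphic side below eight reads
  lo <- classify_sites(make_site(list(A = 6, G = 7), list(G = 6), ref = "G"), cfg)
  expect_equal(lo$label, "filtered")
  expect_equal(lo$filter_reason, "low_mono_coverage")

  # coverage ratio outside the window (ref 12 vs alt 2 in Td: log2 = 2.58 > 1)
  rr <- classify_sites(make_site(list(A = 5, G = 6), list(A = 2, G = 12),
                                 ref = "G"), cfg)
  expect_equal(rr$label, "filtered")
  expect_equal(rr$filter_reason, "ratio_out_of_range")

  # third allele beyond the one-read error tolerance
  tri <- classify_sites(make_site(list(A = 6, G = 7, T = 3), list(G = 9),
                                  ref = "G"), cfg)
  expect_equal(tri$filter_reason, "triallelic")

  # excluded target
  ex <- classify_sites(make_site(list(A = 6, G = 7), list(G = 15), ref = "G"),
                       cfg, excluded_targets = "t1")
  expect_equal(ex$filter_reason, "high_mdc_target")

  # both accessions fixed for different alleles: not classifiable
  nv <- classify_sites(make_site(list(A = 8), list(G = 9), ref = "G"), cfg)
  expect_equal(nv$filter_reason, "no_ivs")
})

test_that("swapping accessions mirrors SNP lineage and keeps GSS calls", {
  cfg <- classifier_config(log2_upper = c(1.6, 1.6))
  snp_fwd <- classify_sites(make_site(list(A = 6, G = 7), list(G = 15),
                                      ref = "G"), cfg)
  snp_rev <- classify_sites(make_site(list(G = 15), list(A = 6, G = 7),
                                      ref = "G"), cfg)
  expect_equal(snp_fwd$label, "SNP"); expect_equal(snp_rev$label, "SNP")
  expect_equal(snp_fwd$lineage, "Ld"); expect_equal(snp_rev$lineage, "Td")
  expect_equal(snp_fwd$derived, snp_rev$derived)

  gss_fwd <- classify_sites(make_site(list(C = 5, T = 6), list(C = 7, T = 4),
                                      ref = "C"), cfg)
  gss_rev <- classify_sites(make_site(list(C = 7, T = 4), list(C = 5, T = 6),
                                      ref = "C"), cfg)
  expect_equal(gss_fwd$label, "GSS")
  expect_equal(gss_rev$label, "GSS")
})

test_that("every variable site receives exactly one label", {
  run <- clean_run()
  expect_false(any(is.na(run$calls$label)))
  expect_true(all(run$calls$label %in% c("GSS", "SNP", "filtered")))
  expect_true(all(!is.na(run$calls[label == "filtered", filter_reason])))
  expect_true(all(is.na(run$calls[label != "filtered", filter_reason])))
})

test_that("flank rescue unmasks hidden GSSs but spares true SNPs", {
  set.seed(20)
  ref <- c(t1 = rand_seq(200))
  substr(ref[["t1"]], 100, 100) <- "G"  # site ancestral base
  cfg <- classifier_config()
  snp <- classify_sites(make_site(list(A = 6, G = 7), list(G = 15), ref = "G",
                                  pos = 100L), cfg)
  snp[, `:=`(ancestral = "G", derived = "A")]  # derived variant A at pos 100

  # a diverged Td read carrying the missing A variant plus 3 extra mismatches
  ctx <- substring(ref[[1]], 81, 120)
  substr(ctx, 20, 20) <- "A"
  hidden <- force_mutate(ctx, c(2L, 12L, 35L))
  res <- flank_rescue(snp, list(Ld = character(0), Td = hidden), ref, cfg)
  expect_equal(res$label, "filtered")
  expect_equal(res$filter_reason, "flank_rescued")

  # reads without the second variant never rescue
  res2 <- flank_rescue(snp, list(Ld = character(0), Td = substring(ref[[1]], 81, 120)),
                       ref, cfg)
  expect_equal(res2$label, "SNP")

  # an empty monomorphic pool never rescues
  res3 <- flank_rescue(snp, list(Ld = character(0), Td = character(0)), ref, cfg)
  expect_equal(res3$label, "SNP")

  # the scan searches both strands
  res4 <- flank_rescue(snp, list(Ld = character(0), Td = revcomp_chr(hidden)),
                       ref, cfg)
  expect_equal(res4$filter_reason, "flank_rescued")
})

test_that("the one-variant theory term matches the Poisson model", {
  expect_equal(round(expected_missed_variant_sites(13, 0.02, 3.5e6), 1), 0.3)
  expect_equal(expected_missed_variant_sites(log(2), 0.001, 1e5), 100)
  expect_equal(expected_missed_variant_sites(1e3, 0.02, 3.5e6), 0,
               tolerance = 1e-12)
  lam <- seq(1, 30, by = 0.5)
  vals <- vapply(lam, expected_missed_variant_sites, 0,
                 divergence_d = 0.02, target_length = 3.5e6)
  expect_true(all(diff(vals) < 0))
  expect_error(expected_missed_variant_sites(0, 0.02, 1e6), "positive")
})

test_that("validation confusion reproduces the published arithmetic", {
  gss_called <- sprintf("s%03d", 1:97)
  gss_truth <- c(gss_called[1:96], sprintf("t%03d", 1:187))
  gss <- validation_confusion(gss_called, gss_truth)
  expect_equal(round(100 * gss$false_positive_rate), 1)
  expect_equal(round(100 * gss$false_negative_rate), 66)

  eq <- validation_confusion(c("a", "b"), c("a", "b"))
  expect_equal(eq$false_positive_rate, 0)
  expect_equal(eq$false_negative_rate, 0)

  snp_called <- sprintf("s%03d", 1:43)
  snp_truth <- c(snp_called[1:30], sprintf("t%03d", 1:28))
  snp <- validation_confusion(snp_called, snp_truth)
  expect_equal(round(100 * snp$false_positive_rate), 30)
  expect_true(is.na(validation_confusion(character(0), "x")$false_positive_rate))
})

test_that("clean deep-coverage runs recover SNPs precisely and GSS alleles exactly", {
  run <- clean_run()
  truth <- run$sim$truth
  snp_calls <- run$calls[label == "SNP"]
  snp_keys <- snp_calls[, paste(target, pos)]
  truth_snp <- truth$snp[, paste(gene, pos)]
  precision <- mean(snp_keys %in% truth_snp)
  expect_gte(precision, 0.95)

  # orientation agrees with the planted mutation direction
  m <- merge(snp_calls, truth$snp,
             by.x = c("target", "pos"), by.y = c("gene", "pos"))
  expect_gt(nrow(m), 0L)
  expect_equal(m$ancestral.x, m$ancestral.y)
  expect_equal(m$derived.x, m$derived.y)
  expect_equal(m$lineage, m$accession)

  gss_calls <- run$calls[label == "GSS"]
  g <- merge(gss_calls, truth$gss,
             by.x = c("target", "pos"), by.y = c("gene", "pos"))
  expect_gt(nrow(g), 0L)
  same_pair <- mapply(function(a1, a2, aa, ab) setequal(c(a1, a2), c(aa, ab)),
                      g$a1, g$a2, g$allele_A, g$allele_B)
  expect_true(all(same_pair))
})
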