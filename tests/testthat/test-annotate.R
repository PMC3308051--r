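toy_model <- list(utr5_len = 10L, cds_len = 30L, utr3_len = 20L)

test_that("positions partition into UTR5/CDS/UTR3 with frame anchoring", {
  expect_equal(locate_region(11L, toy_model)$region, "cds")
  expect_equal(locate_region(11L, toy_model)$codon_index, 0L)
  expect_equal(locate_region(11L, toy_model)$codon_offset, 0L)
  expect_equal(locate_region(10L, toy_model)$region, "utr5")
  expect_equal(locate_region(41L, toy_model)$region, "utr3")
  expect_equal(locate_region(40L, toy_model)$region, "cds")
  expect_equal(locate_region(40L, toy_model)$codon_offset, 2L)
  expect_error(locate_region(0L, toy_model), "outside")
  expect_error(locate_region(61L, toy_model), "outside")

  regions <- vapply(1:60, function(p) locate_region(p, toy_model)$region, "")
  expect_equal(as.vector(table(factor(regions, c("utr5", "cds", "utr3")))),
               c(10L, 30L, 20L))
})

test_that("coding effects follow the standard genetic code", {
  cdna <- paste0(strrep("T", 10),                      # utr5
                 "ATG", "AAA", "CAA", "TAA", strrep("GGC", 6), # cds (30)
                 strrep("T", 20))                      # utr3
  model <- toy_model
  # AAA -> AAG at the third codon position: Lys -> Lys
  syn <- classify_effect(cdna, model, 16L, "A", "G")
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$aa_from, "K")
  # CAA -> TAA: premature stop
  sg <- classify_effect(cdna, model, 17L, "C", "T")
  expect_equal(sg$effect, "stop_gain")
  # TAA -> CAA with ancestral stop: restoration of the ORF
  sl <- classify_effect(cdna, model, 20L, "T", "C")
  expect_equal(sl$effect, "stop_loss")
  # TAA -> TGA: stop to stop is synonymous
  ss <- classify_effect(cdna, model, 21L, "A", "G")
  expect_equal(ss$effect, "synonymous")
  # GGC -> GAC: replacement
  ns <- classify_effect(cdna, model, 24L, "G", "A")
  expect_equal(ns$effect, "nonsynonymous")
  # UTR changes are utr
  expect_equal(classify_effect(cdna, model, 5L, "T", "A")$effect, "utr")
  # ambiguous codon context
  cdna_n <- cdna
  substr(cdna_n, 15, 15) <- "N"
  expect_warning(un <- classify_effect(cdna_n, model, 16L, "A", "G"),
                 "ambiguous")
  expect_equal(un$effect, "unknown")
  expect_error(classify_effect(cdna, model, 16L, "A", "A"), "differ")
})

test_that("SNP density per region matches counts over covered kilobases", {
  eff <- data.table(class = "SNP", lineage = "Ld", region = "cds",
                    effect = "synonymous")[rep(1, 10)]
  d <- density_by_region(eff, c(cds = 5000))
  expect_equal(d$density, 2)
  d0 <- density_by_region(eff[0], c(cds = 5000))
  expect_equal(nrow(d0), 0L)
})

test_that("planted UTR5 SNP rates are recovered from large simulations", {
  # 2 SNPs/kb planted in 5' UTRs; inflate the UTR5 share so the generator
  # plants over >= 50 kb of UTR5 sequence
  cfg <- sim_config(n_genes = 200L, utr5_frac = 0.30, cds_frac = 0.39,
                    utr3_frac = 0.31, n_paralog_genes = 0L,
                    n_homoeolog_deletions = 0L, n_pav_genes = 0L,
                    n_duplicated_families = 0L, seed = 77L)
  sim <- simulate_references(cfg)
  utr5_total <- sum(sim$genes$utr5_len)
  expect_gt(utr5_total, 5e4)
  # both accessions plant at the same rate
  n <- nrow(sim$truth$snp[region == "utr5"])
  expected <- 2 * utr5_total * cfg$snp_rate_utr5
  sd3 <- 3 * sqrt(2 * utr5_total * cfg$snp_rate_utr5)
  expect_lt(abs(n - expected), sd3)

  eff <- data.table(class = "SNP", lineage = sim$truth$snp$accession,
                    region = sim$truth$snp$region, effect = "synonymous")
  dens <- density_by_region(eff, c(utr5 = utr5_total))
  per_acc_expected <- cfg$snp_rate_utr5 * 1000
  expect_lt(max(abs(dens$density - per_acc_expected)),
            3 * sqrt(utr5_total * cfg$snp_rate_utr5) / (utr5_total / 1000))
})

test_that("protein-coding change totals aggregate replacement classes", {
  tab1 <- data.table(
    lineage = c(rep("Ld", 485 + 7 + 5), rep("Td", 363 + 13 + 2)),
    effect = c(rep("nonsynonymous", 485), rep("stop_gain", 7),
               rep("stop_loss", 5),
               rep("nonsynonymous", 363), rep("stop_gain", 13),
               rep("stop_loss", 2))
  )
  s <- protein_change_summary(tab1)
  expect_equal(s$total, 875L)
  expect_equal(s$per_lineage[lineage == "Ld", protein_changes], 497L)
  expect_equal(round(s$per_lineage[lineage == "Ld", share], 3), 0.568)

  none <- protein_change_summary(data.table(lineage = "Ld",
                                            effect = "synonymous"))
  expect_equal(none$total, 0L)

  single <- protein_change_summary(data.table(lineage = "Td",
                                              effect = "nonsynonymous"))
  expect_equal(single$per_lineage$share, 1)
})

test_that("GO enrichment reproduces Fisher tables and flags direction", {
  # 2x2 table: nonsyn/syn x in/out = [[10, 40], [30, 20]]
  genes_in <- sprintf("gi%02d", 1:5)
  genes_out <- sprintf("go%02d", 1:5)
  eff <- data.table(
    target = c(rep(genes_in, length.out = 10), rep(genes_in, length.out = 30),
               rep(genes_out, length.out = 40), rep(genes_out, length.out = 20)),
    effect = c(rep("nonsynonymous", 10), rep("synonymous", 30),
               rep("nonsynonymous", 40), rep("synonymous", 20))
  )
  gomap <- data.table(gene = genes_in, term = "GO:0001")
  res <- go_enrichment(eff, gomap)
  expect_equal(res$nonsyn_in, 10L)
  expect_equal(res$syn_in, 30L)
  expect_equal(res$direction, "under-represented")
  # exhaustive hypergeometric oracle for the two-sided p
  m <- 50L; n_ <- 50L; k <- 40L  # white = non-syn, draws = in-group
  probs <- dhyper(0:40, m, n_, k)
  p_oracle <- sum(probs[probs <= dhyper(10, m, n_, k) * (1 + 1e-7)])
  expect_equal(res$p, p_oracle, tolerance = 1e-9)

  # identical proportions: p = 1, nothing significant
  eff2 <- data.table(
    target = c(rep(genes_in, length.out = 20), rep(genes_out, length.out = 20)),
    effect = rep(c(rep("nonsynonymous", 10), rep("synonymous", 10)), 2)
  )
  res2 <- go_enrichment(eff2, gomap)
  expect_equal(res2$p, 1)
  expect_false(res2$significant)

  # degenerate margins are skipped
  eff3 <- data.table(target = genes_in, effect = "nonsynonymous")
  expect_message(res3 <- go_enrichment(eff3, gomap), "degenerate")
  expect_equal(nrow(res3), 0L)
})

test_that("BH correction matches a step-up oracle across terms", {
  set.seed(30)
  genes <- sprintf("g%02d", 1:40)
  eff <- data.table(
    target = sample(genes, 400, TRUE),
    effect = sample(c("nonsynonymous", "synonymous"), 400, TRUE)
  )
  gomap <- rbindlist(lapply(1:8, function(i) {
    data.table(gene = sample(genes, 12), term = sprintf("GO:%04d", i))
  }))
  res <- go_enrichment(eff, gomap)
  expect_gt(nrow(res), 0L)
  # independent BH step-up implementation
  p <- res$p
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
  adj <- pmin(adj, 1)[order(o)]
  expect_equal(res$fdr, adj, tolerance = 1e-12)
})

test_that("orientation of clean-run SNP effects matches planted truth", {
  run <- clean_run()
  eff <- run$effects
  m <- merge(eff[class == "SNP"], run$sim$truth$snp,
             by.x = c("target", "pos"), by.y = c("gene", "pos"))
  expect_gt(nrow(m), 0L)
  expect_equal(m$region.x, m$region.y)
  expect_equal(m$lineage, m$accession)
})
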