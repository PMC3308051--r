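# End-to-end orchestration: simulate -> demultiplex -> align (+ junction
# rescue) -> pileup -> classify -> CNV/PAV/deletions -> effects, with a run
# report and optional plain-text intermediates.

#' Run the full synthetic capture pipeline
#'
#' Simulates an allotetraploid capture experiment, processes the pooled
#' reads exactly as a real run would (tag demultiplexing, unique alignment
#' with iterative trim rescue, pileup), classifies variable sites, applies
#' flank rescue to SNP calls, detects CNV/PAV and homoeolog deletions, and
#' annotates coding effects. When the truth ledger is used, per-class
#' precision and recall are included in the report.
#'
#' @param config a [sim_config()]
#' @param classifier a [classifier_config()]
#' @param aligner an [aligner_params()]
#' @param alpha per-window CNV significance level
#' @param min_sig_windows significant windows required for a CNV call
#' @param breadth_min coverage breadth required for CNV eligibility
#' @param min_length minimum read length kept by trim rescue
#' @param with_truth include truth-based confusion summaries
#' @param out_dir if non-NULL, write FASTA/FASTQ/TSV/VCF intermediates here
#' @return a list of class `polycap_run`: all intermediate tables plus
#'   `report`
#' @export
run_pipeline <- function(config = sim_config(),
                         classifier = classifier_config(),
                         aligner = aligner_params(),
                         alpha = 0.001, min_sig_windows = 4L,
                         breadth_min = 0.7, min_length = 30L,
                         with_truth = TRUE, out_dir = NULL) {
  accs <- names(config$tag_table)
  sim <- simulate_references(config)
  reads <- simulate_reads(sim)

  dmx <- demultiplex(reads$pool, config$tag_table)
  aln_by_acc <- lapply(stats::setNames(accs, accs), function(a) {
    sub <- dmx$assigned[accession == a]
    res <- align_with_rescue(sub, sim$reference, aligner, min_length)
    res$alignments[, accession := a]
    res
  })
  alignments <- data.table::rbindlist(lapply(aln_by_acc, `[[`, "alignments"),
                                      use.names = TRUE)

  pileup <- build_pileup(alignments, sim$reference)
  summaries <- coverage_summary(pileup)

  structural_genes <- unique(c(sim$truth$paralog$gene, sim$truth$pav$gene,
                               sim$truth$deletion$gene,
                               sim$truth$duplication$gene))
  single_copy <- setdiff(sim$genes$gene, structural_genes)
  mdc_flt <- mdc_target_filter(summaries, single_copy, classifier)

  sites <- call_variable_sites(pileup, classifier)
  calls <- classify_sites(sites, classifier, mdc_flt$excluded, accs)
  raw_by_acc <- lapply(stats::setNames(accs, accs), function(a) {
    dmx$assigned[accession == a, seq]
  })
  calls <- flank_rescue(calls, raw_by_acc, sim$reference, classifier, accs)

  pav <- call_pav(summaries, accessions = accs)
  eligible <- eligible_targets(summaries, breadth_min)
  # whole-gene PAV is the dedicated call for absent targets; they never
  # enter the windowed coverage-ratio detector
  eligible <- setdiff(eligible, pav$target)
  wins <- window_counts(alignments[target %in% eligible],
                        nchar(sim$reference[eligible]), accs)
  cnv <- call_cnv(wins, alpha, min_sig_windows, accs)
  vs_counts <- sites[, .N, by = target]
  vsc <- stats::setNames(vs_counts$N, vs_counts$target)
  non_cnv <- setdiff(eligible, cnv$target)
  baseline <- mean(vsc[non_cnv], na.rm = TRUE)
  if (!is.finite(baseline)) baseline <- 0
  cnv <- cnv_mechanism(cnv, vsc, baseline, accs)
  hdel <- homoeolog_deletion(sites, accessions = accs, targets = eligible)

  effects <- annotate_effects(calls, sim$genes, sim$reference)

  report <- list(
    reads = list(total = nrow(reads$pool),
                 assigned = nrow(dmx$assigned),
                 rejected = nrow(dmx$rejected),
                 aligned = nrow(alignments),
                 rescued = sum(alignments$trim5 + alignments$trim3 > 0),
                 multi_hit = sum(vapply(aln_by_acc, function(x)
                   length(x$multi_hit), 0L)),
                 exhausted = sum(vapply(aln_by_acc, function(x)
                   length(x$exhausted), 0L))),
    coverage = list(mdc_median = stats::median(summaries$mdc_combined),
                    breadth_ge1_mean = mean(summaries$breadth_ge1),
                    mdc_cutoff = mdc_flt$cutoff,
                    n_excluded_targets = length(mdc_flt$excluded)),
    site_calls = as.list(table(calls$label)),
    filter_reasons = as.list(table(calls$filter_reason)),
    structural = list(cnv = nrow(cnv), pav = nrow(pav),
                      homoeolog_deletion = nrow(hdel)),
    effects = as.list(table(effects$effect))
  )
  if (with_truth) {
    called_gss <- calls[label == "GSS", paste(target, pos, sep = ":")]
    truth_gss <- sim$truth$gss[, paste(gene, pos, sep = ":")]
    called_snp <- calls[label == "SNP", paste(target, pos, sep = ":")]
    truth_snp <- sim$truth$snp[, paste(gene, pos, sep = ":")]
    report$confusion <- list(
      GSS = validation_confusion(called_gss, truth_gss),
      SNP = validation_confusion(called_snp, truth_snp)
    )
  }

  run <- structure(list(
    sim = sim, reads = reads, demultiplexed = dmx, alignments = alignments,
    pileup = pileup, summaries = summaries, mdc_filter = mdc_flt,
    sites = sites, calls = calls, windows = wins, cnv = cnv, pav = pav,
    homoeolog_deletions = hdel, effects = effects, report = report
  ), class = "polycap_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_simulation(sim, reads, file.path(out_dir, "sim"))
    write_sam(alignments, sim$reference, file.path(out_dir, "alignments.sam"))
    write_pileup(pileup, file.path(out_dir, "pileup.tsv"))
    write_tsv(summaries, file.path(out_dir, "coverage_summary.tsv"))
    write_vcf(calls, sim$reference, file.path(out_dir, "calls.vcf"))
    write_tsv(calls, file.path(out_dir, "calls.tsv"))
    write_tsv(wins, file.path(out_dir, "cnv_windows.tsv"))
    structural <- data.table::rbindlist(list(
      cnv[, .(target, kind, accession)],
      pav[, .(target, kind, accession)],
      hdel[, .(target, kind, accession)]
    ), use.names = TRUE, fill = TRUE)
    write_tsv(structural, file.path(out_dir, "structural_calls.tsv"))
    write_tsv(effects, file.path(out_dir, "effects.tsv"))
  }
  run
}

#' @export
print.polycap_run <- function(x, ...) {
  r <- x$report
  cat("polycap pipeline run\n")
  cat(sprintf("  reads: %d total, %d assigned, %d aligned (%d rescued, %d multi-hit)\n",
              r$reads$total, r$reads$assigned, r$reads$aligned,
              r$reads$rescued, r$reads$multi_hit))
  cat(sprintf("  coverage: median MDC %.1f, MDC cutoff %.1f (%d targets excluded)\n",
              r$coverage$mdc_median, r$coverage$mdc_cutoff,
              r$coverage$n_excluded_targets))
  cat("  site calls:", paste(names(r$site_calls), unlist(r$site_calls),
                             collapse = ", "), "\n")
  cat(sprintf("  structural: %d CNV, %d PAV, %d homoeolog deletions\n",
              r$structural$cnv, r$structural$pav,
              r$structural$homoeolog_deletion))
  if (!is.null(r$confusion)) {
    cat(sprintf("  GSS: FPR %.3f FNR %.3f | SNP: FPR %.3f FNR %.3f\n",
                r$confusion$GSS$false_positive_rate,
                r$confusion$GSS$false_negative_rate,
                r$confusion$SNP$false_positive_rate,
                r$confusion$SNP$false_negative_rate))
  }
  invisible(x)
}
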