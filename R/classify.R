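# Classification of variable sites in tetraploid capture alignments:
# genome-specific sites (GSS, fixed divergence between the A and B
# subgenomes), lineage SNPs (derived mutation in one accession), and
# filtered artifacts (paralog alignment, repetitive targets, low coverage).
# The classifier operates on exactly two accessions.

#' Classifier configuration
#'
#' @param min_variant_reads minimum pooled reads supporting a second allele
#'   for a position to be considered variable (default 2)
#' @param min_mono_coverage minimum depth to call the non-IVS accession
#'   monomorphic at a SNP site (default 8)
#' @param mdc_percentile percentile of the single-copy MDC distribution
#'   used as the repetitive-target cutoff (default 99)
#' @param mdc_cutoff_override fixed MDC cutoff bypassing the percentile
#' @param mdc_filter_scope `"combined"` (default) or `"per_accession"`:
#'   which MDC the repetitive-target filter inspects
#' @param log2_upper named numeric, per-accession upper threshold on the
#'   log2 reference/alternative coverage ratio (defaults 1.6 and 1.0 for
#'   the first and second accession)
#' @param log2_lower per-accession lower thresholds; default `-log2_upper`
#' @param target_false_ivs_rate target false-IVS discovery rate for
#'   threshold calibration (default 0.05)
#' @param flank_length length of the flank-rescue query in bp (default 40)
#' @param flank_max_mismatches mismatch allowance of the flank scan
#' @param flank_min_overlap minimum read/query overlap in the flank scan
#' @param max_discordant_mono third-allele reads tolerated as sequencing
#'   error before a site is declared triallelic (default 1)
#' @return an object of class `classifier_config`
#' @export
classifier_config <- function(min_variant_reads = 2L,
                              min_mono_coverage = 8L,
                              mdc_percentile = 99,
                              mdc_cutoff_override = NULL,
                              mdc_filter_scope = c("combined", "per_accession"),
                              log2_upper = c(1.6, 1.0),
                              log2_lower = NULL,
                              target_false_ivs_rate = 0.05,
                              flank_length = 40L,
                              flank_max_mismatches = 3L,
                              flank_min_overlap = 20L,
                              max_discordant_mono = 1L) {
  if (mdc_percentile <= 0 || mdc_percentile > 100) {
    stop("mdc_percentile must lie in (0, 100]")
  }
  if (length(log2_upper) != 2L) stop("log2_upper must give two thresholds")
  if (is.null(log2_lower)) log2_lower <- -log2_upper
  if (any(!is.finite(c(log2_upper, log2_lower)))) {
    stop("ratio thresholds must be finite")
  }
  structure(list(
    min_variant_reads = as.integer(min_variant_reads),
    min_mono_coverage = as.integer(min_mono_coverage),
    mdc_percentile = mdc_percentile,
    mdc_cutoff_override = mdc_cutoff_override,
    mdc_filter_scope = match.arg(mdc_filter_scope),
    log2_upper = log2_upper, log2_lower = log2_lower,
    target_false_ivs_rate = target_false_ivs_rate,
    flank_length = as.integer(flank_length),
    flank_max_mismatches = as.integer(flank_max_mismatches),
    flank_min_overlap = as.integer(flank_min_overlap),
    max_discordant_mono = as.integer(max_discordant_mono)
  ), class = "classifier_config")
}

#' Repetitive-target filter from the single-copy MDC distribution
#'
#' The cutoff is the `mdc_percentile`-th percentile (linear interpolation)
#' of the MDC distribution over known single-copy targets, or the explicit
#' override; targets with MDC greater than or equal to the cutoff are
#' excluded from variant calling.
#'
#' @param summaries output of [coverage_summary()]
#' @param single_copy_ids character vector of single-copy target names
#' @param config a [classifier_config()]
#' @return list with `cutoff` and `excluded` (target names)
#' @export
mdc_target_filter <- function(summaries, single_copy_ids,
                              config = classifier_config()) {
  if (is.null(config$mdc_cutoff_override)) {
    sc <- summaries[target %in% single_copy_ids]
    if (nrow(sc) == 0L) stop("single-copy target set is empty")
    cutoff <- unname(stats::quantile(sc$mdc_combined,
                                     config$mdc_percentile / 100, type = 7))
  } else {
    cutoff <- config$mdc_cutoff_override
  }
  if (config$mdc_filter_scope == "combined") {
    excluded <- summaries[mdc_combined >= cutoff, target]
  } else {
    acc_cols <- grep("^mdc_(?!combined)", names(summaries),
                     perl = TRUE, value = TRUE)
    hi <- rowSums(as.matrix(summaries[, acc_cols, with = FALSE]) >= cutoff) > 0
    excluded <- summaries$target[hi]
  }
  list(cutoff = cutoff, excluded = excluded)
}

#' Detect variable sites in a pileup
#'
#' A position is variable when, pooling both accessions, its second most
#' frequent allele is supported by at least `min_variant_reads` reads. The
#' two top pooled alleles define the site's allele pair; per-accession IVS
#' flags mark accessions with at least one read for each pair allele.
#'
#' @param pileup a `polycap_pileup` with exactly two accessions
#' @param config a [classifier_config()]
#' @param targets optional subset of targets to scan
#' @return data.table with one row per variable site: `target`, `pos`,
#'   `ref` (reference base), `a1`/`a2` (pooled major/minor allele),
#'   per-accession pair-allele counts `n1_a1`, `n1_a2`, `n2_a1`, `n2_a2`,
#'   depths `depth1`/`depth2`, third-allele read counts `other1`/`other2`
#'   and IVS flags `ivs1`/`ivs2`; accession order is `pileup$accessions`
#' @export
call_variable_sites <- function(pileup, config = classifier_config(),
                                targets = NULL) {
  if (length(pileup$accessions) != 2L) {
    stop("site classification requires exactly two accessions")
  }
  acc <- pileup$accessions
  if (is.null(targets)) targets <- names(pileup$counts)
  out <- list()
  for (tg in targets) {
    m1 <- pileup$counts[[tg]][[acc[1]]]
    m2 <- pileup$counts[[tg]][[acc[2]]]
    pooled <- m1 + m2
    # second-highest pooled allele count per column
    top2 <- apply(pooled, 2L, function(v) sort(v, decreasing = TRUE)[2L])
    vpos <- which(top2 >= config$min_variant_reads)
    if (!length(vpos)) next
    refb <- substring(pileup$ref_seqs[[tg]], vpos, vpos)
    rows <- lapply(seq_along(vpos), function(j) {
      p <- vpos[j]
      pv <- pooled[, p]
      ord <- order(-pv, BASES)  # count desc, base order for ties
      a1 <- BASES[ord[1]]; a2 <- BASES[ord[2]]
      data.table::data.table(
        target = tg, pos = p, ref = refb[j], a1 = a1, a2 = a2,
        n1_a1 = m1[a1, p], n1_a2 = m1[a2, p],
        n2_a1 = m2[a1, p], n2_a2 = m2[a2, p],
        depth1 = sum(m1[, p]), depth2 = sum(m2[, p]),
        other1 = sum(m1[, p]) - m1[a1, p] - m1[a2, p],
        other2 = sum(m2[, p]) - m2[a1, p] - m2[a2, p],
        third_pooled = if (length(pv) > 2L) sort(pv, decreasing = TRUE)[3L] else 0L
      )
    })
    out[[length(out) + 1L]] <- data.table::rbindlist(rows)
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(target = character(), pos = integer(),
                           ref = character(), a1 = character(), a2 = character(),
                           n1_a1 = integer(), n1_a2 = integer(),
                           n2_a1 = integer(), n2_a2 = integer(),
                           depth1 = integer(), depth2 = integer(),
                           other1 = integer(), other2 = integer(),
                           third_pooled = integer())
  res[, `:=`(ivs1 = n1_a1 >= 1L & n1_a2 >= 1L,
             ivs2 = n2_a1 >= 1L & n2_a2 >= 1L)]
  res[]
}

#' Log2 ratio of reference-matching to alternative variant coverage
#'
#' @param ref_count reads supporting the variant matching the reference base
#' @param alt_count reads supporting the alternative variant
#' @return log2(ref_count / alt_count)
#' @export
log2_variant_ratio <- function(ref_count, alt_count) {
  if (any(ref_count <= 0) || any(alt_count <= 0)) {
    stop("both variants need at least one read to form a coverage ratio")
  }
  log2(ref_count / alt_count)
}

#' Calibrate the upper log2 ratio threshold from validated IVS sets
#'
#' Returns the largest threshold u, searched over the merged observed
#' ratios, such that among sites with ratio <= u the fraction drawn from
#' the false-IVS sample stays at or below `target_rate`.
#'
#' @param true_ratios log2 ratios of validated true IVSs
#' @param false_ratios log2 ratios of sites that failed validation
#' @param target_rate tolerated false-IVS fraction (default 0.05)
#' @return the calibrated upper threshold
#' @export
calibrate_ratio_thresholds <- function(true_ratios, false_ratios,
                                       target_rate = 0.05) {
  if (length(true_ratios) == 0L) stop("true-IVS ratio sample is empty")
  if (length(false_ratios) == 0L) return(max(true_ratios))
  cand <- sort(unique(c(true_ratios, false_ratios)))
  n_t <- findInterval(cand, sort(true_ratios))
  n_f <- findInterval(cand, sort(false_ratios))
  ok <- (n_t + n_f) > 0 & n_f / (n_t + n_f) <= target_rate
  if (!any(ok)) {
    warning("no threshold attains the target false-IVS rate; ",
            "returning the minimum observed ratio")
    return(min(cand))
  }
  max(cand[ok])
}

#' Simulate log2 coverage-ratio samples for true and false IVSs
#'
#' True IVSs draw their allele counts from a binomial 1:1 split (with a
#' configurable bias toward the reference allele) at Poisson depth; false
#' IVSs emulate paralog contamination where three reference-like copies
#' face one alternative copy. Draws are conditioned on both variants being
#' seen at least once, as required for a site to enter the IVS set.
#'
#' @param n_true,n_false sample sizes
#' @param lambda mean site depth
#' @param ref_bias reference-allele probability for true IVSs
#' @param paralog_ref_fraction reference-allele probability under paralog
#'   contamination (default 0.75, the 3:1 expectation)
#' @return list with numeric vectors `true` and `false`
#' @export
simulate_ivs_ratios <- function(n_true, n_false, lambda = 13,
                                ref_bias = 0.55,
                                paralog_ref_fraction = 0.75) {
  draw <- function(n, p) {
    out <- numeric(0)
    while (length(out) < n) {
      depth <- stats::rpois(2L * n, lambda)
      depth <- depth[depth >= 2L]
      x <- stats::rbinom(length(depth), depth, p)
      keep <- x >= 1L & x <= depth - 1L
      out <- c(out, log2(x[keep] / (depth[keep] - x[keep])))
    }
    out[seq_len(n)]
  }
  list(true = draw(n_true, ref_bias), false = draw(n_false, paralog_ref_fraction))
}

#' Classify variable sites into GSS, SNP or filtered
#'
#' A site is a GSS when both accessions carry both pair alleles; a SNP when
#' exactly one accession is an IVS and the other is monomorphic for one of
#' the pair alleles at sufficient depth (the shared allele is ancestral,
#' the unshared allele derived, and the IVS-bearing accession is the
#' derived lineage). Sites failing the per-accession log2 coverage-ratio
#' window, showing a third allele, lacking monomorphic coverage, or lying
#' on excluded targets are filtered with a reason.
#'
#' @param sites output of [call_variable_sites()]
#' @param config a [classifier_config()]
#' @param excluded_targets targets removed by [mdc_target_filter()]
#' @param accessions accession names in the order of the site columns
#' @return the site table with `label` (GSS/SNP/filtered), `filter_reason`,
#'   `lineage`, `ancestral`, `derived`, and per-accession `ratio1`/`ratio2`
#' @export
classify_sites <- function(sites, config = classifier_config(),
                           excluded_targets = character(),
                           accessions = c("Ld", "Td")) {
  n <- nrow(sites)
  sites <- data.table::copy(sites)
  sites[, `:=`(label = NA_character_, filter_reason = NA_character_,
               lineage = NA_character_, ancestral = NA_character_,
               derived = NA_character_,
               ratio1 = NA_real_, ratio2 = NA_real_)]
  if (n == 0L) return(sites[])
  up <- config$log2_upper; lo <- config$log2_lower

  for (i in seq_len(n)) {
    s <- sites[i]
    if (s$target %in% excluded_targets) {
      sites[i, `:=`(label = "filtered", filter_reason = "high_mdc_target")]
      next
    }
    # third allele beyond the sequencing-error tolerance?
    ref_in_pair <- s$ref %in% c(s$a1, s$a2)
    if (s$third_pooled > config$max_discordant_mono || !ref_in_pair) {
      sites[i, `:=`(label = "filtered", filter_reason = "triallelic")]
      next
    }
    ref_is_a1 <- s$ref == s$a1
    r1 <- if (s$ivs1) log2_variant_ratio(
      if (ref_is_a1) s$n1_a1 else s$n1_a2,
      if (ref_is_a1) s$n1_a2 else s$n1_a1) else NA_real_
    r2 <- if (s$ivs2) log2_variant_ratio(
      if (ref_is_a1) s$n2_a1 else s$n2_a2,
      if (ref_is_a1) s$n2_a2 else s$n2_a1) else NA_real_
    sites[i, `:=`(ratio1 = r1, ratio2 = r2)]
    ratio_bad <- (s$ivs1 && (r1 < lo[1] || r1 > up[1])) ||
                 (s$ivs2 && (r2 < lo[2] || r2 > up[2]))
    if (ratio_bad) {
      sites[i, `:=`(label = "filtered", filter_reason = "ratio_out_of_range")]
      next
    }
    if (s$ivs1 && s$ivs2) {
      sites[i, label := "GSS"]
    } else if (s$ivs1 || s$ivs2) {
      ivs_first <- s$ivs1
      mono_depth <- if (ivs_first) s$depth2 else s$depth1
      mono_a1 <- if (ivs_first) s$n2_a1 else s$n1_a1
      mono_a2 <- if (ivs_first) s$n2_a2 else s$n1_a2
      mono_other <- if (ivs_first) s$other2 else s$other1
      if (mono_other > config$max_discordant_mono) {
        sites[i, `:=`(label = "filtered", filter_reason = "triallelic")]
      } else if (mono_depth < config$min_mono_coverage) {
        sites[i, `:=`(label = "filtered", filter_reason = "low_mono_coverage")]
      } else {
        anc_allele <- if (mono_a1 > 0L) s$a1 else s$a2
        der_allele <- if (mono_a1 > 0L) s$a2 else s$a1
        sites[i, `:=`(label = "SNP",
                      lineage = accessions[if (ivs_first) 1L else 2L],
                      ancestral = anc_allele, derived = der_allele)]
      }
    } else {
      # both accessions fixed (for different alleles): homoeolog-deletion
      # signature, not classifiable as GSS or SNP
      sites[i, `:=`(label = "filtered", filter_reason = "no_ivs")]
    }
  }
  sites[]
}

#' Rescue hidden GSSs among SNP calls by scanning raw reads
#'
#' For each SNP call, a query of `flank_length` bp of reference context
#' centred on the site carries the candidate missing (derived) variant; the
#' monomorphic accession's raw reads are scanned on both strands for a
#' match with at most `flank_max_mismatches` mismatches covering the site.
#' A hit means the second variant exists but its diverged reads failed
#' alignment: the SNP call is re-labelled filtered/flank_rescued.
#'
#' @param calls classified site table (only rows with `label == "SNP"` are
#'   inspected)
#' @param reads_by_accession named list of raw read pools (data.tables with
#'   `seq`, or character vectors), one per accession
#' @param reference named character vector of target sequences
#' @param config a [classifier_config()]
#' @param accessions accession names in site-column order
#' @return the call table with rescued SNPs re-labelled and a logical
#'   `flank_rescued` column
#' @export
flank_rescue <- function(calls, reads_by_accession, reference,
                         config = classifier_config(),
                         accessions = c("Ld", "Td")) {
  calls <- data.table::copy(calls)
  calls[, flank_rescued := FALSE]
  idx <- which(calls$label == "SNP")
  if (!length(idx)) return(calls[])
  fl <- config$flank_length
  queries <- character(length(idx))
  centers <- integer(length(idx))
  mono_acc <- character(length(idx))
  shrunk <- FALSE
  for (j in seq_along(idx)) {
    s <- calls[idx[j]]
    tlen <- nchar(reference[[s$target]])
    start <- s$pos - floor(fl / 2)
    if (start < 1L || start + fl - 1L > tlen) shrunk <- TRUE
    start <- max(1L, min(start, tlen - fl + 1L))
    end <- min(tlen, start + fl - 1L)
    q <- substring(reference[[s$target]], start, end)
    center <- s$pos - start + 1L
    substr(q, center, center) <- s$derived
    queries[j] <- q
    centers[j] <- center
    mono_acc[j] <- setdiff(accessions, s$lineage)
  }
  if (shrunk) warning("flank query shrunk at target boundary")
  for (a in unique(mono_acc)) {
    pool <- reads_by_accession[[a]]
    if (is.data.frame(pool)) pool <- pool$seq
    sel <- which(mono_acc == a)
    if (length(pool) == 0L) next
    found <- .cpp_flank_scan(queries[sel], centers[sel], pool,
                             config$flank_max_mismatches,
                             config$flank_min_overlap)
    hit <- idx[sel][found]
    if (length(hit)) {
      calls[hit, `:=`(label = "filtered", filter_reason = "flank_rescued",
                      flank_rescued = TRUE)]
    }
  }
  calls[]
}

#' Expected number of divergent sites with only one variant sequenced
#'
#' Under Poisson depth with mean `lambda` and equal sampling of the two
#' variants, the chance that a divergent site shows only one variant is
#' `2 exp(-lambda)`; multiplying by the expected number of divergent sites
#' `divergence_d * target_length` gives the expected count of such sites.
#' The per-site probability is capped at 1.
#'
#' @param lambda mean read depth at a site (> 0)
#' @param divergence_d per-bp divergence between the subgenomes
#' @param target_length total target length in bp
#' @return expected number of one-variant divergent sites
#' @export
#' @examples
#' expected_missed_variant_sites(13, 0.02, 3.5e6)  # about 0.3
expected_missed_variant_sites <- function(lambda, divergence_d, target_length) {
  if (lambda <= 0) stop("lambda must be positive")
  min(1, 2 * exp(-lambda)) * divergence_d * target_length
}

#' Confusion summary between called and true variant sets
#'
#' Sets are compared by identity keys (e.g. `target:pos:class`). The false
#' positive rate is the fraction of calls absent from the truth; the false
#' negative rate is the fraction of the truth never called.
#'
#' @param called character vector (or data.frame whose columns are pasted
#'   into keys) of called variants
#' @param truth same representation of the true variants
#' @return list with `false_positive_rate`, `false_negative_rate`,
#'   `shared`, `n_called`, `n_truth`
#' @export
validation_confusion <- function(called, truth) {
  as_keys <- function(x) {
    if (is.data.frame(x)) do.call(paste, c(as.list(x), sep = ":")) else
      as.character(x)
  }
  ck <- unique(as_keys(called))
  tk <- unique(as_keys(truth))
  shared <- length(intersect(ck, tk))
  list(
    false_positive_rate = if (length(ck)) (length(ck) - shared) / length(ck)
                          else NA_real_,
    false_negative_rate = if (length(tk)) (length(tk) - shared) / length(tk)
                          else NA_real_,
    shared = shared, n_called = length(ck), n_truth = length(tk)
  )
}

#' Write classified sites as a minimal VCF 4.2 file
#'
#' @param calls classified site table
#' @param reference named character vector (contig headers)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, reference, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(reference),
                   nchar(reference)),
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"GSS or SNP\">",
           "##INFO=<ID=LINEAGE,Number=1,Type=String,Description=\"Derived lineage\">",
           "##INFO=<ID=ANC,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##INFO=<ID=DER,Number=1,Type=String,Description=\"Derived allele\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(calls)), function(i) {
    s <- calls[i]
    alt <- if (s$ref == s$a1) s$a2 else s$a1
    info <- if (!is.na(s$label) && s$label == "SNP") {
      sprintf("CLASS=SNP;LINEAGE=%s;ANC=%s;DER=%s",
              s$lineage, s$ancestral, s$derived)
    } else if (!is.na(s$label) && s$label == "GSS") {
      "CLASS=GSS"
    } else {
      "CLASS=filtered"
    }
    filt <- if (!is.na(s$label) && s$label == "filtered") s$filter_reason else "PASS"
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
            s$target, s$pos, s$ref, alt, filt, info)
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
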