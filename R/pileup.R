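# Per-base, per-accession allele counts over cDNA targets, and the coverage
# summaries (MDC, breadth, expected depth, enrichment) built on them.

#' Build a per-base, per-accession pileup from alignments
#'
#' Every aligned base contributes exactly one count to the column of its
#' target position in its accession. Columns with zero depth are retained
#' (zero-coverage bases enter the median and breadth statistics).
#'
#' @param alignments data.table with `target`, `pos`, `seq`
#'   (reference-oriented) and `accession`
#' @param reference named character vector of target sequences
#' @return object of class `polycap_pileup`: a list with `counts` (per
#'   target, per accession, a 4 x length integer matrix with rows
#'   A/C/G/T), `accessions`, `ref_seqs` and `target_lengths`
#' @export
build_pileup <- function(alignments, reference) {
  stopifnot(all(c("target", "pos", "seq", "accession") %in% names(alignments)))
  tlen <- nchar(reference)
  accs <- sort(unique(alignments$accession))
  aln <- alignments[!is.na(target)]
  bad <- aln[pos < 1L | pos + nchar(seq) - 1L > tlen[target]]
  if (nrow(bad)) {
    stop("alignment exceeds target bounds on ", bad$target[1])
  }
  lens <- nchar(aln$seq)
  long <- data.table::data.table(
    target = rep(aln$target, lens),
    accession = rep(aln$accession, lens),
    pos = sequence(lens, from = aln$pos),
    base = unlist(strsplit(aln$seq, "", fixed = TRUE))
  )
  long <- long[base %in% BASES]
  tab <- long[, .N, by = .(target, accession, pos, base)]

  counts <- lapply(stats::setNames(names(reference), names(reference)), function(tg) {
    lapply(stats::setNames(accs, accs), function(a) {
      m <- matrix(0L, nrow = 4L, ncol = tlen[[tg]], dimnames = list(BASES, NULL))
      sub <- tab[target == tg & accession == a]
      if (nrow(sub)) m[cbind(match(sub$base, BASES), sub$pos)] <- sub$N
      m
    })
  })
  structure(list(counts = counts, accessions = accs,
                 ref_seqs = reference, target_lengths = tlen),
            class = "polycap_pileup")
}

#' Per-base depth of one target
#' @param pileup a `polycap_pileup`
#' @param target target name
#' @param accession accession name, or NULL for the summed (combined) depth
#' @return integer vector of depths along the target
#' @export
pileup_depth <- function(pileup, target, accession = NULL) {
  mats <- pileup$counts[[target]]
  if (is.null(mats)) stop("unknown target: ", target)
  if (is.null(accession)) {
    Reduce(`+`, lapply(mats, colSums))
  } else {
    colSums(mats[[accession]])
  }
}

#' Coverage summaries per target
#'
#' Median depth of coverage (MDC) is computed over all target bases,
#' zero-coverage bases included; breadth is the fraction of bases covered at
#' depth >= 1 (and >= 2) in the pooled alignment. Per-accession MDC and
#' breadth columns are named `mdc_<accession>` / `breadth1_<accession>`.
#'
#' @param pileup a `polycap_pileup`
#' @return data.table with one row per target
#' @export
coverage_summary <- function(pileup) {
  rows <- lapply(names(pileup$counts), function(tg) {
    per_acc <- lapply(pileup$counts[[tg]], colSums)
    comb <- Reduce(`+`, per_acc)
    row <- data.table::data.table(target = tg, len = length(comb))
    for (a in pileup$accessions) {
      row[[paste0("mdc_", a)]] <- stats::median(per_acc[[a]])
      row[[paste0("breadth1_", a)]] <- mean(per_acc[[a]] >= 1L)
    }
    row$mdc_combined <- stats::median(comb)
    row$breadth_ge1 <- mean(comb >= 1L)
    row$breadth_ge2 <- mean(comb >= 2L)
    row
  })
  data.table::rbindlist(rows)
}

#' Expected median depth of coverage
#'
#' The depth expected if aligned bases were spread uniformly over the
#' target space: total aligned bases divided by total target length.
#'
#' @param total_aligned_bases total number of aligned bases (bp)
#' @param total_target_length total targeted length (bp)
#' @return expected reads per base
#' @export
#' @examples
#' expected_mdc(383e6, 3.5e6)  # about 109 reads per base
expected_mdc <- function(total_aligned_bases, total_target_length) {
  if (total_target_length <= 0) stop("target length must be positive")
  if (total_aligned_bases < 0) stop("aligned bases must be non-negative")
  total_aligned_bases / total_target_length
}

#' Fold enrichment of target sequence in a capture
#'
#' Ratio of the on-target read fraction to the genomic fraction the targets
#' represent.
#'
#' @param on_target_fraction fraction of sequenced bases on target, in (0, 1]
#' @param genomic_target_fraction fraction of the genome that is targeted,
#'   in (0, 1]
#' @return fold enrichment
#' @export
fold_enrichment <- function(on_target_fraction, genomic_target_fraction) {
  if (genomic_target_fraction <= 0) stop("genomic target fraction must be > 0")
  if (on_target_fraction <= 0 || on_target_fraction > 1 ||
      genomic_target_fraction > 1) {
    stop("fractions must lie in (0, 1]")
  }
  on_target_fraction / genomic_target_fraction
}

#' Export a pileup as a long TSV
#'
#' One row per (target, accession, position) with A/C/G/T counts and depth.
#' Zero-depth rows are omitted from the file (breadth statistics use the
#' in-memory object).
#'
#' @param pileup a `polycap_pileup`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pileup <- function(pileup, path) {
  rows <- list()
  for (tg in names(pileup$counts)) {
    for (a in pileup$accessions) {
      m <- pileup$counts[[tg]][[a]]
      nz <- which(colSums(m) > 0L)
      if (!length(nz)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        target = tg, pos = nz, accession = a,
        A = m["A", nz], C = m["C", nz], G = m["G", nz], T = m["T", nz],
        depth = colSums(m)[nz]
      )
    }
  }
  write_tsv(data.table::rbindlist(rows), path)
}

#' Export combined per-base depth as BEDGraph
#'
#' @param pileup a `polycap_pileup`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(pileup, path) {
  lines <- character(0)
  for (tg in names(pileup$counts)) {
    d <- pileup_depth(pileup, tg)
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d", tg, starts, ends, r$values))
  }
  writeLines(lines, path)
  invisible(path)
}
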