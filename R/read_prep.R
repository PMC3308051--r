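# Read preparation: tag demultiplexing, bowtie-like unique alignment and the
# iterative trim-and-realign rescue of exon junction reads.

#' Aligner parameter set
#'
#' Semantics follow short-read aligners of the bowtie generation: ungapped
#' end-to-end placement, at most `max_seed_mismatches` mismatches within the
#' first `seed_length` bases, a total mismatch ceiling approximating the
#' quality-sum limit, and suppression of reads with more than one valid
#' placement when `unique_only` is set.
#'
#' @param seed_length seed length in bases (default 28)
#' @param max_seed_mismatches mismatch cap inside the seed (default 2)
#' @param max_total_mismatches mismatch cap over the whole read (default 3)
#' @param unique_only suppress multi-hit reads (default TRUE)
#' @return an object of class `aligner_params`
#' @export
aligner_params <- function(seed_length = 28L, max_seed_mismatches = 2L,
                           max_total_mismatches = 3L, unique_only = TRUE) {
  p <- list(seed_length = as.integer(seed_length),
            max_seed_mismatches = as.integer(max_seed_mismatches),
            max_total_mismatches = as.integer(max_total_mismatches),
            unique_only = isTRUE(unique_only))
  if (p$seed_length < 1L) stop("seed_length must be positive")
  if (p$max_seed_mismatches < 0L || p$max_total_mismatches < 0L) {
    stop("mismatch caps must be >= 0")
  }
  structure(p, class = "aligner_params")
}

#' Demultiplex tagged reads into accessions
#'
#' Reads whose first four bases carry any phred score below
#' `min_tag_quality` are rejected. Remaining reads are assigned by the
#' longest tag prefix matching the read start; a read matching no tag goes
#' to the no-tag accession if the table maps an empty-string tag, otherwise
#' it is rejected. Matched tags are trimmed from sequence and quality.
#'
#' @param reads data.table with `read_id`, `seq`, `qual` (see [read_fastq()])
#' @param tag_table named character vector mapping accession to tag prefix;
#'   names may repeat (several tags per accession) and an entry with tag
#'   `""` declares the no-tag class
#' @param min_tag_quality minimum phred score over the first four bases
#' @return list with `assigned` (read table plus `accession` and the trimmed
#'   sequence/quality) and `rejected` (`read_id`, `reason`)
#' @export
demultiplex <- function(reads, tag_table, min_tag_quality = 15L) {
  tags <- unname(tag_table)
  if (anyDuplicated(tags)) {
    stop("tag table contains two identical tags: configuration error")
  }
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0L) {
    return(list(assigned = data.table::data.table(reads, accession = character(0)),
                rejected = data.table::data.table(read_id = character(0),
                                                  reason = character(0))))
  }
  min_q4 <- vapply(substr(reads$qual, 1L, 4L),
                   function(q) min(utf8ToInt(q)) - 33L, 0L, USE.NAMES = FALSE)
  low_q <- min_q4 < min_tag_quality

  acc <- rep(NA_character_, n)
  trim <- rep(0L, n)
  ord <- order(-nchar(tags))
  for (i in ord) {
    if (!nzchar(tags[i])) next
    hit <- is.na(acc) & !low_q & startsWith(reads$seq, tags[i])
    acc[hit] <- names(tag_table)[i]
    trim[hit] <- nchar(tags[i])
  }
  notag_idx <- which(!nzchar(tags))
  if (length(notag_idx) == 1L) {
    hit <- is.na(acc) & !low_q
    acc[hit] <- names(tag_table)[notag_idx]
  }
  keep <- !is.na(acc)
  assigned <- reads[keep]
  assigned[, accession := acc[keep]]
  tr <- trim[keep]
  assigned[, `:=`(seq = substring(seq, tr + 1L),
                  qual = substring(qual, tr + 1L))]
  rejected <- data.table::data.table(
    read_id = reads$read_id[!keep],
    reason = ifelse(low_q[!keep], "low_tag_quality", "no_tag_match")
  )
  list(assigned = assigned, rejected = rejected)
}

align_status <- c("aligned", "no_hit", "multi_hit")

#' Align reads to a set of cDNA targets
#'
#' Ungapped end-to-end alignment against both strands of every target with
#' bowtie-like uniqueness semantics (see [aligner_params()]). Reverse-strand
#' hits are reported in reference coordinates with the read sequence
#' reverse-complemented.
#'
#' @param reads data.table with `read_id` and `seq`, or a character vector
#' @param reference named character vector of target sequences
#' @param params an [aligner_params()] object
#' @return data.table with `read_id`, `status`
#'   (aligned/no_hit/multi_hit), `target`, `pos` (1-based), `strand`, `nm`
#'   (mismatch count) and `seq` (reference-oriented read sequence)
#' @export
align_reads <- function(reads, reference, params = aligner_params()) {
  if (length(reference) == 0L) stop("empty reference")
  if (is.character(reads)) {
    reads <- data.table::data.table(
      read_id = if (is.null(names(reads))) as.character(seq_along(reads))
                else names(reads),
      seq = unname(reads))
  }
  if (nrow(reads) == 0L) {
    return(data.table::data.table(read_id = character(), status = character(),
                                  target = character(), pos = integer(),
                                  strand = character(), nm = integer(),
                                  seq = character()))
  }
  res <- .cpp_align_batch(reads$seq, unname(reference),
                          params$seed_length, params$max_seed_mismatches,
                          params$max_total_mismatches, params$unique_only)
  out <- data.table::data.table(
    read_id = reads$read_id,
    status = align_status[res$status],
    target = names(reference)[res$target],
    pos = res$pos, strand = res$strand, nm = res$nm,
    seq = reads$seq
  )
  rev <- which(out$strand == "-")
  if (length(rev)) out$seq[rev] <- revcomp_chr(out$seq[rev])
  out
}

#' Iteratively trim unaligned reads and re-align
#'
#' Reads that fail to align (typically because they straddle an exon-intron
#' junction) are trimmed one base at a time and re-aligned, keeping a
#' minimum read length. At each trimmed length all splits of the trim
#' between the 3' and 5' ends are tried, 3'-heavy candidates first, and the
#' first candidate with a unique alignment wins.
#'
#' @param reads data.table with `read_id`, `seq` of previously unaligned reads
#' @param reference named character vector of target sequences
#' @param params an [aligner_params()] object
#' @param min_length smallest read length retained after trimming
#' @return list with `alignments` (as [align_reads()] plus `trim5`, `trim3`)
#'   and `exhausted` (read ids that never aligned)
#' @export
iterative_trim_align <- function(reads, reference, params = aligner_params(),
                                 min_length = 30L) {
  pending <- data.table::as.data.table(reads)[, .(read_id, seq)]
  rescued <- list()
  k <- 0L
  while (nrow(pending) > 0L) {
    k <- k + 1L
    pending <- pending[nchar(seq) - k >= min_length]
    if (nrow(pending) == 0L) break
    # candidates at this level: trim3 = k..0, trim5 = k - trim3
    cand <- data.table::rbindlist(lapply(k:0L, function(t3) {
      t5 <- k - t3
      data.table::data.table(
        read_id = pending$read_id,
        trim5 = t5, trim3 = t3,
        cseq = substring(pending$seq, t5 + 1L, nchar(pending$seq) - t3),
        rank = k - t3  # 0 = all-3' candidate, tried first
      )
    }))
    aln <- align_reads(cand[, .(read_id = paste0(read_id, "#", rank), seq = cseq)],
                       reference, params)
    cand[, status := aln$status]
    hit <- cand[status == "aligned"]
    if (nrow(hit) > 0L) {
      data.table::setorder(hit, read_id, rank)
      hit <- hit[!duplicated(read_id)]
      sub <- aln[match(paste0(hit$read_id, "#", hit$rank), aln$read_id)]
      sub[, read_id := hit$read_id]
      sub[, `:=`(trim5 = hit$trim5, trim3 = hit$trim3)]
      rescued[[length(rescued) + 1L]] <- sub
      pending <- pending[!read_id %in% hit$read_id]
    }
  }
  alignments <- if (length(rescued)) data.table::rbindlist(rescued) else
    data.table::data.table(read_id = character(), status = character(),
                           target = character(), pos = integer(),
                           strand = character(), nm = integer(),
                           seq = character(), trim5 = integer(),
                           trim3 = integer())
  list(alignments = alignments, exhausted = setdiff(reads$read_id, alignments$read_id))
}

#' Trim mismatches near alignment edges
#'
#' Reads crossing exon-intron junctions can align end-to-end while still
#' carrying a short run of intronic bases at one end (the mismatch caps
#' tolerate them). Such residues produce clustered artifact variant columns
#' shared by every read over the junction. Mismatches within `edge` bases
#' of either alignment end are therefore distrusted: the alignment is
#' trimmed through them (iteratively, so a run of edge mismatches is
#' removed) while the minimum length holds. Alignments falling below
#' `min_length` are dropped.
#'
#' @param alignments data.table from [align_reads()] (aligned rows)
#' @param reference named character vector of target sequences
#' @param edge terminal window, in bases, within which mismatches are
#'   distrusted (default 3, the total mismatch cap)
#' @param min_length minimum retained alignment length
#' @return the alignment table with `pos`, `seq`, `nm`, `trim5`, `trim3`
#'   updated and over-trimmed rows removed
#' @export
trim_edge_mismatches <- function(alignments, reference, edge = 3L,
                                 min_length = 30L) {
  if (edge <= 0L || nrow(alignments) == 0L) return(alignments)
  aln <- data.table::copy(alignments)
  if (!"trim5" %in% names(aln)) aln[, `:=`(trim5 = 0L, trim3 = 0L)]
  keep <- rep(TRUE, nrow(aln))
  idx <- which(aln$nm > 0L)
  for (i in idx) {
    s <- utf8ToInt(aln$seq[i])
    len <- length(s)
    r <- utf8ToInt(substring(reference[[aln$target[i]]], aln$pos[i],
                             aln$pos[i] + len - 1L))
    mm <- which(s != r)
    lo <- 1L; hi <- len
    repeat {
      m <- mm[mm >= lo & mm <= hi]
      right <- m[m > hi - edge]
      left <- m[m < lo + edge]
      if (length(right)) hi <- max(right) - 1L
      else if (length(left)) lo <- min(left) + 1L
      else break
      if (hi - lo + 1L < min_length) break
    }
    if (hi - lo + 1L < min_length) { keep[i] <- FALSE; next }
    if (lo > 1L || hi < len) {
      cut5 <- lo - 1L; cut3 <- len - hi
      aln$seq[i] <- substring(aln$seq[i], lo, hi)
      aln$pos[i] <- aln$pos[i] + cut5
      aln$nm[i] <- sum(mm >= lo & mm <= hi)
      if (aln$strand[i] == "+") {
        aln$trim5[i] <- aln$trim5[i] + cut5
        aln$trim3[i] <- aln$trim3[i] + cut3
      } else {
        aln$trim5[i] <- aln$trim5[i] + cut3
        aln$trim3[i] <- aln$trim3[i] + cut5
      }
    }
  }
  aln[keep]
}

#' Align reads with junction-read rescue
#'
#' Full-length alignment followed by [iterative_trim_align()] on the no-hit
#' reads and [trim_edge_mismatches()] on everything aligned. Multi-hit
#' reads are never rescued (they are suppressed, not unalignable).
#'
#' @inheritParams iterative_trim_align
#' @param edge_trim terminal window for [trim_edge_mismatches()]; 0 disables
#' @return list with `alignments` (aligned reads incl. trim history),
#'   `multi_hit` (suppressed read ids) and `exhausted` (unalignable read ids)
#' @export
align_with_rescue <- function(reads, reference, params = aligner_params(),
                              min_length = 30L, edge_trim = 3L) {
  first <- align_reads(reads, reference, params)
  ok <- first[status == "aligned"]
  if (nrow(ok)) ok[, `:=`(trim5 = 0L, trim3 = 0L)]
  nohit <- first[status == "no_hit", .(read_id, seq)]
  # trim candidates work on the original (forward) read sequence
  nohit[, seq := reads$seq[match(read_id, reads$read_id)]]
  res <- iterative_trim_align(nohit, reference, params, min_length)
  alignments <- data.table::rbindlist(list(ok, res$alignments),
                                      use.names = TRUE)
  alignments <- trim_edge_mismatches(alignments, reference, edge_trim,
                                     min_length)
  list(
    alignments = alignments,
    multi_hit = first[status == "multi_hit", read_id],
    exhausted = setdiff(reads$read_id,
                        c(alignments$read_id,
                          first[status == "multi_hit", read_id]))
  )
}

#' Write alignments as minimal SAM records
#'
#' Emits an unsorted SAM file with `@SQ` headers, flag 0/16 for strand,
#' full-length match CIGAR and an `NM` tag — enough for inspection with
#' standard tools.
#'
#' @param alignments data.table from [align_reads()] / [align_with_rescue()]
#' @param reference named character vector used for the `@SQ` headers
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sam <- function(alignments, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  aln <- alignments[status == "aligned"]
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                  aln$read_id, ifelse(aln$strand == "-", 16L, 0L),
                  aln$target, aln$pos, nchar(aln$seq), aln$seq, aln$nm)
  writeLines(c(hdr, body), path)
  invisible(path)
}
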