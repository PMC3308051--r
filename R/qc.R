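# Assay-design quality metrics: GC screen, 2-bit k-mer abundance index and
# repetitive-target flagging.

#' Build a k-mer frequency index
#'
#' Enumerates every k-mer window of the input sequences into a 2-bit-encoded
#' count table. Windows containing non-ACGT bases are skipped. Counting is
#' strand-specific by default, matching a cDNA-versus-genome abundance
#' screen; set `canonical` to merge reverse complements.
#'
#' @param sequences character vector of upper-case DNA sequences
#' @param k k-mer size, at most 32 (one 64-bit word at 2 bits per base)
#' @param canonical merge each k-mer with its reverse complement
#' @return object of class `kmer_index`: list with `k`, `canonical`,
#'   `counts` (data.table `kmer`, `count`, sorted by encoded value) and
#'   `total` (total windows counted)
#' @export
build_kmer_index <- function(sequences, k = 32L, canonical = FALSE) {
  k <- as.integer(k)
  if (k > 32L) stop("k must be <= 32 to fit one 64-bit word")
  if (k < 1L) stop("k must be positive")
  counts <- data.table::as.data.table(
    .cpp_kmer_count(as.character(sequences), k, isTRUE(canonical)))
  structure(list(k = k, canonical = isTRUE(canonical),
                 counts = counts, total = sum(counts$count)),
            class = "kmer_index")
}

#' Encode k-mers into their 2-bit representation
#'
#' @param kmers character vector of A/C/G/T strings of length <= 32
#' @return character vector of 16-digit hexadecimal encodings
#' @export
kmer_encode <- function(kmers) {
  .cpp_kmer_encode(as.character(kmers))
}

#' Decode 2-bit k-mer encodings back to sequence
#'
#' @param codes hexadecimal encodings from [kmer_encode()]
#' @param k the k-mer length
#' @return character vector of k-mers
#' @export
kmer_decode <- function(codes, k) {
  .cpp_kmer_decode(as.character(codes), as.integer(k))
}

#' Median genome abundance of a target sequence
#'
#' Looks up every k-mer window of the target in a genome index and returns
#' the median count; targets rich in genome-abundant k-mers flag as
#' repetitive.
#'
#' @param target_seq target sequence (length >= k)
#' @param index a [build_kmer_index()] over the genome
#' @return median k-mer frequency of the target in the indexed genome
#' @export
target_abundance <- function(target_seq, index) {
  k <- index$k
  if (nchar(target_seq) < k) stop("target shorter than k")
  wins <- data.table::as.data.table(
    .cpp_kmer_count(target_seq, k, index$canonical))
  # expand distinct target k-mers back to per-window observations
  hits <- index$counts[wins, on = "kmer"]
  hits[is.na(count), count := 0]
  stats::median(rep(hits$count, hits$i.count))
}

#' Screen targets for repetitive k-mer content
#'
#' @param targets named character vector of target sequences
#' @param index genome [build_kmer_index()]
#' @param percentile targets whose median abundance exceeds this percentile
#'   of the per-target distribution are flagged (default 99)
#' @return data.table with `target`, `median_abundance`, `repetitive`
#' @export
abundance_screen <- function(targets, index, percentile = 99) {
  med <- vapply(targets, target_abundance, 0, index = index)
  cut <- stats::quantile(med, percentile / 100, type = 7)
  data.table::data.table(target = names(targets), median_abundance = med,
                         repetitive = med > cut)
}

#' GC content of sequences
#'
#' @param sequence character vector of DNA sequences
#' @return fraction of G+C bases per sequence
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  vapply(strsplit(sequence, "", fixed = TRUE), function(ch) {
    mean(ch %in% c("G", "C"))
  }, 0)
}

#' Flag baits outside the efficient GC window
#'
#' Capture efficiency peaks near 53% GC and falls off outside roughly
#' 35-65%; baits outside that window are flagged for redesign.
#'
#' @param sequence character vector of bait sequences
#' @param gc_min,gc_max efficient GC window (defaults 0.35 and 0.65)
#' @return data.table with `gc` and `flagged`
#' @export
gc_screen <- function(sequence, gc_min = 0.35, gc_max = 0.65) {
  gc <- gc_content(sequence)
  data.table::data.table(gc = gc, flagged = gc < gc_min | gc > gc_max)
}
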