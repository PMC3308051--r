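# Shared sequence helpers and plain-text IO.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA strings
#' @param x character vector of A/C/G/T/N strings
#' @return character vector
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic random DNA string(s)
random_dna <- function(n_bases) {
  paste(sample(BASES, n_bases, replace = TRUE), collapse = "")
}

# substitute positions `pos` (1-based) of `seq` with bases drawn uniformly
# from the three non-identical alternatives
mutate_positions <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file into a data.table
#' @param path FASTQ file (phred33)
#' @return data.table with columns `read_id`, `seq`, `qual`
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table::data.table(
    read_id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write reads to FASTQ (phred33)
#' @param reads data.table with `read_id`, `seq`, `qual`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

# write a data.table as TSV (used for truth tables and call tables)
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

# phred33 quality string of constant score
const_qual <- function(n, phred = 35L) {
  strrep(rawToChar(as.raw(33L + phred)), n)
}

# decode a phred33 quality string to integer scores
phred_scores <- function(qual) {
  utf8ToInt(qual) - 33L
}
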