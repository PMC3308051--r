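q40 <- function(n) strrep("I", n)  # phred 40

test_that("demultiplex assigns by longest tag prefix and trims the tag", {
  tags <- c(Ld = "AT", Ld = "GAT", Td = "CCAGT", Td = "")
  reads <- data.table(
    read_id = c("r1", "r2", "r3", "r4"),
    seq = c("ATGGCAAAA", "GATTCAAAA", "CCAGTAAAA", "TTTTTAAAA"),
    qual = rep(q40(9), 4)
  )
  res <- demultiplex(reads, tags)
  expect_equal(res$assigned$accession, c("Ld", "Ld", "Td", "Td"))
  expect_equal(res$assigned$seq[1], "GGCAAAA")   # AT trimmed
  expect_equal(res$assigned$seq[2], "TCAAAA")    # GAT (longest), not AT
  expect_equal(res$assigned$seq[4], "TTTTTAAAA") # no-tag class untouched
  expect_equal(nrow(res$rejected), 0L)
})

test_that("low-quality tags are rejected and the partition is conserved", {
  badq <- paste0("I", rawToChar(as.raw(33 + 10)), "II")  # phred 10 at base 2
  reads <- data.table(
    read_id = c("ok", "bad"),
    seq = c("ATAAAAAA", "ATAAAAAA"),
    qual = c(q40(8), paste0(badq, q40(4)))
  )
  res <- demultiplex(reads, c(Ld = "AT"))
  expect_equal(res$assigned$read_id, "ok")
  expect_equal(res$rejected$read_id, "bad")
  expect_equal(res$rejected$reason, "low_tag_quality")
  expect_equal(nrow(res$assigned) + nrow(res$rejected), nrow(reads))
  expect_error(demultiplex(reads, c(Ld = "AT", Td = "AT")), "identical tags")
})

test_that("unique 40-mers align exactly and repeats are suppressed", {
  set.seed(1)
  core <- rand_seq(400)
  dup <- rand_seq(60)
  ref <- c(t1 = paste0(core, dup), t2 = paste0(rand_seq(200), dup))
  read_uniq <- substring(core, 100, 139)
  read_dup <- substring(dup, 10, 49)
  aln <- align_reads(c(a = read_uniq, b = read_dup), ref)
  expect_equal(aln[read_id == "a", status], "aligned")
  expect_equal(aln[read_id == "a", pos], 100L)
  expect_equal(aln[read_id == "a", nm], 0L)
  expect_equal(aln[read_id == "b", status], "multi_hit")
  expect_error(align_reads("ACGT", character(0)), "empty reference")
})

test_that("seed mismatch cap rejects reads with three seed mismatches", {
  set.seed(2)
  ref <- c(t1 = rand_seq(500))
  read <- substring(ref[[1]], 50, 89)
  bad <- force_mutate(read, c(3L, 10L, 20L))  # 3 mismatches within seed
  aln <- align_reads(c(x = bad), ref, aligner_params(max_total_mismatches = 5L))
  expect_equal(aln$status, "no_hit")
  ok <- force_mutate(read, c(3L, 10L))        # 2 seed mismatches pass
  aln2 <- align_reads(c(x = ok), ref)
  expect_equal(aln2$status, "aligned")
  expect_equal(aln2$nm, 2L)
})

test_that("reverse-strand reads are reported in reference orientation", {
  set.seed(3)
  ref <- c(t1 = rand_seq(300))
  fwd <- substring(ref[[1]], 101, 140)
  aln <- align_reads(c(r = revcomp_chr(fwd)), ref)
  expect_equal(aln$status, "aligned")
  expect_equal(aln$strand, "-")
  expect_equal(aln$pos, 101L)
  expect_equal(aln$seq, fwd)
})

test_that("the seed-indexed aligner matches a brute-force scan", {
  set.seed(4)
  ref <- c(t1 = rand_seq(800), t2 = rand_seq(600))
  reads <- character(120)
  for (i in seq_along(reads)) {
    tg <- sample(names(ref), 1L)
    start <- sample.int(nchar(ref[[tg]]) - 39L, 1L)
    r <- substring(ref[[tg]], start, start + 39L)
    n_mut <- sample(0:5, 1L)
    if (n_mut > 0) r <- force_mutate(r, sample.int(40L, n_mut))
    if (runif(1) < 0.5) r <- revcomp_chr(r)
    reads[i] <- r
  }
  aln <- align_reads(setNames(reads, as.character(seq_along(reads))), ref)
  for (i in seq_along(reads)) {
    want <- oracle_align(reads[i], ref)
    got <- aln[i]
    expect_equal(got$status, want$status, info = paste("read", i))
    if (want$status == "aligned") {
      expect_equal(got$target, want$target, info = paste("read", i))
      expect_equal(got$pos, want$pos, info = paste("read", i))
      expect_equal(got$strand, want$strand, info = paste("read", i))
      expect_equal(got$nm, want$nm, info = paste("read", i))
    }
  }
})

test_that("iterative trimming rescues junction reads down to 30 bp", {
  set.seed(5)
  ref <- c(t1 = rand_seq(500))
  params <- aligner_params(max_seed_mismatches = 0L, max_total_mismatches = 0L)
  exon32 <- substring(ref[[1]], 200, 231)
  # "intronic" bases chosen base-wise different from the adjacent reference
  # so no partially-trimmed candidate can align by accident
  anti <- function(from, to) chartr("ACGT", "TGCA", substring(ref[[1]], from, to))
  r8 <- paste0(exon32, anti(232, 239))       # aligns after eight 3' trims
  r11 <- paste0(substring(ref[[1]], 200, 228), anti(229, 239))  # 29 exonic
  r5p <- paste0(anti(294, 299), substring(ref[[1]], 300, 333))  # 6 junk at 5'
  rjunk <- rand_seq(40)
  res <- iterative_trim_align(
    data.table(read_id = c("r8", "r11", "r5p", "rjunk"),
               seq = c(r8, r11, r5p, rjunk)),
    ref, params)
  a <- res$alignments
  expect_equal(a[read_id == "r8", trim3], 8L)
  expect_equal(a[read_id == "r8", trim5], 0L)
  expect_equal(nchar(a[read_id == "r8", seq]), 32L)
  expect_equal(a[read_id == "r8", pos], 200L)
  expect_equal(a[read_id == "r5p", trim5], 6L)
  expect_equal(a[read_id == "r5p", pos], 300L)
  expect_setequal(res$exhausted, c("r11", "rjunk"))
  expect_true(all(nchar(a$seq) >= 30L))
})

test_that("ties between trim candidates prefer the 3' end", {
  # read embedded so that both one-base-3' and one-base-5' trims align
  set.seed(6)
  ref <- c(t1 = rand_seq(400))
  params <- aligner_params(max_seed_mismatches = 0L, max_total_mismatches = 0L)
  core <- substring(ref[[1]], 100, 140)  # 41 bases, both 40-mers align
  res <- iterative_trim_align(data.table(read_id = "tie", seq = core),
                              ref, params, min_length = 40L)
  expect_equal(res$alignments$trim3, 1L)
  expect_equal(res$alignments$trim5, 0L)
  expect_equal(res$alignments$pos, 100L)
})

test_that("exonic reads from the reference homoeolog are fully recalled", {
  run <- clean_run()
  tr <- run$reads$read_truth
  ref_gen <- run$sim$genes[, setNames(ref_genome, gene)]
  exonic_ref <- tr[exonic_bases == run$sim$config$read_length &
                     copy_id == ref_gen[gene]]
  aligned_ids <- run$alignments$read_id
  recall <- mean(exonic_ref$read_id %in% aligned_ids)
  expect_equal(recall, 1)
})
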