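# Independent oracles and shared fixtures for the test suite.

library(data.table)

# brute-force ungapped aligner: scans every offset of every target on both
# strands, applying the seed and total mismatch caps; independent of the
# package's seed-indexed implementation
oracle_align <- function(read, reference, seed_len = 28L, max_seed_mm = 2L,
                         max_total_mm = 3L) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else rc(read)
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    seed <- min(seed_len, n)
    for (tg in names(reference)) {
      rch <- strsplit(reference[[tg]], "")[[1]]
      if (length(rch) < n) next
      for (start in seq_len(length(rch) - n + 1L)) {
        mm <- ch != rch[start:(start + n - 1L)]
        if (sum(mm[seq_len(seed)]) <= max_seed_mm && sum(mm) <= max_total_mm) {
          hits[[length(hits) + 1L]] <- list(target = tg, pos = start,
                                            strand = strand, nm = sum(mm))
        }
      }
    }
  }
  if (length(hits) == 0L) return(list(status = "no_hit"))
  if (length(hits) > 1L) return(list(status = "multi_hit"))
  c(list(status = "aligned"), hits[[1]])
}

# mutate a sequence at given 1-based positions, cycling substitutions
# deterministically (A->C->G->T->A)
force_mutate <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- chartr("ACGT", "CGTA", ch[pos])
  paste(ch, collapse = "")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# one-row variable-site table in the call_variable_sites() schema, built
# from per-accession base counts
make_site <- function(counts1, counts2, ref, target = "t1", pos = 50L) {
  full <- function(x) {
    v <- setNames(integer(4), c("A", "C", "G", "T"))
    v[names(x)] <- as.integer(x)
    v
  }
  c1 <- full(counts1); c2 <- full(counts2)
  pooled <- c1 + c2
  ord <- order(-pooled, names(pooled))
  a1 <- names(pooled)[ord[1]]; a2 <- names(pooled)[ord[2]]
  data.table(
    target = target, pos = pos, ref = ref, a1 = a1, a2 = a2,
    n1_a1 = c1[[a1]], n1_a2 = c1[[a2]], n2_a1 = c2[[a1]], n2_a2 = c2[[a2]],
    depth1 = sum(c1), depth2 = sum(c2),
    other1 = sum(c1) - c1[[a1]] - c1[[a2]],
    other2 = sum(c2) - c2[[a1]] - c2[[a2]],
    third_pooled = as.integer(sort(pooled, decreasing = TRUE)[3]),
    ivs1 = c1[[a1]] >= 1L & c1[[a2]] >= 1L,
    ivs2 = c2[[a1]] >= 1L & c2[[a2]] >= 1L
  )
}

# memoized clean pipeline run (no structural events, deep coverage) shared
# by classifier/annotation/workflow recovery tests
.fixture_cache <- new.env(parent = emptyenv())
clean_run <- function() {
  if (is.null(.fixture_cache$clean)) {
    cfg <- sim_config(n_genes = 30L, n_paralog_genes = 0L,
                      n_homoeolog_deletions = 0L, n_pav_genes = 0L,
                      n_duplicated_families = 0L, mean_depth_lambda = 30,
                      seq_error_rate = 0, seed = 101L)
    .fixture_cache$clean <- run_pipeline(cfg)
  }
  .fixture_cache$clean
}
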