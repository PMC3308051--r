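# Synthetic allotetraploid exon-capture simulator.
#
# Generates an AABB tetraploid gene space: for every gene an ancestral cDNA
# with a clean ORF, two homoeologous copies (A and B) diverged at rate d,
# two accessions (a cultivated-like "Ld" and a wild-like "Td") carrying
# lineage SNPs at region-specific rates, plus planted paralogs, homoeolog
# deletions, whole-gene PAV and duplicated families. Capture-style 40-bp
# single-end reads are drawn from intron-containing genomic fragments with
# Poisson depth and a divergence-dependent capture-efficiency penalty.
# Every planted event is recorded in a truth set for recovery testing.

ACCESSIONS <- c("Ld", "Td")

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic tetraploid
#' generator. Defaults describe a desk-scale capture experiment: 200 genes of
#' 800-1200 bp cDNA split 4%/65%/31% into 5'UTR/CDS/3'UTR, 2% coding
#' divergence between the A and B subgenomes, lineage SNP rates of
#' 1.3/2.0/1.6 per kb (CDS/5'UTR/3'UTR), 40-bp reads at mean depth 13 with
#' capture efficiency halved per 2% of divergence from the reference copy.
#'
#' @param n_genes number of gene targets
#' @param gene_length_range integer pair, cDNA length range in bp
#' @param utr5_frac,cds_frac,utr3_frac fractions of the cDNA; must sum to 1
#' @param intron_count_range integer pair, introns per gene
#' @param intron_length_range integer pair, intron length in bp
#' @param divergence_d per-bp substitution rate between the A and B
#'   homoeologs in coding sequence
#' @param utr_divergence per-bp homoeolog divergence in UTRs; defaults to
#'   `divergence_d`
#' @param snp_rate_cds,snp_rate_utr5,snp_rate_utr3 per-bp lineage SNP rates
#' @param n_paralog_genes genes given a diverged paralogous copy in both
#'   accessions (false-IVS source)
#' @param paralog_divergence per-bp divergence of paralog copies
#' @param n_homoeolog_deletions homoeolog deletion events (the last one is
#'   partial when more than one is requested)
#' @param n_pav_genes genes entirely absent from one accession
#' @param n_duplicated_families genes with extra diverged copies in one
#'   accession
#' @param dup_extra_copies extra copies per duplicated family
#' @param read_length read length in bp (>= 30)
#' @param mean_depth_lambda expected per-accession depth for an unbiased
#'   single-copy gene (both homoeologs combined)
#' @param seq_error_rate per-base sequencing error rate
#' @param capture_bias apply the divergence-dependent efficiency multiplier
#' @param tag_table named character vector, accession -> tag prefix
#' @param base_quality constant phred score emitted for all bases
#' @param seed integer seed governing all randomness
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_genes = 200L,
                       gene_length_range = c(800L, 1200L),
                       utr5_frac = 0.04, cds_frac = 0.65, utr3_frac = 0.31,
                       intron_count_range = c(1L, 3L),
                       intron_length_range = c(60L, 200L),
                       divergence_d = 0.02,
                       utr_divergence = NULL,
                       snp_rate_cds = 0.0013,
                       snp_rate_utr5 = 0.002,
                       snp_rate_utr3 = 0.0016,
                       n_paralog_genes = 10L,
                       paralog_divergence = 0.05,
                       n_homoeolog_deletions = 4L,
                       n_pav_genes = 3L,
                       n_duplicated_families = 5L,
                       dup_extra_copies = 2L,
                       read_length = 40L,
                       mean_depth_lambda = 13,
                       seq_error_rate = 0.002,
                       capture_bias = TRUE,
                       tag_table = c(Ld = "AT", Td = "CCAGT"),
                       base_quality = 35L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    utr5_frac = utr5_frac, cds_frac = cds_frac, utr3_frac = utr3_frac,
    intron_count_range = as.integer(intron_count_range),
    intron_length_range = as.integer(intron_length_range),
    divergence_d = divergence_d,
    utr_divergence = if (is.null(utr_divergence)) divergence_d else utr_divergence,
    snp_rate_cds = snp_rate_cds,
    snp_rate_utr5 = snp_rate_utr5,
    snp_rate_utr3 = snp_rate_utr3,
    n_paralog_genes = as.integer(n_paralog_genes),
    paralog_divergence = paralog_divergence,
    n_homoeolog_deletions = as.integer(n_homoeolog_deletions),
    n_pav_genes = as.integer(n_pav_genes),
    n_duplicated_families = as.integer(n_duplicated_families),
    dup_extra_copies = as.integer(dup_extra_copies),
    read_length = as.integer(read_length),
    mean_depth_lambda = mean_depth_lambda,
    seq_error_rate = seq_error_rate,
    capture_bias = isTRUE(capture_bias),
    tag_table = tag_table,
    base_quality = as.integer(base_quality),
    seed = as.integer(seed)
  )
  fr <- c(cfg$utr5_frac, cfg$cds_frac, cfg$utr3_frac)
  if (any(fr < 0) || any(fr > 1)) stop("UTR/CDS fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-8) stop("utr5_frac + cds_frac + utr3_frac must sum to 1")
  if (cfg$read_length < 30L) stop("read_length must be >= 30")
  rates <- c(cfg$divergence_d, cfg$utr_divergence, cfg$snp_rate_cds,
             cfg$snp_rate_utr5, cfg$snp_rate_utr3, cfg$paralog_divergence,
             cfg$seq_error_rate)
  if (any(rates < 0) || any(rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (diff(cfg$gene_length_range) < 0) stop("gene_length_range must be increasing")
  n_event_genes <- cfg$n_paralog_genes + cfg$n_pav_genes +
    cfg$n_duplicated_families + cfg$n_homoeolog_deletions
  if (n_event_genes > cfg$n_genes) {
    stop("requested structural events (", n_event_genes,
         ") exceed the number of genes (", cfg$n_genes, ")")
  }
  min_len <- cfg$gene_length_range[1]
  if (floor(cfg$cds_frac * min_len / 3) * 3 < 9L || min_len < 3L * cfg$read_length) {
    stop("genes of length ", min_len,
         " are too short to host an ORF and ", cfg$read_length, "-bp reads")
  }
  if (is.null(names(cfg$tag_table)) || any(!nzchar(names(cfg$tag_table)))) {
    stop("tag_table must be a named accession -> tag map")
  }
  structure(cfg, class = "sim_config")
}

#' Relative capture efficiency at a given divergence from the reference
#'
#' Capture efficiency halves for every 2% of sequence divergence between a
#' genomic copy and the bait (reference) sequence, reflecting the observed
#' two-fold coverage reduction at 2% coding divergence.
#'
#' @param divergence per-bp divergence from the reference, in \[0, 1\]
#' @return multiplier in (0, 1] scaling a fragment's sampling probability
#' @export
#' @examples
#' capture_efficiency(0)     # 1
#' capture_efficiency(0.02)  # 0.5
capture_efficiency <- function(divergence) {
  if (any(divergence < 0)) stop("divergence must be non-negative")
  if (any(divergence > 1)) stop("divergence must be <= 1")
  0.5^(divergence / 0.02)
}

# one ancestral cDNA: random UTRs and an ORF of sense codons (ATG ... stop)
build_ancestral_cdna <- function(len, utr5_frac, cds_frac) {
  u5 <- as.integer(round(utr5_frac * len))
  cds <- as.integer(floor(cds_frac * len / 3) * 3)
  u3 <- len - u5 - cds
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  sense <- setdiff(codons, stops)
  n_mid <- cds / 3L - 2L
  orf <- paste0("ATG",
                paste(sample(sense, n_mid, replace = TRUE), collapse = ""),
                sample(stops, 1L))
  list(seq = paste0(random_dna(u5), orf, random_dna(u3)),
       utr5_len = u5, cds_len = cds, utr3_len = u3)
}

region_vector <- function(utr5_len, cds_len, utr3_len) {
  rep(c("utr5", "cds", "utr3"), times = c(utr5_len, cds_len, utr3_len))
}

# interleave introns into a cDNA; returns genomic string plus per-base maps
build_genomic <- function(cdna, intron_pos, intron_seq) {
  len <- nchar(cdna)
  if (length(intron_pos) == 0L) {
    return(list(gseq = cdna, exonic = rep(TRUE, len),
                cdna_idx = seq_len(len), ins_pos = rep(NA_integer_, len)))
  }
  o <- order(intron_pos)
  intron_pos <- intron_pos[o]; intron_seq <- intron_seq[o]
  pieces <- character(0); exonic <- logical(0)
  cdna_idx <- integer(0); ins_pos <- integer(0)
  prev <- 1L
  for (i in seq_along(intron_pos)) {
    p <- intron_pos[i]
    ex <- substr(cdna, prev, p - 1L)
    pieces <- c(pieces, ex, intron_seq[i])
    exonic <- c(exonic, rep(TRUE, nchar(ex)), rep(FALSE, nchar(intron_seq[i])))
    cdna_idx <- c(cdna_idx, seq(prev, p - 1L), rep(NA_integer_, nchar(intron_seq[i])))
    ins_pos <- c(ins_pos, rep(NA_integer_, nchar(ex)), rep(p, nchar(intron_seq[i])))
    prev <- p
  }
  ex <- substr(cdna, prev, len)
  pieces <- c(pieces, ex)
  exonic <- c(exonic, rep(TRUE, nchar(ex)))
  cdna_idx <- c(cdna_idx, seq(prev, len))
  ins_pos <- c(ins_pos, rep(NA_integer_, nchar(ex)))
  list(gseq = paste(pieces, collapse = ""), exonic = exonic,
       cdna_idx = cdna_idx, ins_pos = ins_pos)
}

seq_divergence <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca != cb)
}

#' Simulate an allotetraploid reference and accession gene space
#'
#' Generates per-gene ancestral cDNAs, A/B homoeologs, accession copies with
#' lineage SNPs, planted structural events and the reference FASTA (one
#' designated homoeolog per gene, alternating A/B by gene index, mirroring a
#' bait set designed from a single diploid gene complement).
#'
#' @param config a [sim_config()] object
#' @return a list of class `polycap_sim` with elements `config`, `genes`
#'   (gene table incl. UTR/CDS spans and designated reference genome),
#'   `reference` (named character vector of reference cDNAs), `homoeologs`
#'   (data.table gene/genome/seq), `introns`, `copies` (every sequencable
#'   copy per accession with divergence from reference and deletion state)
#'   and `truth` (lists of planted GSS, SNP, paralog, deletion, PAV and
#'   duplication events; coordinates 1-based within the cDNA)
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  accs <- names(config$tag_table)

  genes <- vector("list", config$n_genes)
  gss_list <- vector("list", config$n_genes)
  snp_list <- list()
  homoeo <- vector("list", config$n_genes)
  intron_list <- vector("list", config$n_genes)
  lr <- config$gene_length_range

  for (i in seq_len(config$n_genes)) {
    gname <- sprintf("gene%04d", i)
    len <- lr[1] + sample.int(lr[2] - lr[1] + 1L, 1L) - 1L
    anc <- build_ancestral_cdna(len, config$utr5_frac, config$cds_frac)
    reg <- region_vector(anc$utr5_len, anc$cds_len, anc$utr3_len)

    div_rate <- ifelse(reg == "cds", config$divergence_d, config$utr_divergence)
    gss_pos <- which(stats::runif(len) < div_rate)
    seq_a <- anc$seq
    seq_b <- mutate_positions(anc$seq, gss_pos)
    if (length(gss_pos)) {
      gss_list[[i]] <- data.table::data.table(
        gene = gname, pos = gss_pos, region = reg[gss_pos],
        allele_A = substring(seq_a, gss_pos, gss_pos),
        allele_B = substring(seq_b, gss_pos, gss_pos)
      )
    }

    # lineage SNPs, disjoint from GSS positions and from each other
    used <- gss_pos
    snp_rate <- ifelse(reg == "cds", config$snp_rate_cds,
                       ifelse(reg == "utr5", config$snp_rate_utr5,
                              config$snp_rate_utr3))
    for (acc in accs) {
      pos <- setdiff(which(stats::runif(len) < snp_rate), used)
      used <- c(used, pos)
      if (length(pos)) {
        genome <- sample(c("A", "B"), length(pos), replace = TRUE)
        anc_base <- substring(anc$seq, pos, pos)
        der <- vapply(anc_base, function(b) sample(setdiff(BASES, b), 1L), "")
        snp_list[[length(snp_list) + 1L]] <- data.table::data.table(
          gene = gname, pos = pos, region = reg[pos], accession = acc,
          genome = genome, ancestral = anc_base, derived = unname(der)
        )
      }
    }

    ic <- config$intron_count_range
    k <- ic[1] + sample.int(ic[2] - ic[1] + 1L, 1L) - 1L
    if (k > 0L) {
      il <- config$intron_length_range
      ipos <- sort(sample(2:len, k))
      ilen <- il[1] + sample.int(il[2] - il[1] + 1L, k, replace = TRUE) - 1L
      iseq <- vapply(ilen, random_dna, "")
      intron_list[[i]] <- data.table::data.table(
        gene = gname, intron = seq_len(k), cdna_pos = ipos,
        length = ilen, seq = iseq
      )
    }

    genes[[i]] <- data.table::data.table(
      gene = gname, len = len, utr5_len = anc$utr5_len,
      cds_len = anc$cds_len, utr3_len = anc$utr3_len,
      ref_genome = if (i %% 2L == 1L) "A" else "B"
    )
    homoeo[[i]] <- data.table::data.table(
      gene = gname, genome = c("A", "B"), seq = c(seq_a, seq_b)
    )
  }

  genes <- data.table::rbindlist(genes)
  homoeologs <- data.table::rbindlist(homoeo)
  introns <- data.table::rbindlist(intron_list)
  truth_gss <- if (length(gss_list)) data.table::rbindlist(gss_list) else
    data.table::data.table(gene = character(), pos = integer(),
                           region = character(), allele_A = character(),
                           allele_B = character())
  truth_snp <- if (length(snp_list)) data.table::rbindlist(snp_list) else
    data.table::data.table(gene = character(), pos = integer(),
                           region = character(), accession = character(),
                           genome = character(), ancestral = character(),
                           derived = character())

  # assign structural events to disjoint gene sets
  pool <- sample(genes$gene)
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  paralog_genes <- take(config$n_paralog_genes)
  dup_genes <- take(config$n_duplicated_families)
  pav_genes <- take(config$n_pav_genes)
  del_genes <- take(config$n_homoeolog_deletions)

  truth_paralog <- data.table::data.table(gene = paralog_genes)
  truth_dup <- data.table::data.table(
    gene = dup_genes,
    accession = if (length(dup_genes))
      sample(accs, length(dup_genes), replace = TRUE) else character(),
    n_extra_copies = rep(config$dup_extra_copies, length(dup_genes))
  )
  truth_pav <- data.table::data.table(
    gene = pav_genes,
    accession = if (length(pav_genes))
      sample(accs, length(pav_genes), replace = TRUE) else character()
  )
  n_del <- length(del_genes)
  del_type <- rep("full", n_del)
  if (n_del >= 2L) del_type[n_del] <- "partial"
  truth_del <- data.table::data.table(
    gene = del_genes,
    accession = if (n_del) sample(accs, n_del, replace = TRUE) else character(),
    genome = if (n_del) sample(c("A", "B"), n_del, replace = TRUE) else character(),
    type = del_type, block_start = NA_integer_, block_end = NA_integer_
  )
  for (j in seq_len(n_del)) {
    if (truth_del$type[j] == "partial") {
      glen <- genes[gene == truth_del$gene[j], len]
      blen <- as.integer(ceiling(stats::runif(1, 0.5, 0.8) * glen))
      bstart <- sample.int(glen - blen + 1L, 1L)
      truth_del$block_start[j] <- bstart
      truth_del$block_end[j] <- bstart + blen - 1L
    }
  }

  reference <- stats::setNames(
    homoeologs[genes, on = c("gene", genome = "ref_genome"), seq],
    genes$gene
  )

  # every sequencable copy per accession, after SNPs and structural events
  copies <- list()
  seqs_by <- split(homoeologs$seq, paste(homoeologs$gene, homoeologs$genome))
  # pre-draw paralog/dup copy sequences so both accessions share paralogs
  paralog_seqs <- stats::setNames(lapply(paralog_genes, function(g) {
    base <- seqs_by[[paste(g, "A")]]
    len <- nchar(base)
    mutate_positions(base, which(stats::runif(len) < config$paralog_divergence))
  }), paralog_genes)
  dup_seqs <- stats::setNames(lapply(dup_genes, function(g) {
    base <- seqs_by[[paste(g, "A")]]
    len <- nchar(base)
    lapply(seq_len(config$dup_extra_copies), function(j) {
      mutate_positions(base, which(stats::runif(len) < config$paralog_divergence))
    })
  }), dup_genes)

  for (acc in accs) {
    acc_snps <- truth_snp[accession == acc]
    for (i in seq_len(config$n_genes)) {
      g <- genes$gene[i]
      if (g %in% pav_genes && truth_pav[gene == g, accession] == acc) next
      for (gn in c("A", "B")) {
        del <- truth_del[gene == g & accession == acc & genome == gn]
        if (nrow(del) == 1L && del$type == "full") next
        s <- seqs_by[[paste(g, gn)]]
        snp_here <- acc_snps[gene == g & genome == gn]
        if (nrow(snp_here)) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          ch[snp_here$pos] <- snp_here$derived
          s <- paste(ch, collapse = "")
        }
        copies[[length(copies) + 1L]] <- data.table::data.table(
          accession = acc, gene = g, copy_id = gn,
          divergence = seq_divergence(s, reference[[g]]),
          block_start = if (nrow(del) == 1L) del$block_start else NA_integer_,
          block_end = if (nrow(del) == 1L) del$block_end else NA_integer_,
          seq = s
        )
      }
      if (g %in% paralog_genes) {
        s <- paralog_seqs[[g]]
        copies[[length(copies) + 1L]] <- data.table::data.table(
          accession = acc, gene = g, copy_id = "P1",
          divergence = seq_divergence(s, reference[[g]]),
          block_start = NA_integer_, block_end = NA_integer_, seq = s
        )
      }
      if (g %in% dup_genes && truth_dup[gene == g, accession] == acc) {
        for (j in seq_along(dup_seqs[[g]])) {
          s <- dup_seqs[[g]][[j]]
          copies[[length(copies) + 1L]] <- data.table::data.table(
            accession = acc, gene = g, copy_id = paste0("D", j),
            divergence = seq_divergence(s, reference[[g]]),
            block_start = NA_integer_, block_end = NA_integer_, seq = s
          )
        }
      }
    }
  }
  copies <- data.table::rbindlist(copies)

  structure(list(
    config = config, genes = genes, reference = reference,
    homoeologs = homoeologs, introns = introns, copies = copies,
    truth = list(gss = truth_gss, snp = truth_snp, paralog = truth_paralog,
                 deletion = truth_del, pav = truth_pav, duplication = truth_dup)
  ), class = "polycap_sim")
}

#' Simulate capture-style single-end reads from a synthetic tetraploid
#'
#' Fragments are drawn from intron-containing genomic copies so that a
#' fraction of reads straddles exon-intron junctions; per-copy depth is
#' Poisson with mean `(lambda / 2) * capture_efficiency(divergence)` so an
#' unbiased single-copy gene totals `lambda` per accession. Reads come off
#' either strand, carry the accession tag as a prefix and constant phred33
#' qualities with per-base errors injected into the insert.
#'
#' @param sim a `polycap_sim` object from [simulate_references()]
#' @param lambda mean per-accession depth; defaults to the config value
#' @return list with `reads` (per-accession list of data.tables with
#'   `read_id`, `seq`, `qual`), `pool` (combined data.table) and
#'   `read_truth` (origin of every read: accession, gene, copy, genomic
#'   start, strand, exonic base count, error count)
#' @export
simulate_reads <- function(sim, lambda = NULL) {
  stopifnot(inherits(sim, "polycap_sim"))
  config <- sim$config
  if (is.null(lambda)) lambda <- config$mean_depth_lambda
  if (lambda <= 0) stop("mean depth lambda must be positive")
  set.seed((config$seed %% 2100000000L) + 1L)
  rl <- config$read_length
  accs <- names(config$tag_table)
  introns_by_gene <- if (nrow(sim$introns))
    split(sim$introns, by = "gene") else list()

  reads_by_acc <- stats::setNames(vector("list", length(accs)), accs)
  truth_rows <- list()
  for (acc in accs) {
    cps <- sim$copies[accession == acc]
    acc_reads <- list()
    for (j in seq_len(nrow(cps))) {
      cp <- cps[j]
      itr <- introns_by_gene[[cp$gene]]
      gen <- build_genomic(cp$seq,
                           if (is.null(itr)) integer(0) else itr$cdna_pos,
                           if (is.null(itr)) character(0) else itr$seq)
      keep <- rep(TRUE, nchar(gen$gseq))
      if (!is.na(cp$block_start)) {
        b1 <- cp$block_start; b2 <- cp$block_end
        keep <- ifelse(gen$exonic,
                       !(gen$cdna_idx >= b1 & gen$cdna_idx <= b2),
                       !(gen$ins_pos > b1 & gen$ins_pos <= b2))
      }
      gchars <- strsplit(gen$gseq, "", fixed = TRUE)[[1]][keep]
      exonic <- gen$exonic[keep]
      glen <- length(gchars)
      if (glen < rl) next
      gseq <- paste(gchars, collapse = "")
      exon_len <- sum(exonic)
      eff <- if (config$capture_bias) capture_efficiency(cp$divergence) else 1
      n_reads <- stats::rpois(1L, (lambda / 2) * eff * exon_len / rl)
      if (n_reads == 0L) next
      # starts whose window overlaps >= 1 exonic base
      cs <- cumsum(exonic)
      win_ex <- cs[rl:glen] - c(0L, cs)[1:(glen - rl + 1L)]
      valid <- which(win_ex > 0L)
      if (!length(valid)) next
      starts <- valid[sample.int(length(valid), n_reads, replace = TRUE)]
      sq <- substring(gseq, starts, starts + rl - 1L)
      strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
      sq[strand == "-"] <- revcomp_chr(sq[strand == "-"])
      # sequencing errors in the insert
      n_err <- stats::rbinom(n_reads, rl, config$seq_error_rate)
      for (r in which(n_err > 0L)) {
        sq[r] <- mutate_positions(sq[r], sample.int(rl, n_err[r]))
      }
      ids <- sprintf("%s:%s:%s:%d:%s:%d", cp$gene, acc, cp$copy_id,
                     starts, strand, seq_len(n_reads))
      tag <- config$tag_table[[acc]]
      acc_reads[[length(acc_reads) + 1L]] <- data.table::data.table(
        read_id = ids,
        seq = paste0(tag, sq),
        qual = const_qual(nchar(tag) + rl, config$base_quality)
      )
      truth_rows[[length(truth_rows) + 1L]] <- data.table::data.table(
        read_id = ids, accession = acc, gene = cp$gene, copy_id = cp$copy_id,
        gstart = starts, strand = strand,
        exonic_bases = win_ex[match(starts, seq_len(glen - rl + 1L))],
        n_errors = n_err
      )
    }
    reads_by_acc[[acc]] <- if (length(acc_reads))
      data.table::rbindlist(acc_reads) else
      data.table::data.table(read_id = character(), seq = character(),
                             qual = character())
  }
  list(reads = reads_by_acc,
       pool = data.table::rbindlist(reads_by_acc),
       read_truth = if (length(truth_rows)) data.table::rbindlist(truth_rows)
       else data.table::data.table())
}

#' Gene models of a simulation in cDNA coordinates
#'
#' @param sim a `polycap_sim` object
#' @return data.table with `gene`, `len`, `utr5_len`, `cds_len`, `utr3_len`
#' @export
gene_models <- function(sim) {
  sim$genes[, .(gene, len, utr5_len, cds_len, utr3_len)]
}

#' Write a simulation to plain-text files
#'
#' Writes the reference FASTA, both homoeolog FASTAs, per-accession and
#' pooled FASTQ, gene model TSV, truth tables (0-based half-open
#' coordinates) and a flat key=value config file.
#'
#' @param sim a `polycap_sim` object
#' @param reads result of [simulate_reads()] (optional)
#' @param dir output directory, created if needed
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, reads = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  hseq <- stats::setNames(sim$homoeologs$seq,
                          paste0(sim$homoeologs$gene, "_", sim$homoeologs$genome))
  write_fasta(hseq, file.path(dir, "homoeologs.fa"))
  write_tsv(gene_models(sim), file.path(dir, "gene_models.tsv"))

  to0 <- function(dt) {  # 1-based inclusive -> 0-based half-open
    dt <- data.table::copy(dt)
    if ("pos" %in% names(dt)) {
      dt[, `:=`(start = pos - 1L, end = pos)]
      dt[, pos := NULL]
    }
    if ("block_start" %in% names(dt)) {
      dt[, block_start := block_start - 1L]
    }
    dt
  }
  for (nm in names(sim$truth)) {
    write_tsv(to0(sim$truth[[nm]]), file.path(dir, paste0("truth_", nm, ".tsv")))
  }
  cfg <- sim$config
  cfg_lines <- vapply(names(cfg), function(k) {
    paste0(k, "=", paste(cfg[[k]], collapse = ","))
  }, "")
  writeLines(cfg_lines, file.path(dir, "config.txt"))
  if (!is.null(reads)) {
    for (acc in names(reads$reads)) {
      write_fastq(reads$reads[[acc]], file.path(dir, paste0("reads_", acc, ".fq")))
    }
    write_fastq(reads$pool, file.path(dir, "reads_pool.fq"))
    write_tsv(reads$read_truth, file.path(dir, "read_truth.tsv"))
  }
  invisible(dir)
}
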