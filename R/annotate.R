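# Coding-effect annotation of classified sites on cDNA gene models, regional
# density summaries and GO-category enrichment of replacement changes.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locate a cDNA position within a gene model
#'
#' Gene models partition the cDNA into 5' UTR, CDS and 3' UTR; the reading
#' frame is anchored at the CDS start.
#'
#' @param pos 1-based position within the cDNA
#' @param model a list or one-row data.frame with `utr5_len`, `cds_len`,
#'   `utr3_len`
#' @return list with `region` (utr5/cds/utr3) and, for CDS positions,
#'   `codon_index` (0-based) and `codon_offset` (0..2)
#' @export
locate_region <- function(pos, model) {
  len <- model$utr5_len + model$cds_len + model$utr3_len
  if (pos < 1L || pos > len) stop("position ", pos, " outside cDNA of length ", len)
  if (pos <= model$utr5_len) {
    return(list(region = "utr5", codon_index = NA_integer_,
                codon_offset = NA_integer_))
  }
  if (pos <= model$utr5_len + model$cds_len) {
    off0 <- pos - model$utr5_len - 1L
    return(list(region = "cds", codon_index = off0 %/% 3L,
                codon_offset = off0 %% 3L))
  }
  list(region = "utr3", codon_index = NA_integer_, codon_offset = NA_integer_)
}

translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

#' Classify the coding effect of a single-base change
#'
#' Translates the codon containing the site with the ancestral and derived
#' alleles substituted. Equal amino acids (including stop-to-stop) are
#' synonymous; a derived stop in a sense codon is a stop gain; an ancestral
#' stop turned sense is a stop loss; anything else is non-synonymous. UTR
#' positions are classified `utr`.
#'
#' @param cdna reference cDNA sequence of the gene
#' @param model gene model (see [locate_region()])
#' @param pos 1-based site position in the cDNA
#' @param from ancestral (or reference) allele
#' @param to derived (or alternative) allele
#' @return list with `region`, `effect` (synonymous/nonsynonymous/
#'   stop_gain/stop_loss/utr/unknown), `aa_from`, `aa_to`
#' @export
classify_effect <- function(cdna, model, pos, from, to) {
  if (from == to) stop("alleles must differ")
  loc <- locate_region(pos, model)
  if (loc$region != "cds") {
    return(list(region = loc$region, effect = "utr",
                aa_from = NA_character_, aa_to = NA_character_))
  }
  cstart <- model$utr5_len + loc$codon_index * 3L + 1L
  codon <- substring(cdna, cstart, cstart + 2L)
  anc <- codon; der <- codon
  substr(anc, loc$codon_offset + 1L, loc$codon_offset + 1L) <- from
  substr(der, loc$codon_offset + 1L, loc$codon_offset + 1L) <- to
  aa_from <- translate_codon(anc)
  aa_to <- translate_codon(der)
  if (is.na(aa_from) || is.na(aa_to)) {
    warning("ambiguous base in codon at ", pos)
    return(list(region = "cds", effect = "unknown",
                aa_from = aa_from, aa_to = aa_to))
  }
  effect <- if (aa_from == aa_to) "synonymous"
            else if (aa_to == "*") "stop_gain"
            else if (aa_from == "*") "stop_loss"
            else "nonsynonymous"
  list(region = "cds", effect = effect, aa_from = aa_from, aa_to = aa_to)
}

#' Annotate classified sites with coding effects
#'
#' SNPs are oriented ancestral to derived; GSSs use the reference
#' homoeolog's frame with the reference-matching allele as baseline.
#'
#' @param calls classified site table (rows labelled GSS or SNP)
#' @param models data.table of gene models keyed by `gene` (see
#'   [gene_models()])
#' @param reference named character vector of cDNA sequences
#' @return data.table: `target`, `pos`, `class`, `lineage`, `region`,
#'   `effect`, `aa_from`, `aa_to`
#' @export
annotate_effects <- function(calls, models, reference) {
  use <- calls[label %in% c("GSS", "SNP")]
  rows <- lapply(seq_len(nrow(use)), function(i) {
    s <- use[i]
    model <- models[gene == s$target]
    if (nrow(model) == 0L) return(NULL)
    if (s$label == "SNP") {
      from <- s$ancestral; to <- s$derived
    } else {
      from <- if (s$ref %in% c(s$a1, s$a2)) s$ref else s$a1
      to <- if (from == s$a1) s$a2 else s$a1
    }
    eff <- classify_effect(reference[[s$target]], model, s$pos, from, to)
    data.table::data.table(
      target = s$target, pos = s$pos, class = s$label,
      lineage = if (s$label == "SNP") s$lineage else NA_character_,
      region = eff$region, effect = eff$effect,
      aa_from = eff$aa_from, aa_to = eff$aa_to
    )
  })
  if (!length(rows)) {
    return(data.table::data.table(target = character(), pos = integer(),
                                  class = character(), lineage = character(),
                                  region = character(), effect = character(),
                                  aa_from = character(), aa_to = character()))
  }
  data.table::rbindlist(rows)
}

#' Derived-SNP density by gene region
#'
#' @param effects output of [annotate_effects()] (SNP rows are counted)
#' @param covered_lengths named numeric vector of covered bp per region
#'   (`utr5`, `cds`, `utr3`); regions with zero covered length are omitted
#' @return data.table with `lineage`, `region`, `n`, `kb`, `density`
#'   (SNPs per kb)
#' @export
density_by_region <- function(effects, covered_lengths) {
  regions <- names(covered_lengths)[covered_lengths > 0]
  snps <- effects[class == "SNP" & region %in% regions]
  lineages <- sort(unique(snps$lineage))
  grid <- data.table::CJ(lineage = lineages, region = regions)
  cnt <- snps[, .N, by = .(lineage, region)]
  out <- cnt[grid, on = c("lineage", "region")]
  out[is.na(N), N := 0L]
  out[, kb := covered_lengths[region] / 1000]
  out[, density := N / kb]
  data.table::setnames(out, "N", "n")
  out[]
}

#' Summarise protein-coding changes per lineage
#'
#' Protein-coding changes are non-synonymous substitutions plus stop gains
#' and losses.
#'
#' @param effects table with `lineage` and `effect` columns (e.g. the SNP
#'   rows of [annotate_effects()])
#' @return list with `per_lineage` (data.table of counts and shares) and
#'   `total`
#' @export
protein_change_summary <- function(effects) {
  coding <- effects[effect %in% c("nonsynonymous", "stop_gain", "stop_loss")]
  per <- coding[, .N, by = lineage]
  data.table::setnames(per, "N", "protein_changes")
  total <- sum(per$protein_changes)
  per[, share := if (total > 0) protein_changes / total else NA_real_]
  list(per_lineage = per[], total = total)
}

#' GO-term enrichment of non-synonymous relative to synonymous changes
#'
#' For every GO term, mutations are cross-tabulated as replacement
#' (non-synonymous, stop gain/loss) versus synonymous and in-group versus
#' out-group, tested with a two-sided Fisher exact test and corrected by
#' Benjamini-Hochberg FDR. Terms with a degenerate margin are skipped.
#'
#' @param effects table with `target` and `effect` columns (one row per
#'   classified mutation)
#' @param go_map data.table with columns `gene` and `term`
#' @param fdr significance level on the adjusted p-values (default 0.05)
#' @return data.table per tested term: counts, `p`, `fdr`, `direction`
#'   (over/under-represented), `significant`
#' @export
go_enrichment <- function(effects, go_map, fdr = 0.05) {
  eff <- effects[effect %in% c("nonsynonymous", "stop_gain", "stop_loss",
                               "synonymous")]
  eff <- data.table::copy(eff)
  eff[, replacement := effect != "synonymous"]
  terms <- unique(go_map$term)
  rows <- lapply(terms, function(tm) {
    genes_in <- go_map[term == tm, gene]
    inb <- eff$target %in% genes_in
    tab <- matrix(c(sum(eff$replacement & inb), sum(!eff$replacement & inb),
                    sum(eff$replacement & !inb), sum(!eff$replacement & !inb)),
                  nrow = 2L)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      message("skipping GO term with degenerate margins: ", tm)
      return(NULL)
    }
    p <- stats::fisher.test(tab)$p.value
    frac_in <- tab[1, 1] / sum(tab[, 1])
    frac_out <- tab[1, 2] / sum(tab[, 2])
    data.table::data.table(
      term = tm, nonsyn_in = tab[1, 1], syn_in = tab[2, 1],
      nonsyn_out = tab[1, 2], syn_out = tab[2, 2], p = p,
      direction = if (frac_in > frac_out) "over-represented"
                  else "under-represented"
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.table::data.table(term = character(), nonsyn_in = integer(),
                                  syn_in = integer(), nonsyn_out = integer(),
                                  syn_out = integer(), p = numeric(),
                                  direction = character(), fdr = numeric(),
                                  significant = logical()))
  }
  out <- data.table::rbindlist(rows)
  sig_level <- fdr
  out[, fdr := stats::p.adjust(p, method = "BH")]
  out[, significant := fdr < sig_level]
  out[]
}
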