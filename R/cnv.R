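# Copy-number, presence/absence and homoeolog-deletion detection from two
# complementary signals: windowed coverage ratios between accessions, and
# the per-accession variant pattern at variable sites.

#' Targets eligible for coverage-based CNV analysis
#'
#' @param summaries output of [coverage_summary()]
#' @param breadth_min minimum fraction of the target covered by at least
#'   one read (default 0.7)
#' @return character vector of eligible target names
#' @export
eligible_targets <- function(summaries, breadth_min = 0.7) {
  summaries[breadth_ge1 >= breadth_min, target]
}

#' Tile targets into overlapping windows and count reads per accession
#'
#' Windows are 500 bp with 250 bp step; a target shorter than one window
#' yields a single full-length window. Reads are assigned to windows by
#' their alignment start position.
#'
#' @param alignments data.table with `target`, `pos`, `accession`
#' @param target_lengths named integer vector of target lengths
#' @param accessions the two accession names, order fixing the ratio
#'   orientation (x = first accession)
#' @param window_size,window_step window geometry in bp
#' @return data.table with `target`, `start`, `end` (1-based inclusive),
#'   `x`, `y` read counts and library totals `Nx`, `Ny`
#' @export
window_counts <- function(alignments, target_lengths,
                          accessions = c("Ld", "Td"),
                          window_size = 500L, window_step = 250L) {
  Nx <- sum(alignments$accession == accessions[1])
  Ny <- sum(alignments$accession == accessions[2])
  rows <- lapply(names(target_lengths), function(tg) {
    len <- target_lengths[[tg]]
    starts <- seq.int(1L, max(1L, len - window_step + 1L), by = window_step)
    if (len <= window_size) starts <- 1L
    ends <- pmin(starts + window_size - 1L, len)
    sub <- alignments[target == tg]
    x <- vapply(seq_along(starts), function(i)
      sum(sub$accession == accessions[1] & sub$pos >= starts[i] &
            sub$pos <= ends[i]), 0L)
    y <- vapply(seq_along(starts), function(i)
      sum(sub$accession == accessions[2] & sub$pos >= starts[i] &
            sub$pos <= ends[i]), 0L)
    data.table::data.table(target = tg, start = starts, end = ends,
                           x = x, y = y)
  })
  out <- data.table::rbindlist(rows)
  out[, `:=`(Nx = Nx, Ny = Ny)]
  out[]
}

#' Coverage-ratio test for one window
#'
#' The library-normalised coverage ratio `r = (x/Nx)/(y/Ny)` is tested
#' against 1 with the normal approximation to the log ratio of two Poisson
#' counts: `z = ln(r) / sqrt(1/x + 1/y)`, two-sided. Zero counts receive a
#' 0.5 continuity correction.
#'
#' @param x,y read counts in the window for the two accessions
#' @param Nx,Ny library totals
#' @return list with `log2_ratio`, `z`, `p` (vectorised over windows)
#' @export
window_ratio_test <- function(x, y, Nx, Ny) {
  if (any(Nx == 0) || any(Ny == 0)) stop("library totals must be positive")
  if (any(x + y <= 0)) stop("window has no reads in either accession")
  xc <- ifelse(x == 0, 0.5, x)
  yc <- ifelse(y == 0, 0.5, y)
  r <- (xc / Nx) / (yc / Ny)
  z <- log(r) / sqrt(1 / xc + 1 / yc)
  p <- 2 * stats::pnorm(-abs(z))
  list(log2_ratio = log2(r), z = z, p = p)
}

#' Call copy-number variants from windowed coverage ratios
#'
#' A target is a CNV when at least `min_sig_windows` windows are
#' significant at `alpha` and all significant windows agree in ratio sign;
#' the affected accession is the one with the higher coverage. Targets
#' tiled with fewer than `min_sig_windows` windows require every window to
#' be significant.
#'
#' @param windows output of [window_counts()], optionally restricted to
#'   eligible targets; windows without reads are skipped
#' @param alpha per-window significance level (default 0.001)
#' @param min_sig_windows minimum number of significant windows (default 4)
#' @param accessions accession names (x = first)
#' @return data.table of calls: `target`, `kind` ("cnv"), `accession`
#'   (higher-coverage side), `n_sig_windows`, `mean_log2_ratio`
#' @export
call_cnv <- function(windows, alpha = 0.001, min_sig_windows = 4L,
                     accessions = c("Ld", "Td")) {
  w <- windows[x + y > 0]
  if (nrow(w) == 0L) {
    return(data.table::data.table(target = character(), kind = character(),
                                  accession = character(),
                                  n_sig_windows = integer(),
                                  mean_log2_ratio = numeric()))
  }
  tst <- window_ratio_test(w$x, w$y, w$Nx, w$Ny)
  w[, `:=`(log2_ratio = tst$log2_ratio, p_value = tst$p)]
  calls <- w[, {
    sig <- p_value < alpha
    need <- min(min_sig_windows, .N)
    n_sig <- sum(sig)
    consistent <- n_sig > 0L &&
      (all(log2_ratio[sig] > 0) || all(log2_ratio[sig] < 0))
    if (n_sig >= need && consistent) {
      .(kind = "cnv",
        accession = accessions[if (mean(log2_ratio[sig]) > 0) 1L else 2L],
        n_sig_windows = n_sig,
        mean_log2_ratio = mean(log2_ratio[sig]))
    } else NULL
  }, by = target]
  calls[]
}

#' Infer the mechanism behind a coverage CNV call
#'
#' A CNV target without variable sites most likely reflects gene deletion
#' in the lower-coverage accession; a variable-site count above the
#' non-CNV baseline points to copy-number change in a multigene family in
#' the higher-coverage accession. Duplication calls whose margin over the
#' baseline is under 10% are flagged low-confidence.
#'
#' @param calls output of [call_cnv()]
#' @param variable_site_counts named integer vector, variable sites per
#'   target
#' @param baseline_mean mean variable-site count of non-CNV targets
#' @param accessions accession names
#' @return the call table with `kind` refined to
#'   cnv_duplication/cnv_deletion/cnv_ambiguous, `variable_sites`,
#'   `baseline_mean` and `low_confidence`
#' @export
cnv_mechanism <- function(calls, variable_site_counts, baseline_mean,
                          accessions = c("Ld", "Td")) {
  calls <- data.table::copy(calls)
  if (nrow(calls) == 0L) return(calls)
  vs <- variable_site_counts[calls$target]
  vs[is.na(vs)] <- 0L
  calls[, variable_sites := as.integer(vs)]
  calls[, baseline_mean := baseline_mean]
  calls[, low_confidence := FALSE]
  for (i in seq_len(nrow(calls))) {
    cnt <- calls$variable_sites[i]
    if (cnt == 0L) {
      lower <- setdiff(accessions, calls$accession[i])
      calls[i, `:=`(kind = "cnv_deletion", accession = lower)]
    } else if (cnt > baseline_mean) {
      calls[i, kind := "cnv_duplication"]
      if (cnt <= baseline_mean * 1.1) calls[i, low_confidence := TRUE]
    } else {
      calls[i, kind := "cnv_ambiguous"]
    }
  }
  calls[]
}

#' Call presence/absence variation from median depths
#'
#' A target absent from one accession shows zero MDC there while the other
#' accession covers it at `min_present` reads or more.
#'
#' @param summaries output of [coverage_summary()]
#' @param min_present minimum MDC on the present side (default 10)
#' @param accessions accession names matching `mdc_<accession>` columns
#' @return data.table of calls: `target`, `kind` ("pav"), `accession`
#'   (absent side), `mdc_absent`, `mdc_present`
#' @export
call_pav <- function(summaries, min_present = 10L,
                     accessions = c("Ld", "Td")) {
  m1 <- summaries[[paste0("mdc_", accessions[1])]]
  m2 <- summaries[[paste0("mdc_", accessions[2])]]
  absent1 <- m1 == 0 & m2 >= min_present
  absent2 <- m2 == 0 & m1 >= min_present
  hit <- absent1 | absent2
  data.table::data.table(
    target = summaries$target[hit],
    kind = rep("pav", sum(hit)),
    accession = ifelse(absent1[hit], accessions[1], accessions[2]),
    mdc_absent = rep(0, sum(hit)),
    mdc_present = ifelse(absent1[hit], m2[hit], m1[hit])
  )
}

#' Detect homoeolog deletions from variant patterns
#'
#' At former divergence (GSS) positions, loss of one subgenome's copy in
#' one accession leaves that accession with a single variant where the
#' other shows two. Targets where more than `min_fraction` of variable
#' sites show this pattern are called homoeolog deletions; when both
#' accessions are fixed for consistently different alleles the deletion is
#' reciprocal.
#'
#' @param sites output of [call_variable_sites()] (all variable sites of
#'   the targets under test)
#' @param min_fraction single-variant fraction required (strict >, default 0.7)
#' @param min_sites minimum variable sites per target (default 3)
#' @param accessions accession names in site-column order
#' @param targets optional restriction (e.g. [eligible_targets()])
#' @return data.table of calls: `target`, `kind`
#'   (homoeolog_deletion/reciprocal_deletion), `accession` (deleted side,
#'   "both" for reciprocal), `n_sites`, `single_variant_fraction`
#' @export
homoeolog_deletion <- function(sites, min_fraction = 0.7, min_sites = 3L,
                               accessions = c("Ld", "Td"),
                               targets = NULL) {
  s <- data.table::copy(sites)
  if (!is.null(targets)) s <- s[target %in% targets]
  if (nrow(s) == 0L) {
    return(data.table::data.table(target = character(), kind = character(),
                                  accession = character(), n_sites = integer(),
                                  single_variant_fraction = numeric()))
  }
  s[, `:=`(
    single1 = xor(n1_a1 > 0L, n1_a2 > 0L),
    single2 = xor(n2_a1 > 0L, n2_a2 > 0L),
    both1 = n1_a1 > 0L & n1_a2 > 0L,
    both2 = n2_a1 > 0L & n2_a2 > 0L,
    kept1 = ifelse(n1_a1 > 0L, a1, a2),
    kept2 = ifelse(n2_a1 > 0L, a1, a2)
  )]
  calls <- s[, {
    if (.N >= min_sites) {
      f1 <- mean(single1 & both2)
      f2 <- mean(single2 & both1)
      frecip <- mean(single1 & single2 & kept1 != kept2)
      if (frecip > min_fraction) {
        .(kind = "reciprocal_deletion", accession = "both",
          n_sites = .N, single_variant_fraction = frecip)
      } else if (f1 > min_fraction) {
        .(kind = "homoeolog_deletion", accession = accessions[1],
          n_sites = .N, single_variant_fraction = f1)
      } else if (f2 > min_fraction) {
        .(kind = "homoeolog_deletion", accession = accessions[2],
          n_sites = .N, single_variant_fraction = f2)
      } else NULL
    } else NULL
  }, by = target]
  calls[]
}
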