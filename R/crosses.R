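#' Cross-progeny genotype tables
#'
#' A cross table is a tibble with a `progeny` id column and one column per
#' marker holding calls in `{"A", "B", "both", NA}` — the two parental
#' alleles, a heterozygous call that flags the progeny as diploid/aneuploid,
#' or missing. Marker physical positions (kb) are attached as the `markers`
#' attribute, a tibble with columns `marker` and `kb` ordered along the
#' chromosome; marker column order must match.
#'
#' @param genotypes Tibble/data frame: `progeny` + one column per marker.
#' @param markers Tibble with columns `marker`, `kb` (increasing).
#' @return A tibble of class `cross_table`.
#' @export
cross_table <- function(genotypes, markers) {
  genotypes <- as_tibble(genotypes)
  markers <- as_tibble(markers)
  if (!"progeny" %in% names(genotypes)) abort("need a progeny column")
  miss <- setdiff(markers$marker, names(genotypes))
  if (length(miss) > 0) {
    abort(paste0("marker columns missing: ", paste(miss, collapse = ", ")))
  }
  if (is.unsorted(markers$kb, strictly = TRUE)) {
    abort("marker kb positions must be strictly increasing")
  }
  vals <- unlist(genotypes[markers$marker])
  bad <- setdiff(unique(vals[!is.na(vals)]), c("A", "B", "both"))
  if (length(bad) > 0) {
    abort(paste0("invalid genotype calls: ", paste(bad, collapse = ", ")))
  }
  structure(genotypes, markers = markers,
            class = c("cross_table", class(genotypes)))
}

cross_markers <- function(table) attr(table, "markers")

#' Exclude diploid/aneuploid progeny
#'
#' Progeny with a `"both"` call at any marker carry both parental alleles
#' and are removed from all downstream scoring (numerator and denominator).
#'
#' @param table A [cross_table()].
#' @return The filtered `cross_table`, with attribute `n_excluded`.
#' @export
exclude_diploids <- function(table) {
  mk <- cross_markers(table)$marker
  dip <- apply(as_tibble(table)[mk] == "both", 1, any, na.rm = TRUE)
  out <- cross_table(as_tibble(table)[!dip, , drop = FALSE],
                     cross_markers(table))
  attr(out, "n_excluded") <- sum(dip)
  out
}

#' Recombination frequency between two markers
#'
#' Diploid/aneuploid progeny (a `"both"` call at any marker) are excluded
#' from numerator and denominator; progeny missing a call at either marker
#' are dropped with a warning. A progeny is recombinant when its calls at
#' the two markers come from different parents.
#'
#' @param table A [cross_table()].
#' @param markerA,markerB Marker names.
#' @return One-row tibble: `n_recombinant`, `n_total_scored`, `n_excluded`,
#'   `frequency` (recombinants/scored), `cM` (100 x frequency).
#' @export
recombination_frequency <- function(table, markerA, markerB) {
  kept <- exclude_diploids(table)
  n_excluded <- attr(kept, "n_excluded")
  a <- kept[[markerA]]
  b <- kept[[markerB]]
  miss <- is.na(a) | is.na(b)
  if (any(miss)) {
    warn(paste0(sum(miss), " progeny missing a call at ", markerA, "/",
                markerB, "; dropped"))
    a <- a[!miss]
    b <- b[!miss]
  }
  rec <- sum(a != b)
  n <- length(a)
  tibble(n_recombinant = rec, n_total_scored = n,
         n_excluded = n_excluded,
         frequency = rec / n, cM = 100 * rec / n)
}

#' Expected recombinant count for a physical interval
#'
#' Under a genome-average physical-to-genetic ratio, an interval of
#' `region_kb` spans `region_kb / kb_per_cM` centimorgans, i.e. a
#' recombinant fraction of that many percent; the expected count among `n`
#' progeny is `n * (region_kb / kb_per_cM) / 100`.
#'
#' @param region_kb Physical size of the interval (kb).
#' @param kb_per_cM Physical-to-genetic ratio (kb per centimorgan).
#' @param n Number of scored progeny.
#' @return Expected number of recombinant progeny.
#' @export
expected_recombinants <- function(region_kb, kb_per_cM, n) {
  stopifnot(region_kb >= 0, kb_per_cM > 0, n > 0)
  n * (region_kb / kb_per_cM) / 100
}

#' Two-class chi-squared test of an observed recombinant count
#'
#' Goodness-of-fit with classes recombinant / non-recombinant, 1 degree of
#' freedom, no continuity correction:
#' `X^2 = (O-E)^2/E + ((n-O)-(n-E))^2/(n-E)`, with the upper-tail
#' chi-squared probability.
#'
#' @param observed Observed recombinant count.
#' @param region_kb,kb_per_cM,n As in [expected_recombinants()].
#' @return One-row tibble: `observed`, `expected`, `n`, `statistic`, `p`.
#' @examples
#' chi_squared_test(0, region_kb = 240, kb_per_cM = 100, n = 600)
#' @export
chi_squared_test <- function(observed, region_kb, kb_per_cM, n) {
  E <- expected_recombinants(region_kb, kb_per_cM, n)
  if (E <= 0) abort("expected count must be positive",
                    class = "mtpopgen_degenerate_input")
  if (E >= n) abort("expected count reaches the sample size",
                    class = "mtpopgen_degenerate_input")
  stat <- (observed - E)^2 / E + ((n - observed) - (n - E))^2 / (n - E)
  tibble(observed = observed, expected = E, n = n, statistic = stat,
         p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Crossover intervals per recombinant progeny
#'
#' For each progeny, reports every interval between consecutive markers at
#' which the parental origin switches (the minimal-crossover reading of the
#' genotypes). A switch observed across a run of missing calls is reported
#' as an ambiguous interval spanning from the last informative marker to
#' the next one. Diploid progeny are excluded.
#'
#' @param table A [cross_table()] with at least 3 ordered markers.
#' @return Tibble: `progeny`, `from_marker`, `to_marker`, `from_kb`,
#'   `to_kb`, `ambiguous` (TRUE when the interval spans missing calls).
#' @export
assign_crossover_intervals <- function(table) {
  mk <- cross_markers(table)
  if (nrow(mk) < 3) abort("need at least 3 ordered markers")
  kept <- exclude_diploids(table)
  out <- list()
  for (i in seq_len(nrow(kept))) {
    calls <- unlist(as_tibble(kept)[i, mk$marker])
    inf <- which(!is.na(calls))
    if (length(inf) < 2) next
    for (j in seq_len(length(inf) - 1)) {
      i1 <- inf[j]
      i2 <- inf[j + 1]
      if (calls[i1] != calls[i2]) {
        out[[length(out) + 1L]] <- tibble(
          progeny = kept$progeny[i],
          from_marker = mk$marker[i1], to_marker = mk$marker[i2],
          from_kb = mk$kb[i1], to_kb = mk$kb[i2],
          ambiguous = (i2 - i1) > 1L)
      }
    }
  }
  if (length(out) == 0) {
    tibble(progeny = character(), from_marker = character(),
           to_marker = character(), from_kb = numeric(), to_kb = numeric(),
           ambiguous = logical())
  } else {
    bind_rows(out)
  }
}

#' Read/write a cross table as TSV
#'
#' Layout: a `progeny` column plus one column per marker; the marker map is
#' a second TSV with columns `marker`, `kb`.
#'
#' @param genotype_path,marker_path TSV paths.
#' @export
read_cross_table <- function(genotype_path, marker_path) {
  gt <- readr::read_tsv(genotype_path,
                        col_types = readr::cols(.default = "c"),
                        na = c("", "NA"), progress = FALSE)
  mk <- readr::read_tsv(marker_path, col_types = "cd", progress = FALSE)
  cross_table(gt, mk)
}

#' @rdname read_cross_table
#' @param table A [cross_table()].
#' @export
write_cross_table <- function(table, genotype_path, marker_path) {
  readr::write_tsv(as_tibble(table), genotype_path)
  readr::write_tsv(cross_markers(table), marker_path)
  invisible(table)
}
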