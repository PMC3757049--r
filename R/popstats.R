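#' Nucleotide diversity (pi) over a site mask
#'
#' Average number of pairwise differences per analysed site,
#' `pi = [2 / (n(n-1))] * sum_{i<j} diff(i,j) / |mask|`, with a standard
#' deviation estimated by site bootstrap (resampling masked columns with
#' replacement).
#'
#' @param aln A [labeled_alignment()].
#' @param mask A `site_mask`, or one of `"silent"`, `"ungapped"`, `"all"`,
#'   or an integer vector of columns.
#' @param bootstrap_reps Site-bootstrap replicates for `pi_sd` (0 skips).
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble: `pi`, `pi_sd`, `n_sequences`, `n_sites`,
#'   `n_segregating`.
#' @examples
#' aln <- labeled_alignment(
#'   c(a = "AAAA", b = "AATA"), c(a = "G1", b = "G1")
#' )
#' nucleotide_diversity(aln, "all", bootstrap_reps = 0)
#' @export
nucleotide_diversity <- function(aln, mask = "silent",
                                 bootstrap_reps = 1000, seed = 1L) {
  mask <- resolve_mask(aln, mask)
  if (length(mask) == 0) {
    abort("empty site mask", class = "mtpopgen_degenerate_input")
  }
  mat <- aln$seq[, as.integer(mask), drop = FALSE]
  n <- nrow(mat)
  if (n < 2) abort("need at least 2 sequences",
                   class = "mtpopgen_degenerate_input")
  het <- column_heterozygosity(mat)
  pi <- mean(het)
  pi_sd <- NA_real_
  if (bootstrap_reps > 0) {
    pi_sd <- withr::with_seed(seed, {
      reps <- vapply(seq_len(bootstrap_reps), function(i) {
        mean(het[sample.int(length(het), replace = TRUE)])
      }, numeric(1))
      sd(reps)
    })
  }
  tibble(pi = pi, pi_sd = pi_sd, n_sequences = n,
         n_sites = length(mask),
         n_segregating = sum(apply(mat, 2, function(x) length(unique(x)) > 1)))
}

# per-column mean pairwise difference (sample heterozygosity):
# sum_{a<b} c_a c_b / C(n,2)
column_heterozygosity <- function(mat) {
  n <- nrow(mat)
  npairs <- n * (n - 1) / 2
  apply(mat, 2, function(x) {
    cnt <- table(x)
    (npairs - sum(cnt * (cnt - 1) / 2)) / npairs
  })
}

# mean between-group p-distance per column, averaged over columns
between_heterozygosity <- function(mat1, mat2) {
  diffs <- vapply(seq_len(ncol(mat1)), function(j) {
    sum(outer(mat1[, j], mat2[, j], "!=")) / (nrow(mat1) * nrow(mat2))
  }, numeric(1))
  mean(diffs)
}

#' Tajima's D over a site mask
#'
#' D from the number of segregating masked sites S and the total mean
#' pairwise difference count, with the Tajima (1989) constants. When S = 0
#' or n < 4 the statistic is undefined and `defined = FALSE` is returned
#' rather than `NaN`.
#'
#' @inheritParams nucleotide_diversity
#' @return One-row tibble: `d_statistic`, `theta_pi` (mean pairwise
#'   differences, total over the mask), `theta_w` (S / a1), `n_segregating`,
#'   `defined`.
#' @export
tajimas_d <- function(aln, mask = "silent") {
  mask <- resolve_mask(aln, mask)
  mat <- aln$seq[, as.integer(mask), drop = FALSE]
  n <- nrow(mat)
  if (n < 4) abort("Tajima's D needs at least 4 sequences",
                   class = "mtpopgen_insufficient_sample")
  S <- sum(apply(mat, 2, function(x) length(unique(x)) > 1))
  theta_pi <- sum(column_heterozygosity(mat))
  a1 <- sum(1 / seq_len(n - 1))
  if (S == 0) {
    return(tibble(d_statistic = NA_real_, theta_pi = theta_pi,
                  theta_w = 0, n_segregating = 0L, defined = FALSE))
  }
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  tibble(d_statistic = D, theta_pi = theta_pi, theta_w = S / a1,
         n_segregating = as.integer(S), defined = TRUE)
}

jc_correct <- function(p) {
  if (any(p >= 0.75)) {
    abort("p-distance at or beyond Jukes-Cantor saturation (p >= 3/4)",
          class = "mtpopgen_saturation_error")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Differentiation between two groups: d_XY, d_A and Hudson's F_ST
#'
#' `d_xy` is the Jukes-Cantor-corrected mean between-group p-distance,
#' `d_a = d_xy - (d_x + d_y)/2` nets out the (JC-corrected) within-group
#' diversities, and `fst = 1 - Hw/Hb` is the Hudson-Slatkin-Maddison
#' estimator with `Hw = (pi_1 + pi_2)/2` and `Hb` the uncorrected mean
#' between-group p-distance. This estimator can be negative in panmictic
#' samples.
#'
#' @inheritParams nucleotide_diversity
#' @param group1,group2 Group labels present in `aln`. Defaults to the two
#'   panel groups.
#' @return One-row tibble: `d_xy`, `d_a`, `fst`, `pi_within_1`,
#'   `pi_within_2`, `h_between`, `fst_defined`.
#' @export
differentiation <- function(aln, mask = "ungapped",
                            group1 = NULL, group2 = NULL) {
  lv <- group_levels(aln)
  group1 <- group1 %||% lv[1]
  group2 <- group2 %||% lv[2]
  mask <- resolve_mask(aln, mask)
  if (length(mask) == 0) abort("empty site mask",
                               class = "mtpopgen_degenerate_input")
  t1 <- aln_taxa(aln)[aln$groups == group1]
  t2 <- aln_taxa(aln)[aln$groups == group2]
  if (length(t1) < 2 || length(t2) < 2) {
    abort("both groups need at least 2 sequences",
          class = "mtpopgen_insufficient_sample")
  }
  mat1 <- aln$seq[t1, as.integer(mask), drop = FALSE]
  mat2 <- aln$seq[t2, as.integer(mask), drop = FALSE]
  pi1 <- mean(column_heterozygosity(mat1))
  pi2 <- mean(column_heterozygosity(mat2))
  hb <- between_heterozygosity(mat1, mat2)
  d_xy <- jc_correct(hb)
  d_a <- d_xy - (jc_correct(pi1) + jc_correct(pi2)) / 2
  hw <- (pi1 + pi2) / 2
  fst_defined <- hb > 0
  fst <- if (fst_defined) 1 - hw / hb else NA_real_
  if (!fst_defined && hw == 0) {
    warn("no variation within or between groups: F_ST undefined")
  }
  tibble(d_xy = d_xy, d_a = d_a, fst = fst,
         pi_within_1 = pi1, pi_within_2 = pi2,
         h_between = hb, fst_defined = fst_defined)
}

#' Recompute a statistic on a taxon subset
#'
#' The alignment is restricted to `taxa_subset` and the mask is recomputed
#' on the restricted panel (gap and synonymy patterns depend on the sample),
#' mirroring the sub-sampling control used to rule out sampling bias when
#' panels of different size are compared.
#'
#' @inheritParams nucleotide_diversity
#' @param taxa_subset Character vector of taxa (length >= 2).
#' @param statistic `"pi"` or `"tajima"`.
#' @param mask_kind `"silent"`, `"ungapped"` or `"all"` — recomputed on the
#'   subset.
#' @return The statistic's tibble, with an `n_taxa` column appended.
#' @export
subsample_statistic <- function(aln, taxa_subset, statistic = "pi",
                                mask_kind = "silent",
                                bootstrap_reps = 1000, seed = 1L) {
  sub <- subset_taxa(aln, taxa_subset)
  out <- switch(statistic,
                pi = nucleotide_diversity(sub, mask_kind,
                                          bootstrap_reps = bootstrap_reps,
                                          seed = seed),
                tajima = tajimas_d(sub, mask_kind),
                abort(paste0("unknown statistic: ", statistic)))
  mutate(out, n_taxa = length(taxa_subset))
}
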