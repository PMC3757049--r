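#' Specification of a synthetic two-group sequence panel
#'
#' Defaults emulate the study design this package is built around: a panel
#' of 7 isolates of one mating type and 6 of the other, with tunable rates
#' of fixed inter-group differences (`delta_fixed`, the differentiated
#' R-domain regime) and within-group biallelic polymorphism
#' (`theta_within`, the panmictic C/T-domain and autosomal regime), plus
#' optional planted gene-conversion tracts. Within-group minor-allele
#' frequencies are drawn from the lattice `{1/n, 2/n, ...}` so that carrier
#' frequencies such as 1/3 are exactly constructible.
#'
#' @param n_plus,n_minus Group sizes (default 7 and 6).
#' @param L Locus length in columns.
#' @param group_labels Length-2 character: the two group labels.
#' @param theta_within Per-site probability that a column is polymorphic
#'   within a given group.
#' @param delta_fixed Per-site probability of a fixed inter-group
#'   difference.
#' @param maf_counts Candidate derived-allele carrier counts within a
#'   group, sampled uniformly when supplied (so frequencies like 2/6 are
#'   exactly constructible). Default `NULL` draws counts `1 .. n-1` with
#'   weights proportional to `1/k`, the neutral site-frequency spectrum, so
#'   default panels are neutral in the Tajima's-D sense.
#' @param conversion_plants List of plants, each a list with elements
#'   `recipient` (taxon names or indices within the recipient group),
#'   `donor_group` (label), `k` (number of consecutive informative sites),
#'   and optional `at` (index of the first informative site of the tract
#'   among the fixed-difference sites, default centred).
#' @param region_layout Optional annotation tibble (`position`, `region`,
#'   `frame`); defaults to all-intergenic.
#' @param panmictic When `TRUE`, polymorphic-site carriers are drawn from
#'   the pooled panel irrespective of group (the collinear-flank /
#'   autosomal regime, where group labels are arbitrary with respect to
#'   variation); requires `delta_fixed = 0`. When `FALSE` (default) each
#'   group receives its own within-group polymorphisms (the differentiated
#'   regime).
#' @param seed Integer seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_plus = 7, n_minus = 6, L = 2000,
                       group_labels = c("MT+", "MT-"),
                       theta_within = 0.01, delta_fixed = 0.01,
                       maf_counts = NULL, conversion_plants = list(),
                       region_layout = NULL, panmictic = FALSE, seed = 1L) {
  stopifnot(theta_within >= 0, theta_within <= 1,
            delta_fixed >= 0, delta_fixed <= 1,
            n_plus >= 1, n_minus >= 1, L >= 1)
  if (panmictic && delta_fixed > 0) {
    abort("panmictic panels cannot carry fixed inter-group differences",
          class = "mtpopgen_spec_error")
  }
  structure(list(n_plus = n_plus, n_minus = n_minus, L = L,
                 group_labels = group_labels,
                 theta_within = theta_within, delta_fixed = delta_fixed,
                 maf_counts = maf_counts,
                 conversion_plants = conversion_plants,
                 region_layout = region_layout, panmictic = panmictic,
                 seed = seed),
            class = "panel_spec")
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(BASES, x), 1), character(1))
}

#' Simulate a two-group panel
#'
#' Generates an ancestral sequence, plants fixed inter-group differences at
#' per-site rate `delta_fixed`, sprinkles within-group biallelic
#' polymorphisms at rate `theta_within` (independently per group, carrier
#' subsets drawn uniformly at the drawn minor-allele count), then copies
#' donor alleles into the recipients over each planted conversion tract.
#' Bit-reproducible from `spec$seed`.
#'
#' @param spec A [panel_spec()].
#' @return A [labeled_alignment()]. Attribute `truth` records the fixed
#'   difference positions and planted tract coordinates.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  withr::with_seed(spec$seed, simulate_panel_impl(spec))
}

simulate_panel_impl <- function(spec) {
  lv <- spec$group_labels
  taxa <- c(paste0("plus", seq_len(spec$n_plus)),
            paste0("minus", seq_len(spec$n_minus)))
  groups <- setNames(rep(lv, c(spec$n_plus, spec$n_minus)), taxa)
  L <- spec$L
  anc <- sample(BASES, L, replace = TRUE)
  mat <- matrix(rep(anc, each = length(taxa)), nrow = length(taxa),
                dimnames = list(taxa, NULL))
  g1 <- which(groups == lv[1])
  g2 <- which(groups == lv[2])

  fixed_sites <- which(stats::runif(L) < spec$delta_fixed)
  for (col in fixed_sites) {
    mat[g2, col] <- other_base(anc[col])
  }
  pools <- if (isTRUE(spec$panmictic)) list(c(g1, g2)) else list(g1, g2)
  for (gidx in pools) {
    n <- length(gidx)
    if (is.null(spec$maf_counts)) {
      counts <- seq_len(n - 1)
      wts <- 1 / counts  # neutral site-frequency spectrum
    } else {
      counts <- spec$maf_counts[spec$maf_counts < n]
      wts <- rep(1, length(counts))
    }
    if (length(counts) == 0) next
    poly_sites <- which(stats::runif(L) < spec$theta_within)
    for (col in poly_sites) {
      k <- if (length(counts) == 1) counts else
        sample(counts, 1, prob = wts)
      carriers <- gidx[sample.int(n, k)]
      mat[carriers, col] <- other_base(mat[gidx[1], col])
    }
  }
  tracts <- list()
  for (plant in spec$conversion_plants) {
    donor <- plant$donor_group
    recip_lab <- setdiff(lv, donor)
    recip_all <- if (recip_lab == lv[1]) g1 else g2
    donor_all <- if (donor == lv[1]) g1 else g2
    recipients <- plant$recipient
    if (is.numeric(recipients)) recipients <- taxa[recip_all][recipients]
    if (length(fixed_sites) < plant$k) {
      abort("planted tract larger than available informative sites",
            class = "mtpopgen_spec_error")
    }
    at <- plant$at %||% max(1L, floor((length(fixed_sites) - plant$k) / 2))
    if (at + plant$k - 1L > length(fixed_sites)) {
      abort("planted tract exceeds available informative sites",
            class = "mtpopgen_spec_error")
    }
    run <- fixed_sites[at:(at + plant$k - 1L)]
    for (col in run) {
      mat[recipients, col] <- mat[taxa[donor_all][1], col]
    }
    tracts[[length(tracts) + 1L]] <- list(recipients = recipients,
                                          donor_group = donor,
                                          positions = run)
  }
  aln <- labeled_alignment(mat, groups, spec$region_layout)
  attr(aln, "truth") <- list(fixed_sites = fixed_sites, tracts = tracts)
  aln
}

#' Specification of a simulated cross
#'
#' @param markers Tibble with columns `marker`, `kb` (increasing).
#' @param rf_per_interval Recombination fractions between consecutive
#'   markers (length `nrow(markers) - 1`, each in \[0, 0.5\]).
#' @param n_progeny Number of progeny.
#' @param diploid_rate Probability a progeny is diploid/aneuploid and
#'   scored `"both"` at every marker.
#' @param seed Integer seed.
#' @return A `cross_spec` list.
#' @export
cross_spec <- function(markers, rf_per_interval, n_progeny,
                       diploid_rate = 0, seed = 1L) {
  markers <- as_tibble(markers)
  stopifnot(length(rf_per_interval) == nrow(markers) - 1,
            all(rf_per_interval >= 0), all(rf_per_interval <= 0.5),
            !is.unsorted(markers$kb, strictly = TRUE),
            diploid_rate >= 0, diploid_rate <= 1)
  structure(list(markers = markers, rf = rf_per_interval,
                 n_progeny = n_progeny, diploid_rate = diploid_rate,
                 seed = seed),
            class = "cross_spec")
}

#' Simulate haploid cross progeny
#'
#' Each progeny's parental origin is generated marker by marker along the
#' chromosome: the first marker is drawn 50/50 and each interval switches
#' parent with its recombination fraction. Diploid progeny (probability
#' `diploid_rate`) are scored `"both"` at every marker.
#'
#' @param spec A [cross_spec()].
#' @return A [cross_table()].
#' @export
simulate_cross <- function(spec) {
  stopifnot(inherits(spec, "cross_spec"))
  withr::with_seed(spec$seed, {
    m <- nrow(spec$markers)
    rows <- lapply(seq_len(spec$n_progeny), function(i) {
      if (stats::runif(1) < spec$diploid_rate) {
        return(rep("both", m))
      }
      g <- character(m)
      g[1] <- sample(c("A", "B"), 1)
      for (j in seq_len(m - 1)) {
        switch_ <- stats::runif(1) < spec$rf[j]
        g[j + 1] <- if (switch_) setdiff(c("A", "B"), g[j]) else g[j]
      }
      g
    })
    gt <- as_tibble(do.call(rbind, rows), .name_repair = "minimal")
    names(gt) <- spec$markers$marker
    gt <- dplyr::bind_cols(
      tibble(progeny = sprintf("p%04d", seq_len(spec$n_progeny))), gt)
    cross_table(gt, spec$markers)
  })
}

#' Deterministic conversion-tract fixture panel
#'
#' A small fixed panel shaped like the polymorphism tables of the study's
#' differentiated R-domain genes: 7 isolates of one mating type and 6 of
#' the other, a backbone of fixed inter-group differences, within-group
#' polymorphism concentrated in the second group (so the first group's
#' diversity is lower), an exon/intron structure giving both synonymous and
#' non-synonymous segregating sites, and one conversion tract of four
#' consecutive informative sites carried by exactly 2 of the 6 recipients
#' (per-site carrier frequency 1/3, tract probability (1/3)^4 ~ 0.012),
#' with direction from the first group into the second.
#'
#' @return A [labeled_alignment()] with attribute `truth` giving the
#'   planted tract.
#' @export
fixture_fig6 <- function() {
  n_plus <- 7
  n_minus <- 6
  taxa <- c(paste0("plus", 1:n_plus), paste0("minus", 1:n_minus))
  groups <- setNames(rep(c("MT+", "MT-"), c(n_plus, n_minus)), taxa)
  L <- 120
  base <- rep(c("A", "C", "G", "T"), length.out = L)
  mat <- matrix(rep(base, each = length(taxa)), nrow = length(taxa),
                dimnames = list(taxa, NULL))
  plus <- 1:n_plus
  minus <- n_plus + (1:n_minus)

  # fixed differences between the groups (informative backbone)
  fixed_pos <- c(6, 15, 24, 33, 42, 51, 60, 69, 78, 87, 96, 105)
  swap <- c(A = "G", C = "T", G = "A", T = "C")
  for (col in fixed_pos) mat[minus, col] <- swap[[base[col]]]

  # conversion tract: minus5 + minus6 carry the MT+ allele at four
  # consecutive informative sites (42, 51, 60, 69)
  tract_pos <- c(42, 51, 60, 69)
  recipients <- c("minus5", "minus6")
  for (col in tract_pos) mat[recipients, col] <- base[col]

  # within-group polymorphism: one MT+ singleton, four MT- variants
  mat["plus3", 10] <- swap[[base[10]]]
  mat["minus2", 20] <- swap[[base[20]]]
  mat[c("minus3", "minus4"), 29] <- swap[[base[29]]]
  mat["minus1", 38] <- swap[[base[38]]]
  mat[c("minus1", "minus2", "minus3"), 47] <- swap[[base[47]]]

  # exon block 1..60 in frame 1; make position 24 (frame 3) synonymous
  # (GGG->GGA, Gly) and 33 (frame 3) too; 15 (frame 3) CCC->CCT Pro; the
  # backbone pattern ACGT repeats so frame-3 fixed sites are third codon
  # positions; position 6 (G->A at frame 3) AC G -> AC A (Thr/Thr).
  annotation <- tibble(position = 1:L,
                       region = c(rep("exon", 60), rep("intron", 60)),
                       frame = c(rep(1:3, 20), rep(NA_integer_, 60)))
  aln <- labeled_alignment(mat, groups, annotation)
  attr(aln, "truth") <- list(tract = list(recipients = recipients,
                                          donor_group = "MT+",
                                          positions = tract_pos),
                             fixed_sites = setdiff(fixed_pos, tract_pos))
  aln
}
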