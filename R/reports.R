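#' Per-locus population-genetic report
#'
#' Orchestrates the pipeline over a set of loci: for each group-labelled
#' alignment it computes silent-site diversity (total and per group) with
#' bootstrap SDs, Tajima's D, d_XY / d_A / F_ST between the two groups, the
#' polymorphism table and conversion-tract report, and (optionally) the
#' parsimony-splits system. When `out_dir` is given the per-locus tables
#' are written as TSV (`<locus>_polymorphisms.tsv`, `<locus>_tracts.tsv`),
#' the split system as Nexus (`<locus>_splits.nex`), the summary as
#' `locus_report.tsv`, and a `run_log.txt` records package version, seeds
#' and parameters so every number is re-derivable.
#'
#' @param loci Named list of [labeled_alignment()] objects, or a tibble
#'   with columns `locus`, `fasta`, `samplesheet`, `annotation` of input
#'   paths.
#' @param out_dir Output directory (`NULL` = return tibble only).
#' @param mask Mask kind for the diversity statistics
#'   (`"silent"`/`"ungapped"`/`"all"`).
#' @param bootstrap_reps Site-bootstrap replicates for pi SDs.
#' @param alpha Tract-report threshold.
#' @param min_fixation Informative-site threshold for tract detection.
#' @param splits Compute parsimony splits per locus (requires ungapped
#'   panels of <= `max_taxa` distinct haplotypes)?
#' @param splits_bootstrap_reps Bootstrap replicates for split support
#'   (0 = none).
#' @param seed Integer seed driving every stochastic stage.
#' @return A tibble with one row per locus: sample sizes, `pi_sil` x 1000
#'   (total / per group) with SDs, `tajima_d`, `fst`, `d_xy`, `d_a`,
#'   `n_tracts`.
#' @export
run_locus_report <- function(loci, out_dir = NULL, mask = "silent",
                             bootstrap_reps = 1000, alpha = 0.05,
                             min_fixation = 0.5, splits = FALSE,
                             splits_bootstrap_reps = 0, seed = 1L) {
  if (is.data.frame(loci)) {
    paths <- loci
    loci <- lapply(seq_len(nrow(paths)), function(i) {
      read_alignment(paths$fasta[i], paths$samplesheet[i],
                     paths$annotation[i] %||% NULL)
    })
    names(loci) <- paths$locus
  }
  if (length(loci) > 0 && is.null(names(loci))) {
    abort("loci must be named")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  for (nm in names(loci)) {
    aln <- loci[[nm]]
    lv <- group_levels(aln)
    m <- resolve_mask(aln, mask)
    div_total <- nucleotide_diversity(aln, m, bootstrap_reps, seed)
    per_group <- lapply(lv, function(g) {
      taxa <- aln_taxa(aln)[aln$groups == g]
      if (length(taxa) < 2) {
        return(tibble(pi = NA_real_, pi_sd = NA_real_))
      }
      subsample_statistic(aln, taxa, "pi", mask_kind = mask,
                          bootstrap_reps = bootstrap_reps, seed = seed)
    })
    taj <- tajimas_d(aln, m)
    diff <- tryCatch(differentiation(aln, "ungapped", lv[1], lv[2]),
                     error = function(e) {
                       tibble(d_xy = NA_real_, d_a = NA_real_,
                              fst = NA_real_)
                     })
    ptab <- build_polymorphism_table(aln)
    tracts <- detect_tracts(ptab, alpha = alpha,
                            min_fixation = min_fixation)
    if (!is.null(out_dir)) {
      write_polymorphism_table(ptab,
                               file.path(out_dir,
                                         paste0(nm, "_polymorphisms.tsv")))
      write_tract_report(tracts,
                         file.path(out_dir, paste0(nm, "_tracts.tsv")))
    }
    if (splits) {
      ung <- ungapped_mask(aln)
      sub <- labeled_alignment(aln$seq[, as.integer(ung), drop = FALSE],
                               aln$groups)
      ss <- if (splits_bootstrap_reps > 0) {
        bootstrap_splits(sub, reps = splits_bootstrap_reps, seed = seed)
      } else {
        parsimony_splits(sub)
      }
      if (!is.null(out_dir)) {
        write_splits_nexus(ss, file.path(out_dir, paste0(nm, "_splits.nex")))
      }
    }
    rows[[nm]] <- tibble(
      locus = nm,
      n_group1 = sum(aln$groups == lv[1]),
      n_group2 = sum(aln$groups == lv[2]),
      n_sites = div_total$n_sites,
      n_segregating = div_total$n_segregating,
      pi_sil_1000 = 1000 * div_total$pi,
      pi_sil_sd_1000 = 1000 * div_total$pi_sd,
      pi_sil_1000_group1 = 1000 * per_group[[1]]$pi,
      pi_sil_sd_1000_group1 = 1000 * per_group[[1]]$pi_sd,
      pi_sil_1000_group2 = 1000 * per_group[[2]]$pi,
      pi_sil_sd_1000_group2 = 1000 * per_group[[2]]$pi_sd,
      tajima_d = taj$d_statistic,
      fst = diff$fst, d_xy = diff$d_xy, d_a = diff$d_a,
      n_tracts = nrow(tracts))
  }
  report <- bind_rows(rows)
  if (!is.null(out_dir)) {
    readr::write_tsv(report, file.path(out_dir, "locus_report.tsv"))
    writeLines(c(paste0("mtpopgen ",
                        as.character(utils::packageVersion("mtpopgen"))),
                 paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 paste0("mask: ", if (is.character(mask)) mask else "custom"),
                 paste0("bootstrap_reps: ", bootstrap_reps),
                 paste0("alpha: ", alpha),
                 paste0("min_fixation: ", min_fixation),
                 paste0("seed: ", seed)),
               file.path(out_dir, "run_log.txt"))
  }
  report
}

#' Cross recombination report
#'
#' For each configured cross (either observed counts or a full
#' [cross_table()] plus a marker pair) computes the recombination
#' frequency, map distance and, against each supplied kb-per-cM baseline,
#' the expected recombinant count and the two-class chi-squared test.
#'
#' @param crosses Tibble with columns `cross`, `observed` (recombinant
#'   count), `n` (scored progeny) and `region_kb`; alternatively `observed`
#'   and `n` may be omitted row-wise by supplying `table`, `markerA`,
#'   `markerB` list-columns with a cross table to score.
#' @param kb_per_cM Numeric vector of physical-to-genetic baselines to test
#'   (default the genome-wide ~100 kb/cM and the most extreme known
#'   autosomal ratio, 511 kb/cM).
#' @param out_path Optional TSV output path.
#' @return Tibble: one row per cross x baseline with `frequency_pct`, `cM`,
#'   `expected`, `statistic`, `p`.
#' @export
run_cross_report <- function(crosses, kb_per_cM = c(100, 511),
                             out_path = NULL) {
  crosses <- as_tibble(crosses)
  rows <- list()
  for (i in seq_len(nrow(crosses))) {
    cr <- crosses[i, ]
    if ("table" %in% names(cr) && !is.null(cr$table[[1]])) {
      rf <- recombination_frequency(cr$table[[1]], cr$markerA[[1]],
                                    cr$markerB[[1]])
      obs <- rf$n_recombinant
      n <- rf$n_total_scored
    } else {
      obs <- cr$observed
      n <- cr$n
    }
    for (ratio in kb_per_cM) {
      chi <- chi_squared_test(obs, cr$region_kb, ratio, n)
      rows[[length(rows) + 1L]] <- tibble(
        cross = cr$cross, observed = obs, n = n,
        frequency_pct = 100 * obs / n, cM = 100 * obs / n,
        region_kb = cr$region_kb, kb_per_cM = ratio,
        expected = chi$expected, statistic = chi$statistic, p = chi$p)
    }
  }
  report <- bind_rows(rows)
  if (!is.null(out_path)) readr::write_tsv(report, out_path)
  report
}
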