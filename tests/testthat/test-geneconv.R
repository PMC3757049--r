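two_group_aln <- function(seqs_plus, seqs_minus, annotation = NULL) {
  seqs <- c(stats::setNames(seqs_plus, paste0("p", seq_along(seqs_plus))),
            stats::setNames(seqs_minus, paste0("m", seq_along(seqs_minus))))
  groups <- stats::setNames(rep(c("MT+", "MT-"),
                                c(length(seqs_plus), length(seqs_minus))),
                            names(seqs))
  labeled_alignment(seqs, groups, annotation)
}

test_that("polymorphism table lists and classifies segregating sites", {
  # one fixed difference -> one group-differentiating site
  aln <- two_group_aln(c("ACGT", "ACGT"), c("ACAT", "ACAT"))
  tab <- build_polymorphism_table(aln)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$position, 3L)
  expect_equal(tab$class, "fixed")

  # monomorphic alignment -> empty table
  aln <- two_group_aln(c("ACGT", "ACGT"), c("ACGT", "ACGT"))
  expect_equal(nrow(build_polymorphism_table(aln)), 0)

  # single-group panel is a grouping error
  expect_error(
    build_polymorphism_table(
      labeled_alignment(c(a = "AC", b = "AC"), c(a = "G1", b = "G1"))),
    class = "mtpopgen_grouping_error")

  # indel polymorphism appears once as a single event
  aln <- two_group_aln(c("AC--T", "AC--T"), c("ACGGT", "ACGGT"))
  tab <- build_polymorphism_table(aln)
  expect_equal(nrow(tab), 1)
  expect_true(tab$is_indel)
  expect_equal(tab$class, "fixed")
})

test_that("13-taxon panel classification equals a per-column brute force", {
  aln <- simulate_panel(panel_spec(n_plus = 7, n_minus = 6, L = 400,
                                   theta_within = 0.02, delta_fixed = 0.03,
                                   seed = 5))
  tab <- build_polymorphism_table(aln)
  snp <- tab[!tab$is_indel, ]
  mat <- aln$seq
  plus <- which(aln_groups(aln) == "MT+")
  minus <- which(aln_groups(aln) == "MT-")
  expected_positions <- integer()
  for (col in seq_len(ncol(mat))) {
    if (length(unique(mat[, col])) > 1) {
      expected_positions <- c(expected_positions, col)
    }
  }
  expect_identical(snp$position, expected_positions)
  for (i in seq_len(nrow(snp))) {
    col <- snp$position[i]
    a1 <- mat[plus, col]
    a2 <- mat[minus, col]
    cls <- if (length(unique(a1)) > 1 && length(unique(a2)) > 1) {
      "other"
    } else if (length(unique(a1)) == 1 && length(unique(a2)) == 1) {
      "fixed"
    } else {
      seg <- if (length(unique(a1)) > 1) a1 else a2
      mono <- if (length(unique(a1)) > 1) a2[1] else a1[1]
      lab <- if (length(unique(a1)) > 1) "MT+" else "MT-"
      cnt <- sort(table(seg), decreasing = TRUE)
      maj <- if (length(cnt) > 1 && cnt[1] == cnt[2]) NA else names(cnt)[1]
      if (!is.na(maj) && maj != mono) paste0("specific_", lab)
      else paste0("segregating_", lab)
    }
    expect_equal(snp$class[i], cls, label = paste("column", col))
  }
})

test_that("informative sites honour the fixation threshold", {
  # fixed A/G site is informative at min_fixation = 1
  aln <- two_group_aln(c("AT", "AT"), c("GT", "GT"))
  tab <- build_polymorphism_table(aln)
  expect_equal(informative_sites(tab, 1.0), 1L)

  # 50/50 segregation within a group is never informative
  aln <- two_group_aln(c("AT", "GT"), c("GT", "GT"))
  tab <- build_polymorphism_table(aln)
  expect_equal(informative_sites(tab, 1.0), integer())

  # mixed panel vs a counting oracle at min_fixation = 0.8
  aln <- simulate_panel(panel_spec(n_plus = 6, n_minus = 6, L = 300,
                                   theta_within = 0.03, delta_fixed = 0.03,
                                   seed = 9))
  tab <- build_polymorphism_table(aln)
  got <- informative_sites(tab, 0.8)
  mat <- aln$seq
  plus <- which(aln_groups(aln) == "MT+")
  minus <- which(aln_groups(aln) == "MT-")
  want <- integer()
  for (col in seq_len(ncol(mat))) {
    if (length(unique(mat[, col])) < 2) next
    f1 <- sort(table(mat[plus, col]), decreasing = TRUE)
    f2 <- sort(table(mat[minus, col]), decreasing = TRUE)
    tie1 <- length(f1) > 1 && f1[1] == f1[2]
    tie2 <- length(f2) > 1 && f2[1] == f2[2]
    if (tie1 || tie2) next
    if (names(f1)[1] != names(f2)[1] &&
        f1[1] / length(plus) >= 0.8 && f2[1] / length(minus) >= 0.8) {
      want <- c(want, col)
    }
  }
  expect_identical(got, want)
})

test_that("the four-site 1/3-frequency run scores p = (1/3)^4 and is reported", {
  aln <- fixture_fig6()
  tab <- build_polymorphism_table(aln)
  tracts <- detect_tracts(tab, alpha = 0.05)
  expect_equal(nrow(tracts), 1)
  expect_equal(tracts$donor_group, "MT+")
  expect_equal(tracts$recipient_group, "MT-")
  expect_equal(tracts$k, 4L)
  expect_equal(tracts$psi[[1]], rep(1 / 3, 4))
  expect_equal(tracts$p_value, (1 / 3)^4, tolerance = 1e-15)
  expect_lt(tracts$p_value, 0.05)
  # p equals the product of psi exactly
  expect_identical(tracts$p_value, prod(tracts$psi[[1]]))
})

test_that("a single switched site never forms a tract", {
  # 3 informative sites, middle one switched in recipient m2 only
  aln <- two_group_aln(
    c("ACA", "ACA", "ACA"),
    c("TGT", "TCT", "TGT"))  # m2 carries donor allele at site 2 only
  tab <- build_polymorphism_table(aln)
  tracts <- detect_tracts(tab, alpha = 1)
  expect_equal(nrow(tracts), 0)
})

test_that("planted tracts are recovered; null panels stay below alpha", {
  spec <- panel_spec(n_plus = 7, n_minus = 6, L = 1500,
                     theta_within = 0.005, delta_fixed = 0.02,
                     conversion_plants = list(list(
                       recipient = c(2, 5), donor_group = "MT+", k = 5)),
                     seed = 21)
  aln <- simulate_panel(spec)
  truth <- attr(aln, "truth")$tracts[[1]]
  tab <- build_polymorphism_table(aln)
  tracts <- detect_tracts(tab, alpha = 0.05)
  expect_gte(nrow(tracts), 1)
  hit <- tracts[tracts$start == min(truth$positions) &
                  tracts$end == max(truth$positions), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$donor_group, "MT+")
  expect_equal(hit$recipient_group, "MT-")
  expect_equal(sort(strsplit(hit$recipient_taxa, ",")[[1]]),
               sort(truth$recipients))

  # null panels (no conversion, fully fixed differences): false tracts at
  # rate <= alpha
  fp <- vapply(1:50, function(s) {
    aln0 <- simulate_panel(panel_spec(n_plus = 7, n_minus = 6, L = 600,
                                      theta_within = 0.005,
                                      delta_fixed = 0.02, seed = 1000 + s))
    nrow(detect_tracts(build_polymorphism_table(aln0), alpha = 0.05)) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.05 + 2 * sqrt(0.05 * 0.95 / 50))
})

test_that("tract detection is invariant to taxon order and label swap", {
  aln <- fixture_fig6()
  base <- detect_tracts(build_polymorphism_table(aln))

  perm <- withr::with_seed(3, sample(aln_taxa(aln)))
  reord <- detect_tracts(build_polymorphism_table(subset_taxa(aln, perm)))
  expect_equal(reord$start, base$start)
  expect_equal(reord$end, base$end)
  expect_equal(reord$p_value, base$p_value)
  expect_equal(reord$donor_group, base$donor_group)

  # swapping group labels flips direction labels, nothing else
  flipped_groups <- stats::setNames(
    ifelse(aln_groups(aln) == "MT+", "MT-", "MT+"), aln_taxa(aln))
  aln2 <- labeled_alignment(aln$seq, flipped_groups, aln$annotation)
  flip <- detect_tracts(build_polymorphism_table(aln2))
  expect_equal(flip$start, base$start)
  expect_equal(flip$p_value, base$p_value)
  expect_equal(flip$donor_group, "MT-")
  expect_equal(flip$recipient_group, "MT+")
})

test_that("no tracts are reported on fully fixed panels at min_fixation = 1", {
  aln <- simulate_panel(panel_spec(n_plus = 6, n_minus = 6, L = 500,
                                   theta_within = 0, delta_fixed = 0.03,
                                   seed = 77))
  tab <- build_polymorphism_table(aln)
  expect_equal(nrow(detect_tracts(tab, min_fixation = 1)), 0)
})
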