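strip_ct <- function(x) {
  x <- tibble::as_tibble(x)
  attr(x, "markers") <- NULL
  attr(x, "n_excluded") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

# helper: a two-marker cross table built from printed-style counts
counts_table <- function(n_parental, n_recombinant, n_diploid = 0) {
  n <- n_parental + n_recombinant + n_diploid
  half <- floor(n_parental / 2)
  g1 <- c(rep("A", half), rep("B", n_parental - half),
          rep("A", n_recombinant), rep("both", n_diploid))
  g2 <- c(rep("A", half), rep("B", n_parental - half),
          rep("B", n_recombinant), rep("both", n_diploid))
  cross_table(tibble::tibble(progeny = sprintf("p%04d", seq_len(n)),
                             NIC7 = g1, THI10 = g2),
              tibble::tibble(marker = c("NIC7", "THI10"), kb = c(0, 240)))
}

test_that("diploid exclusion removes 'both' progeny from both counts", {
  # 352 putative progeny, 2 carrying both alleles -> 350 scored
  tab <- counts_table(336, 14, 2)
  kept <- exclude_diploids(tab)
  expect_equal(nrow(kept), 350)
  expect_equal(attr(kept, "n_excluded"), 2)

  # no 'both' calls: table unchanged, retained genotypes unaltered
  tab0 <- counts_table(10, 2, 0)
  kept0 <- exclude_diploids(tab0)
  expect_equal(nrow(kept0), 12)
  expect_identical(strip_ct(kept0), strip_ct(tab0))

  # randomized tables vs a brute-force row filter
  for (seed in 1:4) {
    ct <- simulate_cross(cross_spec(
      tibble::tibble(marker = c("m1", "m2", "m3"), kb = c(0, 100, 240)),
      c(0.1, 0.2), n_progeny = 60, diploid_rate = 0.15, seed = seed))
    kept <- exclude_diploids(ct)
    raw <- tibble::as_tibble(ct)
    keep_rows <- logical(nrow(raw))
    for (i in seq_len(nrow(raw))) {
      keep_rows[i] <- !any(unlist(raw[i, c("m1", "m2", "m3")]) == "both",
                           na.rm = TRUE)
    }
    expect_identical(strip_ct(kept), strip_ct(raw[keep_rows, ]))
  }
})

test_that("recombination frequencies reproduce the printed cross counts", {
  # 14 recombinants / 350 scored (after excluding 2 diploids) -> ~4%
  rf <- recombination_frequency(counts_table(336, 14, 2), "NIC7", "THI10")
  expect_equal(rf$n_recombinant, 14)
  expect_equal(rf$n_total_scored, 350)
  expect_equal(100 * rf$frequency, 4, tolerance = 0.01)

  # 17 / 377 -> ~4.5%
  rf <- recombination_frequency(counts_table(360, 17), "NIC7", "THI10")
  expect_equal(100 * rf$frequency, 4.509, tolerance = 1e-3)

  # 26 / 96 -> 27 cM
  rf <- recombination_frequency(counts_table(70, 26), "NIC7", "THI10")
  expect_equal(rf$cM, 27.08, tolerance = 1e-2)

  # 0 / 600 -> frequency 0
  rf <- recombination_frequency(counts_table(600, 0), "NIC7", "THI10")
  expect_equal(rf$frequency, 0)

  # missing genotypes are dropped with a warning
  tab <- counts_table(10, 2)
  raw <- tibble::as_tibble(tab)
  raw$NIC7[1] <- NA
  tab <- cross_table(raw, attr(tab, "markers"))
  expect_warning(rf <- recombination_frequency(tab, "NIC7", "THI10"))
  expect_equal(rf$n_total_scored, 11)
})

test_that("expected recombinants follow the kb-per-cM arithmetic", {
  expect_equal(expected_recombinants(240, 100, 600), 14.4)
  expect_equal(expected_recombinants(0, 100, 600), 0)
  expect_equal(expected_recombinants(240, 511, 600), 600 * (240 / 511) / 100,
               tolerance = 1e-12)
})

test_that("two-class chi-squared reproduces the printed statistics", {
  # 0 observed over 240 kb at 100 kb/cM among 600 progeny
  res <- chi_squared_test(0, 240, 100, 600)
  expect_equal(res$statistic, 14.754, tolerance = 1e-3)
  expect_equal(round(res$statistic, 2), 14.75)
  expect_equal(res$p, 0.000122, tolerance = 1e-2)

  # same counts at the extreme 511 kb/cM autosomal ratio: ~2.83
  res511 <- chi_squared_test(0, 240, 511, 600)
  expect_equal(res511$statistic, 2.83, tolerance = 1e-2)
  expect_equal(res511$p, 0.092, tolerance = 2e-2)

  # O = E gives zero; the statistic grows with |O - E|
  e <- expected_recombinants(240, 100, 600)
  expect_equal(chi_squared_test(e, 240, 100, 600)$statistic, 0)
  stats <- vapply(c(0, 5, 10, 20, 30),
                  function(o) chi_squared_test(o, 240, 100, 600)$statistic,
                  numeric(1))
  expect_true(all(diff(stats[1:2]) < 0))  # approaching E from below
  expect_true(all(diff(stats[3:5]) > 0))  # receding above E

  expect_error(chi_squared_test(0, 0, 100, 600),
               class = "mtpopgen_degenerate_input")
})

test_that("crossover intervals are assigned minimally, with ambiguity flags", {
  mk <- tibble::tibble(marker = paste0("m", 1:4), kb = c(0, 50, 120, 240))
  tab <- cross_table(tibble::tibble(
    progeny = c("r1", "par", "amb"),
    m1 = c("A", "B", "A"),
    m2 = c("A", "B", NA),
    m3 = c("B", "B", NA),
    m4 = c("B", "B", "B")), mk)
  iv <- assign_crossover_intervals(tab)
  expect_equal(nrow(iv), 2)
  r1 <- iv[iv$progeny == "r1", ]
  expect_equal(r1$from_marker, "m2")
  expect_equal(r1$to_marker, "m3")
  expect_false(r1$ambiguous)
  amb <- iv[iv$progeny == "amb", ]
  expect_equal(amb$from_marker, "m1")
  expect_equal(amb$to_marker, "m4")
  expect_true(amb$ambiguous)

  # all-parental progeny contribute nothing
  tab2 <- cross_table(tibble::tibble(progeny = "p", m1 = "A", m2 = "A",
                                     m3 = "A", m4 = "A"), mk)
  expect_equal(nrow(assign_crossover_intervals(tab2)), 0)

  # planted crossovers are recovered exactly
  plant <- list(r1 = 2L, r2 = 1L, r3 = 3L)  # interval index per progeny
  rows <- lapply(names(plant), function(p) {
    g <- rep("A", 4)
    g[(plant[[p]] + 1):4] <- "B"
    c(progeny = p, stats::setNames(as.list(g), mk$marker))
  })
  tab3 <- cross_table(dplyr::bind_rows(lapply(rows, tibble::as_tibble)), mk)
  iv3 <- assign_crossover_intervals(tab3)
  for (p in names(plant)) {
    got <- iv3[iv3$progeny == p, ]
    expect_equal(got$from_marker, paste0("m", plant[[p]]))
    expect_equal(got$to_marker, paste0("m", plant[[p]] + 1))
  }
})

test_that("simulated crosses recover their planted recombination fractions", {
  mk <- tibble::tibble(marker = c("m1", "m2"), kb = c(0, 240))
  # rf = 0: all progeny parental
  ct <- simulate_cross(cross_spec(mk, 0, 200, seed = 1))
  expect_equal(recombination_frequency(ct, "m1", "m2")$n_recombinant, 0)

  # planted rf = 0.04 at n = 350 falls inside the exact binomial 95% CI
  ct <- simulate_cross(cross_spec(mk, 0.04, 350, seed = 2))
  rf <- recombination_frequency(ct, "m1", "m2")
  ci <- stats::binom.test(rf$n_recombinant, rf$n_total_scored)$conf.int
  expect_true(ci[1] <= 0.04 && 0.04 <= ci[2])

  # rf = 0.5: adjacent markers independent, fraction near 0.5 (n = 2000)
  ct <- simulate_cross(cross_spec(mk, 0.5, 2000, seed = 3))
  rf <- recombination_frequency(ct, "m1", "m2")
  ci <- stats::binom.test(rf$n_recombinant, rf$n_total_scored)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])

  # determinism and diploid flagging
  a <- simulate_cross(cross_spec(mk, 0.1, 100, diploid_rate = 0.2, seed = 9))
  b <- simulate_cross(cross_spec(mk, 0.1, 100, diploid_rate = 0.2, seed = 9))
  expect_identical(strip_ct(a), strip_ct(b))
  expect_gt(attr(exclude_diploids(a), "n_excluded"), 0)
})

test_that("cross tables round-trip through TSV", {
  ct <- simulate_cross(cross_spec(
    tibble::tibble(marker = c("m1", "m2", "m3"), kb = c(0, 80, 240)),
    c(0.05, 0.1), 40, diploid_rate = 0.1, seed = 4))
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_cross_table(ct, gp, mp)
  back <- read_cross_table(gp, mp)
  expect_identical(strip_ct(back), strip_ct(ct))
  expect_identical(attr(back, "markers"), attr(ct, "markers"))
})
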