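#' Tabulate polymorphic sites of a two-group panel
#'
#' The machine-readable version of a per-site polymorphism figure: every
#' segregating ungapped column, plus insertion/deletion polymorphisms
#' collapsed to single events (one row per maximal gapped run; carriers are
#' coded `-`, non-carriers `+`). Each site carries its region class, the
#' substitution type for exonic sites (`S` synonymous / `N` non-synonymous),
#' the allele of every taxon, and a mutually exclusive specificity class:
#'
#' * `fixed` — both groups monomorphic for different alleles
#'   (a group-differentiating site);
#' * `specific_<g>` — the other group is monomorphic and group `<g>`'s
#'   majority allele differs from it (a nearly fixed, haplotype-diagnostic
#'   site at which a minority of `<g>` matches the other haplotype);
#' * `segregating_<g>` — the other group is monomorphic and group `<g>`'s
#'   majority matches it (a low-frequency variant inside `<g>`);
#' * `other` — segregating within both groups.
#'
#' @param aln A [labeled_alignment()] with exactly two groups.
#' @return A tibble of class `polymorphism_table` with columns `position`
#'   (1-based), `region`, `type`, `is_indel`, `class`, and one allele column
#'   per taxon. Group labels are attached as attribute `groups`.
#' @export
build_polymorphism_table <- function(aln) {
  lv <- group_levels(aln)
  if (length(lv) != 2) {
    abort("polymorphism table needs exactly two groups",
          class = "mtpopgen_grouping_error")
  }
  mat <- aln$seq
  gapped <- apply(mat == "-" | mat == "N", 2, any)
  seg <- apply(mat, 2, function(x) length(unique(x)) > 1)

  rows <- list()
  # substitution sites: segregating ungapped columns
  for (col in which(seg & !gapped)) {
    alleles <- mat[, col]
    region <- aln$annotation$region[col]
    type <- NA_character_
    if (region == "exon") {
      type <- if (column_is_synonymous(aln, col)) "S" else "N"
    }
    rows[[length(rows) + 1L]] <- c(
      list(position = col, region = region, type = type, is_indel = FALSE,
           class = classify_site(alleles, aln$groups, lv)),
      as.list(alleles))
  }
  # indel events: maximal runs of columns containing a gap
  gap_runs <- rle(apply(mat == "-", 2, any))
  ends <- cumsum(gap_runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (i in which(gap_runs$values)) {
    idx <- starts[i]:ends[i]
    carrier <- apply(mat[, idx, drop = FALSE] == "-", 1, any)
    alleles <- ifelse(carrier, "-", "+")
    names(alleles) <- aln_taxa(aln)
    if (length(unique(alleles)) < 2) next  # gap fixed in everyone
    rows[[length(rows) + 1L]] <- c(
      list(position = starts[i], region = aln$annotation$region[starts[i]],
           type = NA_character_, is_indel = TRUE,
           class = classify_site(alleles, aln$groups, lv)),
      as.list(alleles))
  }
  tab <- if (length(rows) == 0) {
    empty <- c(list(position = integer(), region = character(),
                    type = character(), is_indel = logical(),
                    class = character()),
               setNames(rep(list(character()), nrow(mat)), aln_taxa(aln)))
    as_tibble(empty)
  } else {
    arrange(bind_rows(lapply(rows, as_tibble)), .data$position)
  }
  structure(tab, groups = aln$groups, group_levels = lv,
            class = c("polymorphism_table", class(tab)))
}

classify_site <- function(alleles, groups, lv) {
  a1 <- alleles[names(groups)[groups == lv[1]]]
  a2 <- alleles[names(groups)[groups == lv[2]]]
  p1 <- length(unique(a1)) > 1
  p2 <- length(unique(a2)) > 1
  if (p1 && p2) return("other")
  if (!p1 && !p2) {
    return(if (a1[1] != a2[1]) "fixed" else "invariant")
  }
  seg_g <- if (p1) lv[1] else lv[2]
  seg_alleles <- if (p1) a1 else a2
  mono_allele <- if (p1) a2[1] else a1[1]
  maj <- majority_allele(seg_alleles)
  if (!is.na(maj) && maj != mono_allele) {
    paste0("specific_", seg_g)
  } else {
    paste0("segregating_", seg_g)
  }
}

majority_allele <- function(x) {
  cnt <- sort(table(x), decreasing = TRUE)
  if (length(cnt) > 1 && cnt[1] == cnt[2]) return(NA_character_)  # tie
  names(cnt)[1]
}

#' Haplotype-informative sites
#'
#' Sites at which the two groups' majority alleles differ and each majority
#' frequency is at least `min_fixation` — the "(nearly) fixed between the
#' mating types" sites on which conversion-tract scoring operates. Indel
#' events are excluded. `min_fixation = 1` admits only fully fixed
#' differences; lower it to admit nearly fixed sites.
#'
#' @param table A `polymorphism_table`.
#' @param min_fixation Minimum within-group majority frequency in (0.5, 1].
#' @return Ordered integer vector of 1-based positions.
#' @export
informative_sites <- function(table, min_fixation = 1) {
  groups <- attr(table, "groups")
  lv <- attr(table, "group_levels")
  snp <- filter(table, !.data$is_indel)
  if (nrow(snp) == 0) return(integer())
  keep <- vapply(seq_len(nrow(snp)), function(i) {
    st <- site_group_summary(snp[i, ], groups, lv)
    !is.na(st$maj1) && !is.na(st$maj2) && st$maj1 != st$maj2 &&
      st$freq1 >= min_fixation && st$freq2 >= min_fixation
  }, logical(1))
  snp$position[keep]
}

site_group_summary <- function(row, groups, lv) {
  a1 <- unlist(row[names(groups)[groups == lv[1]]])
  a2 <- unlist(row[names(groups)[groups == lv[2]]])
  m1 <- majority_allele(a1)
  m2 <- majority_allele(a2)
  list(maj1 = m1, maj2 = m2,
       freq1 = if (is.na(m1)) NA_real_ else mean(a1 == m1),
       freq2 = if (is.na(m2)) NA_real_ else mean(a2 == m2))
}

#' Detect gene-conversion tracts (Betran-style criterion)
#'
#' Scans runs of consecutive haplotype-informative sites for members of one
#' group (the recipient) that carry the other group's (the donor's) typical
#' allele — the signature of a conversion tract. Within a candidate run the
#' carrier set must be identical at every site (runs with changing carriers
#' are split), the run must span at least two informative sites, and the
#' tract probability is the product of the per-site donor-allele frequencies
#' within the recipient group, `p = prod(psi_i)` with
#' `psi_i = carriers / recipient group size`. Tracts with `p <= alpha` are
#' reported. Intervening non-informative polymorphisms do not break a run.
#'
#' @param table A `polymorphism_table`.
#' @param informative Optional precomputed vector of informative positions;
#'   by default computed with `informative_sites(table, min_fixation)`.
#' @param alpha Report tracts with tract probability at or below this.
#' @param min_fixation Passed to [informative_sites()]; the default 0.5
#'   (strict majority) admits the nearly fixed sites a conversion event
#'   itself de-fixes.
#' @return Tibble: `donor_group`, `recipient_group`, `recipient_taxa`
#'   (comma-separated), `start`, `end` (1-based positions), `k` (run
#'   length), `psi` (list column of per-site frequencies), `p_value`.
#' @export
detect_tracts <- function(table, informative = NULL, alpha = 0.05,
                          min_fixation = 0.5) {
  groups <- attr(table, "groups")
  lv <- attr(table, "group_levels")
  informative <- informative %||% informative_sites(table, min_fixation)
  empty <- tibble(donor_group = character(), recipient_group = character(),
                  recipient_taxa = character(), start = integer(),
                  end = integer(), k = integer(), psi = list(),
                  p_value = numeric())
  if (length(informative) < 2) return(empty)
  snp <- filter(table, .data$position %in% informative, !.data$is_indel)
  snp <- arrange(snp, .data$position)

  out <- list()
  for (recip in lv) {
    donor <- setdiff(lv, recip)
    recip_taxa <- names(groups)[groups == recip]
    # carrier set per informative site: recipient members with donor allele
    carriers <- lapply(seq_len(nrow(snp)), function(i) {
      st <- site_group_summary(snp[i, ], groups, lv)
      donor_allele <- if (donor == lv[1]) st$maj1 else st$maj2
      a <- unlist(snp[i, recip_taxa])
      recip_taxa[a == donor_allele]
    })
    key <- vapply(carriers, function(x) {
      if (length(x) == 0) "" else paste(sort(x), collapse = ",")
    }, character(1))
    runs <- rle(key)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (r in which(runs$values != "" & runs$lengths >= 2)) {
      idx <- starts[r]:ends[r]
      psi <- vapply(carriers[idx], length, integer(1)) / length(recip_taxa)
      p <- prod(psi)
      if (p <= alpha) {
        out[[length(out) + 1L]] <- tibble(
          donor_group = donor, recipient_group = recip,
          recipient_taxa = runs$values[r],
          start = snp$position[idx[1]], end = snp$position[idx[length(idx)]],
          k = length(idx), psi = list(psi), p_value = p)
      }
    }
  }
  if (length(out) == 0) empty else arrange(bind_rows(out), .data$start)
}

#' Write a polymorphism table or tract report as TSV
#' @param x A `polymorphism_table` or the tibble from [detect_tracts()].
#' @param path Output path.
#' @export
write_polymorphism_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(x)
}

#' @rdname write_polymorphism_table
#' @export
write_tract_report <- function(x, path) {
  flat <- mutate(x, psi = vapply(.data$psi, paste, character(1),
                                 collapse = ","))
  readr::write_tsv(flat, path)
  invisible(x)
}

#' @export
autoplot.polymorphism_table <- function(object, ...) {
  groups <- attr(object, "groups")
  long <- as_tibble(object) |>
    tidyr::pivot_longer(cols = dplyr::all_of(names(groups)),
                        names_to = "taxon", values_to = "allele") |>
    mutate(group = unname(groups[.data$taxon]),
           taxon = factor(.data$taxon, levels = names(sort(groups))))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$position), y = .data$taxon,
                               fill = .data$allele)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "alignment position", y = NULL, fill = "allele") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
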