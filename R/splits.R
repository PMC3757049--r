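#' Quartet support counts
#'
#' For four taxa there are three ways to pair them; a column supports a
#' pairing when the paired taxa share a state and the two pairs carry
#' different states. These per-quartet counts are the kernel of the
#' parsimony-splits construction. Columns with a gap or `N` in any of the
#' four taxa are ignored.
#'
#' @param aln A [labeled_alignment()].
#' @param a,a2,b,b2 Four distinct taxon names.
#' @return Named integer vector of the three pairing supports,
#'   `aa2|bb2`, `ab|a2b2`, `ab2|a2b`.
#' @export
quartet_support <- function(aln, a, a2, b, b2) {
  taxa <- c(a, a2, b, b2)
  stopifnot(length(unique(taxa)) == 4)
  mat <- aln$seq[taxa, , drop = FALSE]
  ok <- !apply(mat == "-" | mat == "N", 2, any)
  mat <- mat[, ok, drop = FALSE]
  count <- function(p1, p2, q1, q2) {
    sum(mat[p1, ] == mat[p2, ] & mat[q1, ] == mat[q2, ] &
          mat[p1, ] != mat[q1, ])
  }
  c(`aa2|bb2` = count(1, 2, 3, 4),
    `ab|a2b2` = count(1, 3, 2, 4),
    `ab2|a2b` = count(1, 4, 2, 3))
}

#' Parsimony-splits system of an ungapped alignment
#'
#' Enumerates every non-trivial bipartition `A|B` of the (collapsed) taxa
#' and accepts it with weight
#' `w(A|B) = min over quartets a,a' in A, b,b' in B of
#' [s(aa'|bb') - min(s(ab|a'b'), s(ab'|a'b))]` when `w > 0`, where `s` are
#' the [quartet_support()] counts. Subtracting the smaller of the two
#' conflicting pairings lets two crossing splits coexist (the boxes of a
#' splits network) while no quartet ever retains its weakest pairing,
#' which is exactly the Bandelt-Dress weak-compatibility margin. All trivial splits are always included
#' (weight = number of columns at which the taxon differs from every other
#' taxon). Identical sequences are collapsed into one node before the
#' enumeration and re-expanded in the output, so candidate counts stay at
#' `2^(n-1)` over distinct haplotypes. The resulting system is weakly
#' compatible in the Bandelt-Dress sense and can be drawn as a network with
#' boxes where splits conflict.
#'
#' @param aln A [labeled_alignment()]; must contain no gaps (apply
#'   [ungapped_mask()] first).
#' @param max_taxa Guard on the number of distinct haplotypes enumerated
#'   exhaustively.
#' @return A `split_system`: list with `taxa`, `nodes` (list of taxon sets
#'   per collapsed node) and `splits`, a tibble with list-columns `side_a`,
#'   `side_b` (original taxa; lexicographically smaller side first),
#'   `weight` and `trivial`.
#' @export
parsimony_splits <- function(aln, max_taxa = 20) {
  mat <- aln$seq
  if (any(mat == "-" | mat == "N")) {
    abort("alignment contains gaps/N; restrict to ungapped_mask() first",
          class = "mtpopgen_alignment_error")
  }
  taxa <- rownames(mat)
  # collapse identical haplotypes
  hap <- apply(mat, 1, paste, collapse = "")
  nodes <- split(taxa, factor(hap, levels = unique(hap)))
  names(nodes) <- vapply(nodes, `[`, character(1), 1)
  cmat <- mat[names(nodes), , drop = FALSE]
  n <- nrow(cmat)
  if (n > max_taxa) {
    abort(paste0(n, " distinct haplotypes exceeds max_taxa = ", max_taxa),
          class = "mtpopgen_size_error")
  }
  splits <- trivial_splits(cmat, nodes)
  if (n >= 4) {
    splits <- bind_rows(splits, nontrivial_splits(cmat, nodes))
  }
  new_split_system(taxa, nodes, splits)
}

trivial_splits <- function(cmat, nodes) {
  n <- nrow(cmat)
  purrr::map_dfr(seq_len(n), function(i) {
    w <- if (n >= 2) {
      sum(vapply(seq_len(ncol(cmat)), function(j) {
        all(cmat[-i, j] != cmat[i, j])
      }, logical(1)))
    } else 0L
    orient_split(nodes[[i]], unlist(nodes[-i], use.names = FALSE),
                 weight = as.numeric(w), trivial = TRUE)
  })
}

nontrivial_splits <- function(cmat, nodes) {
  n <- nrow(cmat)
  qs <- precompute_quartets(cmat)
  out <- list()
  # enumerate splits with node 1 on side B: A over subsets of 2..n
  others <- 2:n
  for (size in 2:(n - 2)) {
    combos <- combn(others, size)
    for (ci in seq_len(ncol(combos))) {
      A <- combos[, ci]
      B <- setdiff(seq_len(n), A)
      w <- split_weight(A, B, qs)
      if (w > 0) {
        out[[length(out) + 1L]] <- orient_split(
          unlist(nodes[A], use.names = FALSE),
          unlist(nodes[B], use.names = FALSE),
          weight = w, trivial = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    tibble(side_a = list(), side_b = list(), weight = numeric(),
           trivial = logical())
  } else {
    bind_rows(out)
  }
}

precompute_quartets <- function(cmat) {
  n <- nrow(cmat)
  qs <- array(NA_real_, dim = c(n, n, n, n, 3))
  quads <- combn(n, 4)
  for (ci in seq_len(ncol(quads))) {
    q <- quads[, ci]
    i <- q[1]; j <- q[2]; k <- q[3]; l <- q[4]
    eij <- cmat[i, ] == cmat[j, ]
    eik <- cmat[i, ] == cmat[k, ]
    eil <- cmat[i, ] == cmat[l, ]
    ekl <- cmat[k, ] == cmat[l, ]
    ejl <- cmat[j, ] == cmat[l, ]
    ejk <- cmat[j, ] == cmat[k, ]
    qs[i, j, k, l, 1] <- sum(eij & ekl & !eik)
    qs[i, j, k, l, 2] <- sum(eik & ejl & !eij)
    qs[i, j, k, l, 3] <- sum(eil & ejk & !eij)
  }
  qs
}

split_weight <- function(A, B, qs) {
  w <- Inf
  pa <- if (length(A) == 2) matrix(A, 2) else combn(A, 2)
  pb <- if (length(B) == 2) matrix(B, 2) else combn(B, 2)
  for (x in seq_len(ncol(pa))) {
    for (y in seq_len(ncol(pb))) {
      q <- sort(c(pa[, x], pb[, y]))
      s <- qs[q[1], q[2], q[3], q[4], ]
      # which canonical pairing puts pa together: partner of q[1]
      partner <- if (q[1] %in% pa[, x]) setdiff(pa[, x], q[1]) else
        setdiff(pb[, y], q[1])
      within_idx <- match(partner, q) - 1L  # 2->1, 3->2, 4->3
      # subtract the smaller of the two conflicting pairings: crossing
      # splits can then both stay positive (a box), while any quartet
      # still rejects its weakest pairing, which keeps the system weakly
      # compatible
      cand <- s[within_idx] - min(s[-within_idx])
      if (cand < w) w <- cand
      if (w <= 0) return(w)
    }
  }
  w
}

orient_split <- function(sa, sb, weight, trivial, bootstrap = NULL) {
  ka <- paste(sort(sa), collapse = ",")
  kb <- paste(sort(sb), collapse = ",")
  if (kb < ka) {
    tmp <- sa; sa <- sb; sb <- tmp
  }
  row <- tibble(side_a = list(sort(sa)), side_b = list(sort(sb)),
                weight = weight, trivial = trivial)
  if (!is.null(bootstrap)) row$bootstrap <- bootstrap
  row
}

new_split_system <- function(taxa, nodes, splits) {
  structure(list(taxa = taxa, nodes = nodes, splits = splits),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat("<split_system> ", length(x$taxa), " taxa (",
      length(x$nodes), " distinct haplotypes), ",
      nrow(x$splits), " splits (", sum(!x$splits$trivial),
      " non-trivial)\n", sep = "")
  invisible(x)
}

#' @export
tidy.split_system <- function(x, ...) {
  mutate(x$splits,
         side_a = vapply(.data$side_a, paste, character(1), collapse = ","),
         side_b = vapply(.data$side_b, paste, character(1), collapse = ","),
         size_a = lengths(x$splits$side_a),
         size_b = lengths(x$splits$side_b))
}

#' @export
glance.split_system <- function(x, ...) {
  tibble(n_taxa = length(x$taxa), n_nodes = length(x$nodes),
         n_splits = nrow(x$splits),
         n_nontrivial = sum(!x$splits$trivial),
         weakly_compatible = is_weakly_compatible(x))
}

#' @export
autoplot.split_system <- function(object, ...) {
  df <- tidy(object) |>
    filter(!.data$trivial) |>
    mutate(split = paste(.data$side_a, .data$side_b, sep = " | "))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$split,
                                                      .data$weight),
                                   y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "split weight (quartet support)") +
    ggplot2::theme_minimal()
}

#' Weak compatibility of a split system
#'
#' Checks the Bandelt-Dress condition by exhaustive verification over all
#' triples of splits: for every choice of sides `A1, A2, A3`, at least one
#' of the four intersections `A1&A2&A3`, `A1&B2&B3`, `B1&A2&B3`,
#' `B1&B2&A3` must be empty.
#'
#' @param ss A `split_system`.
#' @return `TRUE`/`FALSE`.
#' @export
is_weakly_compatible <- function(ss) {
  sp <- ss$splits
  if (nrow(sp) < 3) return(TRUE)
  taxa <- ss$taxa
  amat <- t(vapply(sp$side_a, function(s) taxa %in% s,
                   logical(length(taxa))))
  trips <- combn(nrow(sp), 3)
  for (ci in seq_len(ncol(trips))) {
    tr <- trips[, ci]
    for (flip in 0:7) {
      A1 <- if (bitwAnd(flip, 1L) > 0) !amat[tr[1], ] else amat[tr[1], ]
      A2 <- if (bitwAnd(flip, 2L) > 0) !amat[tr[2], ] else amat[tr[2], ]
      A3 <- if (bitwAnd(flip, 4L) > 0) !amat[tr[3], ] else amat[tr[3], ]
      empties <- c(!any(A1 & A2 & A3), !any(A1 & !A2 & !A3),
                   !any(!A1 & A2 & !A3), !any(!A1 & !A2 & A3))
      if (!any(empties)) return(FALSE)
    }
  }
  TRUE
}

#' Bootstrap support for parsimony splits
#'
#' Site resampling with replacement; each replicate's split system is
#' recomputed (on the collapsed haplotypes of the original data, which are
#' collapsed before resampling) and a split's support is the fraction of
#' replicates whose system contains it. Fully seed-reproducible.
#'
#' @inheritParams parsimony_splits
#' @param reps Bootstrap replicates (the study-style default is 1000).
#' @param seed Integer seed.
#' @return The `split_system` of `aln` with a `bootstrap` column (fraction
#'   in \[0, 1\]) added to `splits`.
#' @export
bootstrap_splits <- function(aln, reps = 1000, seed = 1L, max_taxa = 20) {
  base <- parsimony_splits(aln, max_taxa = max_taxa)
  keyer <- function(splits) {
    vapply(seq_len(nrow(splits)), function(i) {
      paste(sort(splits$side_a[[i]]), collapse = ",")
    }, character(1))
  }
  base_keys <- keyer(base$splits)
  hits <- numeric(length(base_keys))
  L <- ncol(aln$seq)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(L, replace = TRUE)
      rep_aln <- labeled_alignment(aln$seq[, idx, drop = FALSE],
                                   aln$groups,
                                   aln$annotation[idx, ] |>
                                     mutate(position = dplyr::row_number()))
      rep_sys <- parsimony_splits(rep_aln, max_taxa = max_taxa)
      hits <- hits + (base_keys %in% keyer(rep_sys$splits))
    }
  })
  base$splits$bootstrap <- hits / reps
  base
}

#' Export a split system as a Nexus file with a SPLITS block
#'
#' Writes Taxa and Splits blocks readable by standard split-network
#' viewers; bootstrap supports (when present) are written as confidences.
#'
#' @param ss A `split_system`.
#' @param path Output path.
#' @export
write_splits_nexus <- function(ss, path) {
  taxa <- ss$taxa
  sp <- ss$splits
  lines <- c("#NEXUS", "",
             "BEGIN Taxa;",
             paste0("DIMENSIONS ntax=", length(taxa), ";"),
             "TAXLABELS")
  lines <- c(lines, paste0("[", seq_along(taxa), "] '", taxa, "'"), ";",
             "END;", "",
             "BEGIN Splits;",
             paste0("DIMENSIONS ntax=", length(taxa), " nsplits=",
                    nrow(sp), ";"),
             paste0("FORMAT labels=no weights=yes confidences=",
                    if ("bootstrap" %in% names(sp)) "yes" else "no",
                    ";"),
             "MATRIX")
  for (i in seq_len(nrow(sp))) {
    side <- sp$side_a[[i]]
    if (!(taxa[1] %in% side)) side <- sp$side_b[[i]]
    idx <- sort(match(side, taxa))
    conf <- if ("bootstrap" %in% names(sp)) {
      paste0(" ", format(round(100 * sp$bootstrap[i])), " ")
    } else " "
    lines <- c(lines, paste0("[", i, ", size=", length(idx), "]\t",
                             format(sp$weight[i]), conf,
                             paste(idx, collapse = " "), ","))
  }
  lines <- c(lines, ";", "END;")
  writeLines(lines, path)
  invisible(ss)
}

#' Does the system contain a given bipartition?
#' @param ss A `split_system`.
#' @param side A set of taxa (one side of the candidate split).
#' @return `TRUE` if some split has exactly this side (or its complement).
#' @export
has_split <- function(ss, side) {
  key <- paste(sort(side), collapse = ",")
  comp <- paste(sort(setdiff(ss$taxa, side)), collapse = ",")
  for (i in seq_len(nrow(ss$splits))) {
    ka <- paste(sort(ss$splits$side_a[[i]]), collapse = ",")
    if (ka == key || ka == comp) return(TRUE)
  }
  FALSE
}
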