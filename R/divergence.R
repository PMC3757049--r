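#' Tamura 3-parameter distance between two aligned sequences
#'
#' `d = -h*ln(1 - P/h - Q) - ((1-h)/2)*ln(1 - 2Q)` with `h = 2*theta*(1-theta)`,
#' where `P` and `Q` are the transition and transversion proportions over
#' the analysed columns and `theta` is the mean G+C fraction of the two
#' sequences over those columns. Columns containing a gap or `N` in either
#' sequence are dropped (pairwise deletion); gaps are additionally counted
#' as indel events (one event per maximal gap run per sequence). The
#' standard error is a site bootstrap.
#'
#' @param seqA,seqB Aligned sequences (character strings, equal length).
#' @param bootstrap_reps Site-bootstrap replicates for the SE (0 skips).
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble: `d`, `se`, `n_aligned`, `n_indels`,
#'   `n_substitutions`, `P`, `Q`, `theta`.
#' @examples
#' tamura3p("ACGTACGTAC", "ACGTACGTAT", bootstrap_reps = 0)
#' @export
tamura3p <- function(seqA, seqB, bootstrap_reps = 1000, seed = 1L) {
  a <- toupper(strsplit(seqA, "")[[1]])
  b <- toupper(strsplit(seqB, "")[[1]])
  if (length(a) != length(b)) {
    abort("sequences must be aligned to equal length",
          class = "mtpopgen_alignment_error")
  }
  gap <- a %in% c("-", "N") | b %in% c("-", "N")
  n_indels <- count_gap_events(a) + count_gap_events(b)
  aa <- a[!gap]
  bb <- b[!gap]
  L <- length(aa)
  if (L == 0) abort("no ungapped columns", class = "mtpopgen_degenerate_input")
  est <- t3p_from_columns(aa, bb)
  se <- NA_real_
  if (bootstrap_reps > 0) {
    se <- withr::with_seed(seed, {
      reps <- vapply(seq_len(bootstrap_reps), function(i) {
        idx <- sample.int(L, replace = TRUE)
        tryCatch(t3p_from_columns(aa[idx], bb[idx])["d"],
                 error = function(e) NA_real_)
      }, numeric(1))
      sd(reps, na.rm = TRUE)
    })
  }
  tibble(d = unname(est["d"]), se = se, n_aligned = L, n_indels = n_indels,
         n_substitutions = as.integer(est["subs"]),
         P = unname(est["P"]), Q = unname(est["Q"]),
         theta = unname(est["theta"]))
}

count_gap_events <- function(x) {
  r <- rle(x == "-")
  sum(r$values)
}

is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
}

t3p_from_columns <- function(aa, bb) {
  L <- length(aa)
  diff <- aa != bb
  P <- sum(is_transition(aa, bb)) / L
  Q <- (sum(diff) - sum(is_transition(aa, bb))) / L
  theta <- mean(c(aa, bb) %in% c("G", "C"))
  h <- 2 * theta * (1 - theta)
  arg1 <- 1 - P / h - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    abort("Tamura 3-parameter distance saturated (log argument <= 0)",
          class = "mtpopgen_saturation_error")
  }
  c(d = -h * log(arg1) - ((1 - h) / 2) * log(arg2),
    P = P, Q = Q, theta = theta, subs = sum(diff))
}

# ---------------------------------------------------------------------------
# Nei-Gojobori (1986) dN/dS

#' Nei-Gojobori (1986) dN/dS between two aligned coding sequences
#'
#' Fractional synonymous/non-synonymous site counting (changes to stop
#' codons count as non-synonymous; site totals averaged over the two
#' sequences). Codons differing at more than one position are scored by
#' averaging over all minimal mutational pathways, excluding pathways that
#' pass through a stop codon (all pathways are used if every one is
#' blocked). Proportions are Jukes-Cantor corrected:
#' `d = -(3/4)*ln(1 - 4p/3)`. Codon pairs containing a gap or `N` are
#' skipped.
#'
#' @param cdsA,cdsB Aligned coding sequences, lengths divisible by 3, no
#'   internal stop codons.
#' @return One-row tibble: `dN`, `dS`, `dn_ds` (`NA` when `dS = 0`),
#'   `sites_syn`, `sites_nonsyn`, `diffs_syn`, `diffs_nonsyn`,
#'   `n_codons_compared`.
#' @export
ng86_dnds <- function(cdsA, cdsB) {
  a <- toupper(cdsA)
  b <- toupper(cdsB)
  if (nchar(a) != nchar(b)) {
    abort("coding sequences must be aligned to equal length",
          class = "mtpopgen_alignment_error")
  }
  if (nchar(a) %% 3 != 0) {
    abort("length not a multiple of 3", class = "mtpopgen_frame_error")
  }
  codA <- codon_split(a)
  codB <- codon_split(b)
  check_no_internal_stops(codA, "cdsA")
  check_no_internal_stops(codB, "cdsB")
  S <- N <- sd <- nd <- 0
  used <- 0L
  for (i in seq_along(codA)) {
    ca <- codA[i]
    cb <- codB[i]
    if (grepl("[-N]", ca) || grepl("[-N]", cb)) next
    if (ca %in% STOP_CODONS || cb %in% STOP_CODONS) next  # terminal stop
    used <- used + 1L
    S <- S + (codon_syn_sites(ca) + codon_syn_sites(cb)) / 2
    pw <- codon_pair_diffs(ca, cb)
    sd <- sd + pw[1]
    nd <- nd + pw[2]
  }
  N <- 3 * used - S
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  tibble(dN = dN, dS = dS,
         dn_ds = if (dS > 0) dN / dS else NA_real_,
         sites_syn = S, sites_nonsyn = N,
         diffs_syn = sd, diffs_nonsyn = nd,
         n_codons_compared = used)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

codon_split <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

check_no_internal_stops <- function(codons, label) {
  clean <- codons[!grepl("[-N]", codons)]
  internal <- head(codons, -1L)
  internal <- internal[!grepl("[-N]", internal)]
  if (any(internal %in% STOP_CODONS)) {
    abort(paste0("internal stop codon in ", label),
          class = "mtpopgen_coding_error")
  }
  invisible(clean)
}

# fraction of synonymous sites in one codon (cached)
codon_syn_sites <- local({
  cache <- new.env(parent = emptyenv())
  function(codon) {
    hit <- cache[[codon]]
    if (!is.null(hit)) return(hit)
    aa0 <- translate_codon(codon)
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(BASES, substr(codon, pos, pos))
      syn <- vapply(alts, function(bse) {
        mut <- codon
        substr(mut, pos, pos) <- bse
        identical(translate_codon(mut), aa0)  # stops count non-synonymous
      }, logical(1))
      s <- s + sum(syn) / 3
    }
    cache[[codon]] <- s
    s
  }
})

# (syn, nonsyn) differences between two codons, averaged over minimal
# pathways; pathways through stop codons excluded when possible (cached)
codon_pair_diffs <- local({
  cache <- new.env(parent = emptyenv())
  function(ca, cb) {
    key <- paste0(ca, cb)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    res <- if (length(pos) == 0) {
      c(0, 0)
    } else {
      paths <- permutations_of(pos)
      scores <- lapply(paths, function(ord) score_path(ca, cb, ord))
      ok <- !vapply(scores, is.null, logical(1))
      if (any(ok)) scores <- scores[ok]
      else scores <- lapply(paths, function(ord) {
        score_path(ca, cb, ord, allow_stops = TRUE)
      })
      Reduce(`+`, scores) / length(scores)
    }
    cache[[key]] <- res
    res
  }
})

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

score_path <- function(ca, cb, ord, allow_stops = FALSE) {
  cur <- ca
  sdiff <- ndiff <- 0
  for (pos in ord) {
    nxt <- cur
    substr(nxt, pos, pos) <- substr(cb, pos, pos)
    if (!allow_stops && nxt %in% STOP_CODONS) return(NULL)
    if (identical(translate_codon(cur), translate_codon(nxt))) {
      sdiff <- sdiff + 1
    } else {
      ndiff <- ndiff + 1
    }
    cur <- nxt
  }
  c(sdiff, ndiff)
}

# ---------------------------------------------------------------------------
# Codon adaptation index

#' Codon adaptation index of a coding sequence
#'
#' Relative adaptiveness `w(codon) = usage(codon) / max usage within its
#' synonymous family`; CAI is the geometric mean of `w` over scored codons.
#' Methionine, tryptophan and stop codons are excluded from the product.
#'
#' @param cds Coding sequence, length divisible by 3.
#' @param codon_usage_table Tibble/data frame with columns `codon` (64 sense
#'   + stop codons, DNA alphabet) and `count` (usage counts or frequencies).
#' @param epsilon Floor applied to `w` for codons with zero usage (with a
#'   warning).
#' @return One-row tibble: `cai`, `n_codons_scored`.
#' @export
cai <- function(cds, codon_usage_table, epsilon = 0.01) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    abort("length not a multiple of 3", class = "mtpopgen_frame_error")
  }
  usage <- as_tibble(codon_usage_table)
  usage$codon <- toupper(usage$codon)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   STOP_CODONS)
  missing <- setdiff(sense, usage$codon)
  if (length(missing) > 0) {
    abort(paste0("usage table missing codons: ",
                 paste(missing, collapse = ", ")))
  }
  aa_of <- Biostrings::GENETIC_CODE[usage$codon]
  fam_max <- tapply(usage$count, aa_of, max)
  w <- setNames(usage$count / fam_max[aa_of], usage$codon)
  codons <- codon_split(cds)
  codons <- codons[!grepl("[-N]", codons)]
  aa <- Biostrings::GENETIC_CODE[codons]
  scored <- codons[!is.na(aa) & !(aa %in% c("M", "W", "*"))]
  if (length(scored) == 0) {
    abort("no scorable codons", class = "mtpopgen_degenerate_input")
  }
  ws <- w[scored]
  if (any(ws == 0)) {
    warn("zero-usage codon(s) present; flooring w at epsilon")
    ws[ws == 0] <- epsilon
  }
  tibble(cai = exp(mean(log(ws))), n_codons_scored = length(scored))
}
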