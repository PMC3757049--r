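# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package implementations.

oracle_pi <- function(mat, cols) {
  taxa <- rownames(mat)
  total <- 0
  npairs <- 0
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (j <= i) next
      diffs <- 0
      for (col in cols) {
        if (mat[i, col] != mat[j, col]) diffs <- diffs + 1
      }
      total <- total + diffs / length(cols)
      npairs <- npairs + 1
    }
  }
  total / npairs
}

oracle_between <- function(mat, cols, taxa1, taxa2) {
  total <- 0
  npairs <- 0
  for (i in taxa1) {
    for (j in taxa2) {
      diffs <- 0
      for (col in cols) {
        if (mat[i, col] != mat[j, col]) diffs <- diffs + 1
      }
      total <- total + diffs / length(cols)
      npairs <- npairs + 1
    }
  }
  total / npairs
}

oracle_jc <- function(p) -0.75 * log(1 - 4 * p / 3)

oracle_ungapped <- function(mat) {
  keep <- integer()
  for (col in seq_len(ncol(mat))) {
    ok <- TRUE
    for (row in seq_len(nrow(mat))) {
      if (mat[row, col] %in% c("-", "N")) ok <- FALSE
    }
    if (ok) keep <- c(keep, col)
  }
  keep
}

# per-quartet pairing support by naive per-column classification
oracle_quartet <- function(mat4) {
  counts <- c(0L, 0L, 0L)
  for (col in seq_len(ncol(mat4))) {
    x <- mat4[, col]
    if (any(x %in% c("-", "N"))) next
    if (x[1] == x[2] && x[3] == x[4] && x[1] != x[3]) {
      counts[1] <- counts[1] + 1L
    }
    if (x[1] == x[3] && x[2] == x[4] && x[1] != x[2]) {
      counts[2] <- counts[2] + 1L
    }
    if (x[1] == x[4] && x[2] == x[3] && x[1] != x[2]) {
      counts[3] <- counts[3] + 1L
    }
  }
  counts
}

# NG86 pathway scoring for a single codon pair, written independently:
# enumerates mutation orders via recursion over remaining positions.
oracle_codon_pair <- function(ca, cb) {
  tr <- function(cod) Biostrings::GENETIC_CODE[[cod]]
  stops <- c("TAA", "TAG", "TGA")
  walk <- function(cur, remaining, allow_stop) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (!allow_stop && nxt %in% stops) next
      step <- if (tr(cur) == tr(nxt)) c(1, 0) else c(0, 1)
      for (restscore in walk(nxt, setdiff(remaining, p), allow_stop)) {
        out[[length(out) + 1]] <- step + restscore
      }
    }
    out
  }
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  paths <- walk(ca, pos, allow_stop = FALSE)
  if (length(paths) == 0) paths <- walk(ca, pos, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

random_panel <- function(n, L, seed, gap_rate = 0) {
  withr::with_seed(seed, {
    mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE),
                  nrow = n)
    if (gap_rate > 0) {
      gaps <- runif(n * L) < gap_rate
      mat[gaps] <- "-"
    }
    rownames(mat) <- paste0("t", seq_len(n))
    g <- rep(c("G1", "G2"), length.out = n)
    labeled_alignment(mat, stats::setNames(g, rownames(mat)))
  })
}

# panel of sequences related through a shared ancestor (keeps p-distances
# well below Jukes-Cantor saturation)
related_panel <- function(n, L, seed, mut_rate = 0.08) {
  withr::with_seed(seed, {
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    mat <- t(vapply(seq_len(n), function(i) {
      x <- anc
      hit <- which(runif(L) < mut_rate)
      for (p in hit) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
      x
    }, character(L)))
    rownames(mat) <- paste0("t", seq_len(n))
    g <- rep(c("G1", "G2"), length.out = n)
    labeled_alignment(mat, stats::setNames(g, rownames(mat)))
  })
}

random_cds <- function(n_codons, seed) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  withr::with_seed(seed, paste(sample(sense, n_codons, replace = TRUE),
                               collapse = ""))
}
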