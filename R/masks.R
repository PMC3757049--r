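#' Site masks
#'
#' A site mask is the ordered set of 1-based alignment columns a statistic is
#' computed over. `ungapped_mask()` drops every column containing a gap (`-`)
#' or ambiguous base (`N`) in any sequence (complete deletion, the
#' conservative policy for small panels). `silent_mask()` keeps the ungapped
#' non-coding columns plus exon columns at which every observed variant is
#' synonymous in every sequence's codon context; codons containing a gap are
#' excluded from that evaluation. `all_sites_mask()` is the identity mask.
#'
#' @param aln A [labeled_alignment()].
#' @return An integer vector of included columns (strictly increasing) of
#'   class `site_mask`, with a `kind` attribute.
#' @examples
#' aln <- labeled_alignment(
#'   c(a = "ATG-AA", b = "ATGCAA"),
#'   groups = c(a = "G1", b = "G2")
#' )
#' ungapped_mask(aln)
#' @export
ungapped_mask <- function(aln) {
  keep <- !apply(aln$seq == "-" | aln$seq == "N", 2, any)
  new_site_mask(which(keep), "ungapped")
}

#' @rdname ungapped_mask
#' @export
all_sites_mask <- function(aln) {
  new_site_mask(seq_len(ncol(aln$seq)), "all")
}

#' @rdname ungapped_mask
#' @export
silent_mask <- function(aln) {
  ung <- as.integer(ungapped_mask(aln))
  region <- aln$annotation$region
  frame <- aln$annotation$frame
  is_exon <- region == "exon"
  if (any(is_exon & is.na(frame))) {
    abort("exon columns without codon frame",
          class = "mtpopgen_annotation_error")
  }
  keep <- vapply(ung, function(col) {
    if (!is_exon[col]) return(TRUE)
    column_is_synonymous(aln, col)
  }, logical(1))
  new_site_mask(ung[keep], "silent")
}

new_site_mask <- function(cols, kind) {
  structure(as.integer(cols), kind = kind, class = "site_mask")
}

#' @export
print.site_mask <- function(x, ...) {
  cat("<site_mask kind=", attr(x, "kind"), "> ", length(x), " columns\n",
      sep = "")
  invisible(x)
}

# Strict synonymy: a (ungapped) exon column is silent iff, for every
# sequence whose codon at that position is gap-free, replacing the focal
# base by each allele observed in the panel leaves the amino acid unchanged.
column_is_synonymous <- function(aln, col) {
  frame <- aln$annotation$frame[col]
  start <- col - frame + 1L
  idx <- start:(start + 2L)
  if (idx[1] < 1L || idx[3] > ncol(aln$seq)) return(FALSE)
  if (!all(aln$annotation$region[idx] == "exon") ||
      !identical(aln$annotation$frame[idx], 1:3)) {
    # broken codon context (e.g. exon edge): treat conservatively as
    # non-silent
    return(FALSE)
  }
  codons <- aln$seq[, idx, drop = FALSE]
  ok <- !apply(codons == "-" | codons == "N", 1, any)
  if (!any(ok)) return(FALSE)
  alleles <- unique(aln$seq[ok, col])
  for (s in which(ok)) {
    cod <- codons[s, ]
    aa0 <- translate_codon(paste(cod, collapse = ""))
    for (a in alleles) {
      cod2 <- cod
      cod2[frame] <- a
      if (translate_codon(paste(cod2, collapse = "")) != aa0) return(FALSE)
    }
  }
  TRUE
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Export a mask as a one-column TSV of included positions
#' @param mask A `site_mask`.
#' @param path Output TSV path.
#' @export
write_mask <- function(mask, path) {
  readr::write_tsv(tibble(position = as.integer(mask)), path)
  invisible(mask)
}

resolve_mask <- function(aln, mask) {
  if (inherits(mask, "site_mask")) return(mask)
  if (is.character(mask) && length(mask) == 1) {
    return(switch(mask,
                  all = all_sites_mask(aln),
                  ungapped = ungapped_mask(aln),
                  silent = silent_mask(aln),
                  abort(paste0("unknown mask kind: ", mask))))
  }
  new_site_mask(as.integer(mask), "custom")
}
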