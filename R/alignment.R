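#' Group-labelled multiple sequence alignment
#'
#' The container every analysis in mtpopgen consumes: an aligned set of
#' sequences over `{A,C,G,T,-,N}`, a group label per sequence (e.g. `"MT+"`
#' and `"MT-"` for the two mating-type haplotype panels), and a per-column
#' annotation giving the region class (`exon`, `intron`, `UTR`, `intergenic`)
#' and, for exon columns, the codon frame (1, 2 or 3 = position within the
#' codon read left to right on the alignment).
#'
#' @param seqs Named character vector of aligned sequences (equal length),
#'   or a character matrix (rows = taxa, columns = alignment positions) with
#'   rownames.
#' @param groups Named character vector mapping every taxon to its group
#'   label.
#' @param annotation Optional tibble with columns `position`, `region` and
#'   `frame` (one row per alignment column). Defaults to all-`intergenic`.
#' @return An object of class `labeled_alignment` with elements `seq`
#'   (character matrix), `groups` (named character) and `annotation`
#'   (tibble).
#' @examples
#' aln <- labeled_alignment(
#'   c(p1 = "ACGTAC", p2 = "ACGTAC", m1 = "ACCTAC"),
#'   groups = c(p1 = "MT+", p2 = "MT+", m1 = "MT-")
#' )
#' aln
#' @export
labeled_alignment <- function(seqs, groups, annotation = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs))) abort("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      abort("all sequences must have the same aligned length",
            class = "mtpopgen_alignment_error")
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat))) abort("alignment matrix must have rownames")
  taxa <- rownames(mat)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad) > 0) {
    abort(paste0("unexpected characters in alignment: ",
                 paste(bad, collapse = ", ")),
          class = "mtpopgen_alignment_error")
  }
  missing <- setdiff(taxa, names(groups))
  if (length(missing) > 0) {
    abort(paste0("no group label for taxa: ", paste(missing, collapse = ", ")),
          class = "mtpopgen_labeling_error")
  }
  groups <- groups[taxa]
  L <- ncol(mat)
  if (is.null(annotation)) {
    annotation <- tibble(position = seq_len(L),
                         region = "intergenic",
                         frame = NA_integer_)
  }
  annotation <- as_tibble(annotation)
  stopifnot(nrow(annotation) == L)
  if (!all(c("position", "region", "frame") %in% names(annotation))) {
    abort("annotation needs columns position, region, frame",
          class = "mtpopgen_annotation_error")
  }
  if (any(annotation$region == "exon" & is.na(annotation$frame))) {
    abort("exon columns must carry a codon frame",
          class = "mtpopgen_annotation_error")
  }
  structure(list(seq = mat, groups = groups, annotation = annotation),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("<labeled_alignment> ", nrow(x$seq), " taxa x ", ncol(x$seq),
      " columns\n", sep = "")
  tab <- table(x$groups)
  cat("groups: ", paste(names(tab), tab, sep = " n=", collapse = ", "), "\n",
      sep = "")
  cat("regions: ",
      paste(names(table(x$annotation$region)), table(x$annotation$region),
            sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_alignment <- function(x) dim(x$seq)

#' Taxa and groups of an alignment
#' @param aln A `labeled_alignment`.
#' @return `aln_taxa()` a character vector; `aln_groups()` a named character
#'   vector; `group_levels()` the unique labels in panel order.
#' @export
aln_taxa <- function(aln) rownames(aln$seq)

#' @rdname aln_taxa
#' @export
aln_groups <- function(aln) aln$groups

#' @rdname aln_taxa
#' @export
group_levels <- function(aln) unique(unname(aln$groups))

#' Restrict an alignment to a subset of taxa
#'
#' Column annotation is kept; masks must be recomputed on the subset because
#' gap and synonymy patterns change with the panel.
#'
#' @param aln A `labeled_alignment`.
#' @param taxa Character vector of taxon names to keep.
#' @return A `labeled_alignment` over `taxa`.
#' @export
subset_taxa <- function(aln, taxa) {
  unknown <- setdiff(taxa, aln_taxa(aln))
  if (length(unknown) > 0) {
    abort(paste0("unknown taxa: ", paste(unknown, collapse = ", ")),
          class = "mtpopgen_labeling_error")
  }
  labeled_alignment(aln$seq[taxa, , drop = FALSE], aln$groups[taxa],
                    aln$annotation)
}

#' Read a labelled alignment from FASTA + sample sheet + annotation
#'
#' @param fasta_path Aligned FASTA (gaps as `-`).
#' @param samplesheet_path Two-column TSV `taxon<TAB>group`, no header
#'   required (a header line `taxon	group` is tolerated).
#' @param annotation_path Optional BED-like TSV with columns
#'   `start`, `end` (1-based inclusive), `region`, `frame` (frame of the
#'   FIRST column of the block; `NA` or `.` outside exons). Columns not
#'   covered by any block default to `intergenic`.
#' @return A [labeled_alignment()].
#' @export
read_alignment <- function(fasta_path, samplesheet_path,
                           annotation_path = NULL) {
  ss <- Biostrings::readBStringSet(fasta_path)
  seqs <- setNames(as.character(ss), names(ss))
  sheet <- readr::read_tsv(samplesheet_path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(sheet) > 0 && identical(tolower(sheet[[1]][1]), "taxon")) {
    sheet <- sheet[-1, ]
  }
  groups <- setNames(sheet[[2]], sheet[[1]])
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort("FASTA records have unequal aligned lengths",
          class = "mtpopgen_alignment_error")
  }
  missing <- setdiff(names(seqs), names(groups))
  if (length(missing) > 0) {
    abort(paste0("FASTA ids absent from sample sheet: ",
                 paste(missing, collapse = ", ")),
          class = "mtpopgen_labeling_error")
  }
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- read_region_annotation(annotation_path, unique(lens))
  }
  labeled_alignment(seqs, groups, ann)
}

#' @rdname read_alignment
#' @param L Alignment length the annotation must cover.
#' @export
read_region_annotation <- function(annotation_path, L) {
  blocks <- readr::read_tsv(annotation_path,
                            col_names = c("start", "end", "region", "frame"),
                            col_types = "iicc", comment = "#",
                            progress = FALSE)
  region <- rep("intergenic", L)
  frame <- rep(NA_integer_, L)
  for (i in seq_len(nrow(blocks))) {
    idx <- blocks$start[i]:blocks$end[i]
    region[idx] <- blocks$region[i]
    f0 <- suppressWarnings(as.integer(blocks$frame[i]))
    if (!is.na(f0)) {
      frame[idx] <- ((f0 - 1L + seq_along(idx) - 1L) %% 3L) + 1L
    }
  }
  tibble(position = seq_len(L), region = region, frame = frame)
}

#' Write a labelled alignment back to FASTA + sample sheet (+ annotation)
#'
#' Round-trips with [read_alignment()].
#'
#' @param aln A `labeled_alignment`.
#' @param fasta_path,samplesheet_path,annotation_path Output paths;
#'   `annotation_path` may be `NULL` to skip.
#' @return `aln`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, samplesheet_path,
                            annotation_path = NULL) {
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), fasta_path)
  readr::write_tsv(tibble(taxon = aln_taxa(aln),
                          group = unname(aln$groups)),
                   samplesheet_path, col_names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- aln$annotation
    # compress runs of identical (region, frame-phase) into blocks
    key <- paste(ann$region,
                 ifelse(is.na(ann$frame), ".",
                        (ann$frame - ann$position) %% 3L))
    run <- rle(key)
    ends <- cumsum(run$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    blocks <- tibble(start = starts, end = ends,
                     region = ann$region[starts],
                     frame = ifelse(is.na(ann$frame[starts]), ".",
                                    as.character(ann$frame[starts])))
    readr::write_tsv(blocks, annotation_path, col_names = FALSE)
  }
  invisible(aln)
}

#' @export
tidy.labeled_alignment <- function(x, ...) {
  mat <- x$seq
  tibble(taxon = rep(rownames(mat), times = ncol(mat)),
         group = rep(unname(x$groups), times = ncol(mat)),
         position = rep(seq_len(ncol(mat)), each = nrow(mat)),
         base = as.vector(mat)) |>
    left_join(x$annotation, by = "position")
}

#' @export
glance.labeled_alignment <- function(x, ...) {
  tibble(n_taxa = nrow(x$seq), n_columns = ncol(x$seq),
         n_groups = length(unique(x$groups)),
         n_gapped_columns = sum(apply(x$seq == "-" | x$seq == "N", 2, any)))
}
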