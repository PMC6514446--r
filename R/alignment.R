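#' Aligned haplotypes of one homeologous region
#'
#' Container for the aligned haplotype sequences of a single locus region.
#' All sequences must have equal length, use the alphabet `A C G T - N`, and
#' carry unique ids. One haplotype serves as the coordinate reference: variant
#' positions are reported on its ungapped, 1-based coordinates.
#'
#' @param haplotypes Named character vector of aligned sequences, or a
#'   data frame with columns `haplotype_id` and `sequence`.
#' @param region_id Label for the region (default `"region"`).
#' @param reference_id Haplotype used for coordinates; defaults to the first.
#' @return An object of class `region_alignment`: a list with `region_id`,
#'   `haplotypes` (tibble of `haplotype_id`, `sequence`), `reference_id` and
#'   `columns` (alignment length).
#' @export
region_alignment <- function(haplotypes, region_id = "region",
                             reference_id = NULL) {
  if (is.data.frame(haplotypes)) {
    seqs <- setNames(haplotypes$sequence, haplotypes$haplotype_id)
  } else {
    seqs <- haplotypes
  }
  if (length(seqs) < 2) {
    stop("a region alignment needs at least 2 haplotypes", call. = FALSE)
  }
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "") || anyNA(ids)) {
    stop("every haplotype needs an id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate haplotype ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")", call. = FALSE)
  }
  if (any(grepl("[^ACGTN-]", seqs))) {
    stop("sequences must use only A, C, G, T, N and -", call. = FALSE)
  }
  reference_id <- reference_id %||% ids[1]
  if (!reference_id %in% ids) {
    stop("reference_id '", reference_id, "' not among haplotypes",
         call. = FALSE)
  }
  structure(
    list(
      region_id = region_id,
      haplotypes = tibble(haplotype_id = ids, sequence = unname(seqs)),
      reference_id = reference_id,
      columns = unname(lens[1])
    ),
    class = "region_alignment"
  )
}

#' @export
print.region_alignment <- function(x, ...) {
  cat(sprintf("<region_alignment> %s: %d haplotypes x %d columns (ref %s)\n",
              x$region_id, nrow(x$haplotypes), x$columns, x$reference_id))
  invisible(x)
}

#' Load a region alignment from an aligned FASTA file
#'
#' @param fasta_path Path to an aligned multi-FASTA (gaps as `-`).
#' @param metadata Optional data frame with columns `haplotype_id` and
#'   `region_id`; when given, only haplotypes listed for `region_id` are kept.
#' @param region_id Region label; required when `metadata` spans several
#'   regions, otherwise defaults to `"region"`.
#' @param reference_id Coordinate reference haplotype (default: first record).
#' @return A [region_alignment()].
#' @export
read_region_alignment <- function(fasta_path, metadata = NULL,
                                  region_id = NULL, reference_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty FASTA: ", fasta_path, call. = FALSE)
  x <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    if (!is.null(region_id)) {
      metadata <- dplyr::filter(metadata, .data$region_id == !!region_id)
    }
    x <- x[names(x) %in% metadata$haplotype_id]
    if (!length(x)) stop("no haplotypes match the metadata", call. = FALSE)
  }
  region_alignment(x, region_id = region_id %||% "region",
                   reference_id = reference_id)
}

# character matrix view: rows = haplotypes, cols = alignment columns
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$haplotypes$sequence, ""))
  rownames(m) <- aln$haplotypes$haplotype_id
  m
}

# 1-based ungapped reference coordinate for each alignment column; columns
# where the reference is gapped map to the preceding reference base (0 if
# none), the usual anchoring convention for insertions
reference_positions <- function(aln) {
  ref <- strsplit(
    aln$haplotypes$sequence[aln$haplotypes$haplotype_id == aln$reference_id],
    "")[[1]]
  cumsum(ref != "-")
}

#' Annotated gene model on the reference haplotype
#'
#' @param exons Data frame with columns `start` and `end`: 1-based closed
#'   exon intervals on the ungapped reference coordinates, sorted and
#'   non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param gene_id Gene label.
#' @param expected_protein_length Expected protein length in amino acids
#'   (used by [detect_frameshift()]).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(exons, strand = c("+", "-"), gene_id = "gene",
                       expected_protein_length = NULL) {
  strand <- match.arg(strand)
  exons <- as_tibble(exons)[, c("start", "end")]
  stopifnot(all(exons$end >= exons$start))
  if (is.unsorted(exons$start) ||
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons must be sorted and non-overlapping", call. = FALSE)
  }
  cds_len <- sum(exons$end - exons$start + 1)
  if (cds_len %% 3 != 0) {
    warning("annotated CDS length ", cds_len, " is not a multiple of 3")
  }
  structure(list(gene_id = gene_id, exons = exons, strand = strand,
                 expected_protein_length = expected_protein_length),
            class = "gene_model")
}

#' Extract the spliced CDS of every haplotype
#'
#' Maps the gene model's exon intervals (reference coordinates) to alignment
#' columns, concatenates them per haplotype, removes alignment gaps and
#' reverse-complements on the minus strand.
#'
#' @param aln A [region_alignment()].
#' @param model A [gene_model()].
#' @return Named character vector of CDS sequences, one per haplotype.
#' @export
extract_cds <- function(aln, model) {
  stopifnot(inherits(aln, "region_alignment"), inherits(model, "gene_model"))
  refpos <- reference_positions(aln)
  ref_len <- max(refpos)
  if (any(model$exons$end > ref_len) || any(model$exons$start < 1)) {
    stop("exon interval outside the reference sequence (length ", ref_len,
         ")", call. = FALSE)
  }
  # columns anchored inside each exon; reference-gap columns (insertions in
  # other haplotypes) anchor to the preceding reference base and ride along
  cols <- unlist(purrr::pmap(model$exons, function(start, end) {
    which(refpos >= start & refpos <= end)
  }))
  cols <- sort(unique(cols))
  m <- aln_matrix(aln)
  out <- apply(m[, cols, drop = FALSE], 1, function(ch) {
    paste(ch[ch != "-"], collapse = "")
  })
  if (model$strand == "-") out <- setNames(revcomp(out), names(out))
  out
}
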