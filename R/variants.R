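#' Call variants among the haplotypes of a region alignment
#'
#' Scans the alignment column by column and emits one record per polymorphic
#' column run, polarised against the majority:
#' \itemize{
#'   \item single-base substitutions are `snp_transition` (`A<->G`, `C<->T`)
#'     or `snp_transversion`;
#'   \item adjacent substitution columns carried by the same haplotype set
#'     merge into one `substitution_multibase` record (e.g. `GG -> TT`);
#'   \item contiguous gap runs shared by the same haplotype set collapse into
#'     a single `insertion` (gap in the majority) or `deletion` record; a
#'     deleted segment that repeats its flanking sequence is flagged
#'     `deletion_tandem_repeat`;
#'   \item `N` bases never create variants.
#' }
#' `common_state` is the majority state among observed haplotypes and
#' `variant_state` the minority (ties broken lexicographically, the smaller
#' state being called common); multi-allelic columns yield one record per
#' minority state. Positions are 1-based on the ungapped reference haplotype;
#' insertions anchor to the preceding reference base.
#'
#' @param aln A [region_alignment()].
#' @param duplication Optional length-2 vector `c(start, end)` of reference
#'   coordinates; variants inside are flagged `in_duplication`.
#' @return A tibble with columns `position`, `kind`, `common_state`,
#'   `variant_state`, `carriers` (list of haplotype ids), `n_carriers`,
#'   `col_start`, `col_end`, `in_duplication`.
#' @export
call_variants <- function(aln, duplication = NULL) {
  stopifnot(inherits(aln, "region_alignment"))
  m <- aln_matrix(aln)
  ids <- rownames(m)
  refpos <- reference_positions(aln)
  nc <- ncol(m)

  recs <- list()
  add <- function(position, kind, common, variant, carriers, c0, c1) {
    recs[[length(recs) + 1]] <<- tibble(
      position = position, kind = kind, common_state = common,
      variant_state = variant, carriers = list(carriers),
      n_carriers = length(carriers), col_start = c0, col_end = c1
    )
  }

  # ---- indel events: maximal runs of columns with an identical gapped set --
  gap <- m == "-"
  gap_cols <- which(colSums(gap) > 0 & colSums(gap) < nrow(m))
  consumed_gap <- matrix(FALSE, nrow(m), nc, dimnames = dimnames(m))
  if (length(gap_cols)) {
    runs <- split(gap_cols,
                  cumsum(c(TRUE, diff(gap_cols) != 1 |
                             vapply(seq_along(gap_cols)[-1], function(k) {
                               !identical(gap[, gap_cols[k]],
                                          gap[, gap_cols[k - 1]])
                             }, logical(1)))))
    for (run in runs) {
      gapped <- ids[gap[, run[1]]]
      others <- setdiff(ids, gapped)
      consumed_gap[gapped, run] <- TRUE
      # the ungapped-state string over the run, from the first non-gap carrier
      seg <- paste(m[others[1], run], collapse = "")
      gap_str <- strrep("-", length(run))
      majority_gapped <- length(gapped) > length(others)
      if (majority_gapped) {
        kind <- "insertion"
        common <- gap_str; variant <- seg; carriers <- others
      } else {
        kind <- "deletion"
        common <- seg; variant <- gap_str; carriers <- gapped
        if (is_tandem_deletion(m[others[1], ], run)) {
          kind <- "deletion_tandem_repeat"
        }
      }
      pos <- refpos[run[1]]
      add(max(pos, 1L), kind, common, variant, carriers, run[1], run[length(run)])
    }
  }

  # ---- substitution events -------------------------------------------------
  # per column: majority state among non-gap, non-N; one candidate per
  # minority state
  sub_cols <- list()
  for (j in seq_len(nc)) {
    states <- m[, j]
    use <- states != "-" & states != "N"
    if (!any(use)) next
    tab <- table(states[use])
    if (length(tab) < 2) next
    ord <- order(-tab, names(tab)) # majority first; lexicographic on ties
    common <- names(tab)[ord[1]]
    for (v in names(tab)[ord[-1]]) {
      carriers <- ids[use & states == v]
      sub_cols[[length(sub_cols) + 1]] <- list(
        col = j, common = common, variant = v, carriers = carriers)
    }
  }
  # merge adjacent columns sharing an identical carrier set
  k <- 1
  while (k <= length(sub_cols)) {
    cur <- sub_cols[[k]]
    cols <- cur$col
    common <- cur$common
    variant <- cur$variant
    k2 <- k + 1
    while (k2 <= length(sub_cols) &&
           sub_cols[[k2]]$col == cols[length(cols)] + 1 &&
           setequal(sub_cols[[k2]]$carriers, cur$carriers)) {
      cols <- c(cols, sub_cols[[k2]]$col)
      common <- paste0(common, sub_cols[[k2]]$common)
      variant <- paste0(variant, sub_cols[[k2]]$variant)
      k2 <- k2 + 1
    }
    kind <- if (length(cols) > 1) {
      "substitution_multibase"
    } else if (paste0(sort(c(common, variant)), collapse = "") %in%
                 c("AG", "CT")) {
      "snp_transition"
    } else {
      "snp_transversion"
    }
    add(max(refpos[cols[1]], 1L), kind, common, variant,
        sort(cur$carriers), cols[1], cols[length(cols)])
    k <- k2
  }

  if (!length(recs)) {
    out <- tibble(position = integer(), kind = character(),
                  common_state = character(), variant_state = character(),
                  carriers = list(), n_carriers = integer(),
                  col_start = integer(), col_end = integer())
  } else {
    out <- dplyr::arrange(dplyr::bind_rows(recs), .data$col_start)
  }
  out$in_duplication <- if (is.null(duplication)) {
    rep(FALSE, nrow(out))
  } else {
    out$position >= duplication[1] & out$position <= duplication[2]
  }
  out
}

# does the deleted run duplicate the sequence immediately before or after it?
is_tandem_deletion <- function(full_row, run) {
  w <- length(run)
  seg <- paste(full_row[run], collapse = "")
  before <- run[1] - w
  after <- run[length(run)] + w
  (before >= 1 &&
     paste(full_row[seq(before, run[1] - 1)], collapse = "") == seg) ||
    (after <= length(full_row) &&
       paste(full_row[seq(run[length(run)] + 1, after)], collapse = "") == seg)
}

#' Variant density of a region
#'
#' Aligned bases per variant, computed on the ungapped reference length.
#' With zero variants the density is undefined and flagged rather than
#' raising an error.
#'
#' @param aln A [region_alignment()].
#' @param variants Output of [call_variants()] on `aln`.
#' @return A one-row tibble: `n_variants`, `reference_bases`,
#'   `bases_per_variant` (`NA` when undefined), `density_defined`.
#' @export
snp_density <- function(aln, variants) {
  stopifnot(inherits(aln, "region_alignment"))
  ref_len <- max(reference_positions(aln))
  n <- nrow(variants)
  tibble(
    n_variants = n,
    reference_bases = ref_len,
    bases_per_variant = if (n > 0) ref_len / n else NA_real_,
    density_defined = n > 0
  )
}

#' Diagnostic variants between two regions
#'
#' Sites fixed for one state in every haplotype of the first region and a
#' different state in every haplotype of the second (the SNPs that
#' distinguish homeologous region copies). Both alignments must share a
#' coordinate frame (equal column count over the shared segment).
#'
#' @param aln_region1,aln_region2 Two [region_alignment()]s over the same
#'   columns.
#' @return A tibble like [call_variants()]: the fixed-different sites, with
#'   `common_state` the first region's state, `variant_state` the second's,
#'   and `carriers` the second region's haplotypes. Positions are on the
#'   first region's reference.
#' @export
diagnostic_variants <- function(aln_region1, aln_region2) {
  stopifnot(inherits(aln_region1, "region_alignment"),
            inherits(aln_region2, "region_alignment"))
  if (aln_region1$columns != aln_region2$columns) {
    stop("alignments do not share a coordinate frame (",
         aln_region1$columns, " vs ", aln_region2$columns, " columns)",
         call. = FALSE)
  }
  m1 <- aln_matrix(aln_region1)
  m2 <- aln_matrix(aln_region2)
  refpos <- reference_positions(aln_region1)
  recs <- list()
  for (j in seq_len(ncol(m1))) {
    s1 <- unique(m1[, j]); s1 <- s1[!s1 %in% c("N")]
    s2 <- unique(m2[, j]); s2 <- s2[!s2 %in% c("N")]
    if (length(s1) != 1 || length(s2) != 1) next
    if (s1 == s2 || s1 == "-" || s2 == "-") next
    kind <- if (paste0(sort(c(s1, s2)), collapse = "") %in% c("AG", "CT")) {
      "snp_transition"
    } else {
      "snp_transversion"
    }
    recs[[length(recs) + 1]] <- tibble(
      position = max(refpos[j], 1L), kind = kind,
      common_state = s1, variant_state = s2,
      carriers = list(rownames(m2)), n_carriers = nrow(m2),
      col_start = j, col_end = j, in_duplication = FALSE
    )
  }
  if (!length(recs)) {
    return(tibble(position = integer(), kind = character(),
                  common_state = character(), variant_state = character(),
                  carriers = list(), n_carriers = integer(),
                  col_start = integer(), col_end = integer(),
                  in_duplication = logical()))
  }
  dplyr::bind_rows(recs)
}

#' Group near-identical sequences into homeologs
#'
#' Pairwise identity is computed as matching bases over aligned columns,
#' excluding columns gapped in both sequences; `N` never counts as a match.
#' Sequences are grouped by single linkage: any chain of pairs above the
#' identity threshold ends up in one group, each group representing one
#' homeolog/haplotype.
#'
#' @param sequences Named character vector of aligned sequences.
#' @param identity_threshold Pairs with identity strictly above this value
#'   are linked; default 0.99.
#' @return A tibble with `haplotype_id` and `group` (integers numbered by
#'   first appearance).
#' @export
collapse_homeologs <- function(sequences, identity_threshold = 0.99) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]", call. = FALSE)
  }
  n <- length(sequences)
  ids <- names(sequences) %||% paste0("s", seq_len(n))
  if (length(unique(nchar(sequences))) != 1) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  chars <- lapply(toupper(sequences), function(s) strsplit(s, "")[[1]])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a <- chars[[i]]; b <- chars[[j]]
        use <- !(a == "-" & b == "-")
        match <- a == b & a != "-" & a != "N" & b != "N"
        ident <- sum(match[use]) / sum(use)
        if (ident > identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  tibble(haplotype_id = ids,
         group = as.integer(factor(roots, levels = unique(roots))))
}

#' Group gene haplotypes by identical coding sequence
#'
#' Genes with byte-identical spliced CDS are the same gene haplotype; group
#' numbers follow input order.
#'
#' @param cds_sequences Named character vector of CDS sequences (e.g. from
#'   [extract_cds()]).
#' @return A tibble with `haplotype_id`, `cds` and `group`.
#' @export
group_gene_haplotypes <- function(cds_sequences) {
  ids <- names(cds_sequences) %||% paste0("s", seq_along(cds_sequences))
  seqs <- toupper(unname(cds_sequences))
  tibble(
    haplotype_id = ids,
    cds = seqs,
    group = as.integer(factor(seqs, levels = unique(seqs)))
  )
}

#' Translate a CDS and flag frameshifts and premature stops
#'
#' Translates from the first codon with the standard genetic code (ambiguous
#' codons become `X`, never an error). The protein length is the number of
#' codons before the first stop. A premature stop is a stop before the
#' expected protein length; a frameshift is flagged when the CDS length is
#' not a multiple of 3 or differs from `3 * (expected + 1)` (coding length
#' plus the stop codon).
#'
#' @param cds Coding sequence over `A C G T` (ambiguity tolerated).
#' @param expected_protein_length Expected protein length in amino acids.
#' @return A one-row tibble: `protein_length`, `premature_stop`,
#'   `frameshift`, `has_stop` (`FALSE` flags an incomplete ORF whose stop was
#'   never reached).
#' @examples
#' detect_frameshift("ATGAAAGAATAG", 3)
#' @export
detect_frameshift <- function(cds, expected_protein_length) {
  cds <- toupper(cds)
  if (nchar(cds) < 3) stop("CDS shorter than one codon", call. = FALSE)
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                      seq(3, nchar(cds), 3))
  code <- genetic_code()
  aa <- vapply(codons, function(cd) {
    if (grepl("^[ACGT]{3}$", cd)) code[[cd]] else "X"
  }, character(1))
  stop_at <- which(aa == "*")
  has_stop <- length(stop_at) > 0
  protein_length <- if (has_stop) stop_at[1] - 1L else length(aa)
  tibble(
    protein_length = as.integer(protein_length),
    premature_stop = has_stop && protein_length < expected_protein_length,
    frameshift = nchar(cds) %% 3 != 0 ||
      nchar(cds) != 3 * (expected_protein_length + 1),
    has_stop = has_stop
  )
}
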