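#' Assign transcriptome reads to gene haplotypes
#'
#' With the default `max_mismatch = 0` this is the strict 100%-identity rule
#' used for expression classification: a read is assigned to every haplotype
#' whose CDS contains it as an exact substring, searching both strands.
#' Reads matching no haplotype stay unassigned; reads matching every
#' haplotype are shared (uninformative). The assignment is deterministic and
#' independent of read order.
#'
#' With `max_mismatch > 0` reads are placed by ungapped matching tolerating
#' up to that many mismatching bases — the mode used to tally allele counts
#' against a single reference haplotype, where reads carrying novel variant
#' alleles must still be placed (e.g. 10 mismatches on a 100-bp read mirrors
#' mapping at 90% similarity).
#'
#' @param reads Tibble with columns `read_id` and `sequence`, or a named
#'   character vector.
#' @param haplotype_cds Named character vector of haplotype CDS sequences.
#' @param max_mismatch Maximum mismatching bases tolerated per read
#'   (default 0 = exact).
#' @return A tibble with one row per read-haplotype match (plus one
#'   `haplotype_id = NA` row per unassigned read): `read_id`, `haplotype_id`,
#'   `start` (match position in the CDS), `strand`, `n_matches` (haplotypes
#'   matched by the read) and `shared` (matched all haplotypes).
#' @export
assign_reads <- function(reads, haplotype_cds, max_mismatch = 0) {
  if (!length(haplotype_cds)) {
    stop("empty haplotype set", call. = FALSE)
  }
  if (is.data.frame(reads)) {
    read_ids <- reads$read_id
    seqs <- toupper(reads$sequence)
  } else {
    read_ids <- names(reads) %||% paste0("read", seq_along(reads))
    seqs <- toupper(unname(reads))
  }
  hids <- names(haplotype_cds)
  if (is.null(hids)) {
    stop("haplotype_cds must be named", call. = FALSE)
  }
  cds <- toupper(haplotype_cds)
  rc <- revcomp(seqs)

  locate <- function(subject, patterns) {
    if (max_mismatch == 0) {
      return(stringr::str_locate(subject, stringr::fixed(patterns))[, "start"])
    }
    # seed-and-verify: split each read into max_mismatch + 1 seeds, so at
    # least one seed is mismatch-free whenever the read places within the
    # budget (pigeonhole); anchor each exact seed hit and verify the full
    # read by Hamming distance
    found <- rep(NA_integer_, length(patterns))
    widths <- nchar(patterns)
    slen <- nchar(subject)
    n_seed <- max_mismatch + 1L
    for (s in seq_len(n_seed)) {
      todo <- which(is.na(found))
      if (!length(todo)) break
      w <- widths[todo]
      seed_len <- pmax(8L, w %/% n_seed)
      off <- pmin(1L + (s - 1L) * seed_len, w - seed_len + 1L)
      seeds <- substr(patterns[todo], off, off + seed_len - 1L)
      hit <- stringr::str_locate(subject, stringr::fixed(seeds))[, "start"]
      cand <- hit - off + 1L
      ok <- !is.na(cand) & cand >= 1L & cand + w - 1L <= slen
      if (!any(ok)) next
      idx <- todo[ok]
      ref <- substring(subject, cand[ok], cand[ok] + w[ok] - 1L)
      mm <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                   ref, patterns[idx], USE.NAMES = FALSE)
      pass <- mm <= max_mismatch
      found[idx[pass]] <- cand[ok][pass]
    }
    found
  }
  per_hap <- purrr::map(seq_along(cds), function(h) {
    fwd <- locate(cds[[h]], seqs)
    rev <- locate(cds[[h]], rc)
    hit <- !is.na(fwd) | !is.na(rev)
    tibble(
      read_idx = which(hit),
      haplotype_id = rep(hids[h], sum(hit)),
      start = as.integer(ifelse(!is.na(fwd[hit]), fwd[hit], rev[hit])),
      strand = as.character(ifelse(!is.na(fwd[hit]), "+", "-"))
    )
  })
  hits <- dplyr::bind_rows(per_hap)
  n_match <- integer(length(seqs))
  if (nrow(hits)) {
    tab <- table(hits$read_idx)
    n_match[as.integer(names(tab))] <- as.integer(tab)
  }
  unassigned <- which(n_match == 0)
  out <- dplyr::bind_rows(
    dplyr::mutate(hits, read_id = read_ids[.data$read_idx]),
    tibble(read_idx = unassigned,
           haplotype_id = NA_character_,
           start = NA_integer_, strand = NA_character_,
           read_id = read_ids[unassigned])
  )
  out$n_matches <- n_match[out$read_idx]
  out$shared <- out$n_matches == length(cds)
  dplyr::select(dplyr::arrange(out, .data$read_idx),
                "read_id", "haplotype_id", "start", "strand",
                "n_matches", "shared")
}

#' Tally per-SNP coverage and variant coverage from read assignments
#'
#' For each variant site, coverage is the number of assigned reads whose
#' match interval overlaps the position, and variant coverage the subset
#' whose base at the position equals the variant state. Reads carrying `N`
#' at the site count toward coverage but never toward variant coverage.
#' Indel records are passed through with `NA` counts (they need gapped
#' alignment, outside this module's exact-match scope). Sites outside every
#' read and outside the CDS are reported with zero coverage.
#'
#' @param assignments Output of [assign_reads()].
#' @param reads The read tibble given to [assign_reads()].
#' @param variants Variant records ([call_variants()]): `position`,
#'   `variant_state`, `kind`.
#' @return A tibble with `position`, `coverage`, `variant_coverage` and the
#'   variants' `kind`.
#' @export
tally_allele_counts <- function(assignments, reads, variants) {
  if (is.data.frame(reads)) {
    read_seq <- setNames(toupper(reads$sequence), reads$read_id)
  } else {
    read_seq <- setNames(toupper(unname(reads)),
                         names(reads) %||% paste0("read", seq_along(reads)))
  }
  # one placement per read: exact matches to colinear haplotype CDSs agree
  # on coordinates, so the first is representative
  placed <- assignments |>
    dplyr::filter(!is.na(.data$haplotype_id)) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
  placed$width <- nchar(read_seq[placed$read_id])
  placed$seq_fwd <- ifelse(placed$strand == "+",
                           read_seq[placed$read_id],
                           revcomp(read_seq[placed$read_id]))

  purrr::pmap_dfr(
    list(variants$position, variants$variant_state, variants$kind),
    function(pos, vstate, kind) {
      if (!kind %in% c("snp_transition", "snp_transversion",
                       "substitution_multibase")) {
        return(tibble(position = pos, coverage = NA_integer_,
                      variant_coverage = NA_integer_, kind = kind))
      }
      span <- nchar(vstate)
      over <- placed$start <= pos & placed$start + placed$width - 1 >=
        pos + span - 1
      bases <- substr(placed$seq_fwd[over],
                      pos - placed$start[over] + 1,
                      pos - placed$start[over] + span)
      tibble(
        position = pos,
        coverage = sum(over),
        variant_coverage = sum(bases == vstate, na.rm = TRUE),
        kind = kind
      )
    }
  )
}

#' Is a SNP supported by enough transcriptome reads?
#'
#' @param variant_coverage Reads carrying the variant state (vectorised).
#' @param min_reads Detection threshold; default 6 reads.
#' @return Logical vector: `variant_coverage >= min_reads`.
#' @export
snp_detected <- function(variant_coverage, min_reads = 6) {
  variant_coverage >= min_reads
}

#' Classify a gene haplotype as expressed, not expressed or undetermined
#'
#' A haplotype is expressed when transcript reads cover its entire CDS, or
#' when at least one SNP exclusive to it (carried by no other haplotype) is
#' supported by [snp_detected()]. With exclusive SNPs but none detected it is
#' not expressed. A haplotype with no exclusive SNPs and no full coverage is
#' indistinguishable from its relatives: undetermined.
#'
#' @param haplotype_id Gene-haplotype label.
#' @param exclusive_counts Tibble of allele counts
#'   ([tally_allele_counts()] rows) at this haplotype's exclusive SNPs;
#'   zero rows when it has none.
#' @param full_coverage Is every CDS position covered by reads consistent
#'   with this haplotype?
#' @param min_reads Detection threshold passed to [snp_detected()].
#' @return A one-row tibble: `haplotype_id`, `status`, `evidence`,
#'   `exclusive_detected`, `exclusive_total`.
#' @export
classify_expression <- function(haplotype_id, exclusive_counts,
                                full_coverage = FALSE, min_reads = 6) {
  n_excl <- if (is.null(exclusive_counts)) 0L else nrow(exclusive_counts)
  detected <- if (n_excl) {
    sum(snp_detected(exclusive_counts$variant_coverage, min_reads),
        na.rm = TRUE)
  } else 0L
  if (isTRUE(full_coverage)) {
    status <- "expressed"; evidence <- "full_coverage"
  } else if (detected > 0) {
    status <- "expressed"; evidence <- "exclusive_snps"
  } else if (n_excl > 0) {
    status <- "not_expressed"; evidence <- "none"
  } else {
    status <- "undetermined"; evidence <- "none"
  }
  tibble(
    haplotype_id = haplotype_id,
    status = status,
    evidence = evidence,
    exclusive_detected = as.integer(detected),
    exclusive_total = as.integer(n_excl)
  )
}

#' Exclusive variants of one haplotype
#'
#' Variants whose variant state is carried by exactly this haplotype.
#'
#' @param variants Output of [call_variants()].
#' @param haplotype_id Haplotype label.
#' @return The subset of `variants` exclusive to `haplotype_id`.
#' @export
exclusive_variants <- function(variants, haplotype_id) {
  keep <- purrr::map_lgl(variants$carriers,
                         function(cs) identical(cs, haplotype_id) ||
                           (length(cs) == 1 && cs == haplotype_id))
  variants[keep, ]
}
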