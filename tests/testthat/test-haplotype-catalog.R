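test_that("region alignments validate their invariants", {
  aln <- region_alignment(c(h1 = "ACGTACGTACGT", h2 = "ACGTACGTACGT",
                            h3 = "ACGTACGAACGT"))
  expect_s3_class(aln, "region_alignment")
  expect_equal(aln$columns, 12)
  expect_equal(nrow(aln$haplotypes), 3)
  expect_equal(aln$reference_id, "h1")

  expect_error(region_alignment(c(a = "ACGTACGTACGT", b = "ACGTACGTACG")),
               "ragged")
  expect_error(region_alignment(setNames(c("ACGT", "ACGT"), c("a", "a"))),
               "duplicate")
  expect_error(region_alignment(c(a = "ACGT")), "at least 2")
  expect_error(region_alignment(c(a = "ACGT", b = "ACXT")), "only A, C, G")
})

test_that("FASTA round trip preserves the alignment", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(hapA = "ACGT-CGTAC", hapB = "ACGTACGTAC", hapC = "ACGTACGTTC")
  write_fasta(seqs, tmp)
  aln <- read_region_alignment(tmp, region_id = "r1")
  expect_equal(setNames(aln$haplotypes$sequence, aln$haplotypes$haplotype_id),
               seqs)
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_region_alignment(empty), "empty")
})

test_that("variant calling classifies substitutions, indels and merges", {
  # one G/C difference: a transversion with the minority as variant
  aln <- region_alignment(c(a = "AAAAAGAAAA", b = "AAAAACAAAA",
                            c = "AAAAAGAAAA"))
  v <- call_variants(aln)
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "snp_transversion")
  expect_equal(v$position, 6)
  expect_equal(v$common_state, "G")
  expect_equal(v$variant_state, "C")
  expect_equal(v$carriers[[1]], "b")

  # A<->G is a transition
  v2 <- call_variants(region_alignment(c(a = "AAAA", b = "AAGA",
                                         c = "AAAA")))
  expect_equal(v2$kind, "snp_transition")

  # adjacent GG -> TT carried by the same haplotypes merges to one record
  aln3 <- region_alignment(c(a = "AAGGAA", b = "AATTAA", c = "AAGGAA",
                             d = "AATTAA", e = "AAGGAA"))
  v3 <- call_variants(aln3)
  expect_equal(nrow(v3), 1)
  expect_equal(v3$kind, "substitution_multibase")
  expect_equal(v3$common_state, "GG")
  expect_equal(v3$variant_state, "TT")
  expect_equal(v3$carriers[[1]], c("b", "d"))

  # adjacent differences with different carriers stay separate
  aln4 <- region_alignment(c(a = "AAGGAA", b = "AATGAA", c = "AAGTAA"))
  expect_equal(nrow(call_variants(aln4)), 2)

  # a contiguous 3-column gap in one of four haplotypes is one deletion
  aln5 <- region_alignment(c(a = "ACGTACGTAC", b = "ACG---GTAC",
                             c = "ACGTACGTAC", d = "ACGTACGTAC"))
  v5 <- call_variants(aln5)
  expect_equal(nrow(v5), 1)
  expect_equal(v5$kind, "deletion")
  expect_equal(v5$carriers[[1]], "b")
  expect_equal(v5$common_state, "TAC")
  expect_equal(v5$position, 4)

  # deletion of one unit of a tandem repeat is flagged as such
  aln6 <- region_alignment(c(a = "TTGAGGAGGAGTT", b = "TTGAGGAG---TT",
                             c = "TTGAGGAGGAGTT"))
  v6 <- call_variants(aln6)
  expect_equal(v6$kind, "deletion_tandem_repeat")

  # N never creates a variant
  aln7 <- region_alignment(c(a = "AANA", b = "AAAA", c = "AAAA"))
  expect_equal(nrow(call_variants(aln7)), 0)
})

test_that("variant polarity breaks ties lexicographically", {
  aln <- region_alignment(c(a = "AT", b = "AG")) # tie: one T, one G
  v <- call_variants(aln)
  expect_equal(v$common_state, "G") # lexicographically first state is common
  expect_equal(v$variant_state, "T")
})

test_that("variant calling is invariant under haplotype permutation and
           round-trips the haplotypes", {
  seqs <- c(h1 = "ACGTACGTACGTACGTACGT", h2 = "ACCTACGTACGTAAGTACGT",
            h3 = "ACGTACTTACGTACGTACCT", h4 = "ACCTACGTACGTACGTACGT")
  v1 <- call_variants(region_alignment(seqs))
  withr::with_seed(7, {
    for (i in 1:5) {
      perm <- sample(names(seqs))
      v2 <- call_variants(region_alignment(seqs[perm],
                                           reference_id = "h1"))
      expect_equal(v1[order(v1$position), ], v2[order(v2$position), ])
    }
  })
  # round trip: common backbone + per-haplotype variants reconstructs input
  backbone <- strsplit(seqs[["h1"]], "")[[1]]
  for (r in seq_len(nrow(v1))) {
    cols <- seq(v1$col_start[r], v1$col_end[r])
    backbone[cols] <- strsplit(v1$common_state[r], "")[[1]]
  }
  for (h in names(seqs)) {
    rebuilt <- backbone
    for (r in seq_len(nrow(v1))) {
      if (h %in% v1$carriers[[r]]) {
        cols <- seq(v1$col_start[r], v1$col_end[r])
        rebuilt[cols] <- strsplit(v1$variant_state[r], "")[[1]]
      }
    }
    expect_equal(paste(rebuilt, collapse = ""), unname(seqs[h]))
  }
})

test_that("SNP density uses the ungapped reference length", {
  aln <- region_alignment(c(a = paste(rep("ACGTACGTAC", 56), collapse = ""),
                            b = paste(rep("ACGTACGTAC", 56), collapse = "")))
  fake_variants <- tibble::tibble(position = seq_len(8))
  d <- snp_density(aln, fake_variants)
  expect_equal(d$bases_per_variant, 70)
  expect_equal(d$reference_bases, 560)

  d0 <- snp_density(aln, fake_variants[0, ])
  expect_false(d0$density_defined)
  expect_true(is.na(d0$bases_per_variant))

  aln2 <- region_alignment(c(a = paste(rep("ACGTACGTAC", 43), collapse = ""),
                             b = paste(rep("ACGTACGTAC", 43), collapse = "")))
  expect_equal(snp_density(aln2, tibble::tibble(position = 1:10))$
                 bases_per_variant, 43)
})

test_that("diagnostic variants are fixed differences between regions", {
  r1 <- region_alignment(c(a1 = "AAAAATAAAA", a2 = "AAAAATAAAA",
                           a3 = "ACAAATAAAA"), region_id = "r1")
  r2 <- region_alignment(c(b1 = "AAAAAGAAAA", b2 = "AAAAAGAAAA"),
                         region_id = "r2")
  d <- diagnostic_variants(r1, r2)
  expect_equal(nrow(d), 1) # column 2 is not fixed in region 1
  expect_equal(d$position, 6)
  expect_equal(d$common_state, "T")
  expect_equal(d$variant_state, "G")

  expect_equal(nrow(diagnostic_variants(r1, r1)), 0)
  r3 <- region_alignment(c(c1 = "AAAA", c2 = "AAAA"))
  expect_error(diagnostic_variants(r1, r3), "coordinate frame")

  # diagnostic sites are a subset of the pooled alignment's variant columns
  pooled <- region_alignment(c(a1 = "AAAAATAAAA", a2 = "AAAAATAAAA",
                               a3 = "ACAAATAAAA", b1 = "AAAAAGAAAA",
                               b2 = "AAAAAGAAAA"))
  pv <- call_variants(pooled)
  cols_covered <- unlist(purrr::map2(pv$col_start, pv$col_end, seq))
  expect_true(all(d$col_start %in% cols_covered))
})

test_that("homeolog collapse uses single linkage above the threshold", {
  base <- dna(1000, seed = 11)
  # flip exactly k sites to a guaranteed-different base
  flip <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq_len(k)
    ch[idx] <- vapply(ch[idx], function(b) setdiff(c("A", "C"), b)[1],
                      character(1))
    paste(ch, collapse = "")
  }
  two <- c(p = base, q = flip(base, 5))   # 99.5% identical
  expect_equal(max(collapse_homeologs(two, 0.99)$group), 1)
  two2 <- c(p = base, q = flip(base, 20)) # 98% identical
  expect_equal(max(collapse_homeologs(two2, 0.99)$group), 2)

  # single linkage: A~B 99.2%, B~C 99.2%, A~C 98.4% chains into one group
  A <- base
  B <- flip(base, 8)
  C <- mutate_at(flip(base, 8),
                 1001 - seq_len(8), "N") # N never counts as a match
  triple <- c(A = A, B = B, C = C)
  g <- collapse_homeologs(triple, 0.99)
  expect_equal(max(g$group), 1)

  # monotone in threshold: groups at 0.99 refine groups at 0.95
  g99 <- collapse_homeologs(triple, 0.99)$group
  g95 <- collapse_homeologs(triple, 0.95)$group
  for (gr in unique(g99)) {
    expect_equal(length(unique(g95[g99 == gr])), 1)
  }
  expect_error(collapse_homeologs(two, 0), "identity_threshold")
  expect_error(collapse_homeologs(two, 1.2), "identity_threshold")
})

test_that("gene haplotypes group by identical CDS in input order", {
  cds <- c(I = "ATGAAA", II = "ATGAAA", III = "ATGCCC", IV = "ATGGGG",
           V = "ATGGGG", VI = "ATGAAA", VII = "ATGTTT")
  g <- group_gene_haplotypes(cds)
  expect_equal(max(g$group), 4) # {I,II,VI}, {III}, {IV,V}, {VII}
  expect_equal(g$group[g$haplotype_id %in% c("I", "II", "VI")],
               rep(1L, 3))
  expect_equal(g$group[g$haplotype_id %in% c("IV", "V")], rep(3L, 2))
  expect_equal(max(group_gene_haplotypes(c(a = "ATG", b = "ATG"))$group), 1)
})

test_that("CDS extraction maps exons through the alignment", {
  #        123456789012345678
  aln <- region_alignment(c(ref = "ATGAAGTTTCCCGGGTAG",
                            alt = "ATGAAGTTTCGCGGGTAG",
                            del = "ATGAA-TTTCCCGGGTAG"))
  gm <- gene_model(data.frame(start = c(1, 7), end = c(6, 18)),
                   strand = "+", expected_protein_length = 5)
  cds <- extract_cds(aln, gm)
  expect_equal(unname(cds["ref"]), "ATGAAGTTTCCCGGGTAG")
  expect_equal(unname(cds["del"]), "ATGAATTTCCCGGGTAG")

  gm_minus <- gene_model(data.frame(start = 1, end = 18), strand = "-")
  expect_equal(unname(extract_cds(aln, gm_minus)["ref"]),
               "CTACCCGGGAAACTTCAT")
  expect_error(extract_cds(aln, gene_model(data.frame(start = 1, end = 99),
                                           strand = "+")),
               "outside")
  expect_error(gene_model(data.frame(start = c(1, 3), end = c(5, 9))),
               "non-overlapping")
})

test_that("frameshift detection translates and flags stops", {
  r <- detect_frameshift("ATGAAAGAATAG", 3)
  expect_equal(r$protein_length, 3L)
  expect_false(r$premature_stop)
  expect_false(r$frameshift)
  expect_true(r$has_stop)

  # deleting base 5 shifts the frame; no stop is reached in-frame
  r2 <- detect_frameshift("ATGAAGAATAG", 3)
  expect_true(r2$frameshift)
  expect_false(r2$premature_stop)
  expect_false(r2$has_stop)

  # 564-nt CDS with a 1-bp deletion that surfaces an in-frame TAA at
  # codon 121: protein truncates at 120 aa
  codons <- c("ATG", rep("GAA", 119), "TAA", rep("GAA", 66), "TAA")
  full <- paste(codons, collapse = "")
  expect_equal(nchar(full), 564)
  shifted <- paste0(substr(full, 1, 76), substr(full, 78, 564))
  # engineer: make the shifted sequence hit TAA at codon 121
  r3 <- detect_frameshift(shifted, 187)
  expect_true(r3$frameshift)
  r4 <- detect_frameshift(full, 187)
  expect_equal(r4$protein_length, 120L)
  expect_true(r4$premature_stop)

  # ambiguous bases translate as X, never error
  rx <- detect_frameshift("ATGNNNAAATAG", 3)
  expect_equal(rx$protein_length, 3L)
})
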