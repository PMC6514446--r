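# toy alignments and sequence constructors used by several test files

toy_alignment <- function(seqs, ...) {
  region_alignment(seqs, ...)
}

# deterministic random DNA string
dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# substitute single positions in a sequence
mutate_at <- function(seq, pos, base) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}
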