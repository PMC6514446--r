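#' Configuration for a simulated polyploid locus
#'
#' Captures the study conditions for one locus: ploidy and the number of
#' haplotypes actually recovered, the radiation depth of the haplotypes, an
#' optional older duplication producing a paralogous region copy, expression
#' weights per haplotype (zeros silence a haplotype; the genomically missing
#' haplotype is still expressed, which is what its transcript-only SNPs
#' reveal), and the read model.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param ploidy Number of locus copies `P`.
#' @param observed Haplotypes recovered genomically `H <= P`; `P - H` are
#'   "missing" (present in truth, absent from the observed FASTA).
#' @param length Sequence length in bp.
#' @param radiation_time Years since the haplotypes radiated from their
#'   common ancestor (star tree).
#' @param rate Substitution rate, substitutions/site/year.
#' @param duplication Optional `list(age =, ploidy =, observed =)`: a
#'   paralogous copy of the locus that split `age` years ago (age must exceed
#'   `radiation_time`) and radiated into its own haplotype family.
#' @param weights Expression weights over the `ploidy` haplotypes; must sum
#'   to 1 (zeros allowed). Default: equal.
#' @param depth Mean read depth over the locus.
#' @param read_length Read length in bp (must not exceed `length`).
#' @param error_rate Per-base sequencing error probability.
#' @param deletion Optional `list(haplotype =, start =, width =)`: fixed
#'   deletion carved into one haplotype (recorded as gaps, so the truth set
#'   stays aligned).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ploidy = 8L, observed = ploidy - 1L,
                       length = 600L, radiation_time = 5e5,
                       rate = 6.5e-9, duplication = NULL,
                       weights = NULL, depth = 500, read_length = 100L,
                       error_rate = 0.001, deletion = NULL) {
  weights <- weights %||% rep(1 / ploidy, ploidy)
  if (length(weights) != ploidy) {
    stop("weights must have one entry per haplotype", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (observed > ploidy || observed < 1) {
    stop("need 1 <= observed <= ploidy", call. = FALSE)
  }
  if (rate <= 0) stop("substitution rate must be positive", call. = FALSE)
  if (read_length > length) {
    stop("read_length exceeds sequence length", call. = FALSE)
  }
  if (!is.null(duplication)) {
    duplication$ploidy <- duplication$ploidy %||% ploidy
    duplication$observed <- duplication$observed %||% duplication$ploidy
    stopifnot(duplication$age > radiation_time)
  }
  structure(
    list(seed = as.integer(seed), ploidy = as.integer(ploidy),
         observed = as.integer(observed), length = as.integer(length),
         radiation_time = radiation_time, rate = rate,
         duplication = duplication, weights = weights, depth = depth,
         read_length = as.integer(read_length), error_rate = error_rate,
         deletion = deletion),
    class = "sim_config"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Evolve a sequence under the Jukes-Cantor process
#'
#' Each site substitutes with the exact JC probability
#' `3/4 (1 - exp(-4/3 r t))` for a branch of length `r * t` substitutions per
#' site, the target base uniform over the three alternatives — so evolving
#' along consecutive branches composes exactly. Gaps and `N` are carried
#' through unchanged.
#'
#' @param seq Character scalar over `A C G T` (gaps/N tolerated, untouched).
#' @param time Branch duration in years.
#' @param rate Substitution rate, substitutions/site/year (`> 0`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (the convention inside [simulate_locus()], which seeds once).
#' @return The mutated sequence.
#' @export
evolve_sequence <- function(seq, time, rate, seed = NULL) {
  if (rate <= 0) stop("substitution rate must be positive", call. = FALSE)
  run <- function() {
    chars <- strsplit(toupper(seq), "")[[1]]
    d <- rate * time
    p_change <- 3 / 4 * (1 - exp(-4 / 3 * d))
    mutable <- chars %in% c("A", "C", "G", "T")
    hit <- mutable & runif(length(chars)) < p_change
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a polyploid locus with known truth
#'
#' Draws an ancestral sequence, optionally duplicates it `duplication$age`
#' years ago into a paralogous family, radiates each family into its
#' haplotypes along a star tree of depth `radiation_time`, applies any
#' configured deletion, and records the complete truth. Only `observed` of
#' the `ploidy` haplotypes are emitted as "observed"; the remainder are the
#' missing haplotypes whose dosage the binomial test interrogates.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_locus`: `observed` (named character vector,
#'   the sequenced haplotypes), `truth` (list with `haplotypes` — all of
#'   them, aligned, with an `observed` flag —, `variants` — the true variant
#'   table with carriers and expected transcriptome proportions —,
#'   `paralogs` — the duplicated family, if any — and `ancestor`), and
#'   `config`.
#' @export
simulate_locus <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    anc <- random_dna(cfg$length)
    dup <- cfg$duplication
    anc1 <- if (is.null(dup)) anc else {
      evolve_sequence(anc, dup$age - cfg$radiation_time, cfg$rate)
    }
    haps <- vapply(seq_len(cfg$ploidy), function(i) {
      evolve_sequence(anc1, cfg$radiation_time, cfg$rate)
    }, character(1))
    names(haps) <- sprintf("hap%02d", seq_len(cfg$ploidy))
    if (!is.null(cfg$deletion)) {
      del <- cfg$deletion
      target <- if (is.character(del$haplotype)) del$haplotype else
        names(haps)[del$haplotype]
      s <- strsplit(haps[[target]], "")[[1]]
      s[seq(del$start, del$start + del$width - 1)] <- "-"
      haps[[target]] <- paste(s, collapse = "")
    }
    paralogs <- NULL
    if (!is.null(dup)) {
      anc2 <- evolve_sequence(anc, dup$age - cfg$radiation_time, cfg$rate)
      paralogs <- vapply(seq_len(dup$ploidy), function(i) {
        evolve_sequence(anc2, cfg$radiation_time, cfg$rate)
      }, character(1))
      names(paralogs) <- sprintf("par%02d", seq_len(dup$ploidy))
    }
    observed <- haps[seq_len(cfg$observed)]
    truth_var <- truth_variants(haps, cfg$weights)
    list_out <- list(
      observed = observed,
      truth = list(
        haplotypes = tibble(
          haplotype_id = names(haps), sequence = unname(haps),
          observed = seq_along(haps) <= cfg$observed,
          weight = cfg$weights
        ),
        variants = truth_var,
        paralogs = paralogs,
        ancestor = anc
      ),
      config = cfg
    )
    structure(list_out, class = "sim_locus")
  })
}

# independent column scan over the full haplotype set: polymorphic columns
# polarised by majority (lexicographic ties), adjacent same-carrier columns
# merged, gap runs collapsed; expected transcriptome proportion is the summed
# expression weight of the variant carriers
truth_variants <- function(haps, weights) {
  m <- do.call(rbind, strsplit(unname(haps), ""))
  ids <- names(haps)
  w <- setNames(weights, ids)
  events <- list()
  # gap runs (from configured deletions)
  gapped_cols <- which(apply(m == "-", 2, any))
  if (length(gapped_cols)) {
    runs <- split(gapped_cols, cumsum(c(TRUE, diff(gapped_cols) != 1)))
    for (run in runs) {
      del_carriers <- ids[m[, run[1]] == "-"]
      keep <- setdiff(seq_along(ids), match(del_carriers, ids))
      events[[length(events) + 1]] <- tibble(
        position = run[1], kind = "deletion",
        common_state = paste(m[keep[1], run], collapse = ""),
        variant_state = strrep("-", length(run)),
        carriers = list(sort(del_carriers)),
        expected_proportion = sum(w[del_carriers])
      )
    }
  }
  cand <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    use <- col != "-"
    tab <- table(col[use])
    if (length(tab) < 2) next
    ord <- order(-tab, names(tab))
    for (v in names(tab)[ord[-1]]) {
      cand[[length(cand) + 1]] <- list(col = j, common = names(tab)[ord[1]],
                                       variant = v,
                                       carriers = ids[use & col == v])
    }
  }
  k <- 1
  while (k <= length(cand)) {
    cur <- cand[[k]]
    cols <- cur$col; common <- cur$common; variant <- cur$variant
    k2 <- k + 1
    while (k2 <= length(cand) && cand[[k2]]$col == cols[length(cols)] + 1 &&
           setequal(cand[[k2]]$carriers, cur$carriers)) {
      cols <- c(cols, cand[[k2]]$col)
      common <- paste0(common, cand[[k2]]$common)
      variant <- paste0(variant, cand[[k2]]$variant)
      k2 <- k2 + 1
    }
    kind <- if (length(cols) > 1) "substitution_multibase" else if (
      paste0(sort(c(common, variant)), collapse = "") %in% c("AG", "CT")) {
      "snp_transition"
    } else "snp_transversion"
    events[[length(events) + 1]] <- tibble(
      position = cols[1], kind = kind, common_state = common,
      variant_state = variant, carriers = list(sort(cur$carriers)),
      expected_proportion = sum(w[cur$carriers])
    )
    k <- k2
  }
  if (!length(events)) {
    return(tibble(position = integer(), kind = character(),
                  common_state = character(), variant_state = character(),
                  carriers = list(), expected_proportion = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(events), .data$position)
}

#' Simulate transcriptome reads over a simulated locus
#'
#' Reads are drawn haplotype-by-haplotype with multinomial expression
#' weights, uniform start positions along the (ungapped) haplotype sequence,
#' and independent per-base errors at the configured rate. The number of
#' reads is `round(depth * length / read_length)`.
#'
#' @param locus A `sim_locus` from [simulate_locus()].
#' @param seed Seed for the read draw; defaults to `config$seed + 1` so a
#'   locus and its reads are jointly reproducible.
#' @return A tibble of reads: `read_id`, `haplotype_id` (truth origin),
#'   `start` (truth position on the source haplotype), `sequence`.
#' @export
simulate_reads <- function(locus, seed = NULL) {
  stopifnot(inherits(locus, "sim_locus"))
  cfg <- locus$config
  seed <- seed %||% (cfg$seed + 1L)
  withr::with_seed(seed, {
    haps <- setNames(gsub("-", "", locus$truth$haplotypes$sequence),
                     locus$truth$haplotypes$haplotype_id)
    n_reads <- round(cfg$depth * cfg$length / cfg$read_length)
    origin <- sample(names(haps), n_reads, replace = TRUE,
                     prob = cfg$weights)
    starts <- vapply(origin, function(h) {
      sample.int(nchar(haps[[h]]) - cfg$read_length + 1L, 1L)
    }, integer(1))
    seqs <- substr(haps[origin], starts, starts + cfg$read_length - 1L)
    if (cfg$error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        hit <- runif(length(ch)) < cfg$error_rate
        if (any(hit)) {
          ch[hit] <- vapply(ch[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    tibble(
      read_id = sprintf("read%05d", seq_len(n_reads)),
      haplotype_id = unname(origin),
      start = unname(starts),
      sequence = unname(seqs)
    )
  })
}

#' Simulate an LTR pair of known insertion age
#'
#' One ancestral LTR is duplicated at insertion; each copy then evolves
#' independently for `age` years under the JC process, so the pair's
#' corrected distance has expectation `2 * rate * age`.
#'
#' @param age Insertion age in years.
#' @param rate Substitution rate, substitutions/site/year.
#' @param length LTR length in bp.
#' @param seed Integer seed.
#' @return A list: `ltr5`, `ltr3`, `age`, `rate`.
#' @export
simulate_ltr_pair <- function(age, rate = 1.3e-8, length = 2000L, seed = 1L) {
  withr::with_seed(seed, {
    anc <- random_dna(length)
    list(
      ltr5 = evolve_sequence(anc, age, rate),
      ltr3 = evolve_sequence(anc, age, rate),
      age = age, rate = rate
    )
  })
}

#' Write sequences to FASTA / reads to FASTQ
#'
#' Plain-text writers whose output is byte-reproducible under a fixed seed.
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), filepath = path)
  invisible(path)
}

#' @param reads Read tibble from [simulate_reads()].
#' @rdname write_fasta
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(
    paste0("@", reads$read_id),
    reads$sequence,
    "+",
    strrep("I", nchar(reads$sequence))
  ))
  writeLines(lines, path)
  invisible(path)
}
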