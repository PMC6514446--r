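#' Count substitutions between two aligned sequences
#'
#' Columns containing a gap (`-`) or `N` in either sequence are excluded
#' (pairwise deletion). `A<->G` and `C<->T` differences are transitions;
#' all other base differences are transversions.
#'
#' @param seq_a,seq_b Equal-length aligned sequences (character scalars).
#' @return A one-row tibble with `sites` (columns compared), `transitions`,
#'   `transversions`, and the proportions `P`, `Q` and `p = P + Q`.
#' @export
count_substitutions <- function(seq_a, seq_b) {
  a <- toupper(strsplit(seq_a, "")[[1]])
  b <- toupper(strsplit(seq_b, "")[[1]])
  if (length(a) != length(b)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  ok <- !(a %in% c("-", "N", ".")) & !(b %in% c("-", "N", "."))
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (L == 0) stop("no comparable (ungapped, defined) columns", call. = FALSE)
  diff <- a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                  (a == "C" & b == "T") | (a == "T" & b == "C"))
  tibble(
    sites = L,
    transitions = sum(ts),
    transversions = sum(diff & !ts),
    P = sum(ts) / L,
    Q = sum(diff & !ts) / L,
    p = sum(diff) / L
  )
}

distance_estimate <- function(model, d, valid) {
  tibble(model = model, d = if (valid) d else NA_real_, valid = valid)
}

#' Jukes-Cantor (JC69) corrected distance
#'
#' `d = -(3/4) log(1 - (4/3) p)` substitutions per site. For `p >= 3/4` the
#' correction is undefined (saturation) and the estimate is flagged invalid
#' rather than raising an error.
#'
#' @param p Observed mismatch proportion in `[0, 1]`.
#' @return A one-row tibble with `model`, `d` and `valid`.
#' @export
jc69_distance <- function(p) {
  stopifnot(length(p) == 1, p >= 0, p <= 1)
  if (p >= 3 / 4) return(distance_estimate("JC69", NA_real_, FALSE))
  distance_estimate("JC69", -3 / 4 * log(1 - 4 * p / 3), TRUE)
}

#' Kimura 2-parameter (K2P) corrected distance
#'
#' `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)` where `P` and `Q` are the
#' transition and transversion proportions. Outside the log domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the estimate is flagged saturated.
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return A one-row tibble with `model`, `d` and `valid`.
#' @export
k2p_distance <- function(P, Q) {
  stopifnot(length(P) == 1, length(Q) == 1, P >= 0, Q >= 0, P + Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(distance_estimate("K2P", NA_real_, FALSE))
  distance_estimate("K2P", -log(w1) / 2 - log(w2) / 4, TRUE)
}

#' Model-corrected distance between two aligned sequences
#'
#' Convenience wrapper: counts substitutions with pairwise deletion of gap/N
#' columns and applies the chosen correction.
#'
#' @param seq_a,seq_b Equal-length aligned sequences.
#' @param model `"JC69"`, `"K2P"` or `"p"` (raw mismatch proportion).
#' @return A one-row tibble with `model`, `d` and `valid`.
#' @export
pair_distance <- function(seq_a, seq_b, model = c("JC69", "K2P", "p")) {
  model <- match.arg(model)
  cs <- count_substitutions(seq_a, seq_b)
  switch(model,
    p = distance_estimate("p", cs$p, TRUE),
    JC69 = jc69_distance(cs$p),
    K2P = k2p_distance(cs$P, cs$Q)
  )
}

# --- Nei-Gojobori (1986) synonymous / nonsynonymous distances ---------------

ng86_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(ng86_env$code)) ng86_env$code <- Biostrings::GENETIC_CODE
  ng86_env$code
}

# fraction of the nine single-base neighbours of `codon` that are synonymous,
# summed per position; neighbours that are stop codons count as nonsynonymous
syn_sites_codon <- function(codon) {
  code <- genetic_code()
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  cc <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (alt in setdiff(bases, cc[pos])) {
      mut <- cc
      mut[pos] <- alt
      if (code[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn difference counts over all minimal mutational pathways
# between two codons; pathways passing through a stop codon are excluded
# (unless every pathway does, in which case all are averaged)
ng86_diffs_codon <- function(c1, c2) {
  code <- genetic_code()
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  m <- length(pos)
  if (m == 0) return(c(sd = 0, nd = 0))
  paths <- if (m == 1) list(pos) else {
    perms <- all_permutations(pos)
    perms
  }
  step_counts <- function(order) {
    cur <- a
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(nxt, b)) through_stop <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, through_stop)
  }
  res <- t(vapply(paths, step_counts, numeric(3)))
  keep <- res[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(res))
  c(sd = mean(res[keep, 1]), nd = mean(res[keep, 2]))
}

all_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Nei-Gojobori synonymous and nonsynonymous distances (NG86)
#'
#' Counts synonymous and nonsynonymous sites by single-base neighbour
#' enumeration per codon (stop-codon neighbours count as nonsynonymous) and
#' synonymous/nonsynonymous differences averaged over all minimal mutational
#' pathways (pathways through stop codons excluded). Site counts are averaged
#' over the two sequences. `pS` and `pN` are corrected with the Jukes-Cantor
#' formula to give `dS` and `dN`; proportions at or beyond 3/4 are flagged
#' saturated.
#'
#' Codons containing a gap or ambiguous base in either sequence are excluded
#' (pairwise deletion at codon granularity).
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length divisible by 3,
#'   with no internal stop codon.
#' @return A one-row tibble with `codons`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `dS_valid`, `dN_valid`.
#' @examples
#' ng86_distance("AAAGGG", "AATGGG")
#' @export
ng86_distance <- function(cds_a, cds_b) {
  a <- toupper(cds_a)
  b <- toupper(cds_b)
  if (nchar(a) != nchar(b)) stop("CDS lengths differ", call. = FALSE)
  if (nchar(a) %% 3 != 0) {
    stop("CDS length must be a multiple of 3", call. = FALSE)
  }
  code <- genetic_code()
  split_codons <- function(x) {
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  }
  ca <- split_codons(a)
  cb <- split_codons(b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no comparable codons", call. = FALSE)
  ncod <- length(ca)
  # internal stops invalidate the reading frame (terminal stop is allowed)
  internal <- seq_len(ncod - 1)
  if (any(code[ca[internal]] == "*") || any(code[cb[internal]] == "*")) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  if (code[[ca[ncod]]] == "*" || code[[cb[ncod]]] == "*") {
    if (code[[ca[ncod]]] != code[[cb[ncod]]]) {
      stop("internal stop codon in coding sequence", call. = FALSE)
    }
    ca <- ca[-ncod]; cb <- cb[-ncod]
    ncod <- ncod - 1
    if (!ncod) stop("no comparable codons", call. = FALSE)
  }
  s_a <- vapply(ca, syn_sites_codon, numeric(1))
  s_b <- vapply(cb, syn_sites_codon, numeric(1))
  S <- (sum(s_a) + sum(s_b)) / 2
  N <- 3 * ncod - S
  diffs <- vapply(seq_len(ncod),
                  function(i) ng86_diffs_codon(ca[i], cb[i]), numeric(2))
  Sd <- sum(diffs[1, ])
  Nd <- sum(diffs[2, ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  tibble(
    codons = ncod, S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = jc(pS), dN = jc(pN),
    dS_valid = pS < 3 / 4, dN_valid = pN < 3 / 4
  )
}

#' Substitution-rate presets
#'
#' Per-site per-year substitution rates used for molecular-clock dating:
#' `6.5e-9` for coding sequence and `1.3e-8` for noncoding sequence
#' (grass nuclear-gene calibrations).
#'
#' @param preset `"coding"` or `"noncoding"`.
#' @return A rate in substitutions/site/year.
#' @export
substitution_rate <- function(preset = c("coding", "noncoding")) {
  switch(match.arg(preset), coding = 6.5e-9, noncoding = 1.3e-8)
}

#' Molecular-clock divergence time
#'
#' `T = d / (2 r)`: a pairwise distance of `d` substitutions per site at a
#' per-lineage rate `r` dates the split `T` years ago (both lineages
#' accumulate substitutions, hence the factor 2).
#'
#' @param d Model-corrected distance (substitutions/site), or a one-row
#'   distance tibble from [jc69_distance()] and friends.
#' @param rate Substitution rate in substitutions/site/year, or a preset name
#'   accepted by [substitution_rate()].
#' @return Time in years (`NA` with a warning-free flag for saturated `d`).
#' @examples
#' divergence_time(0.0585, "coding")  # ~4.5 My
#' @export
divergence_time <- function(d, rate) {
  if (is.data.frame(d)) {
    if (!isTRUE(d$valid[1])) return(NA_real_)
    d <- d$d[1]
  }
  if (is.character(rate)) rate <- substitution_rate(rate)
  stopifnot(rate > 0)
  if (is.na(d)) return(NA_real_)
  d / (2 * rate)
}

#' Date an LTR retrotransposon insertion from its two terminal repeats
#'
#' The two long terminal repeats of a retroelement are identical at insertion
#' and diverge afterwards, so their model-corrected distance `d` dates the
#' insertion at `d / (2 r)`.
#'
#' @param ltr5,ltr3 The element's two LTR sequences, aligned to equal length.
#' @param rate Substitution rate (substitutions/site/year); default `1.3e-8`.
#' @param model Distance correction, `"K2P"` (default) or `"JC69"`.
#' @return A one-row tibble with `model`, `d`, `rate`, `age_years`, `valid`.
#' @export
ltr_insertion_age <- function(ltr5, ltr3, rate = 1.3e-8,
                              model = c("K2P", "JC69")) {
  model <- match.arg(model)
  est <- pair_distance(ltr5, ltr3, model)
  tibble(
    model = model, d = est$d, rate = rate,
    age_years = if (est$valid) est$d / (2 * rate) else NA_real_,
    valid = est$valid
  )
}
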