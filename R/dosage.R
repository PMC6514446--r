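#' Exact two-sided binomial test
#'
#' P-value of the two-sided exact binomial test under the small-probability
#' summation convention: the p-value is the total probability of all outcomes
#' whose point probability does not exceed that of the observed count `k`
#' (up to a relative tolerance that absorbs floating-point noise). This is the
#' convention of classical exact binomial procedures; no normal approximation
#' is used.
#'
#' Degenerate nulls are handled exactly: under `p0 = 0` only `k = 0` is
#' possible (p-value 1, otherwise 0), and symmetrically for `p0 = 1`.
#'
#' @param k Observed successes (variant read count), `0 <= k <= n`.
#' @param n Number of trials (read coverage), positive integer.
#' @param p0 Null success proportion in `[0, 1]`. Pass exact fractions
#'   (e.g. `1/8`), not display roundings.
#' @param rel_tol Relative tolerance when comparing point probabilities to
#'   the observed one. Default `1e-7`.
#' @return A single p-value in `[0, 1]`.
#' @examples
#' exact_binomial_test(13, 16, 5/8)
#' exact_binomial_test(101, 443, 1/8)
#' @export
exact_binomial_test <- function(k, n, p0, rel_tol = 1e-7) {
  if (length(k) != 1 || length(n) != 1 || length(p0) != 1) {
    stop("k, n and p0 must be scalars", call. = FALSE)
  }
  if (is.na(k) || is.na(n) || n <= 0 || k < 0 || k > n || k != round(k)) {
    stop("k must be an integer with 0 <= k <= n and n > 0", call. = FALSE)
  }
  if (is.na(p0) || p0 < 0 || p0 > 1) {
    stop("p0 must lie in [0, 1]", call. = FALSE)
  }
  if (p0 == 0) return(if (k == 0) 1 else 0)
  if (p0 == 1) return(if (k == n) 1 else 0)
  probs <- dbinom(0:n, n, p0)
  pk <- probs[k + 1]
  min(1, sum(probs[probs <= pk * (1 + rel_tol)]))
}

#' Enumerate the two missing-haplotype dosage hypotheses for a SNP
#'
#' At a locus of ploidy `P` with `H` sequenced haplotypes, `P - H` haplotypes
#' are implied by cytology but unobserved. For a SNP carried by `x` of the
#' observed haplotypes, two genomic dosages are possible: the missing
#' haplotypes carry the common allele (`v = x`) or the variant allele
#' (`v = x + missing`). When the SNP was never seen in the genomic haplotypes
#' (`detected = FALSE`), only the missing haplotypes can carry it, and both
#' hypotheses coincide at `v = missing`.
#'
#' @param detected Logical; was the variant observed in the genomic haplotypes?
#' @param observed_variant_count Number of observed haplotypes carrying the
#'   variant allele (`x`); ignored when `detected` is `FALSE`.
#' @param ploidy Locus ploidy `P` (from cytology), positive integer.
#' @param observed Number of sequenced haplotypes `H <= P`.
#' @return A two-row tibble with columns `scenario`
#'   (`"missing_common"`/`"missing_variant"`), `genomic_variant`,
#'   `genomic_common` and `proportion` (`v / P`, an exact fraction).
#' @examples
#' build_hypotheses(TRUE, 1, ploidy = 8, observed = 7)
#' build_hypotheses(FALSE, 0, ploidy = 8, observed = 7)
#' @export
build_hypotheses <- function(detected, observed_variant_count,
                             ploidy, observed = ploidy - 1L) {
  stopifnot(length(detected) == 1, length(ploidy) == 1)
  if (ploidy < 1 || observed > ploidy || observed < 0) {
    stop("need 0 <= observed <= ploidy", call. = FALSE)
  }
  missing <- ploidy - observed
  x <- if (isTRUE(detected)) observed_variant_count else 0L
  if (is.na(x) || x < 0 || x > observed) {
    stop("observed_variant_count must lie in [0, observed]", call. = FALSE)
  }
  v <- if (isTRUE(detected)) c(x, x + missing) else c(missing, missing)
  if (any(v > ploidy)) {
    stop("variant dosage exceeds ploidy; inconsistent counts", call. = FALSE)
  }
  tibble(
    scenario = c("missing_common", "missing_variant"),
    genomic_variant = as.integer(v),
    genomic_common = as.integer(ploidy - v),
    proportion = v / ploidy
  )
}

#' Test one SNP's transcriptome allele ratio against its dosage hypotheses
#'
#' Runs the exact two-sided binomial test of `variant_coverage` successes in
#' `coverage` trials against each hypothesis' genomic proportion. A hypothesis
#' is accepted when `p >= alpha`, i.e. the transcriptome ratio is compatible
#' with the genomic ratio.
#'
#' @param coverage Total reads overlapping the SNP.
#' @param variant_coverage Reads carrying the variant allele.
#' @param hypotheses A tibble as returned by [build_hypotheses()] (columns
#'   `scenario`, `genomic_variant`, `genomic_common`, `proportion`).
#' @param alpha Acceptance level, default 0.05.
#' @return The `hypotheses` tibble with `p_value` and `accept` columns added,
#'   plus `coverage`, `variant_coverage` and `transcriptome_proportion`
#'   (rounded half-up to two decimals for reporting). With zero coverage the
#'   site is untestable and `p_value`/`accept` are `NA`.
#' @export
test_snp_dosage <- function(coverage, variant_coverage, hypotheses,
                            alpha = 0.05) {
  stopifnot(is.data.frame(hypotheses), "proportion" %in% names(hypotheses))
  out <- as_tibble(hypotheses)
  if (is.na(coverage) || coverage <= 0) {
    out$p_value <- NA_real_
    out$accept <- NA
  } else {
    out$p_value <- vapply(
      out$proportion,
      function(p0) exact_binomial_test(variant_coverage, coverage, p0),
      numeric(1)
    )
    out$accept <- out$p_value >= alpha
  }
  out$coverage <- coverage
  out$variant_coverage <- variant_coverage
  out$transcriptome_proportion <- if (is.na(coverage) || coverage <= 0) {
    NA_real_
  } else {
    round_half_up(variant_coverage / coverage, 2)
  }
  out
}

#' Run the missing-haplotype dosage test over a table of SNP counts
#'
#' The workhorse for reproducing published-style dosage tables. Each row of
#' `counts` describes one polymorphic site with its transcriptome coverage and
#' variant coverage. For each site the two missing-haplotype hypotheses are
#' enumerated (or taken from explicit per-site override columns) and tested
#' with the exact binomial test at exact fractions `v / P`.
#'
#' `counts` must contain `position`, `coverage`, `variant_coverage` and
#' `genomic_detected` (logical or `"Yes"`/`"No"`). Hypotheses come from either:
#' \itemize{
#'   \item `observed_variant_count`: the number of sequenced haplotypes
#'     carrying the variant, combined with `ploidy`/`observed` via
#'     [build_hypotheses()]; or
#'   \item explicit override columns `v_common`, `g_common`, `v_variant`,
#'     `g_variant` giving each hypothesis' variant and common dosage directly
#'     (null proportion `v / (v + g)`). Overrides win where non-missing, which
#'     accommodates sites whose printed support deviates from the default rule.
#' }
#' Sites with `in_duplication = TRUE` are excluded from testing when
#' `exclude_duplication` is set (reads from the paralogous copy confound the
#' ratio) but are retained in the output with empty hypothesis columns.
#'
#' @param counts Tibble of per-SNP counts (see Details).
#' @param ploidy Locus ploidy `P`.
#' @param observed Number of sequenced haplotypes `H`; default `ploidy - 1`.
#' @param alpha Acceptance level for `p >= alpha`.
#' @param exclude_duplication Exclude sites flagged `in_duplication`?
#' @return A tibble of class `"dosage_table"`, one row per site, ordered by
#'   position, with per-hypothesis columns `v_common`, `g_common`,
#'   `prop_common`, `p_common`, `accept_common` (and the `_variant`
#'   counterparts), `transcriptome_proportion`, `tested` and `accepted_any`.
#'   Attributes `alpha` and `ploidy` record the configuration; use
#'   [glance.dosage_table()] for the acceptance summary.
#' @examples
#' counts <- tibble::tibble(
#'   position = c(12, 263), coverage = c(443, 569),
#'   variant_coverage = c(101, 55), genomic_detected = c(TRUE, FALSE),
#'   observed_variant_count = c(1, 0)
#' )
#' run_dosage_table(counts, ploidy = 8)
#' @export
run_dosage_table <- function(counts, ploidy = 8, observed = ploidy - 1L,
                             alpha = 0.05, exclude_duplication = TRUE) {
  counts <- as_tibble(counts)
  need <- c("position", "coverage", "variant_coverage", "genomic_detected")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(counts$genomic_detected)) {
    counts$genomic_detected <- toupper(counts$genomic_detected) %in%
      c("YES", "TRUE", "Y")
  }
  if (!"in_duplication" %in% names(counts)) counts$in_duplication <- FALSE
  if (is.character(counts$in_duplication)) {
    counts$in_duplication <- toupper(counts$in_duplication) %in%
      c("YES", "TRUE", "Y")
  }
  has_override <- all(c("v_common", "g_common", "v_variant", "g_variant") %in%
                        names(counts))

  counts <- dplyr::arrange(counts, .data$position)
  rows <- purrr::pmap(
    list(seq_len(nrow(counts))),
    function(i) {
      row <- counts[i, ]
      if (exclude_duplication && isTRUE(row$in_duplication)) {
        return(tibble(
          scenario = NA_character_, genomic_variant = NA_integer_,
          genomic_common = NA_integer_, proportion = NA_real_,
          p_value = NA_real_, accept = NA,
          coverage = row$coverage, variant_coverage = row$variant_coverage,
          transcriptome_proportion =
            round_half_up(row$variant_coverage / row$coverage, 2),
          tested = FALSE
        ))
      }
      hyp <- if (has_override && !is.na(row$v_common) && !is.na(row$g_common)) {
        v <- c(row$v_common, row$v_variant)
        g <- c(row$g_common, row$g_variant)
        tibble(
          scenario = c("missing_common", "missing_variant"),
          genomic_variant = as.integer(v),
          genomic_common = as.integer(g),
          proportion = v / (v + g)
        )
      } else {
        build_hypotheses(row$genomic_detected,
                         row[["observed_variant_count"]] %||% 0L,
                         ploidy = ploidy, observed = observed)
      }
      res <- test_snp_dosage(row$coverage, row$variant_coverage, hyp, alpha)
      res$tested <- TRUE
      res
    }
  )

  wide <- purrr::map2_dfr(rows, seq_along(rows), function(res, i) {
    row <- counts[i, ]
    keep <- intersect(c("snp", "name", "change", "polymorphism_type"),
                      names(row))
    base <- tibble(
      position = row$position,
      coverage = row$coverage,
      variant_coverage = row$variant_coverage,
      genomic_detected = row$genomic_detected,
      in_duplication = row$in_duplication,
      transcriptome_proportion = res$transcriptome_proportion[1],
      tested = res$tested[1]
    )
    if (length(keep)) base <- dplyr::bind_cols(row[keep], base)
    if (res$tested[1]) {
      base$v_common <- res$genomic_variant[1]
      base$g_common <- res$genomic_common[1]
      base$prop_common <- res$proportion[1]
      base$p_common <- res$p_value[1]
      base$accept_common <- res$accept[1]
      base$v_variant <- res$genomic_variant[2]
      base$g_variant <- res$genomic_common[2]
      base$prop_variant <- res$proportion[2]
      base$p_variant <- res$p_value[2]
      base$accept_variant <- res$accept[2]
    } else {
      base$v_common <- NA_integer_; base$g_common <- NA_integer_
      base$prop_common <- NA_real_; base$p_common <- NA_real_
      base$accept_common <- NA
      base$v_variant <- NA_integer_; base$g_variant <- NA_integer_
      base$prop_variant <- NA_real_; base$p_variant <- NA_real_
      base$accept_variant <- NA
    }
    base$accepted_any <- if (base$tested) {
      isTRUE(base$accept_common) || isTRUE(base$accept_variant)
    } else NA
    base
  })

  structure(wide,
            class = c("dosage_table", class(wide)),
            alpha = alpha, ploidy = ploidy)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' @export
print.dosage_table <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dosage_table> %d sites (%d tested, ploidy %s, alpha %s)\n",
    g$n_sites, g$n_tested, attr(x, "ploidy"), attr(x, "alpha")))
  cat(sprintf(">=1 hypothesis accepted at %d/%d tested sites (%.0f%%)\n",
              g$n_accepted, g$n_tested, 100 * g$prop_accepted))
  NextMethod()
}

#' Tidy a dosage table into one row per site-hypothesis
#'
#' @param x A `dosage_table` from [run_dosage_table()].
#' @param ... Unused.
#' @return A long tibble with columns `position`, `scenario`,
#'   `genomic_variant`, `genomic_total`, `null_proportion`, `p_value`,
#'   `accepted`.
#' @export
tidy.dosage_table <- function(x, ...) {
  tested <- dplyr::filter(as_tibble(x), .data$tested)
  long <- dplyr::bind_rows(
    dplyr::transmute(tested,
      position = .data$position, scenario = "missing_common",
      genomic_variant = .data$v_common,
      genomic_total = .data$v_common + .data$g_common,
      null_proportion = .data$prop_common,
      p_value = .data$p_common, accepted = .data$accept_common),
    dplyr::transmute(tested,
      position = .data$position, scenario = "missing_variant",
      genomic_variant = .data$v_variant,
      genomic_total = .data$v_variant + .data$g_variant,
      null_proportion = .data$prop_variant,
      p_value = .data$p_variant, accepted = .data$accept_variant)
  )
  dplyr::arrange(long, .data$position, .data$scenario)
}

#' One-row summary of a dosage table
#'
#' @param x A `dosage_table`.
#' @param ... Unused.
#' @return A tibble with `n_sites`, `n_tested`, `n_accepted` (sites where at
#'   least one hypothesis was accepted), `prop_accepted` and `alpha`.
#' @method glance dosage_table
#' @export
glance.dosage_table <- function(x, ...) {
  tested <- dplyr::filter(as_tibble(x), .data$tested)
  tibble(
    n_sites = nrow(x),
    n_tested = nrow(tested),
    n_accepted = sum(tested$accepted_any, na.rm = TRUE),
    prop_accepted = if (nrow(tested)) {
      sum(tested$accepted_any, na.rm = TRUE) / nrow(tested)
    } else NA_real_,
    alpha = attr(x, "alpha")
  )
}

#' Plot dosage-test p-values along the gene
#'
#' One point per site and hypothesis, on a -log10 scale, with the acceptance
#' level drawn as a dashed line; points below the line reject the
#' corresponding genomic ratio.
#'
#' @param object A `dosage_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dosage_table
#' @export
autoplot.dosage_table <- function(object, ...) {
  long <- tidy(object)
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$position,
                               y = -log10(pmax(.data$p_value, 1e-40)),
                               colour = .data$scenario)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "CDS position (bp)",
                  y = expression(-log[10] ~ p),
                  colour = "missing haplotype carries") +
    ggplot2::theme_minimal()
}
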