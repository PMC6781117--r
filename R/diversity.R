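#' Allele frequencies by gene counting
#'
#' Relative allele frequencies per locus in a reference population: each
#' typed diploid contributes two allele copies; individuals untyped at a
#' locus are excluded from that locus's denominator only. By convention the
#' reference population is the full adult table (both sexes, all ponds)
#' unless the caller subsets it first.
#'
#' @param individuals An individuals tibble.
#' @param loci Locus metadata table; frequencies are computed for every
#'   locus listed.
#' @return A tibble with columns `locus`, `allele`, `count`, `freq`;
#'   frequencies at each locus sum to one.
#' @export
allele_frequencies <- function(individuals, loci) {
  loci <- validate_loci(loci)
  purrr::map_dfr(loci$locus, function(loc) {
    g <- geno_matrix(individuals, loc)
    copies <- c(g[, 1], g[, 2])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0) {
      stop("no typed individuals at locus ", loc, call. = FALSE)
    }
    tab <- table(copies)
    tibble::tibble(locus = loc,
                   allele = names(tab),
                   count = as.integer(tab),
                   freq = as.numeric(tab) / length(copies))
  })
}

# Observed heterozygosity per locus (share of typed individuals that are het).
observed_het_by_locus <- function(individuals, loci) {
  purrr::map_dfr(loci$locus, function(loc) {
    g <- geno_matrix(individuals, loc)
    typed <- !is.na(g[, 1]) & !is.na(g[, 2])
    tibble::tibble(locus = loc,
                   n_typed = sum(typed),
                   ho = if (sum(typed) == 0) NA_real_ else
                     mean(g[typed, 1] != g[typed, 2]))
  })
}

# Expected heterozygosity (1 - sum p^2) per locus from a freqs table.
expected_het_by_locus <- function(freqs) {
  freqs |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(he = 1 - sum(.data$freq^2), .groups = "drop")
}

#' Individual diversity profiles
#'
#' Per-individual microsatellite diversity indices and MHC heterozygosity
#' flags, the male-side statistics of the heterozygosity-advantage test:
#'
#' * `sh` -- standardised heterozygosity: the proportion of the individual's
#'   typed loci that are heterozygous divided by the mean observed
#'   heterozygosity of those same loci in the reference population, so the
#'   population mean of `sh` over fully typed individuals is close to 1.
#' * `hl` -- heterozygosity by locus: `sum(E_hom) / (sum(E_hom) + sum(E_het))`
#'   where `E` is a locus's expected heterozygosity and the two sums run over
#'   the individual's homozygous and heterozygous typed loci; 0 means fully
#'   heterozygous, 1 fully homozygous.
#' * `ir` -- internal relatedness: `(2H - sum(f)) / (2N - sum(f))` with `H`
#'   homozygous loci, `N` typed loci and `f` the reference frequencies of the
#'   2N allele copies carried; positive values indicate parental similarity.
#' * `d2` -- mean squared difference between the two allele lengths across
#'   typed microsatellite loci, in repeat units by default (base-pair
#'   difference divided by motif length) or raw base pairs with
#'   `d2_unit = "bp"`.
#'
#' Indices that are undefined for an individual (no typed loci, or a
#' degenerate denominator such as a monomorphic reference) are returned as
#' `NA` rather than silently as zero.
#'
#' @param individuals Individuals to profile (any subset of the reference).
#' @param loci Locus metadata table.
#' @param reference Reference population for frequencies and observed
#'   heterozygosity; defaults to `individuals`.
#' @param freqs Optional precomputed [allele_frequencies()] table for the
#'   reference population.
#' @param d2_unit `"repeats"` (default) or `"bp"`.
#' @return A tibble, one row per individual: `id`, `n_typed`, `sh`, `hl`,
#'   `ir`, `d2`, and one logical `het_<locus>` column per MHC locus.
#' @export
diversity_profiles <- function(individuals, loci, reference = individuals,
                               freqs = NULL, d2_unit = c("repeats", "bp")) {
  loci <- validate_loci(loci)
  d2_unit <- match.arg(d2_unit)
  ms_loci <- loci[loci$type == "microsat", ]
  mhc_loci <- loci[loci$type == "mhc", ]
  if (is.null(freqs)) freqs <- allele_frequencies(reference, loci)
  fl <- freq_list(freqs)
  ho_tbl <- observed_het_by_locus(reference, ms_loci)
  ho <- stats::setNames(ho_tbl$ho, ho_tbl$locus)
  he_tbl <- expected_het_by_locus(freqs[freqs$locus %in% ms_loci$locus, ])
  he <- stats::setNames(he_tbl$he, he_tbl$locus)

  n <- nrow(individuals)
  gm <- lapply(ms_loci$locus, function(loc) geno_matrix(individuals, loc))
  names(gm) <- ms_loci$locus

  sh <- hl <- ir <- d2 <- rep(NA_real_, n)
  n_typed <- integer(n)
  for (i in seq_len(n)) {
    typed <- vapply(gm, function(g) !is.na(g[i, 1]) && !is.na(g[i, 2]),
                    logical(1))
    loci_i <- ms_loci$locus[typed]
    n_typed[i] <- length(loci_i)
    if (length(loci_i) == 0) next
    het <- vapply(loci_i, function(loc) gm[[loc]][i, 1] != gm[[loc]][i, 2],
                  logical(1))
    # SH
    mean_ho <- mean(ho[loci_i])
    if (!is.na(mean_ho) && mean_ho > 0) sh[i] <- mean(het) / mean_ho
    # HL
    e <- he[loci_i]
    denom <- sum(e)
    if (denom > 0) hl[i] <- sum(e[!het]) / denom
    # IR
    fsum <- sum(vapply(loci_i, function(loc) {
      p <- fl[[loc]]
      unname(p[gm[[loc]][i, 1]] + p[gm[[loc]][i, 2]])
    }, numeric(1)))
    ir_den <- 2 * length(loci_i) - fsum
    if (abs(ir_den) > 1e-12) ir[i] <- (2 * sum(!het) - fsum) / ir_den
    # d2
    diffs <- vapply(loci_i, function(loc) {
      d <- abs(as.numeric(gm[[loc]][i, 1]) - as.numeric(gm[[loc]][i, 2]))
      if (d2_unit == "repeats") {
        motif <- ms_loci$motif_length[ms_loci$locus == loc]
        r <- d / motif
        if (abs(r - round(r)) > 1e-8) {
          warning(sprintf("non-integer repeat difference at locus %s (%.3f units)",
                          loc, r), call. = FALSE)
        }
        r
      } else {
        d
      }
    }, numeric(1))
    d2[i] <- mean(diffs^2)
  }

  out <- tibble::tibble(id = individuals$id, n_typed = n_typed,
                        sh = sh, hl = hl, ir = ir, d2 = d2)
  for (loc in mhc_loci$locus) {
    g <- geno_matrix(individuals, loc)
    out[[paste0("het_", loc)]] <- ifelse(is.na(g[, 1]) | is.na(g[, 2]),
                                         NA, g[, 1] != g[, 2])
  }
  out
}

#' MHC heterozygote proportion among a male set
#'
#' The proportion of males heterozygous at one MHC locus, over the unique
#' males typed at that locus. `Ho` is the observed statistic of the
#' heterozygosity-advantage test on the MHC side.
#'
#' @param males An individuals tibble restricted to the male set of interest
#'   (e.g. unique breeding males).
#' @param locus MHC locus id.
#' @return A single proportion in `[0, 1]`.
#' @export
mhc_het_proportion <- function(males, locus) {
  if (nrow(males) == 0) stop("empty male set", call. = FALSE)
  males <- dplyr::distinct(males, .data$id, .keep_all = TRUE)
  g <- geno_matrix(males, locus)
  typed <- !is.na(g[, 1]) & !is.na(g[, 2])
  if (sum(typed) == 0) stop("no male typed at locus ", locus, call. = FALSE)
  mean(g[typed, 1] != g[typed, 2])
}

#' Carried-allele frequency score (good-gene statistic)
#'
#' For each individual, the sum of the reference-population frequencies of
#' the two allele copies carried at an MHC locus (`AF`); a homozygote for an
#' allele of frequency p scores 2p, so the score lies in (0, 2]. Under the
#' good-gene hypothesis breeding males would carry preferred (high- or
#' low-frequency) alleles more often than random males.
#'
#' @param individuals Individuals to score.
#' @param freqs [allele_frequencies()] table of the reference population.
#' @param locus MHC locus id.
#' @return A tibble with columns `id` and `af` (`NA` when untyped).
#' @export
good_gene_score <- function(individuals, freqs, locus) {
  p <- freq_list(freqs)[[locus]]
  if (is.null(p)) stop("no frequencies for locus ", locus, call. = FALSE)
  g <- geno_matrix(individuals, locus)
  af <- unname(p[g[, 1]] + p[g[, 2]])
  tibble::tibble(id = individuals$id, af = as.numeric(af))
}
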