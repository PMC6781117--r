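# Pond-stratified Monte-Carlo randomisation test. The null hypothesis of
# random mating is materialised by re-pairing: within each pond, as many
# random female x male pairs are drawn (with replacement, uniformly over
# that pond's candidates) as there are true mating pairs, the statistic is
# averaged over the pooled random pairs, and the procedure is repeated
# n_iter times. The observed mean is compared with the null sample via an
# empirical two-tailed p-value and the 2.5/97.5 percentile interval.

# Evaluate code with a locally seeded RNG, restoring the caller's state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Stratified randomisation design from a pair table
#'
#' Per pond: the number of true mating pairs (which fixes the number of
#' random pairs drawn per replicate) and the candidate females and males of
#' that pond. Ponds are physically closed breeding pools, so candidates are
#' drawn only from the pond's own adults.
#'
#' @param pairs Validated mating-pair tibble (used only for its pond
#'   counts).
#' @param individuals Adult table supplying the candidates.
#' @param candidates `"all"` (default: every adult of the pond) or
#'   `"breeding-only"` (only adults appearing in `pairs`).
#' @return A tibble with columns `pond`, `n_pairs`, `females`, `males` (the
#'   last two are list-columns of candidate ids).
#' @export
stratified_design <- function(pairs, individuals,
                              candidates = c("all", "breeding-only")) {
  candidates <- match.arg(candidates)
  counts <- dplyr::count(pairs, .data$pond, name = "n_pairs")
  pool <- if (candidates == "all") {
    individuals
  } else {
    individuals[individuals$id %in% c(pairs$female_id, pairs$male_id), ]
  }
  design <- counts |>
    dplyr::mutate(
      females = purrr::map(.data$pond, function(p)
        pool$id[pool$pond == p & pool$sex == "female"]),
      males = purrr::map(.data$pond, function(p)
        pool$id[pool$pond == p & pool$sex == "male"]))
  bad <- design$n_pairs > 0 &
    (lengths(design$females) == 0 | lengths(design$males) == 0)
  if (any(bad)) {
    stop("pond with true pairs but no candidate of one sex: ",
         paste(design$pond[bad], collapse = ", "), call. = FALSE)
  }
  design
}

# Draw all replicate indices in one seeded block. Column r of each index
# matrix is replicate r, and replicate r consumes a contiguous chunk of the
# underlying uniform stream, so a single replicate can be reproduced from
# (design, seed, r) alone.
draw_replicate_indices <- function(design, n_iter, seed,
                                   replicates = seq_len(n_iter)) {
  k_pond <- 2L * design$n_pairs
  k_tot <- sum(k_pond)
  want <- max(replicates)
  u <- with_local_seed(seed, stats::runif(want * k_tot))
  u <- matrix(u, nrow = k_tot)[, replicates, drop = FALSE]
  offsets <- c(0L, cumsum(k_pond))
  out <- vector("list", nrow(design))
  names(out) <- design$pond
  for (p in seq_len(nrow(design))) {
    np <- design$n_pairs[p]
    rows <- (offsets[p] + 1L):(offsets[p] + 2L * np)
    block <- u[rows, , drop = FALSE]
    nf <- length(design$females[[p]])
    nm <- length(design$males[[p]])
    fi <- pmin(floor(block[1:np, , drop = FALSE] * nf) + 1L, nf)
    mi <- pmin(floor(block[np + (1:np), , drop = FALSE] * nm) + 1L, nm)
    out[[p]] <- list(female = fi, male = mi)
  }
  out
}

#' Draw one replicate of random within-pond pairs
#'
#' Deterministic given `(design, seed, replicate)`: the same triple always
#' yields the same pair list, independent of how many other replicates are
#' drawn. Sampling is with replacement, so a female or male may recur
#' within a replicate.
#'
#' @param design A [stratified_design()] tibble.
#' @param seed Master seed of the randomisation run.
#' @param replicate Replicate index (1-based).
#' @return A tibble of random pairs: `pond`, `female_id`, `male_id`.
#' @export
sample_null_pairs <- function(design, seed, replicate = 1L) {
  idx <- draw_replicate_indices(design, replicate, seed,
                                replicates = replicate)
  purrr::map_dfr(seq_len(nrow(design)), function(p) {
    tibble::tibble(
      pond = design$pond[p],
      female_id = design$females[[p]][idx[[p]]$female[, 1]],
      male_id = design$males[[p]][idx[[p]]$male[, 1]])
  })
}

# Internal engine. `values` is a named list (by pond):
#   mode "pair":        matrix [females x males] of the pair statistic
#   mode "male":        named numeric vector over the pond's males
#   mode "unique-male": named numeric vector; each replicate averages over
#                       the distinct males it sampled (pooled across ponds)
mc_engine <- function(design, values, observed, mode, n_iter, seed,
                      statistic, locus = NA_character_,
                      na_policy = c("drop", "abort")) {
  na_policy <- match.arg(na_policy)
  idx <- draw_replicate_indices(design, n_iter, seed)
  if (mode == "unique-male") {
    null <- vapply(seq_len(n_iter), function(r) {
      ids <- unlist(lapply(seq_len(nrow(design)), function(p) {
        design$males[[p]][idx[[p]]$male[, r]]
      }), use.names = FALSE)
      v <- values_by_id(values)[unique(ids)]
      mean(v, na.rm = TRUE)
    }, numeric(1))
    n_dropped <- 0L
  } else {
    tot <- matrix(0, nrow = n_iter, ncol = 2)  # sum, count of non-NA
    for (p in seq_len(nrow(design))) {
      np <- design$n_pairs[p]
      v <- if (mode == "pair") {
        m <- values[[design$pond[p]]]
        matrix(m[cbind(as.vector(idx[[p]]$female), as.vector(idx[[p]]$male))],
               nrow = np)
      } else {
        vec <- values[[design$pond[p]]]
        matrix(vec[as.vector(idx[[p]]$male)], nrow = np)
      }
      tot[, 1] <- tot[, 1] + colSums(m_or_zero(v))
      tot[, 2] <- tot[, 2] + colSums(!is.na(v))
    }
    n_dropped <- sum(design$n_pairs) * n_iter - sum(tot[, 2])
    if (n_dropped > 0 && na_policy == "abort") {
      stop("statistic undefined on ", n_dropped, " sampled pair(s)",
           call. = FALSE)
    }
    null <- tot[, 1] / tot[, 2]
  }
  new_mc_result(statistic, locus, mode, observed, null, n_iter, seed,
                n_dropped)
}

values_by_id <- function(values) {
  v <- unlist(unname(values))
  v[!duplicated(names(v))]
}

m_or_zero <- function(v) {
  v[is.na(v)] <- 0
  v
}

# Empirical two-tailed p with the +1 correction (never exactly zero).
empirical_p <- function(observed, null) {
  n <- length(null)
  lo <- sum(null <= observed) + 1L
  hi <- sum(null >= observed) + 1L
  min(1, 2 * min(lo, hi) / (n + 1))
}

new_mc_result <- function(statistic, locus, mode, observed, null, n_iter,
                          seed, n_dropped = 0L) {
  ci <- stats::quantile(null, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  tibble::tibble(
    statistic = statistic,
    locus = locus,
    mode = mode,
    observed = observed,
    p_value = empirical_p(observed, null),
    ci_lower = ci[1],
    ci_upper = ci[2],
    significant = observed < ci[1] | observed > ci[2],
    n_iter = length(null),
    seed = seed,
    n_dropped = n_dropped,
    null = list(null))
}

#' Randomisation test of one statistic
#'
#' Compares an observed mean against the stratified random-pairing null.
#' The significance decision follows the confidence-interval rule (observed
#' outside the null's 2.5-97.5 percentile band); the empirical two-tailed
#' p-value (with the +1 correction, so never exactly zero) is reported
#' alongside.
#'
#' @param design A [stratified_design()] tibble.
#' @param values Pond-keyed list of statistic values: a `females x males`
#'   matrix per pond for `mode = "pair"`, or a named per-male vector for the
#'   male modes.
#' @param observed Observed mean on the true pairs / true breeding males.
#' @param mode `"pair"`, `"male"` (male of each sampled pair, so males are
#'   weighted by how often they are drawn) or `"unique-male"` (each
#'   replicate averages over the distinct males it sampled).
#' @param n_iter Number of Monte-Carlo replicates (study convention: 9999).
#' @param seed Seed for the replicate stream.
#' @param statistic,locus Labels carried into the result row.
#' @param na_policy Sampled pairs on which the statistic is undefined are
#'   dropped from the replicate mean (`"drop"`, logged in `n_dropped`) or
#'   abort the run (`"abort"`).
#' @return A one-row tibble: observed value, empirical p, CI bounds,
#'   significance flag, and the full null sample as a list-column `null`.
#' @export
randomize_statistic <- function(design, values, observed,
                                mode = c("pair", "male", "unique-male"),
                                n_iter = 9999, seed = 1,
                                statistic = "statistic",
                                locus = NA_character_,
                                na_policy = c("drop", "abort")) {
  mode <- match.arg(mode)
  mc_engine(design, values, observed, mode, n_iter, seed, statistic, locus,
            na_policy)
}

#' Exact expectation of the randomisation null mean
#'
#' The large-`n_iter` limit of the null sample mean: the mean of the
#' statistic over all within-pond female x male combinations, weighted by
#' each pond's true pair count. Used as an enumeration oracle for the
#' Monte-Carlo engine.
#'
#' @inheritParams randomize_statistic
#' @return A scalar.
#' @export
expected_null_mean <- function(design, values, mode = c("pair", "male")) {
  mode <- match.arg(mode)
  per_pond <- vapply(seq_len(nrow(design)), function(p) {
    v <- values[[design$pond[p]]]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  sum(per_pond * design$n_pairs) / sum(design$n_pairs)
}
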