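# The full mate-choice hypothesis suite: the complete set of statistics
# tested against the stratified random-pairing null.
#
#   good-gene:              af per MHC locus (male mode)
#   heterozygosity advantage: d2, sh (male mode); ho per MHC locus
#                             (unique-male mode, matching the convention of
#                             counting each breeding male once)
#   compatible-gene:        aa_dist, aa_func_dist, nsa per MHC locus
#                           (pair mode)
#   inbreeding avoidance:   r_qg (pair mode)

# females x males matrix of a vectorised pair function over one pond.
pond_pair_matrix <- function(f_ids, m_ids, fun) {
  grid <- expand.grid(fi = seq_along(f_ids), mi = seq_along(m_ids))
  vals <- fun(f_ids[grid$fi], m_ids[grid$mi])
  matrix(vals, nrow = length(f_ids), ncol = length(m_ids),
         dimnames = list(f_ids, m_ids))
}

# Vectorised allele sharing for 2x2 genotypes.
nsa_vec <- function(fa, fb, ma, mb) {
  two <- (fa == ma & fb == mb) | (fa == mb & fb == ma)
  one <- (fa == ma) | (fa == mb) | (fb == ma) | (fb == mb)
  ifelse(two, 2L, ifelse(one, 1L, 0L))
}

# Vectorised four-term pair distance from a small allele distance matrix.
pair_dist_vec <- function(fa, fb, ma, mb, dm) {
  dm[cbind(fa, ma)] + dm[cbind(fa, mb)] + dm[cbind(fb, ma)] +
    dm[cbind(fb, mb)]
}

#' Run the complete mate-choice hypothesis suite
#'
#' Computes every observed statistic on the true mating pairs (or true
#' breeding males) and tests each against the pond-stratified random-pairing
#' null. True pairs are de-duplicated to unique female x male pairs before
#' testing (a pair observed repeatedly counts once). No multiple-testing
#' correction is applied; the number of tests is the number of rows
#' returned, so readers can apply their own.
#'
#' @param individuals Adult genotype table.
#' @param loci Locus metadata table.
#' @param pairs Validated mating-pair tibble.
#' @param alleles MHC allele catalogue with translated proteins.
#' @param n_iter Monte-Carlo replicates per statistic (default 9999).
#' @param seed Master seed; each statistic receives a distinct stream
#'   derived from it.
#' @param model Amino-acid distance model (`"p"` or `"poisson"`).
#' @param statistics Subset of
#'   `c("af", "d2", "sh", "ho", "aa_dist", "aa_func_dist", "nsa", "r_qg")`.
#' @param candidates Candidate pool per pond, see [stratified_design()].
#' @return A tibble with one row per statistic (x MHC locus where
#'   applicable): observed mean, empirical p, 95% CI of the null,
#'   significance flag and the null sample as a list-column.
#' @export
run_mate_choice_suite <- function(individuals, loci, pairs, alleles = NULL,
                                  n_iter = 9999, seed = 1,
                                  model = c("p", "poisson"),
                                  statistics = c("af", "d2", "sh", "ho",
                                                 "aa_dist", "aa_func_dist",
                                                 "nsa", "r_qg"),
                                  candidates = c("all", "breeding-only")) {
  loci <- validate_loci(loci)
  model <- match.arg(model)
  statistics <- match.arg(statistics, several.ok = TRUE)
  pairs <- validate_pairs(pairs, individuals)
  if (nrow(pairs) == 0) stop("no mating pairs to test", call. = FALSE)
  pairs <- dplyr::distinct(pairs, .data$female_id, .data$male_id,
                           .keep_all = TRUE)
  design <- stratified_design(pairs, individuals, candidates = candidates)
  mhc_loci <- loci$locus[loci$type == "mhc"]
  needs_seq <- any(c("aa_dist", "aa_func_dist") %in% statistics)
  if (needs_seq && is.null(alleles)) {
    stop("allele sequences required for aa_dist / aa_func_dist",
         call. = FALSE)
  }
  freqs <- allele_frequencies(individuals, loci)
  prof <- diversity_profiles(individuals, loci, reference = individuals,
                             freqs = freqs)

  male_tbl <- individuals[individuals$sex == "male", ]
  male_vec <- function(value_by_id) {
    lapply(stats::setNames(design$pond, design$pond), function(p) {
      ids <- design$males[[match(p, design$pond)]]
      stats::setNames(unname(value_by_id[ids]), ids)
    })
  }
  breeding_males <- unique(pairs$male_id)
  pair_males <- pairs$male_id  # pair-weighted male list

  results <- list()
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)
  }

  run_male_stat <- function(name, value_by_id, locus = NA_character_,
                            basis = c("pair", "unique-male")) {
    basis <- match.arg(basis)
    observed <- if (basis == "unique-male") {
      mean(value_by_id[breeding_males], na.rm = TRUE)
    } else {
      mean(value_by_id[pair_males], na.rm = TRUE)
    }
    mode <- if (basis == "unique-male") "unique-male" else "male"
    mc_engine(design, male_vec(value_by_id), observed, mode, n_iter,
              next_seed(), name, locus)
  }
  run_pair_stat <- function(name, mats, observed, locus = NA_character_) {
    mc_engine(design, mats, observed, "pair", n_iter, next_seed(), name,
              locus)
  }

  if ("af" %in% statistics) {
    for (loc in mhc_loci) {
      af <- good_gene_score(individuals, freqs, loc)
      v <- stats::setNames(af$af, af$id)
      results[[length(results) + 1L]] <- run_male_stat("af", v, loc)
    }
  }
  if ("d2" %in% statistics) {
    v <- stats::setNames(prof$d2, prof$id)
    results[[length(results) + 1L]] <- run_male_stat("d2", v)
  }
  if ("sh" %in% statistics) {
    v <- stats::setNames(prof$sh, prof$id)
    results[[length(results) + 1L]] <- run_male_stat("sh", v)
  }
  if ("ho" %in% statistics) {
    for (loc in mhc_loci) {
      het <- prof[[paste0("het_", loc)]]
      v <- stats::setNames(as.numeric(het), prof$id)
      results[[length(results) + 1L]] <-
        run_male_stat("ho", v, loc, basis = "unique-male")
    }
  }

  pair_stats <- intersect(c("aa_dist", "aa_func_dist", "nsa"), statistics)
  if (length(pair_stats) > 0) {
    for (loc in mhc_loci) {
      g <- geno_matrix(individuals, loc)
      ga <- stats::setNames(g[, 1], individuals$id)
      gb <- stats::setNames(g[, 2], individuals$id)
      mats_for <- function(fun) {
        lapply(stats::setNames(design$pond, design$pond), function(p) {
          i <- match(p, design$pond)
          pond_pair_matrix(design$females[[i]], design$males[[i]], fun)
        })
      }
      obs_for <- function(fun) {
        mean(fun(pairs$female_id, pairs$male_id), na.rm = TRUE)
      }
      if ("nsa" %in% pair_stats) {
        fun <- function(f, m) {
          v <- nsa_vec(ga[f], gb[f], ga[m], gb[m])
          as.numeric(v)
        }
        results[[length(results) + 1L]] <-
          run_pair_stat("nsa", mats_for(fun), obs_for(fun), loc)
      }
      if ("aa_dist" %in% pair_stats) {
        dm <- allele_distance_matrix(alleles, loc, kind = "aa",
                                     model = model)
        fun <- function(f, m) pair_dist_vec(ga[f], gb[f], ga[m], gb[m], dm)
        results[[length(results) + 1L]] <-
          run_pair_stat("aa_dist", mats_for(fun), obs_for(fun), loc)
      }
      if ("aa_func_dist" %in% pair_stats) {
        dm <- allele_distance_matrix(alleles, loc, kind = "functional")
        fun <- function(f, m) pair_dist_vec(ga[f], gb[f], ga[m], gb[m], dm)
        results[[length(results) + 1L]] <-
          run_pair_stat("aa_func_dist", mats_for(fun), obs_for(fun), loc)
      }
    }
  }

  if ("r_qg" %in% statistics) {
    ms_loci <- loci[loci$type == "microsat", ]
    fl <- freq_list(freqs[freqs$locus %in% ms_loci$locus, ])
    qg_fun <- function(f, m) {
      i1 <- match(f, individuals$id)
      i2 <- match(m, individuals$id)
      gx <- gy <- list()
      for (loc in ms_loci$locus) {
        g <- geno_matrix(individuals, loc)
        gx[[loc]] <- g[i1, , drop = FALSE]
        gy[[loc]] <- g[i2, , drop = FALSE]
      }
      qg_relatedness(gx, gy, fl, ms_loci$locus)$r
    }
    mats <- lapply(stats::setNames(design$pond, design$pond), function(p) {
      i <- match(p, design$pond)
      pond_pair_matrix(design$females[[i]], design$males[[i]], qg_fun)
    })
    observed <- mean(qg_fun(pairs$female_id, pairs$male_id), na.rm = TRUE)
    results[[length(results) + 1L]] <-
      run_pair_stat("r_qg", mats, observed)
  }

  dplyr::bind_rows(results)
}
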