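# Synthetic population generator. Emulates the structure of a closed
# captive alligator colony: three physically separated breeding ponds, a
# small wild founder base (so background relatedness exists among adults),
# a panel of polymorphic microsatellites, two biallelic MHC class I loci
# with coding sequences, and clutches of Mendelian offspring. Female
# preference enters as a log-linear (softmax) weight on male MHC
# heterozygosity and/or pair functional distance, so the null model is
# exact at zero strength and preference strengths are recoverable.

codons_sense <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# codon -> amino acid, standard genetic code
codon_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[codons_sense()]
}

rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

#' Generator configuration
#'
#' Bundles every tunable of the synthetic colony. Defaults emulate the
#' study system: 123 females and 59 males split proportionally over 3 ponds
#' (41/20, 41/20, 41/19), 13 microsatellite loci with 4-10 alleles and
#' 2-4 bp motifs, 2 biallelic MHC loci with 270 bp coding fragments at a
#' target amino-acid p-distance of 0.10 between alleles, 11 founders,
#' 105 clutches with Poisson(16) clutch sizes (about 1684 offspring).
#'
#' @param seed Master seed; the whole dataset is a deterministic function
#'   of the config including this seed.
#' @param ponds Tibble with `pond`, `n_females`, `n_males`.
#' @param n_microsat_loci,allele_count_range,motif_lengths Microsatellite
#'   panel shape.
#' @param mhc_loci Names of the MHC loci (each gets 2 alleles).
#' @param mhc_coding_length Coding length in bp (multiple of 3).
#' @param mhc_target_p Target amino-acid p-distance between the two alleles
#'   of a locus (per-codon replacement probability).
#' @param n_founders Size of the founder base.
#' @param preference `"null"`, `"heterozygote"`, `"compatibility"` or
#'   `"mixed"`.
#' @param beta Preference strength on male MHC heterozygosity (log-linear).
#' @param gamma Preference strength on pair functional distance.
#' @param preference_locus MHC locus the preference acts on (default the
#'   first).
#' @param n_clutches Number of clutches laid.
#' @param lambda Mean clutch size (Poisson).
#' @param noise_rate Per-allele-call mistyping probability injected into
#'   offspring genotypes (0 = error-free).
#' @param make_offspring Generate offspring genotypes/trios (disable when
#'   only adults and pairings are needed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ponds = tibble::tibble(
                         pond = c("A", "B", "C"),
                         n_females = c(41L, 41L, 41L),
                         n_males = c(20L, 20L, 19L)),
                       n_microsat_loci = 13L,
                       allele_count_range = c(4L, 10L),
                       motif_lengths = 2:4,
                       mhc_loci = c("I1327e3", "I20e2"),
                       mhc_coding_length = 270L,
                       mhc_target_p = 0.10,
                       n_founders = 11L,
                       preference = c("null", "heterozygote",
                                      "compatibility", "mixed"),
                       beta = 2,
                       gamma = 5,
                       preference_locus = NULL,
                       n_clutches = 105L,
                       lambda = 16,
                       noise_rate = 0,
                       make_offspring = TRUE) {
  preference <- match.arg(preference)
  stopifnot(mhc_coding_length %% 3 == 0, n_founders >= 2,
            all(ponds$n_females > 0), all(ponds$n_males > 0),
            n_clutches > 0, lambda > 0, noise_rate >= 0, noise_rate <= 1)
  cfg <- list(seed = as.integer(seed), ponds = tibble::as_tibble(ponds),
              n_microsat_loci = n_microsat_loci,
              allele_count_range = allele_count_range,
              motif_lengths = motif_lengths,
              mhc_loci = mhc_loci,
              mhc_coding_length = mhc_coding_length,
              mhc_target_p = mhc_target_p,
              n_founders = n_founders,
              preference = preference, beta = beta, gamma = gamma,
              preference_locus = preference_locus %||% mhc_loci[1],
              n_clutches = n_clutches, lambda = lambda,
              noise_rate = noise_rate, make_offspring = make_offspring)
  class(cfg) <- "sim_config"
  cfg
}

# Effective (beta, gamma) under the chosen preference model.
preference_strengths <- function(config) {
  switch(config$preference,
         null = c(beta = 0, gamma = 0),
         heterozygote = c(beta = config$beta, gamma = 0),
         compatibility = c(beta = 0, gamma = config$gamma),
         mixed = c(beta = config$beta, gamma = config$gamma))
}

# Random coding sequence of n codons without stop codons.
random_coding <- function(n_codons, pool = codons_sense()) {
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# Second allele: each codon independently replaced (with prob target_p) by
# a codon coding a different amino acid, so the realised amino-acid
# p-distance is Binomial(n_codons, target_p) / n_codons.
diverge_coding <- function(dna, target_p) {
  aa_of <- codon_aa()
  pool <- names(aa_of)
  codons <- substring(dna, seq(1, nchar(dna) - 2, 3),
                      seq(3, nchar(dna), 3))
  flip <- stats::runif(length(codons)) < target_p
  for (i in which(flip)) {
    other <- pool[aa_of != aa_of[codons[i]]]
    codons[i] <- sample(other, 1)
  }
  paste(codons, collapse = "")
}

# Draw founder allele copies at one locus, insisting on polymorphism.
# The frequency vector itself is redrawn when it is so skewed that the
# founder base keeps coming out monomorphic.
draw_founder_copies <- function(alleles, freqs, n_copies) {
  for (round in 1:100) {
    for (try in 1:10) {
      copies <- sample(alleles, n_copies, replace = TRUE, prob = freqs)
      if (length(unique(copies)) >= 2) return(copies)
    }
    freqs <- rdirichlet1(length(alleles))
  }
  stop("could not realise a polymorphic founder locus", call. = FALSE)
}

#' Generate the adult population and MHC allele catalogue
#'
#' Founder genotypes are drawn from Dirichlet-uniform allele frequencies
#' (redrawn until every locus is polymorphic among founders); each adult is
#' a Mendelian offspring of two distinct random founders, which creates the
#' background relatedness of a closed colony. MHC allele coding sequences
#' are random sense codons with a controlled amino-acid divergence between
#' the two alleles of a locus.
#'
#' Call within [simulate_alligator_dataset()] for seeded, manifest-backed
#' output; calling directly uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return A list: `loci`, `individuals`, `alleles`, `founders` (genotype
#'   table of the founder base), `pedigree` (adult -> founder parents).
#' @export
generate_population <- function(config) {
  # locus panel
  n_ms <- config$n_microsat_loci
  ms_names <- sprintf("M%02d", seq_len(n_ms))
  motif <- sample(config$motif_lengths, n_ms, replace = TRUE)
  loci <- tibble::tibble(
    locus = c(ms_names, config$mhc_loci),
    type = c(rep("microsat", n_ms), rep("mhc", length(config$mhc_loci))),
    motif_length = c(motif, rep(NA_integer_, length(config$mhc_loci))))

  # allele catalogues + frequencies
  allele_sets <- list()
  for (i in seq_len(n_ms)) {
    k <- sample(config$allele_count_range[1]:config$allele_count_range[2], 1)
    base <- sample(100:260, 1)
    sizes <- base + motif[i] * (0:(k - 1))
    allele_sets[[ms_names[i]]] <- list(alleles = as.character(sizes),
                                       freqs = rdirichlet1(k))
  }
  mhc_allele_names <- list()
  alleles_cat <- list()
  for (loc in config$mhc_loci) {
    nm <- paste0(loc, "*0", 1:2)
    a1 <- random_coding(config$mhc_coding_length / 3)
    a2 <- diverge_coding(a1, config$mhc_target_p)
    alleles_cat[[loc]] <- tibble::tibble(locus = loc, allele = nm,
                                         dna = c(a1, a2))
    allele_sets[[loc]] <- list(alleles = nm, freqs = rdirichlet1(2))
    mhc_allele_names[[loc]] <- nm
  }
  alleles <- dplyr::bind_rows(alleles_cat)
  aa_of <- codon_aa()
  alleles$protein <- vapply(alleles$dna, function(d) {
    codons <- substring(d, seq(1, nchar(d) - 2, 3), seq(3, nchar(d), 3))
    paste(aa_of[codons], collapse = "")
  }, character(1), USE.NAMES = FALSE)

  # founders
  nf <- config$n_founders
  founder_ids <- sprintf("FD%02d", seq_len(nf))
  founders <- tibble::tibble(id = founder_ids, sex = NA_character_,
                             pond = "founder")
  fg <- list()
  for (loc in loci$locus) {
    set <- allele_sets[[loc]]
    copies <- draw_founder_copies(set$alleles, set$freqs, 2 * nf)
    fg[[loc]] <- matrix(copies, ncol = 2)
  }

  # adults: Mendelian children of two distinct random founders
  n_adults <- sum(config$ponds$n_females) + sum(config$ponds$n_males)
  p1 <- integer(n_adults); p2 <- integer(n_adults)
  for (i in seq_len(n_adults)) {
    pr <- sample(nf, 2, replace = FALSE)
    p1[i] <- pr[1]; p2[i] <- pr[2]
  }
  sexes <- unlist(lapply(seq_len(nrow(config$ponds)), function(p)
    c(rep("female", config$ponds$n_females[p]),
      rep("male", config$ponds$n_males[p]))))
  ponds <- unlist(lapply(seq_len(nrow(config$ponds)), function(p)
    rep(config$ponds$pond[p],
        config$ponds$n_females[p] + config$ponds$n_males[p])))
  ids <- character(n_adults)
  ids[sexes == "female"] <- sprintf("F%03d", seq_len(sum(sexes == "female")))
  ids[sexes == "male"] <- sprintf("M%03d", seq_len(sum(sexes == "male")))

  individuals <- tibble::tibble(id = ids, sex = sexes, pond = ponds)
  for (loc in loci$locus) {
    g <- fg[[loc]]
    a <- g[cbind(p1, sample(1:2, n_adults, replace = TRUE))]
    b <- g[cbind(p2, sample(1:2, n_adults, replace = TRUE))]
    is_ms <- loci$type[loci$locus == loc] == "microsat"
    cols <- locus_cols(loc)
    individuals[[cols[1]]] <- if (is_ms) as.integer(a) else a
    individuals[[cols[2]]] <- if (is_ms) as.integer(b) else b
  }

  founders_tbl <- founders
  for (loc in loci$locus) {
    cols <- locus_cols(loc)
    is_ms <- loci$type[loci$locus == loc] == "microsat"
    founders_tbl[[cols[1]]] <- if (is_ms) as.integer(fg[[loc]][, 1]) else
      fg[[loc]][, 1]
    founders_tbl[[cols[2]]] <- if (is_ms) as.integer(fg[[loc]][, 2]) else
      fg[[loc]][, 2]
  }

  list(loci = loci,
       individuals = validate_individuals(individuals, loci),
       alleles = alleles,
       founders = founders_tbl,
       pedigree = tibble::tibble(id = ids,
                                 parent1 = founder_ids[p1],
                                 parent2 = founder_ids[p2]))
}

# Mendelian offspring genotypes for one clutch, with optional mistyping.
clutch_offspring <- function(mother, father, loci, n, allele_pools,
                             noise_rate) {
  out <- list()
  for (loc in loci$locus) {
    cols <- locus_cols(loc)
    mg <- c(as.character(mother[[cols[1]]]), as.character(mother[[cols[2]]]))
    pg <- c(as.character(father[[cols[1]]]), as.character(father[[cols[2]]]))
    a <- mg[sample(1:2, n, replace = TRUE)]
    b <- pg[sample(1:2, n, replace = TRUE)]
    if (noise_rate > 0) {
      pool <- allele_pools[[loc]]
      for (v in c("a", "b")) {
        x <- get(v)
        flip <- which(stats::runif(n) < noise_rate)
        for (i in flip) {
          other <- setdiff(pool, x[i])
          if (length(other) > 0) x[i] <- sample(other, 1)
        }
        assign(v, x)
      }
    }
    out[[cols[1]]] <- a
    out[[cols[2]]] <- b
  }
  tibble::as_tibble(out)
}

#' Generate matings, clutches and offspring trios
#'
#' Each clutch draws a dam uniformly from all females (a female may breed
#' more than once); her sire is drawn from her own pond with probability
#' proportional to `exp(beta * het_male + gamma * func_dist(female, male))`
#' at the preference locus, so `beta = gamma = 0` is exactly uniform random
#' mating. Clutch sizes are Poisson; offspring genotypes are Mendelian,
#' optionally perturbed by a mistyping rate.
#'
#' Call within [simulate_alligator_dataset()] for seeded output.
#'
#' @param population Output of [generate_population()].
#' @param config The same [sim_config()].
#' @return A list: `clutches` (one row per clutch), `pairs` (unique
#'   female x male with summed offspring), `trios` (one row per offspring),
#'   `choice` (per-clutch realised choice probability of the chosen male).
#' @export
generate_matings <- function(population, config) {
  individuals <- population$individuals
  loci <- population$loci
  st <- preference_strengths(config)
  pref_locus <- config$preference_locus

  g <- geno_matrix(individuals, pref_locus)
  het <- as.numeric(g[, 1] != g[, 2])
  dm <- allele_distance_matrix(population$alleles, pref_locus,
                               kind = "functional")
  ga <- stats::setNames(g[, 1], individuals$id)
  gb <- stats::setNames(g[, 2], individuals$id)
  het_by_id <- stats::setNames(het, individuals$id)

  females <- individuals[individuals$sex == "female", ]
  # per-pond female x male choice-probability matrices
  pond_ids <- unique(females$pond)
  prob_mats <- lapply(stats::setNames(pond_ids, pond_ids), function(p) {
    f_ids <- females$id[females$pond == p]
    m_ids <- individuals$id[individuals$sex == "male" &
                              individuals$pond == p]
    grid_f <- rep(f_ids, times = length(m_ids))
    grid_m <- rep(m_ids, each = length(f_ids))
    fd <- pair_dist_vec(ga[grid_f], gb[grid_f], ga[grid_m], gb[grid_m], dm)
    w <- exp(st["beta"] * het_by_id[grid_m] + st["gamma"] * fd)
    w <- matrix(w, nrow = length(f_ids), dimnames = list(f_ids, m_ids))
    w / rowSums(w)
  })
  dam_idx <- sample(nrow(females), config$n_clutches, replace = TRUE)
  dam_id <- females$id[dam_idx]
  dam_pond <- females$pond[dam_idx]
  sire_id <- character(config$n_clutches)
  prob_chosen <- numeric(config$n_clutches)
  for (cl in seq_len(config$n_clutches)) {
    prob <- prob_mats[[dam_pond[cl]]][dam_id[cl], ]
    sire_i <- sample(length(prob), 1, prob = prob)
    sire_id[cl] <- names(prob)[sire_i]
    prob_chosen[cl] <- prob[sire_i]
  }
  n_off <- stats::rpois(config$n_clutches, config$lambda)
  clutch_ids <- sprintf("C%03d", seq_len(config$n_clutches))
  clutches <- tibble::tibble(clutch_id = clutch_ids, female_id = dam_id,
                             male_id = sire_id, pond = dam_pond,
                             n_offspring = n_off)
  choice_rows <- tibble::tibble(clutch_id = clutch_ids, female_id = dam_id,
                                male_id = sire_id,
                                prob_chosen = prob_chosen)
  pairs <- clutches |>
    dplyr::group_by(.data$female_id, .data$male_id, .data$pond) |>
    dplyr::summarise(n_offspring = sum(.data$n_offspring), .groups = "drop")

  trios <- tibble::tibble()
  if (config$make_offspring) {
    allele_pools <- lapply(stats::setNames(loci$locus, loci$locus),
                           function(loc) {
      g <- geno_matrix(individuals, loc)
      sort(unique(as.vector(g)))
    })
    trio_rows <- list()
    off_counter <- 0L
    for (cl in seq_len(nrow(clutches))) {
      n <- clutches$n_offspring[cl]
      if (n == 0) next
      mother <- individuals[individuals$id == clutches$female_id[cl], ]
      father <- individuals[individuals$id == clutches$male_id[cl], ]
      geno <- clutch_offspring(mother, father, loci, n, allele_pools,
                               config$noise_rate)
      trio_rows[[cl]] <- dplyr::bind_cols(
        tibble::tibble(
          offspring_id = sprintf("O%05d", off_counter + seq_len(n)),
          mother_id = clutches$female_id[cl],
          father_id = clutches$male_id[cl],
          clutch_id = clutches$clutch_id[cl]),
        geno)
      off_counter <- off_counter + n
    }
    trios <- dplyr::bind_rows(trio_rows)
  }

  list(clutches = clutches,
       pairs = validate_pairs(pairs, individuals),
       trios = trios,
       choice = choice_rows)
}

#' Simulate a complete colony dataset with ground truth
#'
#' Seeds the RNG from the config and runs [generate_population()] and
#' [generate_matings()], returning every table the analysis pipeline
#' consumes plus a ground-truth manifest (`truth`) sufficient to reproduce
#' the dataset from the config alone.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `loci`, `individuals`, `alleles`,
#'   `founders`, `pairs`, `clutches`, `trios`, `truth`.
#' @export
simulate_alligator_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    pop <- generate_population(config)
    mat <- generate_matings(pop, config)
    out <- list(loci = pop$loci,
                individuals = pop$individuals,
                alleles = pop$alleles,
                founders = pop$founders,
                pairs = mat$pairs,
                clutches = mat$clutches,
                trios = mat$trios,
                truth = list(config = config,
                             pedigree = pop$pedigree,
                             choice = mat$choice,
                             preference_strengths =
                               as.list(preference_strengths(config))))
    class(out) <- "sim_dataset"
    out
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic colony dataset\n")
  cat(sprintf("  adults: %d (%d F / %d M) in %d ponds\n",
              nrow(x$individuals), sum(x$individuals$sex == "female"),
              sum(x$individuals$sex == "male"),
              length(unique(x$individuals$pond))))
  cat(sprintf("  loci: %d microsat + %d MHC\n",
              sum(x$loci$type == "microsat"), sum(x$loci$type == "mhc")))
  cat(sprintf("  clutches: %d  unique pairs: %d  offspring: %d\n",
              nrow(x$clutches), nrow(x$pairs), nrow(x$trios)))
  cat(sprintf("  preference: %s\n", x$truth$config$preference))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `adults.tsv`, `alleles.fasta`, `pairs.tsv`, `clutches.tsv`,
#' `trios.tsv`, `loci.tsv` and `truth.json` into a directory.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_individuals(dataset$individuals, file.path(dir, "adults.tsv"))
  write_allele_fasta(dataset$alleles, file.path(dir, "alleles.fasta"))
  utils::write.table(dataset$loci, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$clutches, file.path(dir, "clutches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(dataset$trios) > 0) {
    tr <- as.data.frame(dataset$trios)
    utils::write.table(tr, file.path(dir, "trios.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth <- dataset$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
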