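#' Amino-acid distance between two aligned protein sequences
#'
#' Sequence divergence between two alleles of one locus, computed on their
#' translated exon fragments. `model = "p"` (default) is the proportion of
#' differing sites; `model = "poisson"` is the Poisson-corrected distance
#' `-log(1 - p)`. The sequences must already be the same length (alleles of
#' one locus amplified with the same primers are); no implicit alignment is
#' performed.
#'
#' @param protein1,protein2 Amino-acid strings of equal length.
#' @param model `"p"` or `"poisson"`.
#' @return A non-negative distance; `Inf` (with a warning) when the Poisson
#'   correction is applied at saturation (`p = 1`).
#' @export
aa_distance <- function(protein1, protein2, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (nchar(protein1) != nchar(protein2)) {
    stop("sequences differ in length (", nchar(protein1), " vs ",
         nchar(protein2), "); align alleles before computing distances",
         call. = FALSE)
  }
  if (nchar(protein1) == 0) stop("empty sequence", call. = FALSE)
  s1 <- strsplit(protein1, "")[[1]]
  s2 <- strsplit(protein2, "")[[1]]
  p <- mean(s1 != s2)
  if (model == "p") return(p)
  if (p >= 1) {
    warning("p-distance of 1: Poisson correction is infinite", call. = FALSE)
    return(Inf)
  }
  -log(1 - p)
}

#' z-descriptor functional distance between two aligned protein sequences
#'
#' At each aligned site, the Euclidean distance between the two residues'
#' five-dimensional z-descriptor vectors; the allele-level distance is the
#' mean over sites (default) or the raw sum (`normalize = FALSE`). The mean
#' puts loci with different exon lengths on one scale.
#'
#' @inheritParams aa_distance
#' @param ztable z-descriptor table, default [zscale_table()].
#' @param normalize Divide the site sum by the number of compared sites.
#' @param skip_ambiguous Skip sites where either residue is absent from
#'   `ztable` (excluded from the denominator too); if `FALSE` (default) an
#'   unknown residue is an error naming the position.
#' @return A non-negative distance.
#' @export
functional_distance <- function(protein1, protein2, ztable = zscale_table(),
                                normalize = TRUE, skip_ambiguous = FALSE) {
  if (nchar(protein1) != nchar(protein2)) {
    stop("sequences differ in length", call. = FALSE)
  }
  zm <- zscale_matrix(ztable)
  s1 <- strsplit(protein1, "")[[1]]
  s2 <- strsplit(protein2, "")[[1]]
  known <- s1 %in% rownames(zm) & s2 %in% rownames(zm)
  if (!all(known)) {
    if (!skip_ambiguous) {
      pos <- which(!known)[1]
      stop(sprintf("residue without z-descriptors at position %d ('%s'/'%s')",
                   pos, s1[pos], s2[pos]), call. = FALSE)
    }
    s1 <- s1[known]
    s2 <- s2[known]
  }
  if (length(s1) == 0) stop("no comparable sites", call. = FALSE)
  d <- sqrt(rowSums((zm[s1, , drop = FALSE] - zm[s2, , drop = FALSE])^2))
  if (normalize) mean(d) else sum(d)
}

#' Pairwise distance matrix between the alleles of one locus
#'
#' @param alleles Allele catalogue as from [read_allele_fasta()].
#' @param locus Locus id.
#' @param kind `"aa"` for sequence distance, `"functional"` for z-descriptor
#'   distance.
#' @param model Substitution model for `kind = "aa"` (see [aa_distance()]).
#' @param ztable,normalize Passed to [functional_distance()].
#' @return A symmetric, zero-diagonal matrix with allele names as dimnames
#'   and attributes `locus`, `kind`, `model`.
#' @export
allele_distance_matrix <- function(alleles, locus,
                                   kind = c("aa", "functional"),
                                   model = c("p", "poisson"),
                                   ztable = zscale_table(), normalize = TRUE) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  cat <- alleles[alleles$locus == locus, ]
  if (nrow(cat) == 0) stop("no alleles catalogued for locus ", locus,
                           call. = FALSE)
  k <- nrow(cat)
  m <- matrix(0, k, k, dimnames = list(cat$allele, cat$allele))
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        d <- if (kind == "aa") {
          aa_distance(cat$protein[i], cat$protein[j], model = model)
        } else {
          functional_distance(cat$protein[i], cat$protein[j],
                              ztable = ztable, normalize = normalize)
        }
        m[i, j] <- m[j, i] <- d
      }
    }
  }
  attr(m, "locus") <- locus
  attr(m, "kind") <- kind
  attr(m, "model") <- if (kind == "aa") model else "euclidean-z"
  m
}

#' Pair-level MHC distance (four-term sum)
#'
#' The compatibility distance between a female and a male at one MHC locus:
#' the sum of the four distances between each female allele copy and each
#' male allele copy, `D(A,B) + D(A,b) + D(a,B) + D(a,b)`. Symmetric in the
#' two partners; zero exactly when every female copy is distance zero from
#' every male copy (e.g. both homozygous for one allele).
#'
#' @param female,male Length-2 character vectors of allele names.
#' @param dist_matrix Matrix from [allele_distance_matrix()].
#' @return A non-negative scalar.
#' @export
pair_mhc_distance <- function(female, male, dist_matrix) {
  stopifnot(length(female) == 2, length(male) == 2)
  missing_alleles <- setdiff(c(female, male), rownames(dist_matrix))
  if (length(missing_alleles) > 0) {
    stop("allele(s) absent from distance matrix: ",
         paste(missing_alleles, collapse = ", "), call. = FALSE)
  }
  sum(dist_matrix[female, male])
}

#' Allele sharing between two diploid genotypes
#'
#' The number of allele copies shared between the two genotypes at one
#' locus, counted as a maximum matching (each copy matched at most once):
#' 0, 1 or 2.
#'
#' @param female,male Length-2 character vectors of allele names.
#' @return An integer in `{0, 1, 2}`.
#' @export
allele_sharing <- function(female, male) {
  stopifnot(length(female) == 2, length(male) == 2)
  shared <- 0L
  pool <- male
  for (a in female) {
    hit <- match(a, pool)
    if (!is.na(hit)) {
      shared <- shared + 1L
      pool <- pool[-hit]
    }
  }
  shared
}

#' Pair compatibility table for a set of mating pairs
#'
#' Per pair and per MHC locus: allele sharing (`nsa`), amino-acid distance
#' (`aa_dist`) and z-descriptor functional distance (`aa_func_dist`), each
#' the four-term inter-partner sum of [pair_mhc_distance()].
#'
#' @param pairs Mating-pair tibble (`female_id`, `male_id`, ...).
#' @param individuals Adult genotype table.
#' @param loci Locus metadata; only `type == "mhc"` loci are used.
#' @param alleles Allele catalogue with translated proteins.
#' @param model Amino-acid distance model.
#' @param ztable,normalize Functional-distance options.
#' @return A tibble with one row per pair x MHC locus.
#' @export
pair_compatibility <- function(pairs, individuals, loci, alleles,
                               model = c("p", "poisson"),
                               ztable = zscale_table(), normalize = TRUE) {
  loci <- validate_loci(loci)
  model <- match.arg(model)
  mhc <- loci$locus[loci$type == "mhc"]
  idx <- match(pairs$female_id, individuals$id)
  jdx <- match(pairs$male_id, individuals$id)
  purrr::map_dfr(mhc, function(loc) {
    g <- geno_matrix(individuals, loc)
    da <- allele_distance_matrix(alleles, loc, kind = "aa", model = model)
    df <- allele_distance_matrix(alleles, loc, kind = "functional",
                                 ztable = ztable, normalize = normalize)
    purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
      f <- g[idx[r], ]
      m <- g[jdx[r], ]
      if (anyNA(f) || anyNA(m)) {
        return(tibble::tibble(female_id = pairs$female_id[r],
                              male_id = pairs$male_id[r], locus = loc,
                              nsa = NA_integer_, aa_dist = NA_real_,
                              aa_func_dist = NA_real_))
      }
      tibble::tibble(female_id = pairs$female_id[r],
                     male_id = pairs$male_id[r], locus = loc,
                     nsa = allele_sharing(f, m),
                     aa_dist = pair_mhc_distance(f, m, da),
                     aa_func_dist = pair_mhc_distance(f, m, df))
    })
  })
}
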