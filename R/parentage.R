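# Mendelian-consistency audit of assigned offspring trios. Likelihood-based
# parentage assignment is out of scope; this module only checks that an
# assigned mother-father-offspring trio can be explained by Mendelian
# inheritance at the audited loci, with an allowed mismatch budget standing
# in for genotyping error.

# One locus is consistent iff the offspring's two alleles can be split
# one-from-mother, one-from-father, trying both assignments.
locus_mendel_ok <- function(off, mother, father) {
  (off[1] %in% mother & off[2] %in% father) ||
    (off[2] %in% mother & off[1] %in% father)
}

#' Mendelian consistency of one trio
#'
#' @param offspring,mother,father Named lists or one-row data frames holding
#'   `<locus>_a` / `<locus>_b` genotype columns.
#' @param loci Character vector of locus ids to audit.
#' @param max_mismatch Maximum number of mismatching loci tolerated (default
#'   0, the strict rule used for the two MHC loci; a small positive budget
#'   accommodates the ~1% mistyping rate of a microsatellite panel).
#' @return A list: `consistent` (logical), `mismatching_loci` (character),
#'   `skipped_loci` (character; loci with a missing genotype are reported,
#'   never counted as mismatches).
#' @export
trio_consistent <- function(offspring, mother, father, loci,
                            max_mismatch = 0L) {
  mism <- character(0)
  skip <- character(0)
  for (loc in loci) {
    cols <- locus_cols(loc)
    o <- as.character(c(offspring[[cols[1]]], offspring[[cols[2]]]))
    m <- as.character(c(mother[[cols[1]]], mother[[cols[2]]]))
    f <- as.character(c(father[[cols[1]]], father[[cols[2]]]))
    if (anyNA(o) || anyNA(m) || anyNA(f) ||
        length(o) < 2 || length(m) < 2 || length(f) < 2) {
      skip <- c(skip, loc)
      next
    }
    if (!locus_mendel_ok(o, m, f)) mism <- c(mism, loc)
  }
  list(consistent = length(mism) <= max_mismatch,
       mismatching_loci = mism,
       skipped_loci = skip)
}

#' Audit a trio table for Mendelian consistency
#'
#' Looks up parental genotypes in the adult table and applies
#' [trio_consistent()] to every offspring row.
#'
#' @param trios Trio tibble from [read_trios()] (offspring genotypes inline,
#'   parent ids referencing `individuals`).
#' @param individuals Adult genotype table.
#' @param loci Character vector of locus ids to audit (e.g. the MHC loci).
#' @param max_mismatch Mismatch budget per trio; see [trio_consistent()].
#' @return A tibble with one row per trio: `offspring_id`, `mother_id`,
#'   `father_id`, `n_checked`, `n_mismatch`, `n_skipped`,
#'   `mismatching_loci` (comma-joined), `consistent`.
#' @export
audit_trios <- function(trios, individuals, loci, max_mismatch = 0L) {
  if (nrow(trios) == 0) {
    return(tibble::tibble(offspring_id = character(0),
                          mother_id = character(0),
                          father_id = character(0),
                          n_checked = integer(0), n_mismatch = integer(0),
                          n_skipped = integer(0),
                          mismatching_loci = character(0),
                          consistent = logical(0)))
  }
  assert_ids_exist(trios$mother_id, individuals, "mother")
  assert_ids_exist(trios$father_id, individuals, "father")
  mi <- match(trios$mother_id, individuals$id)
  fi <- match(trios$father_id, individuals$id)
  purrr::map_dfr(seq_len(nrow(trios)), function(r) {
    res <- trio_consistent(trios[r, ], individuals[mi[r], ],
                           individuals[fi[r], ], loci,
                           max_mismatch = max_mismatch)
    tibble::tibble(offspring_id = trios$offspring_id[r],
                   mother_id = trios$mother_id[r],
                   father_id = trios$father_id[r],
                   n_checked = length(loci) - length(res$skipped_loci),
                   n_mismatch = length(res$mismatching_loci),
                   n_skipped = length(res$skipped_loci),
                   mismatching_loci = paste(res$mismatching_loci,
                                            collapse = ","),
                   consistent = res$consistent)
  })
}

#' Summarise a parentage audit
#'
#' @param audit Output of [audit_trios()].
#' @return A one-row tibble: `n_trios`, `n_consistent`, `pass_rate`, and
#'   `n_locus_mismatches` (total mismatching locus calls).
#' @export
glance_audit <- function(audit) {
  tibble::tibble(n_trios = nrow(audit),
                 n_consistent = sum(audit$consistent),
                 pass_rate = if (nrow(audit) == 0) NA_real_ else
                   mean(audit$consistent),
                 n_locus_mismatches = sum(audit$n_mismatch))
}
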