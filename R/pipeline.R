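#' Run the full mate-choice analysis pipeline
#'
#' Orchestrates the analysis stages in their reporting order: Mendelian
#' parentage audit (when trios are supplied), the randomisation hypothesis
#' suite (good-gene, heterozygosity-advantage, compatible-gene and
#' relatedness statistics), and the reproductive-success model (when
#' clutches are supplied). Deterministic given the inputs and `seed`; when
#' `out_dir` is given, every result table is written as TSV together with a
#' JSON run manifest recording inputs, options, seed and package version.
#'
#' @param individuals Adult genotype table.
#' @param loci Locus metadata table.
#' @param pairs Mating-pair tibble.
#' @param alleles MHC allele catalogue.
#' @param clutches Optional clutch tibble (`male_id`, `n_offspring`) for the
#'   reproductive-success model; defaults to `pairs` treated as one clutch
#'   per row when `NULL`.
#' @param trios Optional offspring trio tibble for the Mendelian audit.
#' @param n_iter Monte-Carlo replicates for the hypothesis suite.
#' @param seed Master seed.
#' @param glmm_locus MHC locus for the zygosity coding (`NULL` = first MHC
#'   locus).
#' @param max_mismatch Mismatch budget of the Mendelian audit.
#' @param out_dir Optional output directory.
#' @return A list of class `mate_choice_report`: `suite`, `glmm` (a
#'   `repro_fit` or `NULL`), `parentage` (audit tibble or `NULL`),
#'   `parentage_summary`, `manifest`.
#' @export
run_mate_choice_pipeline <- function(individuals, loci, pairs, alleles,
                                     clutches = NULL, trios = NULL,
                                     n_iter = 9999, seed = 1,
                                     glmm_locus = NULL, max_mismatch = 0L,
                                     out_dir = NULL) {
  loci <- validate_loci(loci)
  pairs <- validate_pairs(pairs, individuals)
  mhc <- loci$locus[loci$type == "mhc"]

  parentage <- parentage_summary <- NULL
  if (!is.null(trios) && nrow(trios) > 0) {
    parentage <- audit_trios(trios, individuals, mhc,
                             max_mismatch = max_mismatch)
    parentage_summary <- glance_audit(parentage)
  }

  suite <- run_mate_choice_suite(individuals, loci, pairs, alleles,
                                 n_iter = n_iter, seed = seed)

  glmm <- NULL
  clutch_src <- clutches %||% pairs
  ct <- clutch_table(clutch_src, individuals, loci,
                     locus = glmm_locus %||% mhc[1])
  glmm <- tryCatch(fit_reproductive_success(ct),
                   error = function(e) {
                     warning("reproductive-success model not fitted: ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })

  manifest <- list(
    package = "mhcmate",
    version = as.character(utils::packageVersion("mhcmate")),
    seed = seed,
    n_iter = n_iter,
    n_individuals = nrow(individuals),
    n_pairs = nrow(pairs),
    n_trios = if (is.null(trios)) 0L else nrow(trios),
    loci = loci$locus,
    glmm_locus = glmm_locus %||% mhc[1],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  report <- list(suite = suite, glmm = glmm, parentage = parentage,
                 parentage_summary = parentage_summary, manifest = manifest)
  class(report) <- "mate_choice_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    suite_flat <- dplyr::select(suite, -"null")
    utils::write.table(suite_flat, file.path(out_dir, "hypothesis_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(parentage)) {
      utils::write.table(parentage, file.path(out_dir, "parentage_audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(glmm)) {
      utils::write.table(as.data.frame(tidy(glmm)),
                         file.path(out_dir, "glmm_coefficients.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' @export
print.mate_choice_report <- function(x, ...) {
  cat("Mate-choice analysis report\n")
  if (!is.null(x$parentage_summary)) {
    cat(sprintf("  parentage audit: %d/%d trios Mendelian-consistent\n",
                x$parentage_summary$n_consistent,
                x$parentage_summary$n_trios))
  }
  cat(sprintf("  hypothesis tests (%d Monte-Carlo replicates):\n",
              x$suite$n_iter[1]))
  for (i in seq_len(nrow(x$suite))) {
    r <- x$suite[i, ]
    cat(sprintf("    %-12s %-9s obs = %8.4f  p = %.4f  CI [%.4f, %.4f]%s\n",
                r$statistic, ifelse(is.na(r$locus), "", r$locus),
                r$observed, r$p_value, r$ci_lower, r$ci_upper,
                ifelse(r$significant, "  *", "")))
  }
  if (!is.null(x$glmm)) {
    cat(sprintf("  reproductive success: beta_zyg = %.4f (Wald p = %.4f), sigma_u = %.4f\n",
                x$glmm$beta_zyg, x$glmm$wald_p, x$glmm$sigma_u))
  }
  invisible(x)
}
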