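#' Male MHC zygosity labels
#'
#' Binary zygosity coding for the reproductive-success model: 1 if the male
#' is heterozygous, 0 if homozygous. With `locus = NULL` a male counts as
#' heterozygous when heterozygous at one or more MHC loci; the per-locus
#' coding (the default analysis runs one locus at a time) is obtained by
#' naming the locus.
#'
#' @param individuals Adult genotype table.
#' @param loci Locus metadata table.
#' @param locus One MHC locus id, or `NULL` for the any-locus coding.
#' @return A tibble `id`, `zygosity` (0/1 integer, `NA` when untyped).
#' @export
male_zygosity <- function(individuals, loci, locus = NULL) {
  loci <- validate_loci(loci)
  mhc <- loci$locus[loci$type == "mhc"]
  use <- if (is.null(locus)) mhc else locus
  if (!all(use %in% mhc)) {
    stop("not an MHC locus: ", setdiff(use, mhc)[1], call. = FALSE)
  }
  het <- sapply(use, function(loc) {
    g <- geno_matrix(individuals, loc)
    ifelse(is.na(g[, 1]) | is.na(g[, 2]), NA, g[, 1] != g[, 2])
  })
  het <- matrix(het, nrow = nrow(individuals))
  z <- apply(het, 1, function(h) {
    if (all(is.na(h))) NA_integer_ else as.integer(any(h, na.rm = TRUE))
  })
  tibble::tibble(id = individuals$id, zygosity = z)
}

#' Clutch table for the reproductive-success model
#'
#' One row per clutch: sire id, his zygosity at the chosen MHC locus, and
#' the clutch's offspring count (the response).
#'
#' @param clutches A tibble with columns `male_id` and `n_offspring` (one
#'   row per clutch; a pair table works when each row is one clutch).
#' @param individuals Adult genotype table.
#' @param loci Locus metadata table.
#' @param locus MHC locus for the zygosity coding (`NULL` = any-locus).
#' @return A tibble `male_id`, `zygosity`, `n_offspring` with untyped males
#'   dropped.
#' @export
clutch_table <- function(clutches, individuals, loci, locus = NULL) {
  z <- male_zygosity(individuals, loci, locus)
  out <- tibble::tibble(male_id = clutches$male_id,
                        n_offspring = clutches$n_offspring) |>
    dplyr::left_join(z, by = c(male_id = "id")) |>
    dplyr::select("male_id", "zygosity", "n_offspring")
  dplyr::filter(out, !is.na(.data$zygosity))
}

#' Poisson random-intercept model of male reproductive success
#'
#' Fits `n_offspring ~ zygosity + (1 | male_id)` with a Poisson response
#' and log link: the fixed effect is the log rate ratio of clutch size for
#' MHC-heterozygous versus MHC-homozygous sires, and the per-male random
#' intercept absorbs repeated clutches of the same male. The marginal
#' likelihood is maximised with the Laplace approximation by default
#' (adaptive Gauss-Hermite quadrature via `nAGQ > 1`). With
#' `random_intercept = FALSE` the model collapses to a plain Poisson GLM
#' (the nested sigma_u = 0 fit).
#'
#' @param clutches A [clutch_table()] tibble (`male_id`, `zygosity`,
#'   `n_offspring`).
#' @param random_intercept Include the per-male random intercept.
#' @param nAGQ Number of quadrature points (1 = Laplace).
#' @return An object of class `repro_fit`: a list with the fitted model
#'   (`fit`), `beta0`, `beta_zyg`, `se_beta_zyg`, `wald_p`, `sigma_u`,
#'   `n_clutches`, `n_males`, `converged`, `logLik`.
#' @export
fit_reproductive_success <- function(clutches, random_intercept = TRUE,
                                     nAGQ = 1L) {
  clutches <- dplyr::filter(tibble::as_tibble(clutches),
                            !is.na(.data$zygosity), !is.na(.data$n_offspring))
  if (any(clutches$n_offspring < 0)) {
    stop("negative offspring count", call. = FALSE)
  }
  n_males_class <- clutches |>
    dplyr::distinct(.data$male_id, .data$zygosity) |>
    dplyr::count(.data$zygosity)
  if (nrow(n_males_class) < 2 || any(n_males_class$n < 2)) {
    stop("need at least two males in each zygosity class", call. = FALSE)
  }
  by_class <- clutches |>
    dplyr::group_by(.data$zygosity) |>
    dplyr::summarise(total = sum(.data$n_offspring), .groups = "drop")
  if (any(by_class$total == 0)) {
    stop("complete separation: one zygosity class has only zero counts",
         call. = FALSE)
  }
  # a constant response pins every parameter; the mixed fit is degenerate
  # (sigma_u = 0) and is handled by the plain GLM path
  if (random_intercept && stats::var(clutches$n_offspring) == 0) {
    random_intercept <- FALSE
  }
  if (random_intercept) {
    fit <- lme4::glmer(n_offspring ~ zygosity + (1 | male_id),
                       data = clutches, family = stats::poisson("log"),
                       nAGQ = nAGQ)
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    sigma_u <- sqrt(unname(lme4::VarCorr(fit)$male_id[1, 1]))
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  } else {
    fit <- stats::glm(n_offspring ~ zygosity, data = clutches,
                      family = stats::poisson("log"),
                      control = stats::glm.control(epsilon = 1e-12,
                                                   maxit = 100))
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    sigma_u <- 0
    conv <- fit$converged
  }
  z <- beta[["zygosity"]] / se[["zygosity"]]
  out <- list(fit = fit,
              beta0 = unname(beta[["(Intercept)"]]),
              beta_zyg = unname(beta[["zygosity"]]),
              se_beta_zyg = unname(se[["zygosity"]]),
              wald_p = 2 * stats::pnorm(-abs(z)),
              sigma_u = sigma_u,
              n_clutches = nrow(clutches),
              n_males = length(unique(clutches$male_id)),
              converged = conv,
              logLik = as.numeric(stats::logLik(fit)),
              random_intercept = random_intercept,
              data = clutches)
  class(out) <- "repro_fit"
  out
}

#' @export
print.repro_fit <- function(x, ...) {
  cat("Poisson reproductive-success model",
      if (x$random_intercept) "(random intercept per male)" else
        "(no random intercept)", "\n")
  cat(sprintf("  clutches: %d   males: %d   converged: %s\n",
              x$n_clutches, x$n_males, x$converged))
  cat(sprintf("  beta0 = %.4f   beta_zyg = %.4f (SE %.4f, Wald p = %.4f)\n",
              x$beta0, x$beta_zyg, x$se_beta_zyg, x$wald_p))
  cat(sprintf("  sigma_u = %.4f\n", x$sigma_u))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.repro_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "zygosity"),
    estimate = c(x$beta0, x$beta_zyg),
    std.error = c(sqrt(diag(as.matrix(stats::vcov(x$fit))))[1],
                  x$se_beta_zyg),
    p.value = c(NA_real_, x$wald_p))
}

#' @export
glance.repro_fit <- function(x, ...) {
  tibble::tibble(sigma_u = x$sigma_u, logLik = x$logLik,
                 n_clutches = x$n_clutches, n_males = x$n_males,
                 converged = x$converged)
}

#' Cluster bootstrap band for the fitted zygosity effect
#'
#' Case-resamples males (whole clusters of clutches) with replacement,
#' refits the model, and returns percentile bands for the predicted clutch
#' size of each zygosity class on the response scale.
#'
#' @param clutches A [clutch_table()] tibble.
#' @param n_boot Number of bootstrap resamples (study convention: 10000).
#' @param seed Seed for the resampling stream.
#' @param random_intercept Passed to [fit_reproductive_success()].
#' @return A tibble per zygosity class: point prediction `fitted`,
#'   `ci_lower`, `ci_upper` (2.5/97.5 percentiles over resamples), and the
#'   number of resamples that produced a usable refit.
#' @export
bootstrap_reproductive_ci <- function(clutches, n_boot = 10000, seed = 1,
                                      random_intercept = TRUE) {
  clutches <- tibble::as_tibble(clutches)
  base_fit <- fit_reproductive_success(clutches,
                                       random_intercept = random_intercept)
  males <- clutches |>
    dplyr::distinct(.data$male_id, .keep_all = FALSE)
  by_male <- split(clutches, clutches$male_id)
  preds <- with_local_seed(seed, {
    draws <- matrix(sample(males$male_id, n_boot * nrow(males),
                           replace = TRUE), nrow = n_boot)
    t(apply(draws, 1, function(ids) {
      boot <- dplyr::bind_rows(lapply(seq_along(ids), function(j) {
        d <- by_male[[ids[j]]]
        d$male_id <- paste0(d$male_id, "#", j)  # resampled clusters stay distinct
        d
      }))
      est <- tryCatch({
        f <- suppressMessages(fit_reproductive_success(
          boot, random_intercept = random_intercept))
        c(exp(f$beta0), exp(f$beta0 + f$beta_zyg))
      }, error = function(e) c(NA_real_, NA_real_))
      est
    }))
  })
  fitted <- c(exp(base_fit$beta0), exp(base_fit$beta0 + base_fit$beta_zyg))
  tibble::tibble(
    zygosity = c(0L, 1L),
    fitted = fitted,
    ci_lower = apply(preds, 2, stats::quantile, probs = 0.025,
                     na.rm = TRUE),
    ci_upper = apply(preds, 2, stats::quantile, probs = 0.975,
                     na.rm = TRUE),
    n_boot_used = colSums(!is.na(preds)))
}
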