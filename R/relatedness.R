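# Pairwise relatedness estimators: Queller-Goodnight (primary), Wang (2002)
# and Lynch-Ritland (1999). All three are moment estimators built on
# reference-population allele frequencies; by default the reference includes
# the focal dyad (no leave-two-out correction). Loci untyped in either
# member, or monomorphic in the reference, are dropped pairwise.

# Per-locus Queller-Goodnight components for vectors of dyads.
# a,b = focal genotype; c,d = partner genotype; p = named frequency vector.
qg_locus_components <- function(a, b, c, d, p) {
  pa <- unname(p[a]); pb <- unname(p[b])
  iac <- as.numeric(a == c); iad <- as.numeric(a == d)
  ibc <- as.numeric(b == c); ibd <- as.numeric(b == d)
  iab <- as.numeric(a == b)
  list(num = 0.5 * (iac + iad + ibc + ibd) - pa - pb,
       den = 1 + iab - pa - pb)
}

# Queller-Goodnight relatedness for dyad vectors at one locus panel.
# gx, gy: lists (by locus) of 2-column genotype matrices aligned to dyads.
qg_relatedness <- function(gx, gy, fl, loci_use) {
  n <- nrow(gx[[loci_use[1]]])
  num_x <- den_x <- num_y <- den_y <- numeric(n)
  n_used <- integer(n)
  for (loc in loci_use) {
    p <- fl[[loc]]
    if (length(p) < 2) next  # monomorphic reference locus carries no signal
    a <- gx[[loc]][, 1]; b <- gx[[loc]][, 2]
    c <- gy[[loc]][, 1]; d <- gy[[loc]][, 2]
    ok <- !is.na(a) & !is.na(b) & !is.na(c) & !is.na(d)
    if (!any(ok)) next
    cx <- qg_locus_components(a[ok], b[ok], c[ok], d[ok], p)
    cy <- qg_locus_components(c[ok], d[ok], a[ok], b[ok], p)
    num_x[ok] <- num_x[ok] + cx$num; den_x[ok] <- den_x[ok] + cx$den
    num_y[ok] <- num_y[ok] + cy$num; den_y[ok] <- den_y[ok] + cy$den
    n_used[ok] <- n_used[ok] + 1L
  }
  r <- ifelse(n_used == 0 | abs(den_x) < 1e-12 | abs(den_y) < 1e-12,
              NA_real_,
              0.5 * (num_x / den_x + num_y / den_y))
  list(r = r, n_loci = n_used)
}

# Wang (2002) joint-genotype-category moment estimator.
# Categories of a genotype pair at one locus:
#   1 identical genotypes; 2 one homozygote sharing an allele with the other
#   genotype; 3 two heterozygotes sharing exactly one allele; 4 no sharing.
# With a2, a3, a4 the frequency power sums, the category probabilities are
# linear in the one- and two-pair IBD coefficients (phi, Delta):
#   P1 = b + c*phi + (1-b)*Delta,  P2 = d + e*phi - d*Delta,
#   P3 = f + g*phi - f*Delta
# where b = 2a2^2-a4, c = a2-b, d = 4(a3-a4), e = 2(a2-3a3+2a4),
# f = 4(a2-a2^2-2a3+2a4), g = 1-7a2+4a2^2+10a3-8a4. The three equations are
# solved for (phi, Delta) by least squares after 1/u weighting across loci
# (u = 2a2 - a3), and r = phi/2 + Delta.
wang_relatedness <- function(gx, gy, fl, loci_use) {
  n <- nrow(gx[[loci_use[1]]])
  r <- rep(NA_real_, n)
  n_used <- integer(n)
  coefs <- lapply(loci_use, function(loc) {
    p <- fl[[loc]]
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
    list(b = 2 * a2^2 - a4,
         c = a2 - 2 * a2^2 + a4,
         d = 4 * (a3 - a4),
         e = 2 * (a2 - 3 * a3 + 2 * a4),
         f = 4 * (a2 - a2^2 - 2 * a3 + 2 * a4),
         g = 1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4,
         u = 2 * a2 - a3,
         k = length(p))
  })
  names(coefs) <- loci_use
  cat_of <- function(a, b, c, d) {
    ident <- (a == c & b == d) | (a == d & b == c)
    shared <- (a == c) | (a == d) | (b == c) | (b == d)
    hom <- (a == b) | (c == d)
    ifelse(ident, 1L, ifelse(shared & hom, 2L, ifelse(shared, 3L, 4L)))
  }
  # accumulate weighted indicator and coefficient sums per dyad
  sw <- numeric(n)
  sP <- matrix(0, n, 3)
  sb <- sc <- sd_ <- se <- sf <- sg <- numeric(n)
  for (loc in loci_use) {
    co <- coefs[[loc]]
    if (co$k < 2) next
    a <- gx[[loc]][, 1]; b <- gx[[loc]][, 2]
    c <- gy[[loc]][, 1]; d <- gy[[loc]][, 2]
    ok <- !is.na(a) & !is.na(b) & !is.na(c) & !is.na(d)
    if (!any(ok)) next
    w <- 1 / co$u
    cat <- cat_of(a[ok], b[ok], c[ok], d[ok])
    sP[ok, 1] <- sP[ok, 1] + w * (cat == 1L)
    sP[ok, 2] <- sP[ok, 2] + w * (cat == 2L)
    sP[ok, 3] <- sP[ok, 3] + w * (cat == 3L)
    sw[ok] <- sw[ok] + w
    sb[ok] <- sb[ok] + w * co$b; sc[ok] <- sc[ok] + w * co$c
    sd_[ok] <- sd_[ok] + w * co$d; se[ok] <- se[ok] + w * co$e
    sf[ok] <- sf[ok] + w * co$f; sg[ok] <- sg[ok] + w * co$g
    n_used[ok] <- n_used[ok] + 1L
  }
  for (i in seq_len(n)) {
    if (n_used[i] == 0 || sw[i] <= 0) next
    P <- sP[i, ] / sw[i]
    b <- sb[i] / sw[i]; cc <- sc[i] / sw[i]; d <- sd_[i] / sw[i]
    e <- se[i] / sw[i]; f <- sf[i] / sw[i]; g <- sg[i] / sw[i]
    A <- rbind(c(cc, 1 - b), c(e, -d), c(g, -f))
    y <- c(P[1] - b, P[2] - d, P[3] - f)
    sol <- tryCatch(stats::lm.fit(A, y)$coefficients, error = function(e) NULL)
    if (is.null(sol) || anyNA(sol)) next
    r[i] <- sol[1] / 2 + sol[2]
  }
  list(r = r, n_loci = n_used)
}

# Lynch & Ritland (1999) regression estimator with the source's locus
# weights, symmetrised over the choice of focal individual.
lr_one_direction <- function(gx, gy, fl, loci_use) {
  n <- nrow(gx[[loci_use[1]]])
  num <- den <- numeric(n)
  n_used <- integer(n)
  for (loc in loci_use) {
    p <- fl[[loc]]
    if (length(p) < 2) next
    a <- gx[[loc]][, 1]; b <- gx[[loc]][, 2]
    c <- gy[[loc]][, 1]; d <- gy[[loc]][, 2]
    ok <- !is.na(a) & !is.na(b) & !is.na(c) & !is.na(d)
    if (!any(ok)) next
    pa <- unname(p[a[ok]]); pb <- unname(p[b[ok]])
    sac <- as.numeric(a[ok] == c[ok]); sad <- as.numeric(a[ok] == d[ok])
    sbc <- as.numeric(b[ok] == c[ok]); sbd <- as.numeric(b[ok] == d[ok])
    sab <- as.numeric(a[ok] == b[ok])
    loc_num <- pa * (sbc + sbd) + pb * (sac + sad) - 4 * pa * pb
    loc_den <- (1 + sab) * (pa + pb) - 4 * pa * pb
    w <- loc_den / (2 * pa * pb)
    r_l <- loc_num / loc_den
    usable <- is.finite(w) & is.finite(r_l)
    oki <- which(ok)[usable]
    num[oki] <- num[oki] + (w * r_l)[usable]
    den[oki] <- den[oki] + w[usable]
    n_used[oki] <- n_used[oki] + 1L
  }
  list(r = ifelse(n_used == 0 | abs(den) < 1e-12, NA_real_, num / den),
       n_loci = n_used)
}

lr_relatedness <- function(gx, gy, fl, loci_use) {
  fx <- lr_one_direction(gx, gy, fl, loci_use)
  fy <- lr_one_direction(gy, gx, fl, loci_use)
  list(r = (fx$r + fy$r) / 2, n_loci = pmax(fx$n_loci, fy$n_loci))
}

#' Pairwise relatedness for a table of dyads
#'
#' Moment estimators of pairwise relatedness from microsatellite genotypes
#' and reference allele frequencies: Queller-Goodnight (`r_qg`, the primary
#' estimator), Wang 2002 (`r_wang`) and Lynch-Ritland 1999 (`r_lr`). All
#' estimators are symmetrised over the choice of focal individual, so
#' `r(x, y) = r(y, x)`. Estimates are `NA` when no informative locus is
#' shared.
#'
#' @param dyads A tibble whose first two columns are the two individual ids
#'   (e.g. `female_id`, `male_id` of a pair table).
#' @param individuals Adult genotype table.
#' @param loci Locus metadata; only `type == "microsat"` loci are used.
#' @param freqs Optional precomputed [allele_frequencies()] of the reference
#'   population (default: all of `individuals`).
#' @param estimators Subset of `c("qg", "wang", "lr")`.
#' @return The dyad tibble with `r_qg` / `r_wang` / `r_lr` and `n_loci_used`
#'   appended.
#' @export
pairwise_relatedness <- function(dyads, individuals, loci, freqs = NULL,
                                 estimators = c("qg", "wang", "lr")) {
  loci <- validate_loci(loci)
  estimators <- match.arg(estimators, several.ok = TRUE)
  ms <- loci$locus[loci$type == "microsat"]
  if (length(ms) == 0) stop("no microsatellite loci in panel", call. = FALSE)
  if (is.null(freqs)) {
    freqs <- allele_frequencies(individuals, loci[loci$type == "microsat", ])
  }
  fl <- freq_list(freqs)
  id1 <- dyads[[1]]; id2 <- dyads[[2]]
  assert_ids_exist(id1, individuals, "dyad member")
  assert_ids_exist(id2, individuals, "dyad member")
  i1 <- match(id1, individuals$id); i2 <- match(id2, individuals$id)
  gx <- gy <- list()
  for (loc in ms) {
    g <- geno_matrix(individuals, loc)
    gx[[loc]] <- g[i1, , drop = FALSE]
    gy[[loc]] <- g[i2, , drop = FALSE]
  }
  out <- tibble::as_tibble(dyads)
  n_loci <- NULL
  if ("qg" %in% estimators) {
    res <- qg_relatedness(gx, gy, fl, ms)
    out$r_qg <- res$r; n_loci <- res$n_loci
  }
  if ("wang" %in% estimators) {
    res <- wang_relatedness(gx, gy, fl, ms)
    out$r_wang <- res$r; n_loci <- n_loci %||% res$n_loci
  }
  if ("lr" %in% estimators) {
    res <- lr_relatedness(gx, gy, fl, ms)
    out$r_lr <- res$r; n_loci <- n_loci %||% res$n_loci
  }
  out$n_loci_used <- n_loci
  out
}
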