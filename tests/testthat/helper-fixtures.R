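# Fixture builders and independent brute-force oracles. Oracles are written
# as explicit loops over raw genotype lists so they share no code path with
# the package implementations they check.

# --- fixture builders -------------------------------------------------------

ms_loci <- function(n = 2, motif = 2) {
  tibble::tibble(locus = sprintf("L%d", seq_len(n)), type = "microsat",
                 motif_length = rep(motif, length.out = n))
}

mhc_loci_tbl <- function(names = "MH1") {
  tibble::tibble(locus = names, type = "mhc", motif_length = NA_integer_)
}

# individuals tibble from a list: list(id = list(locus = c(a, b), ...), ...)
make_inds <- function(genos, loci, sex = NULL, pond = "A") {
  ids <- names(genos)
  out <- tibble::tibble(
    id = ids,
    sex = sex %||% rep(c("female", "male"), length.out = length(ids)),
    pond = rep(pond, length.out = length(ids)))
  for (i in seq_len(nrow(loci))) {
    loc <- loci$locus[i]
    a <- sapply(genos, function(g) if (is.null(g[[loc]])) NA else g[[loc]][1])
    b <- sapply(genos, function(g) if (is.null(g[[loc]])) NA else g[[loc]][2])
    if (loci$type[i] == "microsat") {
      out[[paste0(loc, "_a")]] <- as.integer(a)
      out[[paste0(loc, "_b")]] <- as.integer(b)
    } else {
      out[[paste0(loc, "_a")]] <- as.character(a)
      out[[paste0(loc, "_b")]] <- as.character(b)
    }
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random genotype population at given loci, allele pools per locus
random_inds <- function(n, loci, n_alleles = 4, seed = 1) {
  withr::with_seed(seed, {
    genos <- lapply(seq_len(n), function(i) {
      g <- lapply(seq_len(nrow(loci)), function(j) {
        if (loci$type[j] == "microsat") {
          as.character(sample(100 + loci$motif_length[j] * (0:(n_alleles - 1)), 2,
                              replace = TRUE))
        } else {
          sample(paste0("al", 1:n_alleles), 2, replace = TRUE)
        }
      })
      names(g) <- loci$locus
      g
    })
    names(genos) <- sprintf("I%03d", seq_len(n))
    make_inds(genos, loci)
  })
}

# --- diversity oracles (explicit-loop recomputation) ------------------------

# genotype list for one individual: named list locus -> c(a, b) or NULL
geno_list <- function(ind_row, loci) {
  g <- lapply(loci$locus, function(loc) {
    a <- ind_row[[paste0(loc, "_a")]]
    b <- ind_row[[paste0(loc, "_b")]]
    if (is.na(a) || is.na(b)) NULL else c(as.character(a), as.character(b))
  })
  names(g) <- loci$locus
  g[!vapply(g, is.null, logical(1))]
}

oracle_freqs <- function(individuals, loci) {
  freqs <- list()
  for (loc in loci$locus) {
    copies <- character(0)
    for (r in seq_len(nrow(individuals))) {
      g <- geno_list(individuals[r, ], loci)[[loc]]
      if (!is.null(g)) copies <- c(copies, g)
    }
    tab <- table(copies)
    freqs[[loc]] <- as.numeric(tab) / length(copies)
    names(freqs[[loc]]) <- names(tab)
  }
  freqs
}

oracle_sh <- function(ind_row, reference, loci) {
  g <- geno_list(ind_row, loci)
  if (length(g) == 0) return(NA_real_)
  het <- 0
  ho_sum <- 0
  for (loc in names(g)) {
    if (g[[loc]][1] != g[[loc]][2]) het <- het + 1
    n_t <- 0; n_h <- 0
    for (r in seq_len(nrow(reference))) {
      rg <- geno_list(reference[r, ], loci)[[loc]]
      if (!is.null(rg)) {
        n_t <- n_t + 1
        if (rg[1] != rg[2]) n_h <- n_h + 1
      }
    }
    ho_sum <- ho_sum + n_h / n_t
  }
  mean_ho <- ho_sum / length(g)
  if (mean_ho == 0) return(NA_real_)
  (het / length(g)) / mean_ho
}

oracle_hl <- function(ind_row, freqs, loci) {
  g <- geno_list(ind_row, loci)
  e_hom <- 0; e_all <- 0
  for (loc in names(g)) {
    e <- 1 - sum(freqs[[loc]]^2)
    e_all <- e_all + e
    if (g[[loc]][1] == g[[loc]][2]) e_hom <- e_hom + e
  }
  if (e_all == 0) return(NA_real_)
  e_hom / e_all
}

oracle_ir <- function(ind_row, freqs, loci) {
  g <- geno_list(ind_row, loci)
  h <- 0; fsum <- 0; n <- length(g)
  for (loc in names(g)) {
    if (g[[loc]][1] == g[[loc]][2]) h <- h + 1
    fsum <- fsum + freqs[[loc]][g[[loc]][1]] + freqs[[loc]][g[[loc]][2]]
  }
  den <- 2 * n - fsum
  if (abs(den) < 1e-12) return(NA_real_)
  unname((2 * h - fsum) / den)
}

oracle_d2 <- function(ind_row, loci, unit = "repeats") {
  g <- geno_list(ind_row, loci)
  vals <- c()
  for (loc in names(g)) {
    d <- abs(as.numeric(g[[loc]][1]) - as.numeric(g[[loc]][2]))
    if (unit == "repeats") {
      d <- d / loci$motif_length[loci$locus == loc]
    }
    vals <- c(vals, d^2)
  }
  mean(vals)
}

# --- MHC distance oracles ---------------------------------------------------

oracle_aa_dist <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  ndiff <- 0
  for (i in seq_along(a)) if (a[i] != b[i]) ndiff <- ndiff + 1
  ndiff / length(a)
}

oracle_func_dist <- function(s1, s2, ztbl) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  total <- 0
  for (i in seq_along(a)) {
    za <- as.numeric(ztbl[ztbl$residue == a[i], paste0("z", 1:5)])
    zb <- as.numeric(ztbl[ztbl$residue == b[i], paste0("z", 1:5)])
    total <- total + sqrt(sum((za - zb)^2))
  }
  total / length(a)
}

oracle_pair_dist <- function(female, male, dm) {
  total <- 0
  for (fa in female) for (ma in male) total <- total + dm[fa, ma]
  total
}

# maximum matching over the two allele pairs by enumerating assignments
oracle_nsa <- function(female, male) {
  best <- 0
  for (perm in list(c(1, 2), c(2, 1))) {
    m <- 0
    used <- c(FALSE, FALSE)
    for (i in 1:2) {
      j <- perm[i]
      if (!used[j] && female[i] == male[j]) {
        m <- m + 1
        used[j] <- TRUE
      }
    }
    # also try matching female allele i to the other male slot
    best <- max(best, m)
  }
  # exhaustive: all injective partial matchings of 2 female copies to 2 male
  for (f1 in 0:2) for (f2 in 0:2) {
    if (f1 == f2 && f1 != 0) next
    m <- 0
    ok <- TRUE
    if (f1 > 0) { if (female[1] == male[f1]) m <- m + 1 else ok <- FALSE }
    if (ok && f2 > 0) { if (female[2] == male[f2]) m <- m + 1 else ok <- FALSE }
    if (ok) best <- max(best, m)
  }
  best
}

# --- relatedness oracle -----------------------------------------------------

oracle_qg <- function(gx, gy, freqs) {
  # gx, gy: named lists locus -> c(a, b); freqs: named list of named vectors
  one_dir <- function(g1, g2) {
    num <- 0; den <- 0
    for (loc in names(g1)) {
      p <- freqs[[loc]]
      if (length(p) < 2) next
      if (is.null(g2[[loc]])) next
      a <- g1[[loc]][1]; b <- g1[[loc]][2]
      c_ <- g2[[loc]][1]; d <- g2[[loc]][2]
      iac <- as.numeric(a == c_); iad <- as.numeric(a == d)
      ibc <- as.numeric(b == c_); ibd <- as.numeric(b == d)
      num <- num + 0.5 * (iac + iad + ibc + ibd) - p[a] - p[b]
      den <- den + 1 + as.numeric(a == b) - p[a] - p[b]
    }
    unname(num / den)
  }
  (one_dir(gx, gy) + one_dir(gy, gx)) / 2
}

# --- dyad simulators for relatedness calibration ----------------------------

# allele frequency setup: n_loci loci with n_alleles alleles each (Dirichlet)
dyad_freqs <- function(n_loci = 13, n_alleles = 6, seed = 1) {
  withr::with_seed(seed, {
    fr <- lapply(seq_len(n_loci), function(l) {
      g <- rgamma(n_alleles, 1)
      p <- g / sum(g)
      names(p) <- as.character(100 + 2 * (seq_len(n_alleles) - 1))
      p
    })
    names(fr) <- sprintf("L%02d", seq_len(n_loci))
    fr
  })
}

draw_geno <- function(p) sample(names(p), 2, replace = TRUE, prob = p)

# returns individuals tibble + dyads tibble + tidy freqs table
sim_dyads <- function(n_dyads, relation = c("unrelated", "po", "identical"),
                      freqs, seed = 1) {
  relation <- match.arg(relation)
  loci <- tibble::tibble(locus = names(freqs), type = "microsat",
                         motif_length = 2L)
  withr::with_seed(seed, {
    genos <- list()
    dyads <- tibble::tibble(id1 = character(0), id2 = character(0))
    for (d in seq_len(n_dyads)) {
      id1 <- sprintf("X%04d", d); id2 <- sprintf("Y%04d", d)
      g1 <- lapply(freqs, draw_geno)
      g2 <- switch(relation,
        unrelated = lapply(freqs, draw_geno),
        identical = g1,
        po = lapply(names(freqs), function(loc) {
          c(sample(g1[[loc]], 1), draw_geno(freqs[[loc]])[1])
        }))
      names(g2) <- names(freqs)
      genos[[id1]] <- g1
      genos[[id2]] <- g2
      dyads <- rbind(dyads, tibble::tibble(id1 = id1, id2 = id2))
    }
    inds <- make_inds(genos, loci)
    list(individuals = inds, dyads = dyads, loci = loci,
         freqs = tidy_freqs(freqs))
  })
}

tidy_freqs <- function(freq_named_list) {
  dplyr::bind_rows(lapply(names(freq_named_list), function(loc) {
    tibble::tibble(locus = loc, allele = names(freq_named_list[[loc]]),
                   freq = unname(freq_named_list[[loc]]))
  }))
}

# --- independent Poisson GLM oracle (Newton-Raphson / IRLS) -----------------

nr_poisson_glm <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta)
    W <- mu
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# finite-difference SE of glmer variance parameter (theta = sigma_u)
glmer_theta_se <- function(clutches) {
  dev <- lme4::glmer(n_offspring ~ zygosity + (1 | male_id),
                     data = clutches, family = poisson("log"),
                     devFunOnly = TRUE)
  fit <- lme4::glmer(n_offspring ~ zygosity + (1 | male_id),
                     data = clutches, family = poisson("log"))
  opt <- c(lme4::getME(fit, "theta"), lme4::fixef(fit))
  h <- 1e-4
  k <- length(opt)
  H <- matrix(0, k, k)
  f0 <- dev(opt)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- rep(0, k); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (dev(opt + ei + ej) - dev(opt + ei) - dev(opt + ej) + f0) / h^2
  }
  # deviance = -2 logLik, so information = H / 2
  se <- sqrt(diag(solve(H / 2)))
  se[1]
}

# clutch data simulated from the Poisson random-intercept model
sim_clutches <- function(beta0 = 2.5, beta_zyg = 0.3, sigma_u = 0.2,
                         n_males = 40, clutches_per_male = 3, seed = 1) {
  withr::with_seed(seed, {
    zyg <- rep(c(0L, 1L), length.out = n_males)
    u <- rnorm(n_males, 0, sigma_u)
    rows <- lapply(seq_len(n_males), function(m) {
      mu <- exp(beta0 + beta_zyg * zyg[m] + u[m])
      tibble::tibble(male_id = sprintf("M%03d", m), zygosity = zyg[m],
                     n_offspring = rpois(clutches_per_male, mu))
    })
    dplyr::bind_rows(rows)
  })
}
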