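test_that("allele frequencies follow gene counting with missing-data exclusion", {
  loci <- ms_loci(1)
  ind <- make_inds(list(i1 = list(L1 = c(100, 100)),
                        i2 = list(L1 = c(100, 102))), loci)
  fr <- allele_frequencies(ind, loci)
  expect_equal(fr$freq[fr$allele == "100"], 0.75)
  expect_equal(fr$freq[fr$allele == "102"], 0.25)

  # monomorphic population
  mono <- make_inds(list(i1 = list(L1 = c(100, 100)),
                         i2 = list(L1 = c(100, 100))), loci)
  expect_equal(allele_frequencies(mono, loci)$freq, 1.0)

  # untyped individuals leave the denominator
  part <- make_inds(list(i1 = list(L1 = c(100, 102)), i2 = list()), loci)
  expect_equal(sum(allele_frequencies(part, loci)$count), 2L)

  # locus with nobody typed errors by name
  none <- make_inds(list(i1 = list(), i2 = list()), loci)
  expect_error(allele_frequencies(none, loci), "L1")

  # sums to one on a random population (direct summation oracle)
  loci4 <- ms_loci(3)
  rnd <- random_inds(10, loci4, n_alleles = 4, seed = 5)
  fr <- allele_frequencies(rnd, loci4)
  sums <- tapply(fr$freq, fr$locus, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("SH matches its definition and hand-summation oracle", {
  loci <- ms_loci(2)
  # reference engineered to Ho = 0.5 at both loci
  ref <- make_inds(list(r1 = list(L1 = c(100, 102), L2 = c(200, 202)),
                        r2 = list(L1 = c(100, 100), L2 = c(200, 200)),
                        r3 = list(L1 = c(102, 104), L2 = c(202, 204)),
                        r4 = list(L1 = c(104, 104), L2 = c(204, 204))),
                   loci)
  prof <- diversity_profiles(ref, loci, reference = ref)
  # fully heterozygous individual over loci with Ho = 0.5 scores 1/0.5 = 2
  expect_equal(prof$sh[prof$id == "r1"], 2.0)
  # fully homozygous individual scores 0
  expect_equal(prof$sh[prof$id == "r2"], 0)

  # population mean of SH over fully typed individuals is 1
  rnd <- random_inds(20, ms_loci(4), n_alleles = 5, seed = 9)
  p <- diversity_profiles(rnd, ms_loci(4), reference = rnd)
  expect_equal(mean(p$sh), 1, tolerance = 1e-9)

  # per-individual agreement with the explicit-loop oracle
  for (r in c(1, 7, 20)) {
    expect_equal(p$sh[r], oracle_sh(rnd[r, ], rnd, ms_loci(4)),
                 tolerance = 1e-9)
  }

  # monomorphic reference leaves SH undefined, not zero
  mono <- make_inds(list(i1 = list(L1 = c(100, 100)),
                         i2 = list(L1 = c(100, 100))), ms_loci(1))
  expect_true(is.na(diversity_profiles(mono, ms_loci(1))$sh[1]))
})

test_that("HL spans [0,1] and reproduces the two-locus worked case", {
  loci <- ms_loci(2)
  rnd <- random_inds(12, loci, n_alleles = 4, seed = 3)
  p <- diversity_profiles(rnd, loci, reference = rnd)
  expect_true(all(p$hl >= 0 & p$hl <= 1, na.rm = TRUE))

  # worked case: locus E-values 0.5 and 0.375, homozygous at the first only
  # -> HL = 0.5 / (0.5 + 0.375) = 4/7
  freqs <- tibble::tibble(
    locus = c("L1", "L1", "L2", "L2"),
    allele = c("100", "102", "200", "202"),
    freq = c(0.5, 0.5, 0.75, 0.25))  # E = 0.5 and 0.375
  ind <- make_inds(list(x = list(L1 = c(100, 100), L2 = c(200, 202))), loci)
  p1 <- diversity_profiles(ind, loci, freqs = freqs)
  expect_equal(p1$hl, 0.5 / 0.875, tolerance = 1e-12)
  # fully heterozygous -> 0; fully homozygous -> 1
  both <- make_inds(list(het = list(L1 = c(100, 102), L2 = c(200, 202)),
                         hom = list(L1 = c(100, 100), L2 = c(200, 200))),
                    loci)
  p2 <- diversity_profiles(both, loci, freqs = freqs)
  expect_equal(p2$hl, c(0, 1))
})

test_that("IR matches its closed form including degenerate cases", {
  loci <- ms_loci(2)
  freqs <- tibble::tibble(locus = rep(c("L1", "L2"), each = 2),
                          allele = c("100", "102", "200", "202"),
                          freq = rep(0.5, 4))
  het <- make_inds(list(x = list(L1 = c(100, 102), L2 = c(200, 202))), loci)
  expect_equal(diversity_profiles(het, loci, freqs = freqs)$ir, -1)

  # single locus A/B with p = 0.25 each -> (0 - 0.5) / (2 - 0.5) = -1/3
  l1 <- ms_loci(1)
  f1 <- tibble::tibble(locus = "L1", allele = c("100", "102", "104", "106"),
                       freq = rep(0.25, 4))
  ind <- make_inds(list(x = list(L1 = c(100, 102))), l1)
  expect_equal(diversity_profiles(ind, l1, freqs = f1)$ir, -1 / 3,
               tolerance = 1e-12)

  # homozygous for a fixed allele: 0/0, flagged undefined
  ffix <- tibble::tibble(locus = "L1", allele = "100", freq = 1.0)
  hom <- make_inds(list(x = list(L1 = c(100, 100))), l1)
  expect_true(is.na(diversity_profiles(hom, l1, freqs = ffix)$ir))
})

test_that("d2 uses repeat units by default and base pairs on request", {
  l1 <- ms_loci(1, motif = 2)
  ind <- make_inds(list(x = list(L1 = c(100, 104)),
                        hom = list(L1 = c(100, 100))), l1)
  p <- diversity_profiles(ind, l1)
  expect_equal(p$d2[p$id == "x"], 4)     # ((104-100)/2)^2
  expect_equal(p$d2[p$id == "hom"], 0)
  expect_equal(diversity_profiles(ind, l1, d2_unit = "bp")$d2[1], 16)

  # invariant to the storage order of the two alleles
  sw <- make_inds(list(x = list(L1 = c(104, 100))), l1)
  expect_equal(diversity_profiles(sw, l1, reference = ind)$d2[1], 4)

  # warns and keeps the fractional value on a non-integer repeat difference
  l3 <- ms_loci(1, motif = 3)
  odd <- make_inds(list(x = list(L1 = c(100, 104))), l3)
  expect_warning(p3 <- diversity_profiles(odd, l3), "non-integer")
  expect_equal(p3$d2[1], (4 / 3)^2, tolerance = 1e-12)
})

test_that("indices agree with oracles and respect structural invariants", {
  loci <- ms_loci(5)
  rnd <- random_inds(20, loci, n_alleles = 5, seed = 21)
  fr <- allele_frequencies(rnd, loci)
  p <- diversity_profiles(rnd, loci, freqs = fr)
  ofr <- oracle_freqs(rnd, loci)
  for (r in c(2, 11, 19)) {
    expect_equal(p$hl[r], oracle_hl(rnd[r, ], ofr, loci), tolerance = 1e-9)
    expect_equal(p$ir[r], oracle_ir(rnd[r, ], ofr, loci), tolerance = 1e-9)
    expect_equal(p$d2[r], oracle_d2(rnd[r, ], loci), tolerance = 1e-9)
  }

  # relabelling alleles consistently leaves HL and IR unchanged
  relab <- rnd
  for (cn in c("L1_a", "L1_b")) {
    relab[[cn]] <- relab[[cn]] + 1000L
  }
  p2 <- diversity_profiles(relab, loci)
  expect_equal(p2$hl, p$hl, tolerance = 1e-12)
  expect_equal(p2$ir, p$ir, tolerance = 1e-12)

  # a locus untyped in an individual contributes nothing to its indices
  # (typed only in the last individual so reference frequencies exist)
  ext <- rnd
  ext$L9_a <- c(rep(NA_integer_, 19), 100L)
  ext$L9_b <- c(rep(NA_integer_, 19), 102L)
  loci_ext <- rbind(loci, tibble::tibble(locus = "L9", type = "microsat",
                                         motif_length = 2L))
  p3 <- diversity_profiles(ext, loci_ext)
  keep <- 1:19
  expect_equal(p3$sh[keep], p$sh[keep], tolerance = 1e-12)
  expect_equal(p3$hl[keep], p$hl[keep], tolerance = 1e-12)
  expect_equal(p3$ir[keep], p$ir[keep], tolerance = 1e-12)
  expect_equal(p3$d2[keep], p$d2[keep], tolerance = 1e-12)
})

test_that("heterozygosity indices are strongly rank-correlated on simulation", {
  ds <- simulate_alligator_dataset(sim_config(
    seed = 31, ponds = tibble::tibble(pond = "A", n_females = 100L,
                                      n_males = 100L),
    n_founders = 30L, n_clutches = 5L, make_offspring = FALSE))
  p <- diversity_profiles(ds$individuals, ds$loci)
  full <- p[p$n_typed == sum(ds$loci$type == "microsat"), ]
  # SH falls as homozygosity rises; HL and IR rise: check squared Spearman
  expect_gt(cor(full$sh, full$hl, method = "spearman")^2, 0.8)
  expect_gt(cor(full$sh, full$ir, method = "spearman")^2, 0.8)
  expect_gt(cor(full$hl, full$ir, method = "spearman")^2, 0.8)
})

test_that("MHC heterozygote proportion and good-gene score behave", {
  loci <- mhc_loci_tbl("MH1")
  genos <- c(lapply(1:26, function(i) list(MH1 = c("A01", "A02"))),
             lapply(1:15, function(i) list(MH1 = c("A01", "A01"))))
  names(genos) <- sprintf("M%02d", 1:41)
  males <- make_inds(genos, loci, sex = rep("male", 41))
  expect_equal(mhc_het_proportion(males, "MH1"), 26 / 41)
  expect_equal(round(mhc_het_proportion(males, "MH1"), 3), 0.634)

  allhom <- make_inds(list(m1 = list(MH1 = c("A01", "A01")),
                           m2 = list(MH1 = c("A02", "A02"))), loci,
                      sex = c("male", "male"))
  expect_equal(mhc_het_proportion(allhom, "MH1"), 0)
  expect_error(mhc_het_proportion(males[0, ], "MH1"), "empty")

  # duplicated ids count once (unique-male basis)
  dup <- rbind(males, males[1, ])
  expect_equal(mhc_het_proportion(dup, "MH1"), 26 / 41)

  fr <- allele_frequencies(males, loci)
  af <- good_gene_score(males, fr, "MH1")
  p1 <- fr$freq[fr$allele == "A01"]
  p2 <- fr$freq[fr$allele == "A02"]
  expect_equal(af$af[1], p1 + p2)   # heterozygote
  expect_equal(af$af[41], 2 * p1)   # homozygote scores twice its allele freq

  # explicit frequencies: homozygote for p = 0.7 scores 1.4; fixed scores 2
  fr2 <- tibble::tibble(locus = "MH1", allele = c("A01", "A02"),
                        freq = c(0.7, 0.3))
  expect_equal(good_gene_score(allhom, fr2, "MH1")$af, c(1.4, 0.6))
  frfix <- tibble::tibble(locus = "MH1", allele = "A01", freq = 1.0)
  hom1 <- make_inds(list(m = list(MH1 = c("A01", "A01"))), loci)
  expect_equal(good_gene_score(hom1, frfix, "MH1")$af, 2.0)
})
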