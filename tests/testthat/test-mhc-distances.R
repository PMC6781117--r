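test_that("amino-acid distance follows p and Poisson models", {
  expect_equal(aa_distance("ACDE", "ACDE"), 0)
  expect_equal(aa_distance("ACDE", "ACDQ"), 0.25)
  expect_equal(aa_distance("ACDE", "ACDQ", model = "poisson"), -log(0.75))
  expect_error(aa_distance("ACDE", "ACD"), "length")
  expect_warning(d <- aa_distance("AC", "CA", model = "poisson"), "infinite")
  expect_equal(d, Inf)

  # agreement with the character-loop oracle on random sequences
  withr::with_seed(4, {
    for (i in 1:20) {
      s1 <- paste(sample(c("A", "C", "D", "E", "F"), 30, TRUE), collapse = "")
      s2 <- paste(sample(c("A", "C", "D", "E", "F"), 30, TRUE), collapse = "")
      expect_equal(aa_distance(s1, s2), oracle_aa_dist(s1, s2),
                   tolerance = 1e-12)
    }
  })
})

test_that("functional distance is a per-site z-space Euclidean mean", {
  expect_equal(functional_distance("ACDE", "ACDE"), 0)

  # symmetry over every residue pair with the shipped table
  ztbl <- zscale_table()
  for (r in ztbl$residue[c(2, 7, 19)]) {
    d1 <- functional_distance("A", r)
    d2 <- functional_distance(r, "A")
    expect_equal(d1, d2)
    za <- as.numeric(ztbl[ztbl$residue == "A", -1])
    zr <- as.numeric(ztbl[ztbl$residue == r, -1])
    expect_equal(d1, sqrt(sum((za - zr)^2)), tolerance = 1e-12)
  }

  # hand-built two-residue table: "PPP" vs "PQP" -> mean 5/3, sum 5
  toy <- tibble::tibble(residue = c("P", "Q"),
                        z1 = c(0, 3), z2 = c(0, 4), z3 = 0, z4 = 0, z5 = 0)
  expect_equal(functional_distance("PPP", "PQP", ztable = toy), 5 / 3)
  expect_equal(functional_distance("PPP", "PQP", ztable = toy,
                                   normalize = FALSE), 5)

  # unknown residue errors with its position unless skipping is requested
  expect_error(functional_distance("AXA", "AAA"), "position 2")
  expect_equal(functional_distance("AXC", "AXD", skip_ambiguous = TRUE),
               functional_distance("AC", "AD"))

  # a table mapping all residues to one vector nullifies every distance
  flat <- tibble::tibble(residue = ztbl$residue,
                         z1 = 1, z2 = 1, z3 = 1, z4 = 1, z5 = 1)
  expect_equal(functional_distance("ACDEFGHIKL", "LMNPQRSTVW",
                                   ztable = flat), 0)

  # oracle agreement on random sequences
  withr::with_seed(8, {
    for (i in 1:5) {
      s1 <- paste(sample(ztbl$residue, 12, TRUE), collapse = "")
      s2 <- paste(sample(ztbl$residue, 12, TRUE), collapse = "")
      expect_equal(functional_distance(s1, s2),
                   oracle_func_dist(s1, s2, ztbl), tolerance = 1e-9)
    }
  })
})

test_that("allele distance matrices are symmetric with zero diagonal", {
  alleles <- tibble::tibble(
    locus = "MH1", allele = c("A01", "A02", "A03"),
    dna = NA_character_,
    protein = c("ACDEF", "ACDEY", "QCDEY"))
  for (kind in c("aa", "functional")) {
    m <- allele_distance_matrix(alleles, "MH1", kind = kind)
    expect_equal(diag(m), setNames(rep(0, 3), alleles$allele))
    expect_equal(m, t(m))
    expect_true(all(m >= 0))
  }
  m <- allele_distance_matrix(alleles, "MH1", kind = "aa")
  expect_equal(m["A01", "A02"], 0.2)
  expect_equal(m["A01", "A03"], 0.4)
  expect_error(allele_distance_matrix(alleles, "MH9"), "MH9")
})

test_that("pair distance is the four-term sum, symmetric, zero on identity", {
  dm <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("A", "a"), c("A", "a")))
  expect_equal(pair_mhc_distance(c("A", "A"), c("A", "A"), dm), 0)
  # female A/a x male A/a: D(A,A)+D(A,a)+D(a,A)+D(a,a) = 2d
  expect_equal(pair_mhc_distance(c("A", "a"), c("A", "a"), dm), 0.6)
  expect_equal(pair_mhc_distance(c("A", "a"), c("a", "A"), dm),
               pair_mhc_distance(c("a", "A"), c("A", "a"), dm))
  expect_error(pair_mhc_distance(c("A", "Z"), c("A", "a"), dm), "Z")

  # brute-force equivalence over 1000 random genotype pairs
  withr::with_seed(12, {
    k <- 6
    nm <- paste0("x", 1:k)
    m <- matrix(runif(k * k), k, k, dimnames = list(nm, nm))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    for (i in 1:1000) {
      f <- sample(nm, 2, TRUE)
      g <- sample(nm, 2, TRUE)
      expect_equal(pair_mhc_distance(f, g, m), oracle_pair_dist(f, g, m),
                   tolerance = 1e-12)
    }
  })
})

test_that("allele sharing is the maximum-matching count", {
  expect_equal(allele_sharing(c("A", "B"), c("A", "B")), 2L)
  expect_equal(allele_sharing(c("A", "A"), c("A", "B")), 1L)
  expect_equal(allele_sharing(c("A", "B"), c("C", "D")), 0L)
  expect_equal(allele_sharing(c("A", "B"), c("B", "A")), 2L)

  withr::with_seed(3, {
    nm <- paste0("y", 1:4)
    for (i in 1:200) {
      f <- sample(nm, 2, TRUE)
      g <- sample(nm, 2, TRUE)
      expect_equal(allele_sharing(f, g), oracle_nsa(f, g))
      expect_equal(allele_sharing(f, g), allele_sharing(g, f))
    }
  })
})

test_that("pair compatibility table covers loci and flags untyped pairs", {
  loci <- mhc_loci_tbl(c("MH1", "MH2"))
  alleles <- tibble::tibble(
    locus = rep(c("MH1", "MH2"), each = 2),
    allele = c("A01", "A02", "B01", "B02"),
    dna = NA_character_,
    protein = c("ACDEF", "ACDEY", "MMMM", "MMMW"))
  ind <- make_inds(list(
    F1 = list(MH1 = c("A01", "A02"), MH2 = c("B01", "B01")),
    M1 = list(MH1 = c("A01", "A01"), MH2 = c("B01", "B02")),
    M2 = list(MH1 = c("A02", "A02"))), loci,
    sex = c("female", "male", "male"))
  pairs <- tibble::tibble(female_id = c("F1", "F1"), male_id = c("M1", "M2"),
                          pond = "A", n_offspring = c(3, 4))
  pc <- pair_compatibility(pairs, ind, loci, alleles)
  expect_equal(nrow(pc), 4)
  r <- pc[pc$male_id == "M1" & pc$locus == "MH1", ]
  expect_equal(r$nsa, 1L)
  d <- 0.2  # p-distance between A01 and A02
  expect_equal(r$aa_dist, 2 * d, tolerance = 1e-12)
  # M2 is untyped at MH2: flagged NA rather than dropped
  r2 <- pc[pc$male_id == "M2" & pc$locus == "MH2", ]
  expect_true(is.na(r2$nsa) && is.na(r2$aa_dist))
  # identical homozygous partners have distance zero at MH1 for M2 x nobody;
  # instead verify Nsa = 2 forces 0 distance when alleles are identical
  hom <- pair_compatibility(
    tibble::tibble(female_id = "F1", male_id = "M1", pond = "A",
                   n_offspring = 1),
    make_inds(list(F1 = list(MH1 = c("A01", "A01"), MH2 = c("B01", "B01")),
                   M1 = list(MH1 = c("A01", "A01"), MH2 = c("B01", "B01"))),
              loci, sex = c("female", "male")),
    loci, alleles)
  expect_equal(hom$nsa, c(2L, 2L))
  expect_equal(hom$aa_dist, c(0, 0))
  expect_equal(hom$aa_func_dist, c(0, 0))
})
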