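test_that("RSCU matches published hand-checkable values and family identities", {
  # four-fold Ala family from the pooled NPV glycoprotein table
  ala <- counts_to_tbl(c(GCU = 72, GCC = 168, GCA = 28, GCG = 154))
  r <- rscu(ala)
  r <- r[r$family == "Ala", ]
  expect_equal(round_half_up(r$rscu[r$codon == "GCU"], 2), 0.68)
  expect_equal(round_half_up(r$rscu[r$codon == "GCC"], 2), 1.59)

  # equal usage in every family gives RSCU 1 everywhere
  eq <- counts_to_tbl(stats::setNames(rep(7L, 59), sense_codons()$codon_rna))
  expect_equal(rscu(eq)$rscu, rep(1, 59))

  # hand calculation for a 4-fold family with counts (2, 1, 1, 0)
  gly <- counts_to_tbl(c(GGU = 2, GGC = 1, GGA = 1, GGG = 0))
  rg <- rscu(gly)
  rg <- rg[rg$family == "Gly", ]
  expect_equal(rg$rscu[match(c("GGU", "GGC", "GGA", "GGG"), rg$codon)],
               c(2, 1, 1, 0))
})

test_that("RSCU of an unused family is undefined, not zero", {
  one_fam <- counts_to_tbl(c(UUU = 3, UUC = 1))  # only Phe observed
  r <- rscu(one_fam)
  expect_false(any(is.na(r$rscu[r$family == "Phe"])))
  expect_true(all(is.na(r$rscu[r$family == "Ala"])))
})

test_that("RSCU family means equal 1 for every observed family", {
  for (seed in 1:20) {
    counts <- random_sense_counts(seed, lambda = 5)
    r <- rscu(counts_to_tbl(counts))
    means <- as.numeric(tapply(r$rscu, r$family, mean))
    means <- means[!is.na(means)]
    expect_equal(means, rep(1, length(means)), tolerance = 1e-12)
  }
})

test_that("ENC hits its analytic bounds", {
  # one codon per family: every family homozygosity is exactly 1
  one_per_family <- sense_codons() |>
    dplyr::group_by(family) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  counts <- stats::setNames(rep(50L, 18), one_per_family$codon_rna)
  expect_equal(enc(counts_to_tbl(counts))$enc, 20)

  # equal usage of every synonym, large counts: capped at 61
  eq <- stats::setNames(rep(100L, 59), sense_codons()$codon_rna)
  expect_equal(enc(counts_to_tbl(eq))$enc, 61)
})

test_that("ENC matches a hand-evaluated two-family case", {
  # Phe (3,1): F = 0.5; Ala (5,5,5,5): F = 4/19; empty classes imputed
  counts <- counts_to_tbl(c(UUU = 3, UUC = 1,
                            GCU = 5, GCC = 5, GCA = 5, GCG = 5))
  f2 <- 0.5
  f4 <- 4 / 19
  f3 <- mean(c(f2, f4))
  f6 <- mean(c(f2, f4))
  expected <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  expect_equal(enc(counts)$enc, min(61, expected), tolerance = 1e-9)
})

test_that("ENC equals the brute-force oracle on random count tables", {
  for (seed in 1:100) {
    counts <- random_sense_counts(seed, lambda = c(1, 3, 10, 40)[seed %% 4 + 1])
    got <- suppressWarnings(enc(counts_to_tbl(counts))$enc)
    want <- oracle_enc(counts)
    if (is.na(got)) {
      expect_true(is.na(want) || sum(counts) < 2)
    } else {
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("scaling counts moves ENC monotonically toward the asymptotic value", {
  for (seed in c(2, 5, 9)) {
    counts <- random_sense_counts(seed, lambda = 4) + 1L  # keep families usable
    asym <- oracle_enc_asymptotic(counts)
    gaps <- vapply(c(1, 10, 100, 1000), function(k) {
      abs(enc(counts_to_tbl(counts * k))$enc - asym)
    }, numeric(1))
    expect_true(all(diff(gaps) <= 1e-9))
  }
})

test_that("CAI weights normalise to the family maximum with a zero floor", {
  ref <- counts_to_tbl(stats::setNames(rep(10L, 59), sense_codons()$codon_rna))
  ref$count[ref$codon == "UUC"] <- 5L
  ref$count[ref$codon == "GCA"] <- 0L
  w <- cai_weights(ref)
  expect_equal(w$w[w$codon == "UUU"], 1)
  expect_equal(w$w[w$codon == "UUC"], 0.5)
  expect_equal(w$w[w$codon == "GCA"], 0.01)  # floored, never 0
  # max weight is 1 in every family
  expect_equal(as.numeric(tapply(w$w, w$family, max)), rep(1, 18))

  # a family absent from the reference is an error naming it
  gly <- sense_codons()
  gly <- gly$codon_rna[gly$family == "Gly"]
  ref$count[ref$codon %in% gly] <- 0L
  expect_error(cai_weights(ref), "Gly")
})

test_that("CAI is the geometric mean of weights, 1 only for optimal codons", {
  ref <- synthetic_cai_reference()
  w <- cai_weights(ref)
  optimal <- w$codon[w$w == 1]
  counts_opt <- counts_to_tbl(stats::setNames(rep(3L, length(optimal)), optimal))
  expect_equal(cai(counts_opt, w)$cai, 1)

  # equal occurrences at weights 1.0 and 0.25 -> geometric mean 0.5
  w2 <- tibble::tibble(codon = c("UUU", "UUC"), family = "Phe",
                       w = c(1, 0.25))
  counts2 <- counts_to_tbl(c(UUU = 10, UUC = 10))
  expect_equal(cai(counts2, w2)$cai, 0.5, tolerance = 1e-12)

  # duplication invariance of the geometric mean
  counts_mixed <- counts_to_tbl(random_sense_counts(4, lambda = 8))
  expect_equal(cai(counts_mixed, w)$cai,
               cai(dplyr::mutate(counts_mixed, count = count * 2L), w)$cai,
               tolerance = 1e-12)
  expect_true(cai(counts_mixed, w)$cai < 1)
})

test_that("positional composition uses the documented universes", {
  # start excluded: only GGC remains, all third positions G/C
  one <- tibble::tibble(gene_id = "g", sequence = "ATGGGC")
  comp <- codon_composition(one, exclude_stop = FALSE)
  expect_equal(comp$gc3, 100)

  # homopolymer: no G/C anywhere
  aaa <- tibble::tibble(gene_id = "g", sequence = strrep("AAA", 20))
  comp_a <- codon_composition(aaa)
  expect_equal(comp_a[, c("gc", "gc1", "gc2", "gc3")],
               tibble::tibble(gc = 0, gc1 = 0, gc2 = 0, gc3 = 0))

  # identities on random genes: gc = mean(gc1,gc2,gc3); gc12 = mean(gc1,gc2);
  # gc3s = c3s + g3s and the silent-base fractions partition 100 %
  co <- generate_cohort(cohort_spec(n_genes = 6), seed = 3)
  comp_r <- codon_composition(co$sequences)
  expect_equal(comp_r$gc, (comp_r$gc1 + comp_r$gc2 + comp_r$gc3) / 3,
               tolerance = 1e-12)
  expect_equal(comp_r$gc12, (comp_r$gc1 + comp_r$gc2) / 2, tolerance = 1e-12)
  expect_equal(comp_r$gc3s, comp_r$c3s + comp_r$g3s, tolerance = 1e-12)
  expect_equal(comp_r$a3s + comp_r$t3s + comp_r$c3s + comp_r$g3s,
               rep(100, 6), tolerance = 1e-12)
})

test_that("the index table assembles all columns with sane ranges", {
  co <- generate_cohort(cohort_spec(n_genes = 5), seed = 21)
  idx <- codon_usage_indices(co$sequences)
  expect_setequal(
    setdiff(c("gene_id", "length_nt", "gc", "gc1", "gc2", "gc3", "gc12",
              "gc3s", "a3s", "t3s", "c3s", "g3s", "enc", "cai", "group"),
            names(idx)),
    character())
  expect_true(all(idx$enc >= 20 & idx$enc <= 61))
  expect_true(all(idx$cai > 0 & idx$cai <= 1))
  expect_equal(idx$length_nt, nchar(co$sequences$sequence))
})

test_that("report rounding is half-up at 2 decimals", {
  expect_equal(round_half_up(0.125, 2), 0.13)  # base round() would give 0.12
  expect_equal(round_half_up(3.375, 2), 3.38)
  expect_equal(round_half_up(0.394999, 2), 0.39)
})
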