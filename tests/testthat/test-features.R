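test_that("load_aaindex parses H/I records, NA values, and counts entries", {
  path <- tmp_aaindex_known()
  tab <- load_aaindex(path)
  expect_s3_class(tab, "aaindex_table")
  expect_equal(tab$count, 3L)
  expect_equal(length(tab$entries$CONST1), 20L)
  expect_true(all(tab$entries$CONST1 == 1))
  expect_equal(tab$entries$AG0001[["A"]], 2)
  expect_equal(tab$entries$AG0001[["G"]], 4)
  # NA residues are absent from the map
  expect_equal(names(tab$entries$ONLYA1), "A")
  expect_error(load_aaindex(withr::local_tempfile()), "not found")
})

test_that("aaindex_features sums index values and normalizes by covered residues", {
  tab <- load_aaindex(tmp_aaindex_known())
  v <- aaindex_features("AAG", tab)
  expect_equal(attr(v, "dimension"), 3L)
  expect_equal(unname(v[["CONST1"]]), 1)             # constant index -> c
  expect_equal(unname(v[["AG0001"]]), (2 + 2 + 4) / 3)
  # index defined only for A on "AG": normalized by the 1 covered residue
  v2 <- aaindex_features("AG", tab)
  expect_equal(unname(v2[["ONLYA1"]]), 2)
  # no covered residue -> 0
  v3 <- aaindex_features("KW", tab)
  expect_equal(unname(v3[["ONLYA1"]]), 0)
})

test_that("kmer_composition counts overlapping windows over L - k + 1", {
  un <- alphabet("ungrouped")
  v1 <- kmer_composition("AAG", un, 1)
  expect_equal(unname(v1[["A"]]), 2 / 3)
  expect_equal(unname(v1[["G"]]), 1 / 3)
  expect_equal(sum(v1), 1)
  expect_equal(length(v1), 20L)  # full key space enumerated
  v2 <- kmer_composition("AAG", un, 2)
  expect_equal(unname(v2[["AA"]]), 1 / 2)
  expect_equal(unname(v2[["AG"]]), 1 / 2)
  # shorter than k: zero vector, not an error
  v4 <- kmer_composition("AAG", un, 4)
  expect_equal(sum(v4), 0)
  expect_equal(attr(v4, "dimension"), 160000)
})

test_that("composition equals naive counting and the recoding equivalence", {
  naive_kmer <- function(s, k) {
    L <- nchar(s)
    km <- substring(s, 1:(L - k + 1), k:L)
    table(km) / (L - k + 1)
  }
  gc <- alphabet("groupC")
  withr::with_seed(31, {
    for (i in 1:10) {
      s <- random_peptide(sample(20:80, 1))
      k <- sample(1:3, 1)
      v <- kmer_composition(s, alphabet("ungrouped"), k)
      ref <- naive_kmer(s, k)
      expect_equal(unname(v[names(ref)]), unname(as.numeric(ref)))
      expect_equal(sum(v), 1, tolerance = 1e-9)
      expect_true(all(v >= 0 & v <= 1))
      # group-C composition == composition of the recoded string
      vg <- kmer_composition(s, gc, k)
      ref_g <- naive_kmer(recode(s, gc), k)
      expect_equal(unname(vg[names(ref_g)]), unname(as.numeric(ref_g)))
    }
  })
})

test_that("gapped_composition pairs positions i and i + x + 1", {
  un <- alphabet("ungrouped")
  v <- gapped_composition("ACDAC", un, 1)
  expect_equal(unname(v[c("AD", "CA", "DC")]), rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  v2 <- gapped_composition("ACDAC", un, 2)
  expect_equal(unname(v2[c("AA", "CC")]), rep(1 / 2, 2))
  v5 <- gapped_composition("ACDAC", un, 5)
  expect_equal(sum(v5), 0)
  # dimension is |alphabet|^2
  expect_equal(attr(gapped_composition("ACDAC", alphabet("groupC"), 1),
                    "dimension"), 64)
  # ordered pairs: AC with gap contributes to key "AC", not "CA"
  v6 <- gapped_composition("AGC", un, 1)
  expect_equal(unname(v6[["AC"]]), 1)
  expect_equal(unname(v6[["CA"]]), 0)
})

test_that("the registry holds exactly 41 uniquely named specs with exact dimensions", {
  reg <- build_feature_registry()
  expect_length(reg, 41L)
  expect_false(anyDuplicated(names(reg)) > 0)
  fams <- vapply(reg, `[[`, character(1), "family")
  expect_equal(sum(fams == "aaindex"), 1L)
  expect_equal(sum(fams == "composition"), 22L)  # 6 + 8 + 8
  expect_equal(sum(fams == "gapped"), 18L)       # 3 alphabets x 6 gaps
  expect_equal(reg$comp_ungrouped_k4$dimension, 160000)
  expect_equal(reg$comp_ungrouped_k6$dimension, 64000000)
  expect_equal(reg$comp_groupC_k8$dimension, 8^8)
  expect_equal(reg$comp_groupD_k7$dimension, 10^7)
  expect_equal(reg$aaindex$dimension, 494L)
  expect_equal(reg$gap_groupD_x6$dimension, 100)
  # AAindex dimension follows the table when one is supplied
  tab <- load_aaindex(tmp_aaindex_known())
  expect_equal(build_feature_registry(tab)$aaindex$dimension, 3L)
})

test_that("extract_features dispatches to the right family", {
  tab <- load_aaindex(tmp_aaindex_known())
  reg <- build_feature_registry(tab)
  expect_equal(extract_features("AAG", reg$comp_ungrouped_k1, tab),
               kmer_composition("AAG", alphabet("ungrouped"), 1))
  expect_equal(extract_features("AAG", reg$aaindex, tab),
               aaindex_features("AAG", tab))
  expect_equal(extract_features("ACDAC", reg$gap_groupD_x2, tab),
               gapped_composition("ACDAC", alphabet("groupD"), 2))
  bad <- reg$aaindex
  bad$family <- "nonsense"
  expect_error(extract_features("AAG", bad, tab), "unknown feature family")
  expect_error(extract_features("AAG", reg$aaindex, NULL), "require")
})

test_that("large k-mer spaces stay sparse and huge-k vectors never densify", {
  withr::with_seed(8, {
    s <- random_peptide(200)
  })
  v <- kmer_composition(s, alphabet("ungrouped"), 6)
  expect_lte(length(v), 195)         # at most L - k + 1 observed keys
  expect_equal(attr(v, "dimension"), 64000000)
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("feature_matrix builds consistent sparse rows, fixed keys drop unseen", {
  withr::with_seed(12, {
    ps <- peptide_set(sprintf("p%d", 1:6),
                      vapply(rep(60, 6), random_peptide, character(1)))
  })
  reg <- build_feature_registry()
  X <- feature_matrix(ps, reg$comp_ungrouped_k2)
  expect_s4_class(X, "dgCMatrix")
  expect_equal(dim(X), c(6L, 400L))
  expect_equal(unname(Matrix::rowSums(X)), rep(1, 6))
  # row equals the per-sequence extraction
  v <- kmer_composition(ps$sequence[3], alphabet("ungrouped"), 2)
  expect_equal(as.numeric(X[3, names(v)]), unname(as.numeric(v)))
  # restricting to a model key set keeps only those columns, in order
  X2 <- feature_matrix(ps, reg$comp_ungrouped_k2, keys = c("AA", "CD"))
  expect_equal(colnames(X2), c("AA", "CD"))
})

test_that("tetrapeptide_audit counts occurrences, distinct and single-class motifs", {
  # two records of lengths 10 and 7 -> 7 + 4 = 11 occurrences
  ps <- peptide_set(c("a", "b"),
                    c("ACDEFGHIKL", "MNPQRST"),
                    label = c("mit", "chl"))
  aud <- tetrapeptide_audit(ps)
  expect_equal(aud$total_occurrences, 11L)
  # single record AAAA
  one <- peptide_set("a", "AAAA", label = "mit")
  aud1 <- tetrapeptide_audit(one)
  expect_equal(aud1$total_occurrences, 1L)
  expect_equal(aud1$n_distinct, 1L)
  expect_equal(aud1$n_single_class, 1L)
  expect_equal(aud1$motifs$prevalence, 1)
  # motif in both classes is not single-class
  two <- peptide_set(c("a", "b"), c("AAAAC", "AAAAC"),
                     label = c("mit", "chl"))
  aud2 <- tetrapeptide_audit(two)
  m <- aud2$motifs[aud2$motifs$motif == "AAAA", ]
  expect_equal(m$n_classes, 2L)
  expect_equal(aud2$n_single_class, 0L)
  # invariant: distinct <= min(total, 160000)
  withr::with_seed(77, {
    big <- peptide_set(sprintf("r%d", 1:20),
                       vapply(rep(50, 20), random_peptide, character(1)),
                       label = sample(c("mit", "chl", "nuc"), 20,
                                      replace = TRUE))
  })
  audb <- tetrapeptide_audit(big)
  expect_lte(audb$n_distinct, min(audb$total_occurrences, 160000))
  expect_error(tetrapeptide_audit(peptide_set("a", "AAAA")), "labeled")
})
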