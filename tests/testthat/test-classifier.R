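test_that("derived karyotype features follow the counting rules", {
  f <- derived_karyotype_features(c("del(5q)", "-7", "del(17p)"))
  expect_equal(f$n_unbalanced, 3)
  expect_true(f$is_complex)
  f <- derived_karyotype_features("t(8;21)")
  expect_equal(f$n_unbalanced, 0)
  expect_false(f$is_complex)
  # pure-gain karyotypes are never complex, whatever the count
  f <- derived_karyotype_features(c("+8", "+11", "+13", "+21"))
  expect_equal(f$n_trisomies, 4)
  expect_false(f$has_deletion)
  expect_false(f$is_complex)
  # monosomal: two autosomal monosomies, or one plus structural
  expect_true(derived_karyotype_features(c("-7", "-5"))$is_monosomal)
  expect_true(derived_karyotype_features(c("-7", "del(5q)"))$is_monosomal)
  expect_false(derived_karyotype_features(c("-7"))$is_monosomal)
  expect_false(derived_karyotype_features(c("-X/-Y", "-7"))$is_monosomal)
  # empty karyotype: all zero / false
  f <- derived_karyotype_features(character())
  expect_equal(f$n_unbalanced, 0)
  expect_false(f$is_monosomal)
})

test_that("TP53 allelic state reproduces the three multi-hit criteria", {
  two_hits <- mutation_calls(c("TP53", "TP53"), vaf = c(0.3, 0.2),
                             consequence = c("substitution", "indel"))
  one_low <- mutation_calls("TP53", vaf = 0.40)
  one_high <- mutation_calls("TP53", vaf = 0.70)
  expect_equal(tp53_allelic_state(two_hits), "multi_hit")
  expect_equal(tp53_allelic_state(one_low), "mono_allelic")
  expect_equal(tp53_allelic_state(one_high), "multi_hit")
  expect_equal(tp53_allelic_state(one_low, "del(17p)"), "multi_hit")
  expect_equal(tp53_allelic_state(one_low, "-17"), "multi_hit")
  expect_equal(tp53_allelic_state(empty_mutations()), "wild_type")
  # missing VAF cannot trigger the LOH criterion
  expect_equal(tp53_allelic_state(mutation_calls("TP53", vaf = NA)),
               "mono_allelic")
  # order independence of mutation rows
  expect_equal(tp53_allelic_state(two_hits[2:1, ]), "multi_hit")
})

test_that("hierarchy rules fire first-match on worked examples", {
  expect_equal(classify_patient(
    profile_with(c("BCOR", "SF3B1")))$aml_class, "sAML2")
  expect_equal(classify_patient(profile_with())$aml_class, "no_events")
  # NPM1 precedes sAML1/DNMT3A-IDH; ITD is non-class-defining
  p <- profile_with(c("NPM1", "DNMT3A"), itd = TRUE)
  expect_equal(classify_patient(p)$aml_class, "NPM1")
  # WHO entities precede the mutation classes
  expect_equal(classify_patient(
    profile_with(c("SRSF2", "ASXL1"), cyto = "t(15;17)"))$aml_class,
    "APL_t15_17")
  # sAML threshold: 1 gene vs >= 2
  expect_equal(classify_patient(profile_with("SRSF2"))$aml_class,
               "sAML1")
  expect_equal(classify_patient(
    profile_with(c("SRSF2", "ASXL1")))$aml_class, "sAML2")
  # MLL-PTD counts toward the sAML set, MLL substitutions do not
  expect_equal(classify_patient(
    profile_with(c("SRSF2", "MLL"),
                 consequence = c("substitution", "ptd")))$aml_class,
    "sAML2")
  expect_equal(classify_patient(
    profile_with(c("SRSF2", "MLL")))$aml_class, "sAML1")
  # biCEBPA needs two distinct calls; single CEBPA is not class-defining
  p2 <- lesion_profile("x", mutation_calls(c("CEBPA", "CEBPA"),
                                           consequence = c("indel",
                                                           "substitution")))
  expect_equal(classify_patient(p2)$aml_class, "biCEBPA")
  expect_equal(classify_patient(profile_with("CEBPA"))$aml_class,
               "mNOS")
  # TP53/complex by either arm of the rule
  expect_equal(classify_patient(profile_with("TP53"))$aml_class,
               "TP53_complex")
  expect_equal(classify_patient(
    profile_with(cyto = c("del(5q)", "-7", "other_unbalanced")))$aml_class,
    "TP53_complex")
  # trisomies: gains without deletions, tolerant of balanced extras
  expect_equal(classify_patient(
    profile_with(cyto = c("+8", "+13")))$aml_class, "trisomies")
  expect_equal(classify_patient(
    profile_with(cyto = c("+8", "del(5q)")))$aml_class, "mNOS")
  # DNMT3A/IDH and WT1
  expect_equal(classify_patient(
    profile_with(c("DNMT3A", "IDH1")))$aml_class, "DNMT3A_IDH")
  expect_equal(classify_patient(profile_with("WT1"))$aml_class, "WT1")
  expect_equal(classify_patient(
    profile_with(c("WT1"), cyto = "t(8;21)"))$aml_class, "t8_21")
})

test_that("sAML threshold holds for every k up to 11", {
  panel <- load_panel()
  plain <- setdiff(panel$saml_genes, panel$ptd_only)
  for (k in 1:11) {
    genes <- plain[seq_len(min(k, 10))]
    cons <- rep("substitution", length(genes))
    if (k >= 11) {
      genes <- c(genes, "MLL")
      cons <- c(cons, "ptd")
    }
    p <- lesion_profile("x", mutation_calls(genes, consequence = cons))
    expect_equal(classify_patient(p)$aml_class,
                 if (k == 1) "sAML1" else "sAML2")
  }
})

test_that("every profile in an exhaustive small universe gets exactly
           one class and removal of evidence moves it strictly later", {
  vocab <- lesion_vocabulary()
  panel <- load_panel()
  hierarchy <- load_hierarchy()
  lesions <- c("t(15;17)", "inv(16)", "+8", "del(5q)", "-7")
  genes <- c("TP53", "SRSF2", "ASXL1", "NPM1", "WT1")
  n <- 2^10
  bits <- sapply(0:9, function(b) bitwAnd(bitwShiftR(0:(n - 1), b),
                                          1L) == 1L)
  cyto <- matrix(FALSE, n, nrow(vocab),
                 dimnames = list(NULL, vocab$code))
  cyto[, lesions] <- bits[, 1:5]
  muts <- matrix(FALSE, n, length(panel$genes),
                 dimnames = list(NULL, panel$genes))
  muts[, genes] <- bits[, 6:10]
  f <- amlclass:::class_feature_list(cyto, muts, integer(n),
                                     logical(n), panel, vocab)
  res <- amlclass:::classify_feature_table(f, hierarchy)
  expect_false(anyNA(res$aml_class))
  expect_true(all(res$rule_rank >= 1 & res$rule_rank <= 16))
  # matrix engine agrees with the per-profile path on a sample
  set.seed(7)
  for (i in sample(n, 40)) {
    p <- lesion_profile(
      "x",
      mutations = if (any(muts[i, ]))
        mutation_calls(panel$genes[muts[i, ]]) else empty_mutations(),
      cytogenetics = vocab$code[cyto[i, ]])
    expect_equal(classify_patient(p)$aml_class, res$aml_class[i])
  }
  # first-match semantics: strip the fired evidence, rank must increase
  set.seed(8)
  for (i in sample(which(res$rule_rank < 15), 30)) {
    p <- lesion_profile(
      "x",
      mutations = if (any(muts[i, ]))
        mutation_calls(panel$genes[muts[i, ]]) else empty_mutations(),
      cytogenetics = vocab$code[cyto[i, ]])
    a <- classify_patient(p)
    ev <- unique(sub("-PTD$", "", a$evidence))
    p2 <- lesion_profile(
      "x",
      mutations = {
        m <- p$mutations[!p$mutations$gene %in% ev, , drop = FALSE]
        m
      },
      cytogenetics = setdiff(p$cytogenetics, ev))
    a2 <- classify_patient(p2)
    expect_gt(a2$rule_rank, a$rule_rank)
  }
})

test_that("classification is invariant to mutation and lesion order", {
  set.seed(21)
  panel <- load_panel()
  genes_pool <- panel$genes
  cyto_pool <- lesion_vocabulary()$code
  for (rep in 1:25) {
    genes <- sample(genes_pool, sample(0:4, 1))
    cyto <- sample(cyto_pool, sample(0:3, 1))
    p1 <- lesion_profile("x",
                         if (length(genes)) mutation_calls(genes)
                         else empty_mutations(), cyto)
    p2 <- lesion_profile("x",
                         if (length(genes))
                           mutation_calls(rev(genes))
                         else empty_mutations(), rev(cyto))
    expect_equal(classify_patient(p1)$aml_class,
                 classify_patient(p2)$aml_class)
  }
})

test_that("classify_cohort summarises counts and handles empty input", {
  profs <- lapply(1:10, function(i)
    profile_with("NPM1", consequence = "indel", id = paste0("p", i)))
  cc <- classify_cohort(profs)
  expect_equal(cc$summary$fraction[cc$summary$aml_class == "NPM1"], 1)
  expect_equal(sum(cc$summary$fraction), 1)
  empty <- classify_cohort(list())
  expect_equal(nrow(empty$assignments), 0)
})

test_that("evidence is non-empty except for no_events", {
  a <- classify_patient(profile_with(c("SRSF2", "ASXL1")))
  expect_gt(length(a$evidence), 0)
  a0 <- classify_patient(profile_with())
  expect_length(a0$evidence, 0)
})
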