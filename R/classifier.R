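#' @title Hierarchical molecular classification of AML
#' @description The 16 molecular classes and the first-match rule engine
#'   that assigns every lesion profile to exactly one class.
#' @name classifier
NULL

#' The 16 molecular class labels
#' @return Character vector in default hierarchy order.
#' @export
aml_classes <- function() {
  c("APL_t15_17", "inv16", "t8_21", "KMT2A_t11x", "t6_9", "inv3",
    "TP53_complex", "trisomies", "sAML2", "biCEBPA", "NPM1", "sAML1",
    "DNMT3A_IDH", "WT1", "mNOS", "no_events")
}

#' Load a classification hierarchy
#'
#' The hierarchy is a total order over the 16 class labels; rules are
#' evaluated top-down and the first match wins. The final two entries must
#' be the catch-all classes \code{mNOS} and \code{no_events}.
#'
#' @param path Optional YAML file with a top-level \code{hierarchy} list;
#'   defaults to the bundled order.
#' @return Character vector of class labels, rank 1 first.
#' @export
load_hierarchy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hierarchy.yaml",
                        package = "amlclass", mustWork = TRUE)
  }
  h <- yaml::read_yaml(path)$hierarchy
  h <- as.character(h)
  if (!setequal(h, aml_classes()) || length(h) != 16L) {
    stop("hierarchy must be a permutation of the 16 class labels")
  }
  if (!identical(h[15:16], c("mNOS", "no_events"))) {
    stop("hierarchy must end with mNOS, no_events")
  }
  h
}

#' Derived karyotype features
#'
#' Summary features of a coded karyotype used by the classification rules:
#' the number of unbalanced abnormalities, the number of trisomies
#' (whole-chromosome gains), whether any deletion or whole-chromosome loss
#' is present, complex-karyotype status (>= 3 unbalanced abnormalities, at
#' least one of which is not a whole-chromosome gain, so that pure-trisomy
#' karyotypes stay in the trisomy class), and monosomal-karyotype status
#' (>= 2 autosomal monosomies, or one autosomal monosomy plus at least one
#' structural abnormality).
#'
#' @param profile A [lesion_profile()], or a character vector of lesion
#'   codes.
#' @param vocab Lesion vocabulary.
#' @return List with \code{n_unbalanced}, \code{n_trisomies},
#'   \code{has_deletion} (deletion or whole-chromosome loss present),
#'   \code{is_complex}, \code{is_monosomal}.
#' @export
derived_karyotype_features <- function(profile,
                                       vocab = lesion_vocabulary()) {
  codes <- if (inherits(profile, "lesion_profile"))
    profile$cytogenetics else check_lesion_codes(profile, vocab)
  idx <- match(codes, vocab$code)
  cat_ <- vocab$category[idx]
  unb <- vocab$unbalanced[idx]
  n_unbalanced <- sum(unb)
  n_trisomies <- sum(cat_ == "gain")
  has_deletion <- any(cat_ %in% c("deletion", "loss"))
  is_complex <- n_unbalanced >= 3L && any(unb & cat_ != "gain")
  monosomies <- sum(vocab$autosomal_monosomy[idx])
  structural <- any(cat_ %in% c("deletion", "fusion", "other"))
  is_monosomal <- monosomies >= 2L || (monosomies == 1L && structural)
  list(n_unbalanced = n_unbalanced, n_trisomies = n_trisomies,
       has_deletion = has_deletion, is_complex = is_complex,
       is_monosomal = is_monosomal)
}

#' TP53 allelic state
#'
#' Annotates TP53 as wild-type, mono-allelic or multi-hit. Multi-hit
#' requires at least one of: (i) >= 2 TP53 mutations; (ii) >= 1 TP53
#' mutation with concomitant loss of the TP53 locus (del(17p), -17 or a
#' focal 17p deletion); (iii) >= 1 TP53 mutation at VAF > 65%, indicative
#' of loss of heterozygosity. Mono-allelic is a single mutation meeting no
#' multi-hit criterion. A missing VAF simply cannot trigger criterion (iii).
#'
#' @param mutations Mutation data.frame (only TP53 rows are used) or a
#'   [lesion_profile()].
#' @param cytogenetics Character vector of lesion codes (ignored when a
#'   profile is given).
#' @param vocab Lesion vocabulary.
#' @return One of \code{"wild_type"}, \code{"mono_allelic"},
#'   \code{"multi_hit"}.
#' @export
tp53_allelic_state <- function(mutations, cytogenetics = character(),
                               vocab = lesion_vocabulary()) {
  if (inherits(mutations, "lesion_profile")) {
    cytogenetics <- mutations$cytogenetics
    mutations <- mutations$mutations
  }
  tp53 <- mutations[mutations$gene == "TP53" & mutations$oncogenic, ,
                    drop = FALSE]
  n <- nrow(tp53)
  if (n == 0L) return("wild_type")
  locus_loss_codes <- vocab$code[vocab$tp53_locus_loss]
  loss <- any(cytogenetics %in% locus_loss_codes)
  high_vaf <- any(!is.na(tp53$vaf) & tp53$vaf > 0.65)
  if (n >= 2L || loss || high_vaf) "multi_hit" else "mono_allelic"
}

# ---------------------------------------------------------------------------
# Vectorised rule engine. Works on a feature list computed once per batch of
# profiles; classify_patient and classify_cohort share this path, and the
# exhaustive-enumeration checks drive it directly through
# classify_feature_table().

# Build the per-patient feature list from parallel logical matrices:
# cyto: n x nrow(vocab) logical (lesion present), columns named by code;
# muts: n x length(panel$genes) logical (>=1 oncogenic call), columns by gene;
# n_tp53, n_cebpa: integer vectors; mll_ptd: logical (oncogenic MLL PTD);
# tp53_vaf_gt65: logical; any_lesion: logical.
class_feature_list <- function(cyto, muts, n_cebpa, mll_ptd, panel,
                               vocab = lesion_vocabulary(),
                               any_mut = NULL) {
  stopifnot(identical(colnames(cyto), vocab$code))
  gidx <- function(g) if (g %in% colnames(muts))
    muts[, g] else rep(FALSE, nrow(muts))
  cat_ <- vocab$category
  unb <- vocab$unbalanced
  n_unbalanced <- as.integer(cyto %*% unb)
  n_gain <- as.integer(cyto %*% (cat_ == "gain"))
  non_gain_unb <- as.integer(cyto %*% (unb & cat_ != "gain")) > 0L
  has_del_loss <- as.integer(cyto %*% (cat_ %in% c("deletion", "loss"))) > 0L
  is_complex <- n_unbalanced >= 3L & non_gain_unb
  has <- function(code) cyto[, code]
  # count of distinct class-defining sAML genes (MLL only via PTD)
  plain_saml <- setdiff(panel$saml_genes, panel$ptd_only)
  plain_saml <- intersect(plain_saml, colnames(muts))
  n_saml <- if (length(plain_saml))
    as.integer(rowSums(muts[, plain_saml, drop = FALSE])) else
      integer(nrow(muts))
  ptd_saml <- intersect(panel$saml_genes, panel$ptd_only)
  if (length(ptd_saml)) n_saml <- n_saml + as.integer(mll_ptd)
  list(
    n = nrow(cyto),
    has = has,
    gene = gidx,
    n_saml = n_saml,
    n_cebpa = as.integer(n_cebpa),
    is_complex = is_complex,
    n_gain = n_gain,
    has_del_loss = has_del_loss,
    any_mut = if (is.null(any_mut)) rowSums(muts) > 0L | mll_ptd
      else any_mut,
    any_lesion = rowSums(cyto) > 0L
  )
}

# Predicate for each class label over a feature list; returns logical vector.
class_predicate <- function(label, f) {
  switch(label,
    APL_t15_17 = f$has("t(15;17)"),
    inv16      = f$has("inv(16)"),
    t8_21      = f$has("t(8;21)"),
    KMT2A_t11x = f$has("t(11;x)") | f$has("t(9;11)"),
    t6_9       = f$has("t(6;9)"),
    inv3       = f$has("inv(3)"),
    TP53_complex = f$gene("TP53") | f$is_complex,
    trisomies  = f$n_gain >= 1L & !f$has_del_loss,
    sAML2      = f$n_saml >= 2L,
    biCEBPA    = f$n_cebpa >= 2L,
    NPM1       = f$gene("NPM1"),
    sAML1      = f$n_saml == 1L,
    DNMT3A_IDH = f$gene("DNMT3A") & (f$gene("IDH1") | f$gene("IDH2")),
    WT1        = f$gene("WT1"),
    mNOS       = f$any_mut | f$any_lesion,
    no_events  = rep(TRUE, f$n),
    stop("unknown class label: ", label)
  )
}

# First-match classification over a feature list; returns
# data.frame(aml_class, rule_rank).
classify_feature_table <- function(f, hierarchy = load_hierarchy()) {
  rank <- rep(NA_integer_, f$n)
  for (r in seq_along(hierarchy)) {
    p <- class_predicate(hierarchy[r], f)
    rank[is.na(rank) & p] <- r
  }
  data.frame(aml_class = hierarchy[rank], rule_rank = rank,
             stringsAsFactors = FALSE)
}

# Build the logical matrices for a list of profiles.
profiles_to_features <- function(profiles, panel,
                                 vocab = lesion_vocabulary()) {
  n <- length(profiles)
  cyto <- matrix(FALSE, n, nrow(vocab),
                 dimnames = list(NULL, vocab$code))
  muts <- matrix(FALSE, n, length(panel$genes),
                 dimnames = list(NULL, panel$genes))
  n_cebpa <- integer(n)
  mll_ptd <- logical(n)
  any_onco <- logical(n)
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    if (length(p$cytogenetics)) cyto[i, p$cytogenetics] <- TRUE
    m <- p$mutations
    m <- m[m$oncogenic & m$gene %in% panel$genes, , drop = FALSE]
    if (nrow(m)) {
      # FLT3-ITD is never class-defining, not even for the mNOS
      # any-driver predicate
      any_onco[i] <- any(!(m$gene == "FLT3" & m$consequence == "itd"))
      muts[i, unique(m$gene)] <- TRUE
      n_cebpa[i] <- sum(m$gene == "CEBPA")
      mll_ptd[i] <- any(m$gene %in% panel$ptd_only &
                          m$consequence == "ptd")
      # ptd_only genes count as mutated only through PTD calls
      for (g in intersect(unique(m$gene), panel$ptd_only)) {
        muts[i, g] <- any(m$gene == g & m$consequence == "ptd")
      }
    }
  }
  class_feature_list(cyto, muts, n_cebpa, mll_ptd, panel, vocab,
                     any_mut = any_onco)
}

#' Classify a single patient
#'
#' Walks the hierarchy top-down and returns the first class whose rule
#' fires, together with its rank and the supporting evidence. Every
#' profile receives exactly one class; FLT3-ITD status never influences
#' the assignment (it is not class-defining).
#'
#' @param profile A [lesion_profile()].
#' @param panel Gene panel.
#' @param hierarchy Ordered class labels from [load_hierarchy()].
#' @param vocab Lesion vocabulary.
#' @return A list of class \code{class_assignment}: \code{patient_id},
#'   \code{aml_class}, \code{rule_rank}, \code{evidence} (character
#'   vector, empty only for \code{no_events}) and
#'   \code{karyotype_available}.
#' @export
#' @examples
#' p <- lesion_profile("pt1",
#'   mutations = mutation_calls(c("BCOR", "SF3B1")))
#' classify_patient(p)$aml_class  # "sAML2"
classify_patient <- function(profile, panel = load_panel(),
                             hierarchy = load_hierarchy(),
                             vocab = lesion_vocabulary()) {
  stopifnot(inherits(profile, "lesion_profile"))
  f <- profiles_to_features(list(profile), panel, vocab)
  res <- classify_feature_table(f, hierarchy)
  ev <- assignment_evidence(profile, res$aml_class[1], panel, vocab)
  structure(
    list(patient_id = profile$patient_id,
         aml_class = res$aml_class[1],
         rule_rank = res$rule_rank[1],
         evidence = ev,
         karyotype_available = profile$karyotype_available),
    class = "class_assignment")
}

# Lesions/mutations that satisfied the fired rule.
assignment_evidence <- function(profile, label, panel, vocab) {
  m <- profile$mutations
  m <- m[m$oncogenic & m$gene %in% panel$genes, , drop = FALSE]
  genes <- unique(m$gene)
  cyto <- profile$cytogenetics
  saml_ev <- function() {
    plain <- intersect(genes, setdiff(panel$saml_genes, panel$ptd_only))
    ptd <- unique(m$gene[m$gene %in% panel$ptd_only &
                           m$consequence == "ptd"])
    c(plain, if (length(ptd)) paste0(ptd, "-PTD"))
  }
  idx <- match(cyto, vocab$code)
  switch(label,
    APL_t15_17 = "t(15;17)",
    inv16 = "inv(16)",
    t8_21 = "t(8;21)",
    KMT2A_t11x = intersect(cyto, c("t(11;x)", "t(9;11)")),
    t6_9 = "t(6;9)",
    inv3 = "inv(3)",
    TP53_complex = c(if ("TP53" %in% genes) "TP53",
                     cyto[vocab$unbalanced[idx]]),
    trisomies = cyto[vocab$category[idx] == "gain"],
    sAML2 = saml_ev(),
    biCEBPA = rep("CEBPA", sum(m$gene == "CEBPA")),
    NPM1 = "NPM1",
    sAML1 = saml_ev(),
    DNMT3A_IDH = intersect(c("DNMT3A", "IDH1", "IDH2"), genes),
    WT1 = "WT1",
    mNOS = c(unique(m$gene[!(m$gene == "FLT3" &
                               m$consequence == "itd")]), cyto),
    no_events = character(),
    character()
  )
}

#' Classify a cohort
#'
#' @param cohort An \code{aml_cohort} or a list of [lesion_profile()]s.
#' @param panel Gene panel (taken from the cohort when present).
#' @param hierarchy Ordered class labels.
#' @param vocab Lesion vocabulary.
#' @return A list of class \code{cohort_classification} with
#'   \code{assignments} (data.frame: patient_id, aml_class, rule_rank,
#'   evidence) and \code{summary} (per-class counts and fractions over all
#'   16 labels; fractions sum to 1).
#' @export
classify_cohort <- function(cohort, panel = NULL,
                            hierarchy = load_hierarchy(),
                            vocab = lesion_vocabulary()) {
  profiles <- if (inherits(cohort, "aml_cohort")) cohort$profiles
    else cohort
  if (is.null(panel)) {
    panel <- if (inherits(cohort, "aml_cohort")) cohort$panel
      else load_panel()
  }
  if (!length(profiles)) {
    return(structure(list(
      assignments = data.frame(patient_id = character(),
                               aml_class = character(),
                               rule_rank = integer(),
                               evidence = character(),
                               stringsAsFactors = FALSE),
      summary = data.frame(aml_class = hierarchy, n = 0L,
                           fraction = NA_real_,
                           stringsAsFactors = FALSE)),
      class = "cohort_classification"))
  }
  f <- profiles_to_features(profiles, panel, vocab)
  res <- classify_feature_table(f, hierarchy)
  ev <- vapply(seq_along(profiles), function(i)
    paste(assignment_evidence(profiles[[i]], res$aml_class[i], panel,
                              vocab), collapse = ";"), "")
  assignments <- data.frame(
    patient_id = vapply(profiles, `[[`, "", "patient_id"),
    aml_class = res$aml_class,
    rule_rank = res$rule_rank,
    evidence = ev,
    stringsAsFactors = FALSE)
  counts <- table(factor(assignments$aml_class, levels = hierarchy))
  summary <- data.frame(aml_class = hierarchy,
                        n = as.integer(counts),
                        fraction = as.numeric(counts) / nrow(assignments),
                        stringsAsFactors = FALSE)
  structure(list(assignments = assignments, summary = summary),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat("Cohort classification,", nrow(x$assignments), "patients\n")
  print(x$summary[x$summary$n > 0, ], row.names = FALSE)
  invisible(x)
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(x$patient_id, "->", x$aml_class,
      sprintf("(rule %d;", x$rule_rank),
      if (length(x$evidence)) paste(x$evidence, collapse = ", ")
      else "no events", ")\n")
  invisible(x)
}
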