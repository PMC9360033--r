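#' Construct a per-patient lesion profile
#'
#' A lesion profile is the classifier's sole input: the set of oncogenic
#' mutation calls plus coded cytogenetic abnormalities for one patient.
#' FLT3-ITD and NPM1 flags are derived from the mutation set; an ITD
#' allelic ratio may be attached but never influences class assignment.
#'
#' @param patient_id Patient identifier.
#' @param mutations A data.frame of mutation calls with columns
#'   \code{gene}, \code{vaf} (fraction in \[0,1\] or NA),
#'   \code{consequence} (one of substitution, indel, splice, itd, ptd)
#'   and \code{oncogenic} (logical). May have zero rows.
#' @param cytogenetics Character vector of coded lesions from the
#'   controlled vocabulary; empty means normal karyotype when
#'   \code{karyotype_available} is TRUE.
#' @param karyotype_available Whether a karyotype was assessable.
#' @param flt3_itd_ratio Optional FLT3-ITD allelic ratio (nonnegative).
#' @param vocab Lesion vocabulary used to validate codes.
#' @return A \code{lesion_profile} object.
#' @export
lesion_profile <- function(patient_id,
                           mutations = empty_mutations(),
                           cytogenetics = character(),
                           karyotype_available = TRUE,
                           flt3_itd_ratio = NA_real_,
                           vocab = lesion_vocabulary()) {
  mutations <- validate_mutations(mutations)
  cytogenetics <- check_lesion_codes(cytogenetics, vocab)
  flt3_itd <- any(mutations$gene == "FLT3" &
                    mutations$consequence == "itd" & mutations$oncogenic)
  npm1 <- any(mutations$gene == "NPM1" & mutations$oncogenic)
  if (!is.na(flt3_itd_ratio) && flt3_itd_ratio < 0) {
    stop("flt3_itd_ratio must be nonnegative")
  }
  structure(
    list(patient_id = as.character(patient_id),
         mutations = mutations,
         cytogenetics = cytogenetics,
         karyotype_available = isTRUE(karyotype_available),
         flt3_itd = flt3_itd,
         flt3_itd_ratio = flt3_itd_ratio,
         npm1 = npm1),
    class = "lesion_profile"
  )
}

#' Empty mutation table with the canonical columns
#' @return Zero-row mutation data.frame.
#' @export
empty_mutations <- function() {
  data.frame(gene = character(), vaf = numeric(),
             consequence = character(), oncogenic = logical(),
             stringsAsFactors = FALSE)
}

#' Build a mutation-call table from vectors
#'
#' @param gene Gene symbols.
#' @param vaf Variant allele fractions in \[0,1\], NA allowed.
#' @param consequence One of substitution, indel, splice, itd, ptd.
#' @param oncogenic Logical; only oncogenic calls are class-defining.
#' @return A mutation data.frame suitable for [lesion_profile()].
#' @export
mutation_calls <- function(gene, vaf = NA_real_,
                           consequence = "substitution",
                           oncogenic = TRUE) {
  validate_mutations(data.frame(gene = gene, vaf = vaf,
                                consequence = consequence,
                                oncogenic = oncogenic,
                                stringsAsFactors = FALSE))
}

.consequences <- c("substitution", "indel", "splice", "itd", "ptd")

validate_mutations <- function(mutations) {
  required <- c("gene", "vaf", "consequence", "oncogenic")
  missing <- setdiff(required, names(mutations))
  if (length(missing)) {
    stop("mutation table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  mutations <- mutations[required]
  mutations$vaf <- as.numeric(mutations$vaf)
  bad_vaf <- !is.na(mutations$vaf) &
    (mutations$vaf < 0 | mutations$vaf > 1)
  if (any(bad_vaf)) stop("vaf outside [0,1]")
  bad_cons <- !mutations$consequence %in% .consequences
  if (any(bad_cons)) {
    stop("unknown consequence value(s): ",
         paste(unique(mutations$consequence[bad_cons]), collapse = ", "))
  }
  mutations$oncogenic <- as.logical(mutations$oncogenic)
  mutations
}

#' @export
print.lesion_profile <- function(x, ...) {
  cat("Lesion profile", x$patient_id, "\n")
  cat("  mutations:",
      if (nrow(x$mutations)) paste(x$mutations$gene, collapse = ", ")
      else "(none)", "\n")
  cat("  cytogenetics:",
      if (length(x$cytogenetics)) paste(x$cytogenetics, collapse = ", ")
      else if (x$karyotype_available) "normal" else "not available", "\n")
  if (x$flt3_itd) cat("  FLT3-ITD present\n")
  invisible(x)
}
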