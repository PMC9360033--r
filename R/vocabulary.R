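#' Controlled vocabulary of coded cytogenetic lesions
#'
#' Cytogenetic findings are consumed as pre-coded lesion tokens from a
#' controlled vocabulary rather than free-text ISCN karyotype strings.
#' Every code maps to exactly one category (fusion, gain, loss, deletion,
#' other); gains, losses and deletions are unbalanced abnormalities while
#' reciprocal translocations and inversions are balanced.
#'
#' @param path Optional path to a tab-separated vocabulary file with
#'   columns \code{code}, \code{category}, \code{unbalanced},
#'   \code{autosomal_monosomy}, \code{tp53_locus_loss}. Defaults to the
#'   bundled vocabulary.
#' @return A data.frame, one row per lesion code.
#' @export
lesion_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lesion_vocabulary.tsv",
                        package = "amlclass", mustWork = TRUE)
  }
  vocab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  required <- c("code", "category", "unbalanced",
                "autosomal_monosomy", "tp53_locus_loss")
  missing <- setdiff(required, names(vocab))
  if (length(missing)) {
    stop("lesion vocabulary is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  vocab$unbalanced <- as.logical(vocab$unbalanced)
  vocab$autosomal_monosomy <- as.logical(vocab$autosomal_monosomy)
  vocab$tp53_locus_loss <- as.logical(vocab$tp53_locus_loss)
  bad <- vocab$category %in% c("gain", "loss", "deletion") & !vocab$unbalanced
  if (any(bad)) {
    stop("gain/loss/deletion codes must be unbalanced: ",
         paste(vocab$code[bad], collapse = ", "))
  }
  if (anyDuplicated(vocab$code)) {
    stop("duplicate lesion codes in vocabulary")
  }
  vocab
}

#' Validate a set of lesion codes against the vocabulary
#'
#' @param codes Character vector of lesion codes.
#' @param vocab Vocabulary data.frame from [lesion_vocabulary()].
#' @return The deduplicated codes, invisibly erroring on unknown codes.
#' @keywords internal
check_lesion_codes <- function(codes, vocab = lesion_vocabulary()) {
  codes <- unique(codes[!is.na(codes) & nzchar(codes)])
  unknown <- setdiff(codes, vocab$code)
  if (length(unknown)) {
    stop("unknown lesion code(s): ", paste(unknown, collapse = ", "))
  }
  codes
}
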