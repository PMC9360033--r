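#' Read a cohort from mutation, cytogenetics and clinical tables
#'
#' Joins three tab-separated tables into one record per patient. The
#' clinical table drives the patient universe: patients present there but
#' absent from the mutation table get empty mutation sets. Mutation rows
#' for genes outside the panel are skipped with a warning; unknown lesion
#' codes are rejected with the offending row identified.
#'
#' Expected schemas (tab-separated, header row):
#' \describe{
#'   \item{mutations}{\code{patient_id}, \code{gene}, \code{vaf},
#'     \code{consequence}, \code{oncogenic}}
#'   \item{cytogenetics}{\code{patient_id}, \code{lesions}
#'     (comma-separated codes; empty = normal karyotype),
#'     \code{karyotype_available}}
#'   \item{clinical}{\code{patient_id}, \code{age_years}, \code{sex},
#'     \code{wbc}, \code{hb}, \code{platelets}, \code{bm_blast_pct},
#'     \code{ahd}, \code{performance_status}, \code{disease_type},
#'     \code{flt3_itd_ratio}, \code{t_cr}, \code{t_relapse},
#'     \code{t_last}, \code{dead}}
#' }
#' Times are in years from diagnosis.
#'
#' @param mutations_path,cytogenetics_path,clinical_path File paths.
#' @param panel Gene panel from [load_panel()].
#' @param vocab Lesion vocabulary from [lesion_vocabulary()].
#' @return An \code{aml_cohort}: list with \code{profiles} (named list of
#'   [lesion_profile()]), \code{clinical} (data.frame), \code{outcomes}
#'   (data.frame with \code{patient_id}, \code{t_cr}, \code{t_relapse},
#'   \code{t_last}, \code{dead}) and \code{panel}.
#' @export
read_cohort <- function(mutations_path, cytogenetics_path, clinical_path,
                        panel = load_panel(),
                        vocab = lesion_vocabulary()) {
  muts <- read_table_checked(mutations_path,
                             c("patient_id", "gene", "vaf",
                               "consequence", "oncogenic"))
  cyto <- read_table_checked(cytogenetics_path,
                             c("patient_id", "lesions",
                               "karyotype_available"))
  clin <- read_table_checked(clinical_path,
                             c("patient_id", "age_years", "sex", "wbc",
                               "hb", "platelets", "bm_blast_pct", "ahd",
                               "performance_status", "disease_type",
                               "flt3_itd_ratio", "t_cr", "t_relapse",
                               "t_last", "dead"))
  if (anyDuplicated(clin$patient_id)) {
    stop("duplicate patient_id in clinical table: ",
         paste(unique(clin$patient_id[duplicated(clin$patient_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(cyto$patient_id)) {
    stop("duplicate patient_id in cytogenetics table: ",
         paste(unique(cyto$patient_id[duplicated(cyto$patient_id)]),
               collapse = ", "))
  }
  off_panel <- !muts$gene %in% panel$genes
  if (any(off_panel)) {
    warning("skipping ", sum(off_panel),
            " mutation row(s) for gene(s) outside the panel: ",
            paste(unique(muts$gene[off_panel]), collapse = ", "))
    muts <- muts[!off_panel, , drop = FALSE]
  }
  ids <- as.character(clin$patient_id)
  cyto_idx <- match(ids, as.character(cyto$patient_id))
  profiles <- vector("list", length(ids))
  names(profiles) <- ids
  mut_split <- split(muts, factor(as.character(muts$patient_id),
                                  levels = ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    pm <- mut_split[[id]]
    if (is.null(pm) || !nrow(pm)) pm <- empty_mutations() else
      pm <- pm[c("gene", "vaf", "consequence", "oncogenic")]
    lesions <- character()
    kavail <- TRUE
    ci <- cyto_idx[i]
    if (!is.na(ci)) {
      kavail <- as.logical(cyto$karyotype_available[ci])
      raw <- cyto$lesions[ci]
      if (!is.na(raw) && nzchar(trimws(raw))) {
        lesions <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
      }
      lesions <- tryCatch(
        check_lesion_codes(lesions, vocab),
        error = function(e) stop("cytogenetics row for patient ", id,
                                 ": ", conditionMessage(e)))
    } else {
      kavail <- FALSE
    }
    profiles[[i]] <- lesion_profile(
      id, mutations = pm, cytogenetics = lesions,
      karyotype_available = kavail,
      flt3_itd_ratio = as.numeric(clin$flt3_itd_ratio[i]),
      vocab = vocab)
  }
  outcomes <- data.frame(
    patient_id = ids,
    t_cr = as.numeric(clin$t_cr),
    t_relapse = as.numeric(clin$t_relapse),
    t_last = as.numeric(clin$t_last),
    dead = as.logical(clin$dead),
    stringsAsFactors = FALSE)
  clinical <- clin[setdiff(names(clin),
                           c("t_cr", "t_relapse", "t_last", "dead"))]
  structure(list(profiles = profiles, clinical = clinical,
                 outcomes = outcomes, panel = panel),
            class = "aml_cohort")
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("table ", basename(path), " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' Write a cohort back to the three-table layout
#'
#' Inverse of [read_cohort()]: emits mutations.tsv, cytogenetics.tsv and
#' clinical.tsv into a directory so that re-reading reproduces the lesion
#' and mutation sets exactly.
#'
#' @param cohort An \code{aml_cohort}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aml_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mut_rows <- lapply(cohort$profiles, function(p) {
    if (!nrow(p$mutations)) return(NULL)
    cbind(patient_id = p$patient_id, p$mutations)
  })
  muts <- do.call(rbind, mut_rows)
  if (is.null(muts)) {
    muts <- cbind(patient_id = character(), empty_mutations())
  }
  cyto <- data.frame(
    patient_id = vapply(cohort$profiles, `[[`, "", "patient_id"),
    lesions = vapply(cohort$profiles,
                     function(p) paste(p$cytogenetics, collapse = ","),
                     ""),
    karyotype_available = vapply(cohort$profiles, `[[`, TRUE,
                                 "karyotype_available"),
    stringsAsFactors = FALSE)
  clin <- merge(cohort$clinical, cohort$outcomes, by = "patient_id",
                sort = FALSE)
  paths <- file.path(dir, c("mutations.tsv", "cytogenetics.tsv",
                            "clinical.tsv"))
  utils::write.table(muts, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(cyto, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(clin, paths[3], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Export joined cohort records as JSON
#'
#' @param cohort An \code{aml_cohort}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
cohort_to_json <- function(cohort, path) {
  stopifnot(inherits(cohort, "aml_cohort"))
  recs <- lapply(cohort$profiles, function(p) {
    i <- match(p$patient_id, cohort$clinical$patient_id)
    list(patient_id = p$patient_id,
         mutations = p$mutations,
         cytogenetics = p$cytogenetics,
         karyotype_available = p$karyotype_available,
         flt3_itd = p$flt3_itd,
         npm1 = p$npm1,
         clinical = as.list(cohort$clinical[i, , drop = FALSE]),
         outcomes = as.list(cohort$outcomes[i, , drop = FALSE]))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @export
print.aml_cohort <- function(x, ...) {
  cat("AML cohort:", length(x$profiles), "patients\n")
  invisible(x)
}
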