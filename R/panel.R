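#' Load a gene panel
#'
#' The classifier operates over a fixed mutation panel. The bundled default
#' has 32 genes, 11 of which are the secondary-AML-like (sAML)
#' class-defining features: SRSF2, SF3B1, U2AF1, ZRSR2, ASXL1, EZH2, BCOR,
#' STAG2, RUNX1, SETBP1 and MLL-PTD. MLL is flagged \code{ptd_only}: only
#' partial-tandem-duplication calls in MLL count as the class-defining
#' feature.
#'
#' @param path Optional path to a tab-separated panel file with columns
#'   \code{gene}, \code{saml_class_defining}, \code{ptd_only}. Defaults to
#'   the bundled 32-gene panel.
#' @return An object of class \code{aml_gene_panel}: a list with elements
#'   \code{genes} (ordered character vector), \code{saml_genes} (the
#'   class-defining subset) and \code{ptd_only} (genes whose class-defining
#'   status requires a PTD consequence).
#' @export
#' @examples
#' panel <- load_panel()
#' length(panel$genes)       # 32
#' length(panel$saml_genes)  # 11
load_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_panel.tsv",
                        package = "amlclass", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  required <- c("gene", "saml_class_defining", "ptd_only")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("panel file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab$saml_class_defining <- as.logical(tab$saml_class_defining)
  tab$ptd_only <- as.logical(tab$ptd_only)
  if (anyDuplicated(tab$gene)) stop("duplicate gene symbols in panel")
  panel <- structure(
    list(genes = tab$gene,
         saml_genes = tab$gene[tab$saml_class_defining],
         ptd_only = tab$gene[tab$ptd_only]),
    class = "aml_gene_panel"
  )
  validate_panel(panel)
  panel
}

#' Construct a gene panel in code
#'
#' @param genes Ordered character vector of gene symbols.
#' @param saml_genes Class-defining sAML subset; must be contained in
#'   \code{genes}.
#' @param ptd_only Genes counted as class-defining only via PTD calls.
#' @return An \code{aml_gene_panel}.
#' @export
gene_panel <- function(genes, saml_genes, ptd_only = character()) {
  panel <- structure(
    list(genes = genes, saml_genes = saml_genes, ptd_only = ptd_only),
    class = "aml_gene_panel"
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  out <- setdiff(panel$saml_genes, panel$genes)
  if (length(out)) {
    stop("sAML class-defining gene(s) not in panel: ",
         paste(out, collapse = ", "))
  }
  invisible(panel)
}

#' @export
print.aml_gene_panel <- function(x, ...) {
  cat("AML gene panel:", length(x$genes), "genes,",
      length(x$saml_genes), "sAML class-defining\n")
  invisible(x)
}
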