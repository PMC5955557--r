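#' Kinase subfamily-to-group catalog
#'
#' Plant kinomes are conventionally partitioned into seven groups (RLK, AGC,
#' CAMK, CMGC, STE, TKL and "other"), each containing many subfamilies named
#' after the profile-HMM library used to classify them. The catalog maps each
#' subfamily name to its group. A default catalog covering the subfamilies
#' used throughout this package ships with the package and can be replaced by
#' any two-column table.
#'
#' @param path Path to a tab-separated file with columns `subfamily` and
#'   `group`. Defaults to the catalog bundled with the package.
#' @return A tibble with columns `subfamily` and `group`.
#' @export
#' @examples
#' head(subfamily_catalog())
subfamily_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "subfamily_groups.tsv", package = "kinomevo")
  cat <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("subfamily", "group") %in% names(cat))) {
    abort("catalog must have columns 'subfamily' and 'group'")
  }
  bad <- setdiff(unique(cat$group), kinase_groups())
  if (length(bad) > 0) {
    abort(paste0("unknown kinase group(s) in catalog: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(cat$subfamily)) abort("duplicate subfamily names in catalog")
  tibble::as_tibble(cat[, c("subfamily", "group")])
}

#' The seven kinase group names
#'
#' @return Character vector of the seven recognised kinase groups.
#' @export
kinase_groups <- function() {
  c("RLK", "AGC", "CAMK", "CMGC", "STE", "TKL", "other")
}
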