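#' Parse phosphosite identifiers
#'
#' Site identifiers use the machine-readable dialect `"PROTEIN_S123"`:
#' the protein accession, an underscore, the phosphorylated residue
#' (serine `S`, threonine `T` or tyrosine `Y`) and its 1-based sequence
#' position. `format_site_key()` is the exact inverse.
#'
#' @param x Character vector of site identifiers.
#' @return A data.frame with columns `site`, `protein_id`, `residue`
#'   and `position`.
#' @examples
#' parse_site_key("RPS6_S235")
#' @export
parse_site_key <- function(x) {
  if (!is.character(x)) stop2("site keys must be character")
  m <- regmatches(x, regexec("^(.+)_([A-Za-z])([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop2("malformed site key(s): ", paste(utils::head(x[bad], 5), collapse = ", "))
  }
  protein_id <- vapply(m, `[[`, "", 2L)
  residue <- vapply(m, `[[`, "", 3L)
  position <- as.integer(vapply(m, `[[`, "", 4L))
  if (any(!residue %in% c("S", "T", "Y"))) {
    stop2("residue must be one of S, T, Y: ",
          paste(unique(x[!residue %in% c("S", "T", "Y")]), collapse = ", "))
  }
  if (any(position < 1L)) stop2("site position must be >= 1")
  data.frame(site = x, protein_id = protein_id, residue = residue,
             position = position, stringsAsFactors = FALSE)
}

#' @rdname parse_site_key
#' @param protein_id,residue,position Components of the key.
#' @export
format_site_key <- function(protein_id, residue, position) {
  if (any(!residue %in% c("S", "T", "Y"))) stop2("residue must be one of S, T, Y")
  if (any(position < 1)) stop2("site position must be >= 1")
  paste0(protein_id, "_", residue, position)
}

#' Class-I phosphosite call
#'
#' A site is "class I" when its localization probability exceeds 0.75,
#' the conventional cut-off for confidently localized phosphosites.
#'
#' @param localization_prob Numeric vector of localization probabilities
#'   in `[0, 1]`.
#' @return Logical vector; `NA` probabilities give `FALSE`.
#' @export
is_class_one <- function(localization_prob) {
  if (any(localization_prob < 0 | localization_prob > 1, na.rm = TRUE)) {
    stop2("localization probabilities must lie in [0, 1]")
  }
  !is.na(localization_prob) & localization_prob > 0.75
}
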