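#' Build SNP panels against a marker map
#'
#' Each panel is the intersection of a requested SNP-id list with the
#' (QC-retained) map, order preserved.  With `nested = TRUE` the panels
#' must satisfy low panel is a subset of every higher panel (panels are
#' given from lowest to highest density).
#'
#' @param gd a [GenotypeData] (or a character vector of retained SNP ids).
#' @param definitions named list of SNP-id character vectors, lowest
#'   density first.
#' @param nested verify nesting.
#' @return list of [PanelDef]s.
#' @export
buildPanels <- function(gd, definitions, nested = FALSE) {
  retained <- if (is.character(gd)) gd else snpIds(gd)
  if (!length(definitions)) stop("no panel definitions")
  panels <- lapply(seq_along(definitions), function(i) {
    ids <- definitions[[i]]
    if (!length(ids)) stop("empty panel definition")
    kept <- ids[ids %in% retained]
    if (!length(kept))
      stop("panel '", names(definitions)[i] %||% i,
           "' is empty after intersecting with the map")
    PanelDef(names(definitions)[i] %||% paste0("panel", i), kept)
  })
  if (nested && length(panels) > 1) {
    for (i in seq_len(length(panels) - 1)) {
      if (!all(panels[[i]]@snps %in% panels[[i + 1]]@snps))
        stop("panels are not nested: '", panels[[i]]@name,
             "' is not a subset of '", panels[[i + 1]]@name, "'")
    }
  }
  panels
}

#' Evenly spaced nested panels
#'
#' Convenience constructor for simulation studies: the highest-density
#' panel takes every retained SNP, and each lower panel takes an evenly
#' spaced subset of the next denser one, guaranteeing nesting by
#' construction (mirroring commercial low-density chips designed as
#' subsets of denser products).
#'
#' @param gd a [GenotypeData] (or character vector of SNP ids in map order).
#' @param sizes named integer vector of panel sizes, lowest first; the last
#'   entry may be `NA` meaning "all SNPs".
#' @return list of [PanelDef]s, lowest density first.
#' @export
nestedPanels <- function(gd, sizes) {
  ids <- if (is.character(gd)) gd else snpIds(gd)
  sizes <- rev(sizes)   # build from densest down
  panels <- vector("list", length(sizes))
  cur <- ids
  for (i in seq_along(sizes)) {
    n <- sizes[[i]]
    if (!is.na(n)) {
      if (n > length(cur)) stop("panel size exceeds available SNPs")
      cur <- cur[unique(round(seq(1, length(cur), length.out = n)))]
    }
    panels[[i]] <- PanelDef(names(sizes)[i] %||% paste0("panel", i), cur)
  }
  rev(panels)
}

#' Mask genotypes down to a panel
#'
#' Sets every SNP outside the panel to missing while keeping the full SNP
#' frame (set and order unchanged), so that true and imputed matrices stay
#' aligned and downstream imputers see the untyped loci.  Masking is
#' idempotent.
#'
#' @param gd a [GenotypeData].
#' @param panel a [PanelDef]; every panel SNP must be present in `gd`.
#' @return A [GenotypeData] with identical frame and masked entries.
#' @export
maskToPanel <- function(gd, panel) {
  stopifnot(is(gd, "GenotypeData"), is(panel, "PanelDef"))
  absent <- setdiff(panel@snps, snpIds(gd))
  if (length(absent))
    stop("panel SNPs absent from genotypes: ",
         paste(head(absent, 5), collapse = ", "))
  d <- dosages(gd)
  d[!(rownames(d) %in% panel@snps), ] <- NA_integer_
  GenotypeData(d, markerMapFrame(gd))
}
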