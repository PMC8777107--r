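#' Assay coverage geometry
#'
#' The inverse-PCR single-molecule assay reads the interior of a cfDNA
#' fragment between its two targeting primers, so coverage is bounded by the
#' typical cfDNA fragment length minus twice the primer length; primers placed
#' in the flanking introns extend coverage into the exon-proximal intronic
#' sequence by their offset from the exon-intron boundary.
#'
#' @param mean_fragment_bp mean cfDNA fragment length in bp (default 166).
#' @param mean_primer_bp mean primer length in bp (default 21).
#' @param mean_primer_offset_bp mean primer distance from the exon-intron
#'   boundary in bp (default 55).
#' @return list of class `assay_geometry`.
#' @export
assay_geometry <- function(mean_fragment_bp = 166, mean_primer_bp = 21,
                           mean_primer_offset_bp = 55) {
  if (mean_fragment_bp <= 0 || mean_primer_bp <= 0 ||
      mean_primer_offset_bp < 0)
    stop_with("csmart_parameter_error", "geometry lengths must be positive")
  if (mean_fragment_bp <= 2 * mean_primer_bp)
    stop_with("csmart_parameter_error",
              "fragment must be longer than two primers")
  structure(list(mean_fragment_bp = mean_fragment_bp,
                 mean_primer_bp = mean_primer_bp,
                 mean_primer_offset_bp = mean_primer_offset_bp),
            class = "assay_geometry")
}

#' Maximum insert length covered by one primer pair
#'
#' `mean_fragment_bp - 2 * mean_primer_bp`: with the defaults,
#' 166 - 2*21 = 124 bp.
#'
#' @param geometry an [assay_geometry()].
#' @return length in bp.
#' @export
max_covered_insert <- function(geometry = assay_geometry()) {
  stopifnot(inherits(geometry, "assay_geometry"))
  geometry$mean_fragment_bp - 2 * geometry$mean_primer_bp
}

#' Maximum exon-proximal flanking coverage
#'
#' `mean_primer_offset_bp + mean_fragment_bp - 2 * mean_primer_bp`: with the
#' defaults, 55 + 166 - 42 = 179 bp of flanking intron reachable.
#'
#' @param geometry an [assay_geometry()].
#' @return length in bp.
#' @export
max_flank_coverage <- function(geometry = assay_geometry()) {
  stopifnot(inherits(geometry, "assay_geometry"))
  geometry$mean_primer_offset_bp + max_covered_insert(geometry)
}
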