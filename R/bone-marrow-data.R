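#' Published per-class counts of the combined bone-marrow cytology dataset
#'
#' Per cell-type image counts of a combined three-source single-cell dataset:
#' a bone-marrow aspirate smear collection from a clinical laboratory
#' (source 1), a peripheral-blood single-cell collection (source 2), and a
#' bone-marrow smear collection from an AML imaging archive (source 3) —
#' 19 source cell types in total. The counts let all manifest arithmetic
#' (multi-source combination, cell-family merging, class-balancing deficits)
#' be reproduced without the image files themselves.
#'
#' @return A tibble with `label`, `source` (`"1"`, `"2"`, `"3"`) and `n`;
#'   combinations absent from a source are omitted.
#' @seealso [bone_marrow_manifest()] to expand the counts into a manifest.
#' @export
bone_marrow_counts <- function() {
  tab <- dplyr::tribble(
    ~label,                  ~s1,   ~s2,  ~s3,
    "basophil",               570,  420,  234,
    "eosinophil",            1061, 1356, 1121,
    "erythroblast",           540,  500,  507,
    "immature_granulocytes", 1266, 1615,   NA,
    "lymphocyte",              NA, 1213,   NA,
    "lymphocyte_atypical",      4,   NA,    3,
    "lymphocyte_typical",    1790,   NA, 2028,
    "metamyelocyte",            8,   NA,    5,
    "monoblast",               14,   NA,   12,
    "monocyte",               912, 1013,  658,
    "myeloblast",            1246,   NA, 1858,
    "myelocyte",               22,   NA,   17,
    "neutrophil",              NA, 3316,   NA,
    "neutrophil_band",         42,   NA,   40,
    "neutrophil_segmented",  3588,   NA, 3758,
    "platelet",              1650,  689,   NA,
    "promyelocyte",            26,   NA,   43,
    "promyelocyte_bilobed",    10,   NA,    8,
    "smudge_cells",             7,   NA,    8
  )
  long <- tidyr::pivot_longer(tab, cols = c("s1", "s2", "s3"),
                              names_to = "source", values_to = "n")
  long <- dplyr::filter(long, !is.na(.data$n))
  long$source <- sub("^s", "", long$source)
  long$n <- as.integer(long$n)
  long
}

#' Expand class counts into a count-only manifest
#'
#' Each (label, source) count becomes that many records with `path = NA` and
#' a stable synthetic id (`src<source>_<label>_<k>`), so that manifest
#' operations (merging, exclusion, splitting, deficits) run on the published
#' dataset composition without image files.
#'
#' @param counts A tibble with `label`, `source`, `n`; defaults to
#'   [bone_marrow_counts()].
#' @return A manifest tibble with one row per image.
#' @export
bone_marrow_manifest <- function(counts = bone_marrow_counts()) {
  rows <- tidyr::uncount(counts, weights = .data$n, .id = "k")
  rows$id <- sprintf("src%s_%s_%05d", rows$source, rows$label, rows$k)
  rows$path <- NA_character_
  as_manifest(rows[, c("id", "path", "label", "source")])
}

#' Expert-review exclusions for the combined bone-marrow dataset
#'
#' After cell-family merging, the published post-preprocessing neutrophil
#' count is one image short of the sum of its source counts: expert review
#' removed a single neutrophil record. Which physical image was removed is
#' not recoverable from the publication, so the exclusion names one
#' (synthetic-id) segmented-neutrophil record.
#'
#' @return Character vector of record ids to exclude.
#' @export
bone_marrow_exclusions <- function() {
  "src3_neutrophil_segmented_03758"
}

#' Reproduce the published post-preprocessing class composition
#'
#' Expands the published source counts, merges cell families with the
#' default taxonomy and applies the expert-review exclusion, yielding the
#' 12-family composition of the combined dataset (33,177 images).
#'
#' @return A manifest tibble with merged labels.
#' @export
bone_marrow_preprocessed <- function() {
  m <- bone_marrow_manifest()
  m <- dedupe(m, exclusions = bone_marrow_exclusions())
  merge_cell_types(m, default_merge_taxonomy())
}
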