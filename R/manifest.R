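#' Image manifests
#'
#' A manifest is a tibble with one row per single-cell image and columns
#' `id` (stable record identifier), `path` (image file, `NA` for count-only
#' manifests), `label` (cell type), `source` (dataset identifier) and
#' `split` (`"train"`, `"val"`, `"test"` or `"unassigned"`). All
#' manifest-level operations are plain data-frame transformations, so
#' manifests compose with dplyr verbs.
#'
#' @param records A data frame with at least `path`, `label` and `source`
#'   columns; `id` and `split` are filled in when absent.
#' @return A tibble with the five manifest columns.
#' @export
#' @examples
#' as_manifest(data.frame(path = "a.png", label = "basophil", source = "1"))
as_manifest <- function(records) {
  records <- as_tibble(records)
  required <- c("path", "label", "source")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop_input(paste0("manifest is missing column(s): ", paste(missing, collapse = ", ")),
               "cytosynth_format_error")
  }
  if (!"split" %in% names(records)) records$split <- "unassigned"
  if (!"id" %in% names(records)) {
    records$id <- ifelse(is.na(records$path),
                         sprintf("rec%06d", seq_len(nrow(records))),
                         as.character(records$path))
  }
  records$label <- as.character(records$label)
  records$source <- as.character(records$source)
  bad <- setdiff(unique(records$split), c("train", "val", "test", "unassigned", "synthetic"))
  if (length(bad) > 0) {
    stop_input(paste0("unknown split value(s): ", paste(bad, collapse = ", ")),
               "cytosynth_format_error")
  }
  dplyr::select(records, "id", "path", "label", "source", "split")
}

#' Read image manifests from delimited files
#'
#' Each file must be a comma-separated table with columns `path,label,source`
#' (optionally `split`). Records are concatenated across files in order.
#'
#' @param paths Character vector of manifest CSV files.
#' @param taxonomy Optional [merge_taxonomy()]; with `strict = TRUE`, labels
#'   absent from the taxonomy raise an error.
#' @param strict Enforce taxonomy membership of every label.
#' @return A manifest tibble (zero rows for an empty `paths`).
#' @export
load_manifest <- function(paths, taxonomy = NULL, strict = FALSE) {
  if (length(paths) == 0) {
    return(as_manifest(tibble(path = character(), label = character(),
                              source = character())))
  }
  tabs <- lapply(paths, function(p) {
    tab <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    missing <- setdiff(c("path", "label", "source"), names(tab))
    if (length(missing) > 0) {
      stop_input(sprintf("manifest '%s' is missing column(s): %s", p,
                         paste(missing, collapse = ", ")), "cytosynth_format_error")
    }
    tab
  })
  m <- as_manifest(dplyr::bind_rows(tabs))
  # re-key: identical paths from different files must stay distinct records
  m$id <- sprintf("%s#%04d", m$id, seq_len(nrow(m)))
  if (strict && !is.null(taxonomy)) {
    known <- taxonomy_labels(taxonomy)
    unknown <- setdiff(unique(m$label), known)
    if (length(unknown) > 0) {
      stop_input(paste0("label(s) not in taxonomy: ", paste(unknown, collapse = ", ")),
                 "cytosynth_taxonomy_error")
    }
  }
  m
}

#' Write a manifest to CSV
#' @param manifest A manifest tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(as_manifest(manifest)[, c("path", "label", "source", "split")], path)
  invisible(path)
}

#' Per-class image counts
#' @param manifest A manifest tibble.
#' @return A tibble with `label` and `n`, sorted by label.
#' @export
class_counts <- function(manifest) {
  dplyr::arrange(dplyr::count(as_manifest(manifest), .data$label), .data$label)
}

#' Cell-family merge taxonomy
#'
#' Maps source cell-type labels onto merged cell families. Every source label
#' must belong to exactly one group; labels listed in `passthrough` map to
#' themselves.
#'
#' @param groups Named list: merged label -> character vector of source labels.
#' @param passthrough Labels mapped to themselves.
#' @return An object of class `merge_taxonomy`.
#' @seealso [default_merge_taxonomy()] for the bone-marrow cytology rules.
#' @export
merge_taxonomy <- function(groups = list(), passthrough = character()) {
  groups <- c(groups, setNames(as.list(passthrough), passthrough))
  all_sources <- unlist(groups, use.names = FALSE)
  dup <- unique(all_sources[duplicated(all_sources)])
  if (length(dup) > 0) {
    stop_input(paste0("source label(s) in more than one group: ",
                      paste(dup, collapse = ", ")), "cytosynth_taxonomy_error")
  }
  if (anyDuplicated(names(groups))) {
    stop_input("duplicated merged label", "cytosynth_taxonomy_error")
  }
  structure(list(groups = groups), class = "merge_taxonomy")
}

#' @export
print.merge_taxonomy <- function(x, ...) {
  cat("<merge_taxonomy>", length(x$groups), "merged labels,",
      length(taxonomy_labels(x)), "source labels\n")
  invisible(x)
}

#' Source labels known to a taxonomy
#' @param taxonomy A [merge_taxonomy()].
#' @return Character vector of source labels.
#' @export
taxonomy_labels <- function(taxonomy) {
  unlist(taxonomy$groups, use.names = FALSE)
}

# named vector: source label -> merged label
taxonomy_map <- function(taxonomy) {
  map <- rep(names(taxonomy$groups), lengths(taxonomy$groups))
  names(map) <- unlist(taxonomy$groups, use.names = FALSE)
  map
}

#' Default cell-family merging rules for bone-marrow cytology
#'
#' Lymphocyte variants (typical/atypical), neutrophil maturation stages
#' (band/segmented), bilobed promyelocytes and the immature granulocyte
#' stages (myelocyte, metamyelocyte) are each collapsed into a single cell
#' family; all remaining cell types pass through unchanged, reducing the 19
#' combined source labels to 12 families.
#'
#' @param extra_passthrough Additional labels to map to themselves.
#' @return A [merge_taxonomy()].
#' @export
default_merge_taxonomy <- function(extra_passthrough = character()) {
  merge_taxonomy(
    groups = list(
      lymphocyte = c("lymphocyte", "lymphocyte_atypical", "lymphocyte_typical"),
      neutrophil = c("neutrophil", "neutrophil_band", "neutrophil_segmented"),
      promyelocyte = c("promyelocyte", "promyelocyte_bilobed"),
      immature_granulocytes = c("immature_granulocytes", "myelocyte", "metamyelocyte")
    ),
    passthrough = unique(c("basophil", "eosinophil", "erythroblast", "monoblast",
                           "monocyte", "myeloblast", "platelet", "smudge_cells",
                           extra_passthrough))
  )
}

#' Read / write a merge taxonomy as YAML
#'
#' The YAML file has two top-level keys, `groups` (mapping merged label to a
#' list of source labels) and `passthrough` (a list of labels kept as-is).
#'
#' @param path YAML file.
#' @return `read_taxonomy()` returns a [merge_taxonomy()]; `write_taxonomy()`
#'   returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  spec <- yaml::read_yaml(path)
  merge_taxonomy(groups = lapply(spec$groups %||% list(), unlist),
                 passthrough = unlist(spec$passthrough %||% character()))
}

#' @rdname read_taxonomy
#' @param taxonomy A [merge_taxonomy()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  self <- vapply(names(taxonomy$groups), function(g)
    identical(taxonomy$groups[[g]], g), logical(1))
  yaml::write_yaml(list(groups = lapply(taxonomy$groups[!self], as.list),
                        passthrough = as.list(names(taxonomy$groups)[self])), path)
  invisible(path)
}

#' Merge cell types into cell families
#'
#' Relabels every record to its merged cell family. The total record count
#' is conserved exactly; only labels change.
#'
#' @param manifest A manifest tibble.
#' @param taxonomy A [merge_taxonomy()]; defaults to the bone-marrow rules.
#' @return The relabeled manifest.
#' @export
merge_cell_types <- function(manifest, taxonomy = default_merge_taxonomy()) {
  manifest <- as_manifest(manifest)
  map <- taxonomy_map(taxonomy)
  unknown <- setdiff(unique(manifest$label), names(map))
  if (length(unknown) > 0) {
    stop_input(paste0("label(s) not covered by taxonomy: ",
                      paste(unknown, collapse = ", ")), "cytosynth_taxonomy_error")
  }
  manifest$label <- unname(map[manifest$label])
  manifest
}

#' Remove duplicate and excluded records
#'
#' Byte-identical images (equal file content hash) are collapsed to the
#' first occurrence; records whose `id` (or content hash) appears in
#' `exclusions` are dropped. Unknown exclusion ids are ignored with a
#' warning. Records without a file on disk are never hashed.
#'
#' @param manifest A manifest tibble.
#' @param exclusions Character vector of record ids or content hashes.
#' @return The deduplicated manifest.
#' @export
dedupe <- function(manifest, exclusions = character()) {
  manifest <- as_manifest(manifest)
  hashable <- !is.na(manifest$path) & file.exists(manifest$path)
  hash <- rep(NA_character_, nrow(manifest))
  if (any(hashable)) hash[hashable] <- unname(tools::md5sum(manifest$path[hashable]))
  keep <- !duplicated(hash, incomparables = NA_character_)
  matched <- manifest$id %in% exclusions | (!is.na(hash) & hash %in% exclusions)
  unknown <- setdiff(exclusions, c(manifest$id, hash[!is.na(hash)]))
  if (length(unknown) > 0) {
    rlang::warn(paste0("ignoring ", length(unknown), " unknown exclusion id(s)"))
  }
  manifest[keep & !matched, ]
}

#' Train/validation/test split specification
#'
#' The defaults follow the common 70/30 train/test protocol with 20% of the
#' training portion held out for validation, i.e. 56/14/30 percent of each
#' class overall.
#'
#' @param train_fraction Fraction of each class used for training (incl. val).
#' @param test_fraction Fraction held out for testing.
#' @param val_fraction_of_train Fraction of the training portion used for
#'   validation.
#' @param seed Integer seed controlling the (per-class) shuffle.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.70, test_fraction = 1 - train_fraction,
                       val_fraction_of_train = 0.20, seed = 1L) {
  if (abs(train_fraction + test_fraction - 1) > 1e-9) {
    stop_input("train_fraction + test_fraction must equal 1", "cytosynth_config_error")
  }
  if (train_fraction <= 0 || train_fraction >= 1 ||
      val_fraction_of_train <= 0 || val_fraction_of_train >= 1) {
    stop_input("split fractions must lie in (0, 1)", "cytosynth_config_error")
  }
  structure(list(train_fraction = train_fraction, test_fraction = test_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Stratified train/val/test assignment
#'
#' Within every class, `floor(n * test_fraction)` records go to test,
#' `floor(remaining * val_fraction_of_train)` to validation, and the rest to
#' train; the within-class order is shuffled deterministically from the seed.
#'
#' @param manifest A manifest tibble; every class needs at least 3 records.
#' @param spec A [split_spec()].
#' @return The manifest with its `split` column assigned.
#' @export
stratified_split <- function(manifest, spec = split_spec()) {
  manifest <- as_manifest(manifest)
  counts <- class_counts(manifest)
  small <- counts$label[counts$n < 3]
  if (length(small) > 0) {
    stop_input(paste0("class(es) with fewer than 3 records cannot be split: ",
                      paste(small, collapse = ", ")), "cytosynth_split_error")
  }
  manifest$split <- "unassigned"
  with_seed_(spec$seed, {
    for (lab in counts$label) {
      idx <- which(manifest$label == lab)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_test <- floor(n * spec$test_fraction)
      n_val <- floor((n - n_test) * spec$val_fraction_of_train)
      manifest$split[idx[seq_len(n_test)]] <- "test"
      manifest$split[idx[n_test + seq_len(n_val)]] <- "val"
      manifest$split[idx[(n_test + n_val + 1):n]] <- "train"
    }
  })
  manifest
}

#' Per-class synthesis deficits for balancing
#'
#' How many synthetic images each class needs so that every class reaches
#' the target count (by default the size of the largest class).
#'
#' @param manifest A manifest tibble.
#' @param target `"max"` (largest class) or an integer at least the largest
#'   class count.
#' @return A tibble with `label`, `n` (current) and `deficit`.
#' @export
class_deficits <- function(manifest, target = "max") {
  counts <- class_counts(manifest)
  if (identical(target, "max")) {
    target_n <- max(counts$n)
  } else {
    target_n <- as.integer(target)
    if (target_n < max(counts$n)) {
      stop_input(sprintf("target (%d) is below the largest class count (%d)",
                         target_n, max(counts$n)), "cytosynth_config_error")
    }
  }
  dplyr::mutate(counts, deficit = pmax(target_n - .data$n, 0L), target = target_n)
}
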