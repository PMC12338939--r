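#' @importFrom rlang .data
NULL

manifest_partitions <- c("training", "validation", "testing")
manifest_modalities <- c("dermoscopic", "clinical")
manifest_csv_columns <- c(
  "record_id", "image_path", "source", "modality",
  "raw_class", "raw_subclass", "partition"
)

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(invisible(records))
  }
  needed <- c(
    "record_id", "source", "modality", "raw_class", "label", "partition"
  )
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("records are missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup)) {
    stop("duplicate record_id: ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  bad_part <- setdiff(unique(records$partition), manifest_partitions)
  if (length(bad_part)) {
    stop("unknown partition value(s): ", paste(bad_part, collapse = ", "),
      call. = FALSE
    )
  }
  bad_label <- setdiff(unique(records$label), lesion_class_codes())
  if (length(bad_label)) {
    stop("unknown label(s): ", paste(bad_label, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(records)
}

#' Aggregate lesion records into a dataset manifest
#'
#' Tallies a record table into per-(partition, source, class) counts, the
#' bookkeeping used to describe multi-source cohorts. Counts are exact
#' tallies, so totals are additive over sources and classes.
#'
#' @param records A data frame of lesion records with columns `record_id`,
#'   `source`, `modality`, `raw_class`, `label`, `partition` (and usually
#'   `image_path`, `raw_subclass`).
#' @return An object of class `dataset_manifest`: a list with `records`
#'   (tibble) and `counts`, a tibble with columns `partition`, `source`,
#'   `label`, `n`.
#' @examples
#' recs <- tibble::tibble(
#'   record_id = c("a", "b"), source = "toy", modality = "dermoscopic",
#'   raw_class = c("melanoma", "benign nevus"), label = c("MEL", "NEV"),
#'   partition = "training"
#' )
#' aggregate_manifest(recs)
#' @export
aggregate_manifest <- function(records) {
  if (nrow(records) == 0L) {
    counts <- tibble::tibble(
      partition = character(), source = character(),
      label = character(), n = integer()
    )
  } else {
    validate_records(records)
    counts <- records |>
      dplyr::count(.data$partition, .data$source, .data$label, name = "n") |>
      dplyr::arrange(
        match(.data$partition, manifest_partitions),
        .data$source,
        match(.data$label, lesion_class_codes())
      )
  }
  structure(
    list(records = tibble::as_tibble(records), counts = counts),
    class = "dataset_manifest"
  )
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(
    "<dataset_manifest> ", nrow(x$records), " records, ",
    length(unique(x$counts$source)), " source(s)\n",
    sep = ""
  )
  print(partition_totals(x))
  invisible(x)
}

#' Per-partition record totals of a manifest
#'
#' @param manifest A `dataset_manifest`.
#' @return A tibble with columns `partition` and `n`, summing the manifest
#'   counts over sources and classes.
#' @export
partition_totals <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  manifest$counts |>
    dplyr::group_by(.data$partition) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(match(.data$partition, manifest_partitions))
}

#' Read a manifest CSV
#'
#' The CSV carries the raw metadata (header `record_id, image_path, source,
#' modality, raw_class, raw_subclass, partition`); class labels are derived
#' from `raw_class`/`raw_subclass` through [normalize_label()] while reading.
#' Empty `raw_subclass` cells become `NA` (absent).
#'
#' @param path Path to the CSV file.
#' @param map Subclass map used for label normalization.
#' @return A `dataset_manifest` (see [aggregate_manifest()]).
#' @export
read_manifest_csv <- function(path, map = default_subclass_map()) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(manifest_csv_columns, names(raw))
  if (length(missing)) {
    stop("manifest CSV is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(!raw$partition %in% manifest_partitions)
  if (length(bad)) {
    stop(
      "unknown partition ", dQuote(raw$partition[bad[1]]),
      " in row ", bad[1],
      call. = FALSE
    )
  }
  raw$raw_subclass[!is.na(raw$raw_subclass) & raw$raw_subclass == ""] <- NA
  raw$label <- purrr::map2_chr(
    raw$raw_class, raw$raw_subclass,
    function(rc, rs) normalize_label(rc, rs, map = map)
  )
  aggregate_manifest(raw[c(manifest_csv_columns, "label")])
}

#' Write a manifest CSV
#'
#' Inverse of [read_manifest_csv()]: writes the raw metadata columns; the
#' derived `label` column is not stored since it is recomputed on read.
#'
#' @param manifest A `dataset_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  out <- manifest$records
  for (col in setdiff(manifest_csv_columns, names(out))) {
    out[[col]] <- NA_character_
  }
  readr::write_csv(out[manifest_csv_columns], path, na = "", progress = FALSE)
  invisible(path)
}

#' Published per-source composition of the multi-source lesion cohort
#'
#' Per-source, per-class record counts of the multi-source dermoscopy and
#' clinical-photography cohort over the three partitions, shipped as a
#' plain-text input so partition totals can be recomputed by aggregation
#' (the grand totals are 11652 training, 2616 validation and 16386 testing
#' records). One internally inconsistent published cell (the validation
#' melanoma count of the Derm7pt source) is reconciled to the value implied
#' by the published row and column totals.
#'
#' @return A tibble with columns `partition`, `source`, and one count column
#'   per class code (`BEK`, `NEV`, `ACK`, `BCC`, `MEL`).
#' @examples
#' comp <- cohort_composition()
#' manifest <- aggregate_manifest(composition_records(comp))
#' partition_totals(manifest)
#' @export
cohort_composition <- function() {
  path <- system.file("extdata", "cohort_composition.csv",
    package = "dermcolearn", mustWork = TRUE
  )
  readr::read_csv(path,
    col_types = readr::cols(
      partition = readr::col_character(),
      source = readr::col_character(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' Expand a composition table into individual lesion records
#'
#' Produces one record row per counted image so that count tables can flow
#' through [aggregate_manifest()] like any other record list. Image paths are
#' unset: the expansion carries metadata only.
#'
#' @param composition A tibble as returned by [cohort_composition()].
#' @return A tibble of records suitable for [aggregate_manifest()].
#' @export
composition_records <- function(composition) {
  codes <- lesion_class_codes()
  stopifnot(all(codes %in% names(composition)))
  long <- composition |>
    tidyr::pivot_longer(
      dplyr::all_of(codes),
      names_to = "label", values_to = "n"
    ) |>
    dplyr::filter(.data$n > 0)
  long <- long[rep(seq_len(nrow(long)), long$n), ]
  cls <- lesion_classes()
  tibble::tibble(
    record_id = sprintf("rec%06d", seq_len(nrow(long))),
    image_path = NA_character_,
    source = long$source,
    modality = "dermoscopic",
    raw_class = cls$display_name[match(long$label, cls$code)],
    raw_subclass = NA_character_,
    label = long$label,
    partition = long$partition
  )
}
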