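#' Paired lesion cohort container
#'
#' Bundles the three ingredients of a co-learning experiment: a record
#' table (metadata, labels, partitions), the images, and the per-record
#' report pairs. Synthetic cohorts from [generate_cohort()] and cohorts
#' read from disk with [read_cohort()] share this container, so the rest of
#' the package cannot tell them apart.
#'
#' @param records Record tibble (see [aggregate_manifest()] for columns).
#' @param images Named list of HxWx3 arrays in `[0, 1]`, keyed by
#'   `record_id`.
#' @param reports Tibble with columns `record_id`, `structured`,
#'   `synthesized` (may have zero rows for image-only work).
#' @return An object of class `lesion_cohort`.
#' @export
lesion_cohort <- function(records, images, reports) {
  validate_records(records)
  missing_img <- setdiff(records$record_id, names(images))
  if (length(missing_img)) {
    stop("records without images: ", paste(utils::head(missing_img, 3),
      collapse = ", "
    ), call. = FALSE)
  }
  structure(
    list(
      records = tibble::as_tibble(records),
      images = images,
      reports = tibble::as_tibble(reports)
    ),
    class = "lesion_cohort"
  )
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(
    "<lesion_cohort> ", nrow(x$records), " records, ",
    nrow(x$reports), " report pairs\n",
    sep = ""
  )
  print(dplyr::count(x$records, .data$partition, .data$label))
  invisible(x)
}

cohort_subset <- function(cohort, partition) {
  recs <- cohort$records[cohort$records$partition == partition, ]
  list(
    records = recs,
    images = cohort$images[recs$record_id],
    reports = cohort$reports[
      match(recs$record_id, cohort$reports$record_id), ,
      drop = FALSE
    ]
  )
}

#' Write a cohort to a directory
#'
#' Produces the on-disk layout shared with real cohorts: `images/` with one
#' PNG per record, `manifest.csv` in the standard manifest schema, and
#' `reports.jsonl` with one JSON object (record_id, structured, synthesized)
#' per line.
#'
#' @param cohort A `lesion_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  recs <- cohort$records
  recs$image_path <- file.path("images", paste0(recs$record_id, ".png"))
  for (i in seq_len(nrow(recs))) {
    png::writePNG(
      cohort$images[[recs$record_id[i]]],
      file.path(dir, recs$image_path[i])
    )
  }
  write_manifest_csv(aggregate_manifest(recs), file.path(dir, "manifest.csv"))
  lines <- purrr::map_chr(seq_len(nrow(cohort$reports)), function(i) {
    jsonlite::toJSON(
      as.list(cohort$reports[i, c("record_id", "structured", "synthesized")]),
      auto_unbox = TRUE
    )
  })
  writeLines(lines, file.path(dir, "reports.jsonl"))
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Inverse of [write_cohort()]: reads `manifest.csv`, the referenced PNG or
#' JPEG images (paths relative to the directory), and `reports.jsonl` when
#' present.
#'
#' @param dir Cohort directory.
#' @param map Subclass map for label normalization.
#' @return A `lesion_cohort`.
#' @export
read_cohort <- function(dir, map = default_subclass_map()) {
  manifest <- read_manifest_csv(file.path(dir, "manifest.csv"), map = map)
  recs <- manifest$records
  images <- lapply(seq_len(nrow(recs)), function(i) {
    path <- file.path(dir, recs$image_path[i])
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
  names(images) <- recs$record_id
  reports_path <- file.path(dir, "reports.jsonl")
  reports <- if (file.exists(reports_path)) {
    rows <- lapply(readLines(reports_path), jsonlite::fromJSON)
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  } else {
    tibble::tibble(
      record_id = character(), structured = character(),
      synthesized = character()
    )
  }
  lesion_cohort(recs, images, reports)
}
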