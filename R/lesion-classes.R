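#' The five lesion classes
#'
#' The classification target is a fixed five-class taxonomy of skin lesions:
#' benign keratosis (BEK), benign nevus (NEV), actinic keratosis (ACK,
#' pre-malignant), basal-cell cancer (BCC) and melanoma (MEL). The table
#' carries, for each class, its code, display name and malignancy status;
#' the status drives the wording of generated reports.
#'
#' @return A tibble with columns `code`, `display_name`, `malignancy`
#'   (one of `"benign"`, `"pre-malignant"`, `"malignant"`), one row per class
#'   in canonical order BEK, NEV, ACK, BCC, MEL.
#' @examples
#' lesion_classes()
#' @export
lesion_classes <- function() {
  tibble::tibble(
    code = c("BEK", "NEV", "ACK", "BCC", "MEL"),
    display_name = c(
      "benign keratosis", "benign nevus", "actinic keratosis",
      "basal-cell cancer", "melanoma"
    ),
    malignancy = c(
      "benign", "benign", "pre-malignant", "malignant", "malignant"
    )
  )
}

#' Canonical class codes
#'
#' @return Character vector of the five class codes in canonical order.
#' @export
lesion_class_codes <- function() lesion_classes()$code

# lower-cases, trims, and collapses internal whitespace
normalize_string <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Default subclass-to-class mapping
#'
#' Dataset metadata often records a finer-grained diagnosis than the five
#' target classes; a subclass map links those strings to a class (for
#' example melanocytic nevus is a subclass of benign nevus, and Bowen's
#' disease a subclass of actinic keratosis). The default map ships those
#' two entries plus common synonyms, and can be extended by the user.
#'
#' @param extra Optional named character vector of additional entries,
#'   names are raw subclass strings, values are class codes.
#' @return A tibble with columns `subclass` (normalized string) and `code`.
#' @examples
#' default_subclass_map()
#' default_subclass_map(extra = c("superficial bcc" = "BCC"))
#' @export
default_subclass_map <- function(extra = NULL) {
  map <- tibble::tibble(
    subclass = c(
      "melanocytic nevus", "bowen's disease", "bowens disease",
      "nevus", "naevus", "dysplastic nevus", "blue nevus",
      "seborrheic keratosis", "solar lentigo", "lichenoid keratosis",
      "solar keratosis", "actinic cheilitis",
      "nodular basal cell carcinoma", "superficial basal cell carcinoma",
      "lentigo maligna", "nodular melanoma", "superficial spreading melanoma"
    ),
    code = c(
      "NEV", "ACK", "ACK",
      "NEV", "NEV", "NEV", "NEV",
      "BEK", "BEK", "BEK",
      "ACK", "ACK",
      "BCC", "BCC",
      "MEL", "MEL", "MEL"
    )
  )
  if (!is.null(extra)) {
    stopifnot(is.character(extra), !is.null(names(extra)))
    map <- dplyr::bind_rows(
      map,
      tibble::tibble(
        subclass = normalize_string(names(extra)),
        code = unname(extra)
      )
    )
    map <- dplyr::distinct(map, .data$subclass, .keep_all = TRUE)
  }
  stopifnot(all(map$code %in% lesion_class_codes()))
  map
}

# direct raw_class vocabulary: codes, display names, frequent synonyms
class_name_table <- function() {
  cls <- lesion_classes()
  tibble::tibble(
    name = c(
      tolower(cls$code), cls$display_name,
      "benign keratoses", "keratosis, benign",
      "benign nevi", "melanoma, malignant", "malignant melanoma",
      "basal cell carcinoma", "basal-cell carcinoma", "basal cell cancer",
      "actinic keratoses", "intraepithelial carcinoma"
    ),
    code = c(
      cls$code, cls$code,
      "BEK", "BEK",
      "NEV", "MEL", "MEL",
      "BCC", "BCC", "BCC",
      "ACK", "ACK"
    )
  )
}

#' Normalize a raw class string to one of the five lesion classes
#'
#' Resolution is deterministic and insensitive to case and surrounding or
#' repeated whitespace. The raw class string is matched first against the
#' class codes, display names and common synonyms; only when that fails is
#' the subclass string consulted against the subclass map.
#'
#' @param raw_class Raw class string from metadata, non-empty.
#' @param raw_subclass Optional raw subclass string (`NULL` or `NA` if absent).
#' @param map Subclass map tibble, see [default_subclass_map()].
#' @return A single class code (`"BEK"`, `"NEV"`, `"ACK"`, `"BCC"` or `"MEL"`).
#' @examples
#' normalize_label("melanoma")
#' normalize_label("benign nevus", "Melanocytic Nevus")
#' normalize_label("unknown thing", "bowen's disease")
#' @export
normalize_label <- function(raw_class, raw_subclass = NULL,
                            map = default_subclass_map()) {
  if (length(raw_class) != 1L || is.na(raw_class) || !nzchar(trimws(raw_class))) {
    stop("`raw_class` must be a single non-empty string", call. = FALSE)
  }
  key <- normalize_string(raw_class)
  direct <- class_name_table()
  hit <- match(key, direct$name)
  if (!is.na(hit)) {
    return(direct$code[hit])
  }
  # fall back to the subclass string
  if (!is.null(raw_subclass) && length(raw_subclass) == 1L &&
      !is.na(raw_subclass) && nzchar(trimws(raw_subclass))) {
    skey <- normalize_string(raw_subclass)
    shit <- match(skey, map$subclass)
    if (!is.na(shit)) {
      return(map$code[shit])
    }
    # the raw_class itself may be a subclass string
  }
  shit <- match(key, map$subclass)
  if (!is.na(shit)) {
    return(map$code[shit])
  }
  stop(
    "unmappable label: raw_class = ", dQuote(raw_class),
    if (!is.null(raw_subclass) && !is.na(raw_subclass[1])) {
      paste0(", raw_subclass = ", dQuote(raw_subclass))
    } else {
      ""
    },
    call. = FALSE
  )
}
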