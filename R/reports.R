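#' Default descriptor vocabulary for synthesized reports
#'
#' Synthesized reports extend the structured template with one clause per
#' descriptor field — skin structure, overall image colour, dermoscopic
#' structures and lesion symmetry. Every field is a closed set of options:
#' the synthesizer may only pick from these strings, which is the mechanism
#' preventing hallucinated findings. The default sets use standard
#' dermoscopy vocabulary; a custom vocabulary can be loaded from YAML with
#' [read_vocabulary()].
#'
#' @return A named list (ordered) mapping field name to a character vector
#'   of at least two allowed options.
#' @examples
#' names(default_vocabulary())
#' @export
default_vocabulary <- function() {
  path <- system.file("extdata", "descriptor_vocabulary.yaml",
    package = "dermcolearn", mustWork = TRUE
  )
  read_vocabulary(path)
}

#' Read a descriptor vocabulary from a YAML file
#'
#' @param path YAML file mapping field names to lists of option strings.
#' @return Named list of character vectors, in file order.
#' @export
read_vocabulary <- function(path) {
  vocab <- yaml::read_yaml(path)
  validate_vocabulary(vocab)
  lapply(vocab, as.character)
}

validate_vocabulary <- function(vocab) {
  if (!is.list(vocab) || is.null(names(vocab)) || any(names(vocab) == "")) {
    stop("vocabulary must be a named list of option vectors", call. = FALSE)
  }
  n_opt <- vapply(vocab, length, integer(1))
  if (any(n_opt < 2L)) {
    stop(
      "vocabulary field(s) with fewer than 2 options: ",
      paste(names(vocab)[n_opt < 2L], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(vocab)
}

malignancy_word <- function(label) {
  cls <- lesion_classes()
  cls$malignancy[match(label, cls$code)]
}

#' Structured report from class metadata
#'
#' Fills the fixed template
#' `"The image includes a {malignancy} skin lesion, specifically a {class}"`,
#' appending `" (specifically a {subclass})"` only when a subclass string is
#' available. The malignancy slot renders the three-way status of the class
#' (benign / pre-malignant / malignant).
#'
#' @param label Class code (one of `lesion_class_codes()`).
#' @param subclass Optional subclass string (`NULL` or `NA` when absent).
#' @return A single string.
#' @examples
#' make_structured_report("MEL")
#' make_structured_report("NEV", "melanocytic nevus")
#' @export
make_structured_report <- function(label, subclass = NULL) {
  cls <- lesion_classes()
  idx <- match(label, cls$code)
  if (is.na(idx)) {
    stop("unknown class code: ", dQuote(label), call. = FALSE)
  }
  text <- sprintf(
    "The image includes a %s skin lesion, specifically a %s",
    cls$malignancy[idx], cls$display_name[idx]
  )
  if (!is.null(subclass) && length(subclass) == 1L && !is.na(subclass) &&
      nzchar(trimws(subclass))) {
    text <- sprintf("%s (specifically a %s)", text, trimws(tolower(subclass)))
  }
  text
}

#' Synthesized report with constrained descriptor fields
#'
#' Deterministically extends the structured report with one clause per
#' vocabulary field, choosing each option uniformly at random under the
#' given seed. Because every choice comes from the closed option set, the
#' output can never contain a descriptor outside the vocabulary. Clauses
#' follow vocabulary order. The default backend is this template
#' synthesizer; see [report_backend()] for plugging in another generator.
#'
#' @inheritParams make_structured_report
#' @param vocab Descriptor vocabulary, see [default_vocabulary()].
#' @param seed Integer seed controlling the descriptor choices.
#' @return A list with elements `text` (string) and `descriptor_choices`
#'   (named character vector of the selected option per field).
#' @examples
#' make_synthesized_report("MEL", seed = 1)$text
#' @export
make_synthesized_report <- function(label, subclass = NULL,
                                    vocab = default_vocabulary(),
                                    seed = 0L) {
  validate_vocabulary(vocab)
  base <- make_structured_report(label, subclass)
  choices <- withr_seed(seed, {
    vapply(vocab, function(opts) sample(opts, 1L), character(1))
  })
  clauses <- sprintf(
    "The %s is %s.",
    gsub("_", " ", names(vocab)), unname(choices)
  )
  list(
    text = paste(c(paste0(base, "."), clauses), collapse = " "),
    descriptor_choices = choices
  )
}

# evaluates expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Report generation backends
#'
#' The synthesizer is pluggable: a backend is a function
#' `function(label, subclass, vocab, seed)` returning the
#' `list(text, descriptor_choices)` contract of [make_synthesized_report()].
#' The shipped `"template"` backend is the deterministic constrained-options
#' synthesizer; an external language-model backend can be registered by the
#' user, and must still restrict descriptor values to the closed vocabulary.
#'
#' @param name Backend name; only `"template"` ships with the package.
#' @return The backend function.
#' @export
report_backend <- function(name = "template") {
  switch(name,
    template = make_synthesized_report,
    stop("unknown report backend: ", dQuote(name), call. = FALSE)
  )
}

#' Generate a report pair for one record
#'
#' @inheritParams make_synthesized_report
#' @param backend Backend function, see [report_backend()].
#' @return A list of class `report_pair` with elements `structured`,
#'   `synthesized`, `descriptor_choices`, `seed`.
#' @export
make_report_pair <- function(label, subclass = NULL,
                             vocab = default_vocabulary(), seed = 0L,
                             backend = report_backend()) {
  syn <- backend(label, subclass, vocab, seed)
  structure(
    list(
      structured = make_structured_report(label, subclass),
      synthesized = syn$text,
      descriptor_choices = syn$descriptor_choices,
      seed = as.integer(seed)
    ),
    class = "report_pair"
  )
}

#' Synthesize report pairs for every record of a manifest
#'
#' Per-record seeds are derived deterministically from `seed` and the record
#' index, so the full table is reproducible.
#'
#' @param records A record tibble (e.g. `manifest$records`).
#' @param vocab Descriptor vocabulary.
#' @param seed Integer base seed.
#' @param backend Backend function, see [report_backend()].
#' @return A tibble with columns `record_id`, `structured`, `synthesized`,
#'   plus one `choice_*` column per descriptor field.
#' @export
synthesize_reports <- function(records, vocab = default_vocabulary(),
                               seed = 0L, backend = report_backend()) {
  pairs <- purrr::imap(records$record_id, function(id, i) {
    sub <- if ("raw_subclass" %in% names(records)) {
      records$raw_subclass[i]
    } else {
      NULL
    }
    make_report_pair(records$label[i], sub,
      vocab = vocab,
      seed = (seed * 10007L + i) %% .Machine$integer.max,
      backend = backend
    )
  })
  choices <- purrr::map(pairs, function(p) {
    tibble::as_tibble(as.list(p$descriptor_choices))
  })
  out <- tibble::tibble(
    record_id = records$record_id,
    structured = purrr::map_chr(pairs, "structured"),
    synthesized = purrr::map_chr(pairs, "synthesized")
  )
  choice_tbl <- dplyr::bind_rows(choices)
  names(choice_tbl) <- paste0("choice_", names(choice_tbl))
  dplyr::bind_cols(out, choice_tbl)
}

#' Report-turnover augmentation
#'
#' During multimodal training the text fed to the model is randomly turned
#' over between the two report renditions of a record: with probability
#' `p_synthesized` the descriptor-rich synthesized report is used, otherwise
#' the structured template report.
#'
#' @param pair A `report_pair`, or any list with `structured` and
#'   `synthesized` strings.
#' @param p_synthesized Probability of drawing the synthesized report.
#' @return One of the two report strings.
#' @export
augment_report <- function(pair, p_synthesized = 0.5) {
  stopifnot(
    is.numeric(p_synthesized), p_synthesized >= 0, p_synthesized <= 1
  )
  if (stats::runif(1) < p_synthesized) pair$synthesized else pair$structured
}

#' @export
print.report_pair <- function(x, ...) {
  cat("<report_pair>\n structured : ", x$structured, "\n synthesized: ",
    x$synthesized, "\n",
    sep = ""
  )
  invisible(x)
}
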