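#' Synthetic cohort configuration
#'
#' Controls the paired (image, metadata) fixture generator. Each class is
#' rendered as a distinct parametric motif on a skin-tone background:
#' ellipse (benign nevus), ragged polygon (melanoma), ring (basal-cell
#' cancer), stippled patch (actinic keratosis) and scaly grid (benign
#' keratosis), each with a class base colour. `motif_separation` scales how
#' far the lesion colours sit from the background (1 = fully distinct,
#' 0 = invisible), `noise_sd` adds Gaussian pixel noise as a fraction of
#' the dynamic range, and `subclass_rate` controls how many records carry a
#' subclass string in their metadata.
#'
#' @param n_per_class Records per class (>= 0).
#' @param image_size Square image side in pixels (>= 16).
#' @param noise_sd Additive pixel noise standard deviation in `[0, 1]`.
#' @param subclass_rate Fraction of records given a subclass string.
#' @param motif_separation Visual distinctness of the class motifs, in
#'   `[0, 1]`.
#' @param seed Integer seed; the cohort (images, metadata, reports) is a
#'   deterministic function of the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 40L, image_size = 64L,
                         noise_sd = 0.1, subclass_rate = 0.3,
                         motif_separation = 0.7, seed = 1L) {
  stopifnot(
    n_per_class >= 0, image_size >= 16, noise_sd >= 0, noise_sd <= 1,
    subclass_rate >= 0, subclass_rate <= 1,
    motif_separation >= 0, motif_separation <= 1
  )
  structure(
    list(
      n_per_class = as.integer(n_per_class),
      image_size = as.integer(image_size),
      noise_sd = noise_sd, subclass_rate = subclass_rate,
      motif_separation = motif_separation, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

synth_background <- c(0.87, 0.72, 0.60)

synth_class_colors <- function() {
  list(
    BEK = c(0.62, 0.48, 0.25),
    NEV = c(0.45, 0.28, 0.18),
    ACK = c(0.80, 0.42, 0.38),
    BCC = c(0.85, 0.55, 0.55),
    MEL = c(0.15, 0.10, 0.12)
  )
}

# lesion mask for one image; draws shape parameters from the current RNG
synth_motif_mask <- function(code, s) {
  cx <- stats::runif(1, -0.12, 0.12)
  cy <- stats::runif(1, -0.12, 0.12)
  theta <- stats::runif(1, 0, pi)
  ax <- seq(-1, 1, length.out = s)
  x <- outer(ax, rep(1, s)) - cy
  y <- outer(rep(1, s), ax) - cx
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  rho <- sqrt(x^2 + y^2)
  switch(code,
    NEV = (xr / 0.55)^2 + (yr / 0.35)^2 <= 1,
    MEL = {
      phi <- atan2(yr, xr)
      k <- sample(4:7, 1)
      r <- 0.42 * (1 + 0.35 * sin(k * phi + stats::runif(1, 0, 2 * pi)) +
        0.15 * sin((k + 3) * phi))
      sqrt(xr^2 + yr^2) <= r
    },
    BCC = {
      width <- stats::runif(1, 0.10, 0.16)
      rho >= 0.42 - width & rho <= 0.42 + width
    },
    ACK = {
      mask <- matrix(FALSE, s, s)
      n_dots <- 22L + sample.int(8L, 1)
      for (d in seq_len(n_dots)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rr <- 0.55 * sqrt(stats::runif(1))
        dx <- x - rr * cos(ang)
        dy <- y - rr * sin(ang)
        mask <- mask | (dx^2 + dy^2 <= stats::runif(1, 0.003, 0.008))
      }
      mask
    },
    BEK = {
      f <- stats::runif(1, 5, 7)
      disk <- rho <= 0.52
      scales <- sin(pi * f * xr) * sin(pi * f * yr) > -0.2
      disk & scales
    },
    stop("unknown class code: ", code)
  )
}

synth_image <- function(code, cfg) {
  s <- cfg$image_size
  bg <- synth_background + stats::runif(3, -0.03, 0.03)
  col <- synth_background +
    cfg$motif_separation * (synth_class_colors()[[code]] - synth_background)
  img <- array(rep(bg, each = s * s), c(s, s, 3))
  mask <- synth_motif_mask(code, s)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- col[ch]
    img[, , ch] <- plane
  }
  if (cfg$noise_sd > 0) {
    img <- img + array(stats::rnorm(s * s * 3, sd = cfg$noise_sd), dim(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic paired cohort
#'
#' Produces `n_per_class` records per class with class identity rendered as
#' a visual motif plus noise, metadata whose `raw_class` is the class
#' display name (optionally enriched with a subclass string drawn from the
#' subclass map), and report pairs synthesized from that metadata — so the
#' reports are genuinely informative about image class. All records start
#' in the training partition; use [split_cohort()] to partition.
#'
#' @param cfg A [synth_config()].
#' @param vocab Descriptor vocabulary for the synthesized reports.
#' @return A [lesion_cohort()].
#' @export
generate_cohort <- function(cfg = synth_config(),
                            vocab = default_vocabulary()) {
  stopifnot(inherits(cfg, "synth_config"))
  cls <- lesion_classes()
  map <- default_subclass_map()
  withr_seed(cfg$seed, {
    rows <- list()
    images <- list()
    for (code in cls$code) {
      subs <- map$subclass[map$code == code]
      for (i in seq_len(cfg$n_per_class)) {
        id <- sprintf("synth_%s_%03d", code, i)
        images[[id]] <- synth_image(code, cfg)
        has_sub <- length(subs) > 0 && stats::runif(1) < cfg$subclass_rate
        rows[[id]] <- tibble::tibble(
          record_id = id,
          image_path = NA_character_,
          source = "synthetic",
          modality = "dermoscopic",
          raw_class = cls$display_name[cls$code == code],
          raw_subclass = if (has_sub) sample(subs, 1) else NA_character_,
          label = code,
          partition = "training"
        )
      }
    }
    records <- dplyr::bind_rows(rows)
    if (nrow(records) == 0L) {
      records <- tibble::tibble(
        record_id = character(), image_path = character(),
        source = character(), modality = character(),
        raw_class = character(), raw_subclass = character(),
        label = character(), partition = character()
      )
    }
    reports <- if (nrow(records) > 0) {
      synthesize_reports(records, vocab = vocab, seed = cfg$seed)
    } else {
      tibble::tibble(
        record_id = character(), structured = character(),
        synthesized = character()
      )
    }
    lesion_cohort(records, images, reports)
  })
}

#' Stratified partition split
#'
#' Assigns every record to training / validation / testing, stratified by
#' class: within each class the records are shuffled and allocated
#' `round(n * fraction)` to training and validation, with the remainder
#' testing, so partitions are disjoint and exhaustive.
#'
#' @param cohort A [lesion_cohort()].
#' @param fractions Length-3 numeric (training, validation, testing)
#'   summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return The cohort with reassigned `partition` column.
#' @export
split_cohort <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(
    inherits(cohort, "lesion_cohort"), length(fractions) == 3,
    all(fractions >= 0), all(fractions <= 1),
    abs(sum(fractions) - 1) < 1e-8
  )
  recs <- cohort$records
  withr_seed(seed, {
    for (code in unique(recs$label)) {
      idx <- which(recs$label == code)
      idx <- sample(idx)
      n <- length(idx)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      n_va <- min(n_va, n - n_tr)
      parts <- c(
        rep("training", n_tr), rep("validation", n_va),
        rep("testing", n - n_tr - n_va)
      )
      recs$partition[idx] <- parts
    }
  })
  cohort$records <- recs
  cohort
}
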