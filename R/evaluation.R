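#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between predicted
#' and true labels, with `p_o` the observed agreement and `p_e` the
#' agreement expected from the two marginal label distributions. Returns 1
#' when both vectors agree perfectly even if `p_e = 1` (single constant
#' label). Invariant under any simultaneous relabeling of both vectors.
#'
#' @param y_true,y_pred Equal-length label vectors (any atomic type).
#' @return A scalar in `[-1, 1]`.
#' @examples
#' cohen_kappa(c(0, 0, 1, 1), c(0, 0, 0, 0)) # chance level: 0
#' @export
cohen_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  n <- length(y_true)
  stopifnot(n >= 1)
  levels <- union(unique(y_true), unique(y_pred))
  t_i <- factor(y_true, levels = levels)
  p_i <- factor(y_pred, levels = levels)
  p_o <- mean(t_i == p_i)
  p_e <- sum(
    (table(t_i) / n) * (table(p_i) / n)
  )
  if (p_e >= 1) {
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Mean silhouette score
#'
#' For each sample, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is
#' the mean Euclidean distance to the other members of its own class and
#' `b(i)` the smallest mean distance to the members of any other class;
#' singleton classes contribute 0, as does the degenerate `a = b = 0` case.
#' The score is invariant to global translation and uniform scaling of the
#' embedding.
#'
#' @param embeddings N x d numeric matrix.
#' @param labels Length-N class labels with at least two distinct values.
#' @return A scalar in `[-1, 1]` (mean over samples).
#' @export
silhouette_score <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(labels) != n) {
    stop("labels length does not match embeddings", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("need at least 2 distinct labels", call. = FALSE)
  }
  d <- as.matrix(stats::dist(embeddings))
  cls <- unique(labels)
  # mean distance of each sample to each class
  class_mean <- vapply(cls, function(cl) {
    rowMeans(d[, labels == cl, drop = FALSE])
  }, numeric(n))
  counts <- table(labels)[cls]
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- match(labels[i], cls)
    nk <- as.integer(counts[k])
    if (nk == 1L) {
      s[i] <- 0
      next
    }
    a <- class_mean[i, k] * nk / (nk - 1) # exclude self (distance 0)
    b <- min(class_mean[i, -k])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `a - b`. Zero differences are
#' dropped; ties among the absolute differences receive midranks. For up to
#' 12 remaining pairs the null distribution of the positive-rank sum is
#' enumerated exactly over all sign assignments; for larger n a normal
#' approximation with tie correction is used.
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @return A list with `p_value`, `statistic` (positive-rank sum `W`), `n`
#'   (pairs after dropping zeros) and `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = 0, n = 0L, all_zero = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 12L) {
    # exact: enumerate all 2^n sign assignments of the midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- 2 * min(mean(w_all <= w), mean(w_all >= w))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p_value = min(p, 1), statistic = w, n = n, all_zero = FALSE)
}

#' Repeat a training setup and summarize test-set metrics
#'
#' Trains `n_runs` independent models with seeds `base_seed`,
#' `base_seed + 1`, ... and evaluates each on the testing partition:
#' Cohen's kappa of the image-only predictions, per test source, and the
#' silhouette score of the projected image embeddings under the true
#' labels. The summary reports the per-source mean and sample standard
#' deviation (n - 1 denominator) across runs.
#'
#' @param cohort A [lesion_cohort()] with a testing partition.
#' @param config A [train_config()]; its seed is overridden per run.
#' @param n_runs Number of repetitions (>= 2).
#' @param base_seed First seed.
#' @param spec An [encoder_spec()].
#' @return An object of class `metric_report`: list with `per_run` (tibble:
#'   `run`, `seed`, `source`, `kappa`, `silhouette`), `summary` (tibble:
#'   `source`, `metric`, `mean`, `sd`), `config`.
#' @export
repeat_experiment <- function(cohort, config = desk_config(), n_runs = 10L,
                              base_seed = 0L, spec = encoder_spec()) {
  stopifnot(n_runs >= 2L)
  te <- cohort_subset(cohort, "testing")
  if (nrow(te$records) == 0L) stop("empty testing partition", call. = FALSE)
  rows <- purrr::map(seq_len(n_runs), function(run) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + run - 1L)
    fit <- train_colearn(cohort, cfg, spec)
    pred <- predict_images(fit, unname(te$images))
    emb <- encode_images(unname(te$images), fit$model)
    proj <- project_embeddings(emb, fit$model)
    by_source <- split(seq_len(nrow(te$records)), te$records$source)
    purrr::imap(by_source, function(idx, src) {
      tibble::tibble(
        run = run, seed = cfg$seed, source = src,
        kappa = cohen_kappa(te$records$label[idx], pred[idx]),
        silhouette = silhouette_score(
          proj[idx, , drop = FALSE], te$records$label[idx]
        )
      )
    }) |> dplyr::bind_rows()
  })
  per_run <- dplyr::bind_rows(rows)
  summary <- per_run |>
    tidyr::pivot_longer(c("kappa", "silhouette"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$source, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value),
      .groups = "drop"
    )
  structure(
    list(per_run = per_run, summary = summary, config = config),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(
    "<metric_report> ", x$config$mode,
    " (", x$config$loss_weights$ssl_kind, "), ",
    max(x$per_run$run), " runs\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' Compare two repeated setups with the Wilcoxon signed-rank test
#'
#' Pairs the per-seed kappa values of two [repeat_experiment()] reports per
#' test source (runs with the same index are paired) and tests the
#' two-sided difference.
#'
#' @param report_a,report_b `metric_report`s run over the same seeds and
#'   sources.
#' @param alpha Significance level for the star marking.
#' @return A tibble with one row per source: mean +/- sd of each setup, the
#'   Wilcoxon p-value and a `significant` flag.
#' @export
compare_experiments <- function(report_a, report_b, alpha = 0.05) {
  ab <- dplyr::inner_join(
    report_a$per_run, report_b$per_run,
    by = c("run", "source"), suffix = c("_a", "_b")
  )
  ab |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(
      mean_a = mean(.data$kappa_a), sd_a = stats::sd(.data$kappa_a),
      mean_b = mean(.data$kappa_b), sd_b = stats::sd(.data$kappa_b),
      p_value = wilcoxon_signed_rank(.data$kappa_a, .data$kappa_b)$p_value,
      .groups = "drop"
    ) |>
    dplyr::mutate(significant = .data$p_value < alpha)
}

#' Render a comparison as a markdown table
#'
#' One row per source, `mean±sd` per setup, significant differences marked
#' with `*` on the better setup.
#'
#' @param comparison Output of [compare_experiments()].
#' @param names_ab Character vector of the two setup names.
#' @return A character scalar of markdown.
#' @export
format_comparison_md <- function(comparison,
                                 names_ab = c("setup A", "setup B")) {
  fmt <- function(m, s, star) {
    sprintf("%.3f±%.3f%s", m, s, ifelse(star, "*", ""))
  }
  star_a <- comparison$significant & comparison$mean_a > comparison$mean_b
  star_b <- comparison$significant & comparison$mean_b > comparison$mean_a
  lines <- c(
    paste0("| Dataset | ", names_ab[1], " | ", names_ab[2], " |"),
    "|---|---|---|",
    sprintf(
      "| %s | %s | %s |", comparison$source,
      fmt(comparison$mean_a, comparison$sd_a, star_a),
      fmt(comparison$mean_b, comparison$sd_b, star_b)
    )
  )
  paste(lines, collapse = "\n")
}
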