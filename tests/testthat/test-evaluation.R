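test_that("kappa handles the defining boundary cases", {
  expect_equal(cohen_kappa(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  expect_equal(cohen_kappa(c(0, 0, 1, 1), c(0, 0, 0, 0)), 0)
  expect_equal(cohen_kappa(c("A", "A"), c("A", "A")), 1) # p_e = 1, perfect
  expect_error(cohen_kappa(1:3, 1:4), "differ")
})

test_that("kappa matches the confusion-matrix oracle on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(10:50, 1)
    y1 <- sample(lesion_class_codes(), n, replace = TRUE)
    y2 <- sample(lesion_class_codes(), n, replace = TRUE)
    expect_equal(cohen_kappa(y1, y2), oracle_kappa(y1, y2),
      tolerance = 1e-10
    )
  }
})

test_that("kappa is invariant under simultaneous relabeling", {
  set.seed(12)
  y1 <- sample(5, 40, replace = TRUE)
  y2 <- sample(5, 40, replace = TRUE)
  perm <- sample(5)
  expect_equal(cohen_kappa(perm[y1], perm[y2]), cohen_kappa(y1, y2))
})

test_that("silhouette handles the defining boundary cases", {
  x <- matrix(c(0, 0, 10, 10), 4, 1)
  expect_equal(silhouette_score(x, c("A", "A", "B", "B")), 1)
  same <- matrix(1, 4, 2)
  expect_equal(silhouette_score(same, c("A", "A", "B", "B")), 0)
  expect_error(silhouette_score(x, rep("A", 4)), "distinct")
  expect_error(silhouette_score(x[1, , drop = FALSE], "A"), "2 samples")
})

test_that("silhouette matches the double-loop oracle on random instances", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(6:20, 1)
    x <- matrix(rnorm(n * 3), n)
    labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(
      silhouette_score(x, labels), oracle_silhouette(x, labels),
      tolerance = 1e-10
    )
  }
})

test_that("silhouette is invariant to translation and uniform scaling", {
  set.seed(14)
  x <- matrix(rnorm(30), 10)
  labels <- rep(c("a", "b"), 5)
  base <- silhouette_score(x, labels)
  expect_equal(silhouette_score(3.7 * x, labels), base)
  shifted <- sweep(x, 2, c(5, -2, 100), `+`)
  expect_equal(silhouette_score(shifted, labels), base)
})

test_that("signed-rank test enumerates the exact null for small n", {
  # all-positive distinct differences at n = 5: one-tailed 1/32, two-sided 2/32
  out <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(out$p_value, 0.0625)
  expect_equal(out$statistic, 15)

  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res$p_value, 1)
  expect_true(res$all_zero)
})

test_that("signed-rank test matches full enumeration for n = 10", {
  set.seed(15)
  for (rep in 1:10) {
    a <- rnorm(10)
    b <- rnorm(10)
    expect_equal(
      wilcoxon_signed_rank(a, b)$p_value, oracle_wilcoxon(a, b),
      tolerance = 1e-12
    )
  }
})

test_that("large-n normal approximation is sane and tie-corrected", {
  set.seed(16)
  a <- rnorm(30)
  b <- a + 0.005 * sign(rnorm(30)) # symmetric small differences
  p <- wilcoxon_signed_rank(a, b)$p_value
  expect_gt(p, 0.01)
  # strong one-directional shift is detected
  p2 <- wilcoxon_signed_rank(a + 1, a)$p_value
  expect_lt(p2, 1e-4)
  # ties in |d| do not break the computation
  p3 <- wilcoxon_signed_rank(c(rep(1.5, 8), rnorm(6)), rep(0, 14))$p_value
  expect_true(p3 >= 0 && p3 <= 1)
})

test_that("repeated-run summaries aggregate per-run metrics exactly", {
  # two-point mean/sd formula on a synthetic per-run table
  vals <- c(0.5, 0.7)
  expect_equal(mean(vals), 0.6)
  expect_equal(stats::sd(vals), sqrt(sum((vals - 0.6)^2) / 1))

  co <- tiny_cohort()
  cfg <- desk_config("unimodal", seed = 0, epochs = 2)
  rep2 <- repeat_experiment(co, cfg, n_runs = 2, base_seed = 21,
    spec = encoder_spec(
      d = 8, head_width = 4, image_size = 32,
      channels = c(2, 3, 4), hash_buckets = 64
    )
  )
  expect_equal(sort(unique(rep2$per_run$seed)), c(21L, 22L))
  # summary re-aggregates the per-run values exactly
  for (src in unique(rep2$per_run$source)) {
    k <- rep2$per_run$kappa[rep2$per_run$source == src]
    row <- rep2$summary[
      rep2$summary$source == src & rep2$summary$metric == "kappa",
    ]
    expect_equal(row$mean, mean(k))
    expect_equal(row$sd, stats::sd(k))
  }
  g <- glance(rep2)
  expect_equal(g$n_runs, 2)
  expect_equal(g$mean_kappa, mean(rep2$per_run$kappa))
})

test_that("experiment comparison pairs runs and renders markdown", {
  mk_report <- function(kappas) {
    structure(
      list(
        per_run = tibble::tibble(
          run = seq_along(kappas), seed = seq_along(kappas),
          source = "synthetic", kappa = kappas, silhouette = 0
        ),
        summary = NULL,
        config = desk_config("unimodal")
      ),
      class = "metric_report"
    )
  }
  a <- mk_report(c(0.8, 0.82, 0.78, 0.81, 0.79, 0.8))
  b <- mk_report(c(0.6, 0.63, 0.58, 0.61, 0.6, 0.59))
  cmp <- compare_experiments(a, b)
  expect_equal(nrow(cmp), 1L)
  expect_equal(
    cmp$p_value,
    wilcoxon_signed_rank(a$per_run$kappa, b$per_run$kappa)$p_value
  )
  md <- format_comparison_md(cmp, c("MM", "unimodal"))
  expect_match(md, "\\| synthetic \\|")
  expect_match(md, "\\*", fixed = FALSE) # significant star present
})
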