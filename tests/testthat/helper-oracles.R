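# Independent brute-force oracles used to check the package's closed-form
# implementations. Deliberately written as explicit loops over anchors,
# negatives and sample pairs, sharing no code with the implementation.

oracle_cross_entropy <- function(logits, idx) {
  total <- 0
  for (i in seq_len(nrow(logits))) {
    z <- logits[i, ]
    p <- exp(z) / sum(exp(z))
    total <- total - log(p[idx[i]])
  }
  total / nrow(logits)
}

oracle_cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# 2N-view NT-Xent: loop over every anchor, sum exp similarities over all
# other rows of the stack
oracle_nt_xent <- function(e_img, e_txt, tau) {
  z <- rbind(e_img, e_txt)
  n <- nrow(e_img)
  m <- 2 * n
  pos <- c((n + 1):m, 1:n)
  total <- 0
  for (a in seq_len(m)) {
    denom <- 0
    for (k in seq_len(m)) {
      if (k != a) denom <- denom + exp(oracle_cosine(z[a, ], z[k, ]) / tau)
    }
    num <- exp(oracle_cosine(z[a, ], z[pos[a], ]) / tau)
    total <- total - log(num / denom)
  }
  total / m
}

# symmetric cross-modal InfoNCE: directional softmax in each direction
oracle_info_nce <- function(e_img, e_txt, tau) {
  n <- nrow(e_img)
  l_i2t <- 0
  for (i in seq_len(n)) {
    denom <- 0
    for (j in seq_len(n)) {
      denom <- denom + exp(oracle_cosine(e_img[i, ], e_txt[j, ]) / tau)
    }
    l_i2t <- l_i2t -
      log(exp(oracle_cosine(e_img[i, ], e_txt[i, ]) / tau) / denom)
  }
  l_t2i <- 0
  for (j in seq_len(n)) {
    denom <- 0
    for (i in seq_len(n)) {
      denom <- denom + exp(oracle_cosine(e_txt[j, ], e_img[i, ]) / tau)
    }
    l_t2i <- l_t2i -
      log(exp(oracle_cosine(e_txt[j, ], e_img[j, ]) / tau) / denom)
  }
  (l_i2t / n + l_t2i / n) / 2
}

# confusion-matrix kappa
oracle_kappa <- function(y_true, y_pred) {
  lev <- union(unique(y_true), unique(y_pred))
  cm <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(y_true)) {
    cm[as.character(y_true[i]), as.character(y_pred[i])] <-
      cm[as.character(y_true[i]), as.character(y_pred[i])] + 1
  }
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (p_e >= 1) {
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

# explicit double-loop silhouette
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dmat[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- setdiff(same, i)
    if (length(same) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(dmat[i, same])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dmat[i, labels == cl]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive 2^n two-sided signed-rank p-value
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    w_all[mask + 1] <- sum(r[bits == 1])
  }
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# hand-written pixel-statistic rule: estimate the background from the image
# border, average the clearly-lesional pixels, and pick the nearest class
# colour at the configured separation
oracle_motif_rule <- function(image, cfg) {
  s <- dim(image)[1]
  border <- rbind(
    matrix(image[1, , ], ncol = 3), matrix(image[s, , ], ncol = 3),
    matrix(image[, 1, ], ncol = 3), matrix(image[, s, ], ncol = 3)
  )
  bg <- colMeans(border)
  px <- matrix(image, ncol = 3)
  dist_bg <- sqrt(rowSums((px - rep(bg, each = nrow(px)))^2))
  lesional <- px[dist_bg > max(0.08, 2 * stats::median(dist_bg)), , drop = FALSE]
  if (nrow(lesional) == 0) lesional <- px[order(-dist_bg)[1:20], , drop = FALSE]
  mean_col <- colMeans(lesional)
  targets <- vapply(
    dermcolearn:::synth_class_colors(),
    function(col) {
      dermcolearn:::synth_background +
        cfg$motif_separation * (col - dermcolearn:::synth_background)
    },
    numeric(3)
  )
  codes <- colnames(targets)
  dists <- apply(targets, 2, function(tc) sqrt(sum((mean_col - tc)^2)))
  codes[which.min(dists)]
}

oracle_rule_accuracy <- function(cohort, cfg) {
  pred <- vapply(
    cohort$records$record_id,
    function(id) oracle_motif_rule(cohort$images[[id]], cfg),
    character(1)
  )
  mean(pred == cohort$records$label)
}

# tiny separable cohort shared by the fast training tests; built once
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(
        synth_config(n_per_class = 12, image_size = 32, noise_sd = 0,
          motif_separation = 1, seed = 11)
      )
      cache <<- split_cohort(co, c(0.5, 0.25, 0.25), seed = 11)
    }
    cache
  }
})

# full-scale noise-free cohort for the learnability sanity check
separable_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(
        synth_config(n_per_class = 40, noise_sd = 0, motif_separation = 1,
          seed = 1)
      )
      cache <<- split_cohort(co, c(0.6, 0.2, 0.2), seed = 1)
    }
    cache
  }
})
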