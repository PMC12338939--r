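#' Loss weights for the composite objective
#'
#' The composite training objective weights five components: image
#' cross-entropy, text cross-entropy, L1 alignment, cosine alignment and a
#' self-supervised contrastive term. The presets fix all weights at 1
#' except the contrastive weight, which is 0.5 with temperature 0.5 when
#' NT-Xent is used and 0.25 with temperature 0.07 when InfoNCE is used; the
#' `"unimodal"` preset zeroes every text-dependent component so training
#' reduces to image classification.
#'
#' @param preset One of `"nt_xent_default"`, `"info_nce_default"`,
#'   `"unimodal"`.
#' @param w_ce_image,w_ce_text,w_l1,w_cos,w_ssl Optional overrides of the
#'   preset weights.
#' @param tau Optional override of the contrastive temperature (> 0).
#' @return An object of class `loss_weights`: list with fields `w_ce_image`,
#'   `w_ce_text`, `w_l1`, `w_cos`, `w_ssl`, `ssl_kind`, `tau`.
#' @examples
#' loss_weights("nt_xent_default")
#' loss_weights("info_nce_default")
#' @export
loss_weights <- function(preset = c(
                           "nt_xent_default", "info_nce_default", "unimodal"
                         ),
                         w_ce_image = NULL, w_ce_text = NULL, w_l1 = NULL,
                         w_cos = NULL, w_ssl = NULL, tau = NULL) {
  preset <- match.arg(preset)
  w <- switch(preset,
    nt_xent_default = list(
      w_ce_image = 1, w_ce_text = 1, w_l1 = 1, w_cos = 1,
      w_ssl = 0.5, ssl_kind = "nt_xent", tau = 0.5
    ),
    info_nce_default = list(
      w_ce_image = 1, w_ce_text = 1, w_l1 = 1, w_cos = 1,
      w_ssl = 0.25, ssl_kind = "info_nce", tau = 0.07
    ),
    unimodal = list(
      w_ce_image = 1, w_ce_text = 0, w_l1 = 0, w_cos = 0,
      w_ssl = 0, ssl_kind = "nt_xent", tau = 0.5
    )
  )
  for (field in c("w_ce_image", "w_ce_text", "w_l1", "w_cos", "w_ssl")) {
    override <- get(field)
    if (!is.null(override)) w[[field]] <- override
  }
  if (!is.null(tau)) {
    stopifnot(tau > 0)
    w$tau <- tau
  }
  structure(w, class = "loss_weights")
}

#' @export
print.loss_weights <- function(x, ...) {
  cat(
    "<loss_weights> ce_img=", x$w_ce_image, " ce_txt=", x$w_ce_text,
    " l1=", x$w_l1, " cos=", x$w_cos, " ssl=", x$w_ssl,
    " (", x$ssl_kind, ", tau=", x$tau, ")\n",
    sep = ""
  )
  invisible(x)
}

# labels -> integer index 1..5 (accepts codes, factors, or 1-based integers)
label_index <- function(labels) {
  codes <- lesion_class_codes()
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, codes)
  } else {
    idx <- as.integer(labels)
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > 5L)) {
    stop("labels must be class codes or integers in 1..5", call. = FALSE)
  }
  idx
}

log_softmax <- function(logits) {
  m <- apply(logits, 1L, max)
  s <- logits - m
  s - log(rowSums(exp(s)))
}

#' Multiclass cross-entropy
#'
#' Mean negative log-softmax probability of the true class.
#'
#' @param logits N x 5 numeric matrix.
#' @param labels Length-N class codes (or 1-based integer indices).
#' @return A nonnegative scalar.
#' @examples
#' cross_entropy(matrix(0, 2, 5), c("MEL", "NEV")) # log(5)
#' @export
cross_entropy <- function(logits, labels) {
  idx <- label_index(labels)
  if (nrow(logits) != length(idx)) {
    stop("logits and labels lengths differ", call. = FALSE)
  }
  ls <- log_softmax(logits)
  -mean(ls[cbind(seq_along(idx), idx)])
}

cross_entropy_grad <- function(logits, labels) {
  idx <- label_index(labels)
  n <- nrow(logits)
  ls <- log_softmax(logits)
  p <- exp(ls)
  y <- matrix(0, n, ncol(logits))
  y[cbind(seq_len(n), idx)] <- 1
  list(
    value = -mean(ls[cbind(seq_len(n), idx)]),
    dlogits = (p - y) / n
  )
}

check_pair_shapes <- function(e_img, e_txt) {
  if (!identical(dim(e_img), dim(e_txt))) {
    stop("embedding matrices must have identical shapes", call. = FALSE)
  }
}

#' L1 alignment loss
#'
#' Mean absolute difference over all entries of the paired embedding
#' matrices. Zero iff the matrices are equal; the mean (not sum) reduction
#' keeps the weight comparable across embedding widths.
#'
#' @param e_img,e_txt N x d matrices of paired embeddings (row i of each is
#'   the same record).
#' @return A nonnegative scalar.
#' @export
l1_alignment <- function(e_img, e_txt) {
  check_pair_shapes(e_img, e_txt)
  mean(abs(e_img - e_txt))
}

l1_alignment_grad <- function(e_img, e_txt) {
  check_pair_shapes(e_img, e_txt)
  s <- sign(e_img - e_txt) / length(e_img)
  list(value = mean(abs(e_img - e_txt)), d_img = s, d_txt = -s)
}

row_norms <- function(x) sqrt(rowSums(x^2))

normalize_rows <- function(x) {
  n <- row_norms(x)
  if (any(n < 1e-12)) {
    stop("zero-norm embedding row", call. = FALSE)
  }
  x / n
}

# chain a gradient w.r.t. unit rows back to the raw rows
unnormalize_grad <- function(du, x) {
  n <- row_norms(x)
  u <- x / n
  (du - u * rowSums(du * u)) / n
}

#' Cosine alignment loss
#'
#' Mean over pairs of `1 - cos(e_img_i, e_txt_i)`; range `[0, 2]`, zero for
#' identical directions.
#'
#' @inheritParams l1_alignment
#' @return A scalar in `[0, 2]`.
#' @export
cosine_alignment <- function(e_img, e_txt) {
  check_pair_shapes(e_img, e_txt)
  u <- normalize_rows(e_img)
  v <- normalize_rows(e_txt)
  mean(1 - rowSums(u * v))
}

cosine_alignment_grad <- function(e_img, e_txt) {
  check_pair_shapes(e_img, e_txt)
  u <- normalize_rows(e_img)
  v <- normalize_rows(e_txt)
  n <- nrow(u)
  list(
    value = mean(1 - rowSums(u * v)),
    d_img = unnormalize_grad(-v / n, e_img),
    d_txt = unnormalize_grad(-u / n, e_txt)
  )
}

#' NT-Xent contrastive loss
#'
#' Normalized temperature-scaled cross-entropy over the 2N views obtained by
#' stacking the two modality batches. The positive of image row i is text
#' row i (and vice versa); every other row of the stack — both intra- and
#' cross-modality — is a negative. Similarities are cosine, divided by the
#' temperature `tau`. With N = 1 the only candidate is the positive, so the
#' loss is 0. Invariant to row-wise rescaling of either matrix.
#'
#' @inheritParams l1_alignment
#' @param tau Temperature, > 0.
#' @return A nonnegative scalar.
#' @export
nt_xent <- function(e_img, e_txt, tau = 0.5) {
  nt_xent_grad(e_img, e_txt, tau, grad = FALSE)$value
}

nt_xent_grad <- function(e_img, e_txt, tau = 0.5, grad = TRUE) {
  check_pair_shapes(e_img, e_txt)
  stopifnot(tau > 0)
  n <- nrow(e_img)
  z <- rbind(normalize_rows(e_img), normalize_rows(e_txt))
  m <- 2L * n
  s <- tcrossprod(z) / tau
  pos <- c((n + 1L):m, 1L:n)
  # row-wise log-sum-exp excluding the diagonal (self)
  diag(s) <- -Inf
  rmax <- apply(s, 1L, max)
  lse <- rmax + log(rowSums(exp(s - rmax)))
  value <- mean(lse - s[cbind(seq_len(m), pos)])
  if (!grad) {
    return(list(value = value))
  }
  p <- exp(s - lse) # softmax over k != a (diag contributes 0)
  g <- p / m
  g[cbind(seq_len(m), pos)] <- g[cbind(seq_len(m), pos)] - 1 / m
  dz <- ((g + t(g)) %*% z) / tau
  list(
    value = value,
    d_img = unnormalize_grad(dz[1:n, , drop = FALSE], e_img),
    d_txt = unnormalize_grad(dz[(n + 1L):m, , drop = FALSE], e_txt)
  )
}

#' InfoNCE contrastive loss (symmetric cross-modal)
#'
#' For each image row the paired text row is the positive and the remaining
#' text rows are the negatives (image-to-text direction); the text-to-image
#' direction is symmetric, and the returned value is the mean of the two
#' directional means. Negatives are cross-modality only, which is what
#' distinguishes this option from [nt_xent()]'s full 2N pool. Similarities
#' are cosine divided by `tau`. N = 1 gives 0.
#'
#' @inheritParams nt_xent
#' @return A nonnegative scalar.
#' @export
info_nce <- function(e_img, e_txt, tau = 0.07) {
  info_nce_grad(e_img, e_txt, tau, grad = FALSE)$value
}

info_nce_grad <- function(e_img, e_txt, tau = 0.07, grad = TRUE) {
  check_pair_shapes(e_img, e_txt)
  stopifnot(tau > 0)
  n <- nrow(e_img)
  u <- normalize_rows(e_img)
  v <- normalize_rows(e_txt)
  s <- tcrossprod(u, v) / tau
  rmax <- apply(s, 1L, max)
  lse_r <- rmax + log(rowSums(exp(s - rmax)))
  cmax <- apply(s, 2L, max)
  lse_c <- cmax + log(colSums(exp(t(t(s) - cmax))))
  value <- (mean(lse_r - diag(s)) + mean(lse_c - diag(s))) / 2
  if (!grad) {
    return(list(value = value))
  }
  p_row <- exp(s - lse_r)
  p_col <- exp(t(t(s) - lse_c))
  ds <- (p_row + p_col) / (2 * n)
  diag(ds) <- diag(ds) - 1 / n
  list(
    value = value,
    d_img = unnormalize_grad((ds %*% v) / tau, e_img),
    d_txt = unnormalize_grad((crossprod(ds, u)) / tau, e_txt)
  )
}

#' Composite co-learning loss
#'
#' Weighted sum of the five components; the breakdown is returned for
#' logging and for verifying that the total reproduces the weighted sum.
#' Components whose weight is zero are skipped, so text inputs may be `NULL`
#' in unimodal training.
#'
#' @param logits_img,logits_txt N x 5 logit matrices (text may be `NULL`
#'   when all text-dependent weights are zero).
#' @param labels Length-N labels.
#' @param e_img,e_txt N x h matrices of aligned (post-projection)
#'   embeddings.
#' @param weights A [loss_weights()] object.
#' @return A `loss_breakdown`: list with `total`, `ce_image`, `ce_text`,
#'   `l1`, `cosine`, `ssl`.
#' @export
composite_loss <- function(logits_img, logits_txt, labels, e_img, e_txt,
                           weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  ssl_fun <- switch(weights$ssl_kind,
    nt_xent = nt_xent,
    info_nce = info_nce
  )
  ce_image <- cross_entropy(logits_img, labels)
  ce_text <- if (weights$w_ce_text != 0) {
    cross_entropy(logits_txt, labels)
  } else {
    0
  }
  l1 <- if (weights$w_l1 != 0) l1_alignment(e_img, e_txt) else 0
  cosine <- if (weights$w_cos != 0) cosine_alignment(e_img, e_txt) else 0
  ssl <- if (weights$w_ssl != 0) ssl_fun(e_img, e_txt, weights$tau) else 0
  new_loss_breakdown(ce_image, ce_text, l1, cosine, ssl, weights)
}

new_loss_breakdown <- function(ce_image, ce_text, l1, cosine, ssl, weights) {
  structure(
    list(
      total = weights$w_ce_image * ce_image + weights$w_ce_text * ce_text +
        weights$w_l1 * l1 + weights$w_cos * cosine + weights$w_ssl * ssl,
      ce_image = ce_image, ce_text = ce_text,
      l1 = l1, cosine = cosine, ssl = ssl
    ),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total=%.4f (ce_img=%.4f ce_txt=%.4f l1=%.4f cos=%.4f ssl=%.4f)\n",
    x$total, x$ce_image, x$ce_text, x$l1, x$cosine, x$ssl
  ))
  invisible(x)
}
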