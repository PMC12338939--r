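#' Encoder specification
#'
#' Describes the two modality branches and the shared head. The reference
#' image encoder is a three-block strided 3x3 convolutional network
#' (channels `channels`, stride 2, zero padding 1, ReLU) followed by global
#' average pooling and a linear map to width `d`; the reference text encoder
#' is a token-hash bag-of-words (`hash_buckets` buckets, term-frequency
#' normalized) followed by a linear map to the same width `d`. Both feed the
#' shared projection (`d -> head_width`) and the shared 5-class classifier.
#' Heavier backbones can be swapped in by supplying pre-computed embeddings
#' of width `d` to [classify()]; nothing in the package requires downloads.
#'
#' @param d Shared embedding width produced by both encoders (>= 2).
#' @param head_width Width of the shared projection space where the
#'   alignment losses operate.
#' @param image_size Expected square image side in pixels (>= 16).
#' @param channels Integer vector of the three conv block output channels.
#' @param hash_buckets Number of hash buckets of the bag-of-words encoder.
#' @param init_seed Seed for parameter initialization, so that repeated
#'   runs are reproducible.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(d = 32L, head_width = 16L, image_size = 64L,
                         channels = c(8L, 16L, 32L), hash_buckets = 512L,
                         init_seed = 0L) {
  stopifnot(d >= 2, head_width >= 2, image_size >= 16, length(channels) == 3)
  structure(
    list(
      d = as.integer(d), head_width = as.integer(head_width),
      image_size = as.integer(image_size), channels = as.integer(channels),
      hash_buckets = as.integer(hash_buckets),
      init_seed = as.integer(init_seed)
    ),
    class = "encoder_spec"
  )
}

# ---- parameter initialization -------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Initialize a co-learning model
#'
#' Creates the full parameter set (image branch, text branch, shared
#' projection and classifier) from an [encoder_spec()], using He-scaled
#' Gaussian initialization under `spec$init_seed`. The projection and
#' classifier parameters are a single set serving both modalities; no
#' per-modality copies exist anywhere in the model.
#'
#' @param spec An [encoder_spec()].
#' @return An object of class `colearn_model`: list with `spec` and `params`
#'   (named list of weight matrices / bias vectors).
#' @export
init_model <- function(spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"))
  ch <- spec$channels
  params <- withr_seed(spec$init_seed, {
    list(
      conv1_W = he_init(9 * 3, ch[1], 9 * 3),
      conv1_b = numeric(ch[1]),
      conv2_W = he_init(9 * ch[1], ch[2], 9 * ch[1]),
      conv2_b = numeric(ch[2]),
      conv3_W = he_init(9 * ch[2], ch[3], 9 * ch[2]),
      conv3_b = numeric(ch[3]),
      # small non-zero biases so a fully dead ReLU stack cannot produce an
      # exactly-zero embedding row (which the cosine-based losses reject)
      img_W = he_init(ch[3], spec$d, ch[3]),
      img_b = stats::rnorm(spec$d, sd = 0.01),
      txt_W = he_init(spec$hash_buckets, spec$d, 32),
      txt_b = stats::rnorm(spec$d, sd = 0.01),
      proj_W = he_init(spec$d, spec$head_width, spec$d),
      proj_b = stats::rnorm(spec$head_width, sd = 0.01),
      cls_W = he_init(spec$head_width, 5L, spec$head_width),
      cls_b = numeric(5L)
    )
  })
  structure(list(spec = spec, params = params), class = "colearn_model")
}

image_param_names <- c(
  "conv1_W", "conv1_b", "conv2_W", "conv2_b", "conv3_W", "conv3_b",
  "img_W", "img_b"
)
text_param_names <- c("txt_W", "txt_b")
head_param_names <- c("proj_W", "proj_b", "cls_W", "cls_b")

# ---- im2col machinery ----------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

# index matrix mapping (output position, patch entry) -> linear index into
# the zero-padded input array; 3x3 kernel, stride 2, pad 1
im2col_index <- function(h, w, c) {
  key <- paste(h, w, c, sep = "_")
  if (!is.null(.idx_cache[[key]])) {
    return(.idx_cache[[key]])
  }
  hp <- h + 2L
  wp <- w + 2L
  ho <- (h - 1L) %/% 2L + 1L
  wo <- (w - 1L) %/% 2L + 1L
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  top <- (oi - 1L) * 2L + 1L
  left <- (oj - 1L) * 2L + 1L
  dr <- rep(0:2, times = 3)
  dc <- rep(0:2, each = 3)
  # rows: positions (i fastest); cols: (dr, dc) fastest then channel
  base <- outer(top, dr, `+`) + outer(left, dc, `+`) * hp - hp
  idx <- matrix(0L, ho * wo, 9L * c)
  for (ch in seq_len(c)) {
    idx[, (ch - 1L) * 9L + 1:9] <- base + (ch - 1L) * hp * wp
  }
  # inverse map for the backward scatter-add: each padded pixel appears in
  # at most 4 (position, kernel-offset) slots at stride 2; inv[p, k] holds
  # the k-th such slot's linear index into the col matrix (0 = unused)
  npix <- hp * wp * c
  ids <- as.vector(idx)
  ord <- order(ids)
  sorted <- ids[ord]
  rl <- rle(sorted)
  occ <- sequence(rl$lengths)
  inv <- matrix(0L, npix, max(rl$lengths))
  inv[cbind(sorted, occ)] <- ord
  out <- list(
    idx = idx, inv = inv, h = h, w = w, c = c, ho = ho, wo = wo
  )
  .idx_cache[[key]] <- out
  out
}

pad_image <- function(x) {
  d <- dim(x)
  out <- array(0, d + c(2L, 2L, 0L))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

conv_forward <- function(x, w, b, geom) {
  col <- matrix(pad_image(x)[geom$idx], nrow(geom$idx), ncol(geom$idx))
  pre <- col %*% w
  pre <- sweep(pre, 2L, b, `+`)
  out <- array(pmax(pre, 0), c(geom$ho, geom$wo, ncol(w)))
  list(out = out, col = col, pre = pre)
}

conv_backward <- function(dout, cache, w, geom, need_dx = TRUE) {
  dmat <- matrix(dout, geom$ho * geom$wo, dim(dout)[3])
  dmat <- dmat * (cache$pre > 0)
  dw <- crossprod(cache$col, dmat)
  db <- colSums(dmat)
  if (!need_dx) {
    return(list(dx = NULL, dw = dw, db = db))
  }
  dcol <- tcrossprod(dmat, w)
  hp <- geom$h + 2L
  wp <- geom$w + 2L
  v <- c(0, as.vector(dcol))
  dpad <- array(
    .rowSums(v[geom$inv + 1L], nrow(geom$inv), ncol(geom$inv)),
    c(hp, wp, geom$c)
  )
  list(
    dx = dpad[2:(geom$h + 1L), 2:(geom$w + 1L), , drop = FALSE],
    dw = dw, db = db
  )
}

# full image branch forward for one image; returns pooled feature + caches
image_forward_one <- function(x, params, keep_cache = FALSE) {
  d <- dim(x)
  g1 <- im2col_index(d[1], d[2], 3L)
  c1 <- conv_forward(x, params$conv1_W, params$conv1_b, g1)
  g2 <- im2col_index(g1$ho, g1$wo, ncol(params$conv1_W))
  c2 <- conv_forward(c1$out, params$conv2_W, params$conv2_b, g2)
  g3 <- im2col_index(g2$ho, g2$wo, ncol(params$conv2_W))
  c3 <- conv_forward(c2$out, params$conv3_W, params$conv3_b, g3)
  pooled <- apply(c3$out, 3L, mean)
  if (keep_cache) {
    list(pooled = pooled, c1 = c1, c2 = c2, c3 = c3, g1 = g1, g2 = g2, g3 = g3)
  } else {
    list(pooled = pooled)
  }
}

image_backward_one <- function(dpooled, cache, params) {
  g3 <- cache$g3
  npix3 <- g3$ho * g3$wo
  dout3 <- array(
    rep(dpooled / npix3, each = npix3),
    c(g3$ho, g3$wo, length(dpooled))
  )
  b3 <- conv_backward(dout3, cache$c3, params$conv3_W, g3)
  b2 <- conv_backward(b3$dx, cache$c2, params$conv2_W, cache$g2)
  b1 <- conv_backward(b2$dx, cache$c1, params$conv1_W, cache$g1,
    need_dx = FALSE
  )
  list(
    conv1_W = b1$dw, conv1_b = b1$db,
    conv2_W = b2$dw, conv2_b = b2$db,
    conv3_W = b3$dw, conv3_b = b3$db
  )
}

# ---- text featurization --------------------------------------------------

hash_token <- function(token, buckets) {
  h <- 0
  for (b in utf8ToInt(token)) {
    h <- (h * 31 + b) %% buckets
  }
  as.integer(h) + 1L
}

#' Bag-of-words features via token hashing
#'
#' Tokenizes on non-alphanumeric characters, hashes each token into a fixed
#' number of buckets, and returns L2-normalized count vectors (the usual
#' normalization for hashed bag-of-words features). Deterministic,
#' vocabulary-free, and identical across sessions.
#'
#' @param texts Character vector of non-empty report strings.
#' @param buckets Number of hash buckets.
#' @return A `length(texts)` x `buckets` numeric matrix.
#' @export
text_features <- function(texts, buckets = 512L) {
  if (any(!nzchar(texts)) || anyNA(texts)) {
    stop("empty report text", call. = FALSE)
  }
  x <- matrix(0, length(texts), buckets)
  for (i in seq_along(texts)) {
    tokens <- strsplit(tolower(texts[i]), "[^a-z0-9']+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens)) {
      stop("report ", i, " contains no tokens", call. = FALSE)
    }
    idx <- vapply(tokens, hash_token, integer(1), buckets = buckets)
    tab <- table(idx)
    counts <- as.integer(tab)
    x[i, as.integer(names(tab))] <- counts / sqrt(sum(counts^2))
  }
  x
}

# ---- public encoding surface --------------------------------------------

as_image_list <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- list(images)
  }
  stopifnot(is.list(images), length(images) >= 1L)
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1L) {
    stop("all images in a batch must share the same shape", call. = FALSE)
  }
  d <- dims[[1]]
  if (length(d) != 3L || d[3] != 3L || d[1] < 8L || d[2] < 8L) {
    stop("images must be HxWx3 arrays with H, W >= 8", call. = FALSE)
  }
  images
}

new_embedding_batch <- function(matrix, modality, labels = NULL) {
  stopifnot(all(is.finite(matrix)))
  structure(
    list(matrix = matrix, modality = modality, labels = labels,
         d = ncol(matrix)),
    class = "embedding_batch"
  )
}

#' @export
print.embedding_batch <- function(x, ...) {
  cat(
    "<embedding_batch> ", nrow(x$matrix), " x ", x$d,
    " (", x$modality, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Encode a batch of images
#'
#' Runs the image branch: conv blocks, global average pooling and the
#' linear map to the shared width. Evaluation mode is deterministic for
#' fixed parameters; `train` mode differs only in that callers typically
#' feed augmented images.
#'
#' @param images List of HxWx3 numeric arrays in `[0, 1]` (a single array is
#'   accepted), all with the same shape.
#' @param model A [init_model()] object (or a trained fit's `$model`).
#' @param mode `"eval"` or `"train"`.
#' @param labels Optional label vector carried along for evaluation.
#' @return An `embedding_batch` with an N x d matrix, `modality = "image"`.
#' @export
encode_images <- function(images, model, mode = c("eval", "train"),
                          labels = NULL) {
  mode <- match.arg(mode)
  images <- as_image_list(images)
  pooled <- t(vapply(
    images,
    function(x) image_forward_one(x, model$params)$pooled,
    numeric(ncol(model$params$conv3_W))
  ))
  e <- sweep(pooled %*% model$params$img_W, 2L, model$params$img_b, `+`)
  new_embedding_batch(e, "image", labels)
}

#' Encode a batch of report texts
#'
#' Runs the text branch: hashed bag-of-words features and the linear map to
#' the shared width (equal to the image branch's width).
#'
#' @param texts Character vector of non-empty report strings.
#' @inheritParams encode_images
#' @return An `embedding_batch` with an N x d matrix, `modality = "text"`.
#' @export
encode_texts <- function(texts, model, mode = c("eval", "train"),
                         labels = NULL) {
  mode <- match.arg(mode)
  x <- text_features(texts, model$spec$hash_buckets)
  e <- sweep(x %*% model$params$txt_W, 2L, model$params$txt_b, `+`)
  new_embedding_batch(e, "text", labels)
}

#' Project embeddings into the shared alignment space
#'
#' Applies the shared projection (one parameter set for both modalities).
#' The alignment losses and the silhouette evaluation operate in this space.
#'
#' @param emb An `embedding_batch` of width `spec$d`.
#' @param model A `colearn_model`.
#' @return An N x `head_width` matrix.
#' @export
project_embeddings <- function(emb, model) {
  stopifnot(inherits(emb, "embedding_batch"))
  if (emb$d != nrow(model$params$proj_W)) {
    stop("embedding width ", emb$d, " does not match head input width ",
      nrow(model$params$proj_W),
      call. = FALSE
    )
  }
  sweep(emb$matrix %*% model$params$proj_W, 2L, model$params$proj_b, `+`)
}

#' Classify embeddings with the shared head
#'
#' The same projection + classifier parameters are applied regardless of the
#' batch's modality: weight sharing is the alignment mechanism, so image and
#' text embeddings with identical values receive identical logits.
#'
#' @inheritParams project_embeddings
#' @return An N x 5 logit matrix with columns named by class code.
#' @export
classify <- function(emb, model) {
  h <- project_embeddings(emb, model)
  logits <- sweep(h %*% model$params$cls_W, 2L, model$params$cls_b, `+`)
  colnames(logits) <- lesion_class_codes()
  logits
}

#' @export
print.colearn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(
    "<colearn_model> d = ", x$spec$d, ", head width = ", x$spec$head_width,
    ", ", n_par, " parameters\n",
    sep = ""
  )
  invisible(x)
}
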