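#' Image augmentation configuration
#'
#' The training augmentation composes a sampled right-angle rotation,
#' optional horizontal/vertical flips (each applied with probability 0.5
#' when enabled), and a light per-channel RGB shift drawn uniformly from
#' `[-rgb_jitter, rgb_jitter]` (fraction of the dynamic range, clipped to
#' `[0, 1]`).
#'
#' @param rotation_angles Degrees to sample from; multiples of 90 only, so
#'   small fixtures avoid interpolation artifacts.
#' @param hflip,vflip Enable the corresponding flip.
#' @param rgb_jitter Jitter magnitude in `[0, 0.1]`.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_angles = c(0, 90, 180, 270),
                           hflip = TRUE, vflip = TRUE, rgb_jitter = 0.05) {
  stopifnot(
    all(rotation_angles %% 90 == 0),
    rgb_jitter >= 0, rgb_jitter <= 0.1
  )
  structure(
    list(
      rotation_angles = rotation_angles %% 360,
      hflip = isTRUE(hflip), vflip = isTRUE(vflip),
      rgb_jitter = rgb_jitter
    ),
    class = "augment_config"
  )
}

#' No-op augmentation
#'
#' @return An `augment_config` under which [augment_image()] is the
#'   identity.
#' @export
no_augment <- function() {
  augment_config(
    rotation_angles = 0, hflip = FALSE, vflip = FALSE,
    rgb_jitter = 0
  )
}

rotate90_cw <- function(x) {
  aperm(x[rev(seq_len(dim(x)[1])), , , drop = FALSE], c(2, 1, 3))
}

#' Augment one image
#'
#' Draws the augmentation from the current RNG stream: one rotation angle,
#' the flips, and the RGB jitter. With [no_augment()] the input is returned
#' unchanged. Rotations and flips permute pixels, so they preserve the
#' multiset of pixel values; only the jitter changes intensities.
#'
#' @param image HxWx3 array in `[0, 1]`.
#' @param cfg An [augment_config()].
#' @return An array of the same shape.
#' @export
augment_image <- function(image, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  angle <- if (length(cfg$rotation_angles) > 1L) {
    sample(cfg$rotation_angles, 1L)
  } else {
    cfg$rotation_angles
  }
  for (k in seq_len((angle %/% 90) %% 4)) {
    image <- rotate90_cw(image)
  }
  if (cfg$hflip && stats::runif(1) < 0.5) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  }
  if (cfg$vflip && stats::runif(1) < 0.5) {
    image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
  }
  if (cfg$rgb_jitter > 0) {
    shift <- stats::runif(3, -cfg$rgb_jitter, cfg$rgb_jitter)
    image <- sweep(image, 3L, shift, `+`)
    image <- pmin(pmax(image, 0), 1)
  }
  image
}

#' Training configuration
#'
#' Defaults are the hyperparameters used for full-scale training of the
#' pretrained backbones: 10 epochs, Adam with learning rate 1e-4, batch
#' size 32, weight decay 1e-5, report-turnover probability 0.5. For the
#' package's small reference encoders trained from scratch see
#' [desk_config()], which rescales the optimizer.
#'
#' @param epochs Number of training epochs (>= 0).
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param weight_decay L2 penalty coupled into the Adam gradient.
#' @param loss_weights A [loss_weights()] object.
#' @param mode `"multimodal"` (images + reports) or `"unimodal"` (images
#'   only; all text-dependent loss weights are forced to zero and the text
#'   branch receives no updates).
#' @param turnover_probability Probability that the synthesized report (as
#'   opposed to the structured one) is fed for a training record.
#' @param seed Integer seed determining sampling, augmentation, turnover
#'   and parameter initialization; identical configs and seeds give
#'   identical histories and parameters.
#' @param augmentation An [augment_config()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, learning_rate = 1e-4,
                         batch_size = 32L, weight_decay = 1e-5,
                         loss_weights = dermcolearn::loss_weights(),
                         mode = c("multimodal", "unimodal"),
                         turnover_probability = 0.5, seed = 0L,
                         augmentation = augment_config()) {
  mode <- match.arg(mode)
  stopifnot(
    epochs >= 0, learning_rate > 0, batch_size >= 1,
    weight_decay >= 0, turnover_probability >= 0, turnover_probability <= 1
  )
  if (mode == "unimodal") {
    loss_weights <- dermcolearn::loss_weights(
      "unimodal",
      w_ce_image = loss_weights$w_ce_image
    )
  }
  structure(
    list(
      epochs = as.integer(epochs), learning_rate = learning_rate,
      optimizer = "adam", batch_size = as.integer(batch_size),
      weight_decay = weight_decay, loss_weights = loss_weights,
      mode = mode, turnover_probability = turnover_probability,
      seed = as.integer(seed), augmentation = augmentation
    ),
    class = "train_config"
  )
}

#' Desk-scale training configuration
#'
#' The reference encoders are trained from random initialization on small
#' synthetic cohorts, so the optimizer is rescaled relative to the
#' full-scale defaults: learning rate 1e-3 and 40 epochs. Like the
#' full-scale setting, this is a fixed, conservative optimization budget —
#' training is deliberately not run to convergence, which is the regime
#' the co-learning strategy targets; see the package vignette. Everything
#' else (batch size, weight decay, loss weights, turnover) keeps its
#' default.
#'
#' @param mode `"multimodal"` or `"unimodal"`.
#' @param ssl Contrastive preset, `"nt_xent_default"` or
#'   `"info_nce_default"`.
#' @param seed Integer seed.
#' @param epochs,learning_rate Desk-scale optimizer settings.
#' @param ... Further overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_config <- function(mode = c("multimodal", "unimodal"),
                        ssl = c("nt_xent_default", "info_nce_default"),
                        seed = 0L, epochs = 40L, learning_rate = 1e-3, ...) {
  mode <- match.arg(mode)
  ssl <- match.arg(ssl)
  train_config(
    epochs = epochs, learning_rate = learning_rate,
    loss_weights = loss_weights(if (mode == "unimodal") "unimodal" else ssl),
    mode = mode, seed = seed, ...
  )
}

#' Per-record class-balancing weights
#'
#' Inverse-frequency weights making the per-draw class probability uniform
#' over the classes present while keeping records within a class uniform.
#'
#' @param labels Vector of class labels.
#' @return Numeric weights summing to 1.
#' @export
class_balance_weights <- function(labels) {
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("class with zero records", call. = FALSE)
  }
  w <- 1 / (length(counts) * as.numeric(counts[match(labels, names(counts))]))
  w
}

#' Draw a class-balanced sample of record ids
#'
#' Weighted sampling with replacement under the current RNG stream,
#' instead of physically duplicating minority-class records. The training
#' loop uses the same weights but draws each mini-batch without
#' replacement within the batch, so that a batch never carries duplicate
#' records (a duplicate would act as a false negative in the contrastive
#' pool).
#'
#' @param records Record tibble with `record_id` and `label`.
#' @param n Number of draws (defaults to `nrow(records)`).
#' @return Character vector of record ids.
#' @export
balanced_sample_ids <- function(records, n = nrow(records)) {
  w <- class_balance_weights(records$label)
  sample(records$record_id, n, replace = TRUE, prob = w)
}

# ---- optimizer -----------------------------------------------------------

adam_init <- function(params, names) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (wd > 0) g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- forward/backward over a mini-batch ---------------------------------

head_forward <- function(e, params) {
  h <- sweep(e %*% params$proj_W, 2L, params$proj_b, `+`)
  logits <- sweep(h %*% params$cls_W, 2L, params$cls_b, `+`)
  list(h = h, logits = logits)
}

# computes the composite loss and all parameter gradients for one batch
train_step <- function(params, images, texts, labels, w, multimodal) {
  n <- length(images)
  caches <- lapply(images, image_forward_one, params = params,
    keep_cache = TRUE
  )
  p_img <- t(vapply(caches, `[[`, numeric(ncol(params$conv3_W)), "pooled"))
  e_img <- sweep(p_img %*% params$img_W, 2L, params$img_b, `+`)
  fi <- head_forward(e_img, params)
  grads <- list()

  ce_i <- cross_entropy_grad(fi$logits, labels)
  dlog_i <- w$w_ce_image * ce_i$dlogits

  if (multimodal) {
    x_txt <- text_features(texts, nrow(params$txt_W))
    e_txt <- sweep(x_txt %*% params$txt_W, 2L, params$txt_b, `+`)
    ft <- head_forward(e_txt, params)
    ce_t <- cross_entropy_grad(ft$logits, labels)
    l1g <- l1_alignment_grad(fi$h, ft$h)
    cosg <- cosine_alignment_grad(fi$h, ft$h)
    sslg <- switch(w$ssl_kind,
      nt_xent = nt_xent_grad(fi$h, ft$h, w$tau),
      info_nce = info_nce_grad(fi$h, ft$h, w$tau)
    )
    breakdown <- new_loss_breakdown(
      ce_i$value, ce_t$value, l1g$value, cosg$value, sslg$value, w
    )
    dlog_t <- w$w_ce_text * ce_t$dlogits
    dh_i <- tcrossprod(dlog_i, params$cls_W) +
      w$w_l1 * l1g$d_img + w$w_cos * cosg$d_img + w$w_ssl * sslg$d_img
    dh_t <- tcrossprod(dlog_t, params$cls_W) +
      w$w_l1 * l1g$d_txt + w$w_cos * cosg$d_txt + w$w_ssl * sslg$d_txt
    grads$cls_W <- crossprod(fi$h, dlog_i) + crossprod(ft$h, dlog_t)
    grads$cls_b <- colSums(dlog_i) + colSums(dlog_t)
    grads$proj_W <- crossprod(e_img, dh_i) + crossprod(e_txt, dh_t)
    grads$proj_b <- colSums(dh_i) + colSums(dh_t)
    de_txt <- tcrossprod(dh_t, params$proj_W)
    grads$txt_W <- crossprod(x_txt, de_txt)
    grads$txt_b <- colSums(de_txt)
  } else {
    breakdown <- new_loss_breakdown(ce_i$value, 0, 0, 0, 0, w)
    dh_i <- tcrossprod(dlog_i, params$cls_W)
    grads$cls_W <- crossprod(fi$h, dlog_i)
    grads$cls_b <- colSums(dlog_i)
    grads$proj_W <- crossprod(e_img, dh_i)
    grads$proj_b <- colSums(dh_i)
  }

  de_img <- tcrossprod(dh_i, params$proj_W)
  grads$img_W <- crossprod(p_img, de_img)
  grads$img_b <- colSums(de_img)
  dp <- tcrossprod(de_img, params$img_W)
  for (i in seq_len(n)) {
    gi <- image_backward_one(dp[i, ], caches[[i]], params)
    for (nm in names(gi)) {
      grads[[nm]] <- if (is.null(grads[[nm]])) gi[[nm]] else grads[[nm]] + gi[[nm]]
    }
  }
  list(grads = grads, breakdown = breakdown)
}

# ---- training loop -------------------------------------------------------

#' Train the co-learning model
#'
#' Runs mini-batch optimization of the composite objective over the
#' cohort's training partition, with class-balanced sampling (one epoch
#' covers roughly the partition size; each batch is drawn without
#' replacement within the batch), image augmentation and, in multimodal
#' mode, report-turnover augmentation. After each epoch the image cross-entropy
#' on the validation partition is computed, and the parameters of the epoch
#' minimizing it are the ones returned (checkpoint selection); validation
#' never sees text, matching image-only deployment. The run is fully
#' reproducible from `(config, spec, cohort)`.
#'
#' @param cohort A [lesion_cohort()] with non-empty training and validation
#'   partitions; multimodal mode additionally requires a report pair for
#'   every training record.
#' @param config A [train_config()].
#' @param spec An [encoder_spec()]; its `init_seed` is replaced by
#'   `config$seed` unless `model` is supplied.
#' @param model Optional pre-initialized [init_model()] to start from.
#' @return An object of class `colearn_fit`: list with `model` (parameters
#'   of the selected epoch), `final_model`, `history` (per-epoch tibble),
#'   `selected_epoch`, `config`, `spec`.
#' @export
train_colearn <- function(cohort, config = desk_config(),
                          spec = encoder_spec(), model = NULL) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(config, "train_config"))
  multimodal <- config$mode == "multimodal"
  tr <- cohort_subset(cohort, "training")
  va <- cohort_subset(cohort, "validation")
  if (nrow(tr$records) == 0L) stop("empty training partition", call. = FALSE)
  if (multimodal &&
      (nrow(tr$reports) == 0L || anyNA(tr$reports$record_id))) {
    stop("multimodal mode requires a report pair for every training record",
      call. = FALSE
    )
  }
  if (is.null(model)) {
    spec$init_seed <- config$seed
    model <- init_model(spec)
  } else {
    spec <- model$spec
  }
  params <- model$params
  trainable <- c(image_param_names, head_param_names)
  if (multimodal) trainable <- c(trainable, text_param_names)
  w <- config$loss_weights

  history <- list()
  best <- list(val_ce = Inf, params = params, epoch = 0L)
  final_params <- params

  withr_seed(config$seed, {
    state <- adam_init(params, trainable)
    bal_w <- class_balance_weights(tr$records$label)
    n_train <- nrow(tr$records)
    bs <- min(config$batch_size, n_train)
    n_batches <- max(1L, round(n_train / bs))
    for (epoch in seq_len(config$epochs)) {
      # one weighted draw per batch, without replacement within the batch:
      # minority classes are still oversampled across batches, but a batch
      # never holds the same record twice (a duplicate would be a false
      # negative in the contrastive pool)
      batches <- lapply(seq_len(n_batches), function(b) {
        sample(tr$records$record_id, bs, replace = FALSE, prob = bal_w)
      })
      comp <- numeric(0)
      sums <- c(total = 0, ce_image = 0, ce_text = 0, l1 = 0, cosine = 0,
        ssl = 0)
      for (batch_ids in batches) {
        rows <- match(batch_ids, tr$records$record_id)
        imgs <- lapply(tr$images[batch_ids], augment_image,
          cfg = config$augmentation
        )
        texts <- NULL
        if (multimodal) {
          rrows <- match(batch_ids, tr$reports$record_id)
          texts <- vapply(rrows, function(j) {
            augment_report(
              tr$reports[j, ],
              p_synthesized = config$turnover_probability
            )
          }, character(1))
        }
        step <- train_step(
          params, imgs, texts, tr$records$label[rows], w, multimodal
        )
        upd <- adam_step(
          params, step$grads, state,
          lr = config$learning_rate, wd = config$weight_decay
        )
        params <- upd$params
        state <- upd$state
        b <- step$breakdown
        sums <- sums + c(b$total, b$ce_image, b$ce_text, b$l1, b$cosine, b$ssl)
      }
      sums <- sums / length(batches)
      val_ce <- if (nrow(va$records) > 0L) {
        m <- list(spec = spec, params = params)
        class(m) <- "colearn_model"
        emb <- encode_images(unname(va$images), m)
        cross_entropy(classify(emb, m), va$records$label)
      } else {
        NA_real_
      }
      sums <- unname(sums)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, total = sums[1], ce_image = sums[2],
        ce_text = sums[3], l1 = sums[4], cosine = sums[5], ssl = sums[6],
        val_ce = val_ce
      )
      if (!is.na(val_ce) && val_ce < best$val_ce) {
        best <- list(val_ce = val_ce, params = params, epoch = epoch)
      }
    }
    final_params <- params
  })

  if (config$epochs == 0L || is.infinite(best$val_ce)) {
    best <- list(val_ce = NA_real_, params = final_params,
      epoch = config$epochs)
  }
  best_model <- structure(
    list(spec = spec, params = best$params),
    class = "colearn_model"
  )
  final_model <- structure(
    list(spec = spec, params = final_params),
    class = "colearn_model"
  )
  structure(
    list(
      model = best_model, final_model = final_model,
      history = dplyr::bind_rows(history),
      selected_epoch = best$epoch,
      config = config, spec = spec
    ),
    class = "colearn_fit"
  )
}

#' @export
print.colearn_fit <- function(x, ...) {
  cat(
    "<colearn_fit> mode = ", x$config$mode,
    ", ssl = ", x$config$loss_weights$ssl_kind,
    ", ", nrow(x$history), " epoch(s), selected epoch ", x$selected_epoch,
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict class labels for images
#'
#' Image-only inference: encodes the images with the selected-epoch
#' parameters, applies the shared head and takes the per-row argmax.
#' Deterministic, and invariant to how the images are split into batches
#' because every image is processed independently.
#'
#' @param fit A `colearn_fit` (or a `colearn_model`).
#' @param images List of HxWx3 arrays (possibly empty).
#' @return Character vector of predicted class codes.
#' @export
predict_images <- function(fit, images) {
  model <- if (inherits(fit, "colearn_fit")) fit$model else fit
  if (length(images) == 0L) {
    return(character(0))
  }
  logits <- classify(encode_images(images, model), model)
  lesion_class_codes()[max.col(logits, ties.method = "first")]
}

#' @export
predict.colearn_fit <- function(object, images, ...) {
  predict_images(object, images)
}
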