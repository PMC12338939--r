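test_that("cross-entropy matches the closed form on boundary cases", {
  # uniform logits over 5 classes
  expect_equal(cross_entropy(matrix(0, 3, 5), c(1, 2, 5)), log(5))
  # near-one-hot logits drive the loss to zero
  big <- matrix(-50, 2, 5)
  big[cbind(1:2, c(3, 4))] <- 50
  expect_lt(cross_entropy(big, c(3, 4)), 1e-10)
  expect_error(cross_entropy(matrix(0, 2, 5), c(1, 9)), "labels")
  expect_error(cross_entropy(matrix(0, 2, 5), 1), "differ")
})

test_that("cross-entropy matches a direct softmax oracle on random inputs", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    logits <- matrix(rnorm(n * 5, sd = 3), n, 5)
    idx <- sample(5, n, replace = TRUE)
    expect_equal(
      cross_entropy(logits, idx), oracle_cross_entropy(logits, idx),
      tolerance = 1e-6
    )
  }
})

test_that("L1 alignment is the mean absolute entrywise difference", {
  e <- matrix(rnorm(12), 3)
  expect_equal(l1_alignment(e, e), 0)
  expect_equal(l1_alignment(matrix(1, 2, 3), matrix(0, 2, 3)), 1)
  set.seed(2)
  a <- matrix(rnorm(40), 5)
  b <- matrix(rnorm(40), 5)
  expect_equal(l1_alignment(a, b), mean(abs(a - b)))
  expect_error(l1_alignment(a, b[1:3, ]), "identical shapes")
})

test_that("cosine alignment spans [0, 2] with the defining geometry", {
  a <- matrix(rnorm(20), 4)
  expect_equal(cosine_alignment(a, a), 0)
  expect_equal(cosine_alignment(a, -a), 2)
  u <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  v <- matrix(c(0, 3, 5, 0), 2, byrow = TRUE)
  expect_equal(cosine_alignment(u, v), 1)
  expect_error(cosine_alignment(a, matrix(0, 4, 6)), "shapes")
  expect_error(cosine_alignment(matrix(0, 2, 3), matrix(1, 2, 3)), "zero-norm")
})

test_that("contrastive losses match brute-force enumeration oracles", {
  set.seed(303)
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    d <- sample(2:8, 1)
    a <- matrix(rnorm(n * d), n, d)
    b <- matrix(rnorm(n * d), n, d)
    tau <- sample(c(0.07, 0.2, 0.5, 1), 1)
    expect_equal(nt_xent(a, b, tau), oracle_nt_xent(a, b, tau),
      tolerance = 1e-6
    )
    expect_equal(info_nce(a, b, tau), oracle_info_nce(a, b, tau),
      tolerance = 1e-6
    )
  }
})

test_that("a single pair yields zero contrastive loss", {
  a <- matrix(c(1, 2), 1)
  b <- matrix(c(-3, 0.5), 1)
  expect_equal(nt_xent(a, b, 0.5), 0)
  expect_equal(info_nce(a, b, 0.07), 0)
})

test_that("contrastive losses are invariant to rescaling and pair permutation", {
  set.seed(9)
  a <- matrix(rnorm(24), 4)
  b <- matrix(rnorm(24), 4)
  expect_equal(nt_xent(10 * a, 10 * b, 0.5), nt_xent(a, b, 0.5))
  expect_equal(info_nce(0.1 * a, 10 * b, 0.07), info_nce(a, b, 0.07))
  # per-row rescaling (cosine only sees directions)
  scales <- runif(4, 0.5, 5)
  expect_equal(nt_xent(a * scales, b, 0.5), nt_xent(a, b, 0.5))
  perm <- c(3, 1, 4, 2)
  expect_equal(nt_xent(a[perm, ], b[perm, ], 0.5), nt_xent(a, b, 0.5))
  expect_equal(info_nce(a[perm, ], b[perm, ], 0.07), info_nce(a, b, 0.07))
})

test_that("increasing a positive pair's similarity decreases nt_xent", {
  base <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  txt <- function(theta) {
    rbind(c(cos(theta), sin(theta)), c(0, 1))
  }
  # rotating text row 1 toward image row 1 monotonically lowers the loss
  angles <- seq(1.2, 0.1, by = -0.1)
  losses <- vapply(angles, function(t) nt_xent(base, txt(t), 0.5), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("analytic gradients agree with finite differences", {
  num_grad <- function(f, x, eps = 1e-6) {
    g <- x
    for (i in seq_along(x)) {
      xp <- x
      xp[i] <- x[i] + eps
      xm <- x
      xm[i] <- x[i] - eps
      g[i] <- (f(xp) - f(xm)) / (2 * eps)
    }
    g
  }
  set.seed(17)
  a <- matrix(rnorm(15), 3)
  b <- matrix(rnorm(15), 3)
  checks <- list(
    list(
      g = dermcolearn:::nt_xent_grad(a, b, 0.5),
      fa = function(x) nt_xent(x, b, 0.5),
      fb = function(x) nt_xent(a, x, 0.5)
    ),
    list(
      g = dermcolearn:::info_nce_grad(a, b, 0.07),
      fa = function(x) info_nce(x, b, 0.07),
      fb = function(x) info_nce(a, x, 0.07)
    ),
    list(
      g = dermcolearn:::cosine_alignment_grad(a, b),
      fa = function(x) cosine_alignment(x, b),
      fb = function(x) cosine_alignment(a, x)
    )
  )
  for (chk in checks) {
    expect_equal(chk$g$d_img, num_grad(chk$fa, a), tolerance = 1e-5)
    expect_equal(chk$g$d_txt, num_grad(chk$fb, b), tolerance = 1e-5)
  }
})

test_that("composite totals reproduce the preset weighted sums", {
  # fabricated component values pushed through the two presets
  set.seed(5)
  n <- 4
  e_img <- matrix(rnorm(n * 6), n)
  e_txt <- matrix(rnorm(n * 6), n)
  logits_img <- matrix(rnorm(n * 5), n)
  logits_txt <- matrix(rnorm(n * 5), n)
  labels <- sample(5, n, replace = TRUE)
  for (preset in c("nt_xent_default", "info_nce_default")) {
    w <- loss_weights(preset)
    bd <- composite_loss(logits_img, logits_txt, labels, e_img, e_txt, w)
    manual <- w$w_ce_image * bd$ce_image + w$w_ce_text * bd$ce_text +
      w$w_l1 * bd$l1 + w$w_cos * bd$cosine + w$w_ssl * bd$ssl
    expect_equal(bd$total, manual, tolerance = 1e-6)
    ssl_direct <- if (preset == "nt_xent_default") {
      nt_xent(e_img, e_txt, 0.5)
    } else {
      info_nce(e_img, e_txt, 0.07)
    }
    expect_equal(bd$ssl, ssl_direct)
    expect_true(all(unlist(bd) >= 0 | names(unlist(bd)) == "total"))
  }
  # all weights zero annihilates the total
  w0 <- loss_weights(
    w_ce_image = 0, w_ce_text = 0, w_l1 = 0, w_cos = 0, w_ssl = 0
  )
  bd0 <- composite_loss(logits_img, logits_txt, labels, e_img, e_txt, w0)
  expect_equal(bd0$total, 0)
})

test_that("preset weights and temperatures are as published", {
  ntx <- loss_weights("nt_xent_default")
  expect_equal(
    unlist(ntx[c("w_ce_image", "w_ce_text", "w_l1", "w_cos", "w_ssl", "tau")]),
    c(w_ce_image = 1, w_ce_text = 1, w_l1 = 1, w_cos = 1, w_ssl = 0.5,
      tau = 0.5)
  )
  inf <- loss_weights("info_nce_default")
  expect_equal(inf$w_ssl, 0.25)
  expect_equal(inf$tau, 0.07)
  uni <- loss_weights("unimodal")
  expect_equal(uni$w_ce_text + uni$w_l1 + uni$w_cos + uni$w_ssl, 0)
})
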