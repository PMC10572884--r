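test_that("both losses vanish on perfect predictions and hit 1 on disjoint ones", {
  lab <- matrix(c(0, 1, 2, 1, 2, 0, 1, 2, 0, 1, 2, 0), 3, 4)
  y <- one_hot(lab, 3)
  cfg0 <- loss_config(smooth = 0)
  expect_equal(dice_loss(y, y, cfg0), 0)
  expect_equal(focal_tversky_loss(y, y, cfg0), 0)
  # truth all NM, prediction all M: zero overlap on both included channels
  yn <- one_hot(matrix(1L, 4, 4), 3)
  pm <- one_hot(matrix(2L, 4, 4), 3)
  cfg_nm_m <- loss_config(smooth = 0, excluded_classes = 0L)
  expect_equal(focal_tversky_loss(yn, pm, cfg_nm_m), 1)
  expect_equal(dice_loss(yn, pm, cfg_nm_m), 1)
})

test_that("dice loss on a uniform prediction matches the closed form", {
  # y one-hot on M over k pixels, p = 1/3 everywhere, M channel only
  lab <- matrix(0L, 6, 6); lab[2:3, 2:4] <- 2L
  k <- sum(lab == 2); n <- length(lab)
  y <- one_hot(lab, 3)
  p <- array(1 / 3, dim = c(6, 6, 3))
  cfg <- loss_config(smooth = 0, excluded_classes = c(0L, 1L))
  expect_equal(dice_loss(y, p, cfg), 1 - 2 * (k / 3) / (k + n / 3))
})

test_that("losses agree with scalar brute-force evaluation on random maps", {
  set.seed(42)
  cfg <- loss_config(smooth = 0)
  for (i in 1:25) {
    y <- random_truth(4, 4, 3)
    p <- random_probs(4, 4, 3)
    expect_equal(dice_loss(y, p, cfg), brute_masked_loss(y, p, "dice", cfg),
                 tolerance = 1e-12)
    expect_equal(focal_tversky_loss(y, p, cfg),
                 brute_masked_loss(y, p, "focal_tversky", cfg),
                 tolerance = 1e-12)
  }
})

test_that("focal Tversky collapses to Dice at alpha = beta = 1/2, gamma = 1", {
  set.seed(7)
  cfg <- loss_config(alpha = 0.5, beta = 0.5, gamma = 1, smooth = 0)
  for (i in 1:10) {
    y <- random_truth(5, 5, 3)
    p <- random_probs(5, 5, 3)
    expect_equal(focal_tversky_loss(y, p, cfg), dice_loss(y, p, cfg),
                 tolerance = 1e-12)
  }
})

test_that("losses are permutation-invariant over pixels", {
  set.seed(8)
  y <- random_truth(6, 6, 3); p <- random_probs(6, 6, 3)
  perm <- sample(36)
  permute <- function(a) {
    out <- a
    for (k in 1:3) {
      ch <- a[, , k]
      out[, , k] <- matrix(ch[perm], 6, 6)
    }
    out
  }
  cfg <- loss_config(smooth = 0)
  expect_equal(dice_loss(permute(y), permute(p), cfg), dice_loss(y, p, cfg))
  expect_equal(focal_tversky_loss(permute(y), permute(p), cfg),
               focal_tversky_loss(y, p, cfg))
})

test_that("increasing overlap at fixed marginals strictly decreases both losses", {
  # two pixels of class M in truth; move probability mass onto the correct one
  y <- one_hot(matrix(c(2L, 0L, 0L, 2L), 2, 2), 3)
  make_p <- function(eps) {
    p <- array(0, dim = c(2, 2, 3))
    p[, , 3] <- matrix(c(eps, 0.5 - eps, 0.5 - eps, eps), 2, 2)
    p[, , 1] <- 1 - p[, , 3]
    p
  }
  cfg <- loss_config(smooth = 0, excluded_classes = c(0L, 1L))
  d <- vapply(c(0.1, 0.3, 0.5), function(e) dice_loss(y, make_p(e), cfg), numeric(1))
  f <- vapply(c(0.1, 0.3, 0.5), function(e) focal_tversky_loss(y, make_p(e), cfg), numeric(1))
  expect_true(all(diff(d) < 0))
  expect_true(all(diff(f) < 0))
})

test_that("the background channel contributes no loss term of its own", {
  set.seed(9)
  y <- random_truth(6, 6, 3); p <- random_probs(6, 6, 3)
  cfg <- loss_config()
  base <- masked_multiclass_loss(y, p, cfg, "focal_tversky")
  p2 <- p
  p2[, , 1] <- p2[, , 1] * 0.5 + 0.1   # perturb only the BG channel terms
  expect_equal(masked_multiclass_loss(y, p2, cfg, "focal_tversky"), base)
  expect_equal(masked_multiclass_loss(y, p2, cfg, "dice"),
               masked_multiclass_loss(y, p, cfg, "dice"))
  g <- boneseg:::masked_loss_grad(y, p, cfg, "focal_tversky")
  expect_true(all(g[, , 1] == 0))
})

test_that("with no exclusions the masked loss is the plain per-class mean", {
  set.seed(10)
  y <- random_truth(5, 5, 3); p <- random_probs(5, 5, 3)
  cfg_all <- loss_config(excluded_classes = integer(0), smooth = 0)
  per_class <- vapply(1:3, function(k) {
    ck <- loss_config(excluded_classes = setdiff(0:2, k - 1L), smooth = 0)
    dice_loss(y, p, ck)
  }, numeric(1))
  expect_equal(masked_multiclass_loss(y, p, cfg_all, "dice"), mean(per_class))
  expect_equal(masked_multiclass_loss(y, y, loss_config(), "dice"), 0)
  expect_error(loss_config(alpha = 0), "alpha")
  expect_error(dice_loss(y, p[, 1:3, ], loss_config()), "dimensions")
  expect_error(masked_multiclass_loss(y, p, loss_config(excluded_classes = 0:2)),
               "excluded")
})

test_that("analytic loss gradients match finite differences", {
  set.seed(11)
  y <- random_truth(4, 4, 3)
  p <- random_probs(4, 4, 3)
  cfg <- loss_config()
  for (base in c("dice", "focal_tversky")) {
    g <- boneseg:::masked_loss_grad(y, p, cfg, base)
    eps <- 1e-7
    for (idx in sample(length(p), 8)) {
      p_hi <- p; p_hi[idx] <- p_hi[idx] + eps
      p_lo <- p; p_lo[idx] <- p_lo[idx] - eps
      num <- (masked_multiclass_loss(y, p_hi, cfg, base) -
                masked_multiclass_loss(y, p_lo, cfg, base)) / (2 * eps)
      expect_equal(g[idx], num, tolerance = 1e-5)
    }
  }
})
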