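# Metrics, AUC, Shapley attribution, Type II ANOVA and the NCP diagnostics.

test_that("confusion metrics match a hand-computed 3-class table", {
  classes <- lts_classes()
  truth <- rep(classes, each = 10)
  pred <- truth
  # diagonal (8, 6, 4): send 2, 4, 6 to the next class
  pred[9:10] <- classes[2]
  pred[17:20] <- classes[3]
  pred[25:30] <- classes[1]
  m <- confusion_and_accuracy(truth, pred)
  expect_equal(m$overall_accuracy, 18 / 30)
  expect_equal(sum(m$confusion), 30)
  expect_equal(unname(diag(m$confusion)), c(8, 6, 4))
  # hand-computed one-vs-rest rates for class 1 (dys): tp=8, fn=2, fp=6, tn=14
  dys <- m$per_class[m$per_class$class == "dys", ]
  expect_equal(dys$tpr, 0.8)
  expect_equal(dys$tnr, 14 / 20)
  expect_equal(dys$balanced_accuracy, (0.8 + 0.7) / 2)
  # perfect predictions
  p <- confusion_and_accuracy(truth, truth)
  expect_equal(p$overall_accuracy, 1)
  expect_true(all(p$per_class$balanced_accuracy == 1))
  # constant predictor: its class has TPR 1 and TNR 0
  allc <- confusion_and_accuracy(truth, rep(classes[1], 30))
  row1 <- allc$per_class[allc$per_class$class == classes[1], ]
  expect_equal(row1$tpr, 1)
  expect_equal(row1$tnr, 0)
  expect_error(confusion_and_accuracy(character(0), character(0)), "empty")
})

test_that("one-vs-rest AUC handles perfect, reversed and null scores", {
  truth <- rep(c("dys", "oligo"), each = 50)
  probs <- cbind(dys = c(seq(0.5, 1, length.out = 50),
                         seq(0, 0.49, length.out = 50)))
  probs <- cbind(probs, oligo = 1 - probs[, "dys"])
  a <- roc_auc_ovr(truth, probs)
  expect_equal(unname(a$per_class["dys"]), 1)
  rev <- roc_auc_ovr(rev(truth), probs)
  expect_equal(unname(rev$per_class["dys"]), 0)
  # scores independent of labels: AUC within 3 sd of 0.5
  set.seed(4)
  n <- 2000
  truth2 <- sample(c("dys", "oligo"), n, replace = TRUE)
  s <- runif(n)
  a2 <- roc_auc_ovr(truth2, cbind(dys = s, oligo = runif(n)))
  n1 <- sum(truth2 == "dys"); n0 <- n - n1
  sd_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a2$per_class[["dys"]] - 0.5), 3 * sd_null)
  # single-class truth flags NA and macro averages over defined classes
  a3 <- roc_auc_ovr(rep("dys", 10), cbind(dys = runif(10), oligo = runif(10)))
  expect_true(is.na(a3$per_class[["dys"]]))
})

test_that("midrank AUC equals the O(n^2) pairwise oracle including ties", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(20:300, 1)
    truth <- sample(lts_classes(), n, replace = TRUE)
    # coarse scores force plenty of ties
    probs <- matrix(round(runif(n * 3), 1), n, 3,
                    dimnames = list(NULL, lts_classes()))
    got <- roc_auc_ovr(truth, probs)$per_class
    for (cc in lts_classes()) {
      expect_equal(got[[cc]], pairwise_auc(truth == cc, probs[, cc]),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact Shapley values satisfy the closed form and the axioms", {
  set.seed(3)
  bg <- matrix(rnorm(200), ncol = 4, dimnames = list(NULL, paste0("x", 1:4)))
  w <- c(1.5, -2, 0, 0.7)
  f_lin <- function(m) as.numeric(m %*% w + 3)
  x <- c(0.5, 1, -1, 2)
  sv <- shap_exact(f_lin, x, bg)
  # additive model: phi_i = w_i (x_i - mean background_i)
  expect_equal(unname(sv$phi), unname(w * (x - colMeans(bg))), tolerance = 1e-10)
  # dummy axiom: ignored feature gets exactly zero
  expect_identical(unname(sv$phi)[3], 0)
  # efficiency on an arbitrary nonlinear model
  f_nl <- function(m) sin(m[, 1]) * m[, 2] + exp(0.3 * m[, 3] * m[, 4])
  sv2 <- shap_exact(f_nl, x, bg)
  expect_equal(sum(sv2$phi), sv2$fx - sv2$baseline, tolerance = 1e-6)
  # symmetry: exchangeable features with equal coordinates get equal phi
  f_sym <- function(m) m[, 1] * m[, 2] + m[, 1] + m[, 2]
  bg_sym <- bg; bg_sym[, 2] <- bg_sym[, 1]
  sv3 <- shap_exact(f_sym, c(1, 1, 0, 0), bg_sym)
  expect_equal(sv3$phi[[1]], sv3$phi[[2]], tolerance = 1e-10)
  expect_error(shap_exact(f_lin, x, bg[0, ]), "empty background")
})

test_that("model Shapley attributions track the NCP spectral signatures", {
  tab <- small_training()
  fit <- get_fixture("small_fit", lts(tab, k = 5, seed = 1))
  set.seed(31)
  rows <- tab[unlist(lapply(lts_classes(), function(cc) {
    sample(which(tab$trophic_state == cc), 5)
  })), ]
  sv <- shap_values(fit$models$mlr, rows, background = tab,
                    classes = "oligo", seed = 2)
  sm <- shap_summary(sv, rows)
  # oligotrophic probability attributions: high blue helps, high red hurts
  assoc <- sm$association[sm$association$class == "oligo", ]
  expect_gt(assoc$spearman_rho[assoc$feature == "z_blue"], 0)
  expect_lt(assoc$spearman_rho[assoc$feature == "z_red"], 0)
  # efficiency holds for a real model
  expect_true(all(abs(rowSums(sv[, paste0("phi_", c("red", "green", "blue",
                                                    "nir"))]) -
                        (sv$fx - sv$baseline)) < 1e-6))
  # a constant model attributes nothing
  const <- shap_exact(function(m) rep(0.5, nrow(m)), rep(0, 4),
                      as.matrix(tab[, paste0("z_", c("red", "green", "blue",
                                                     "nir"))]))
  expect_true(all(abs(const$phi) < 1e-12))
})

test_that("shap_summary ranks a single-feature model's only feature first", {
  set.seed(9)
  feats <- data.frame(z_red = rnorm(20), z_green = rnorm(20),
                      z_blue = rnorm(20), z_nir = rnorm(20))
  bg <- as.matrix(feats)
  f_blue <- function(m) plogis(2 * m[, 3])
  rows <- lapply(seq_len(20), function(r) {
    sv <- shap_exact(f_blue, as.numeric(feats[r, ]), bg)
    data.frame(row = r, class = "oligo", phi_red = sv$phi[[1]],
               phi_green = sv$phi[[2]], phi_blue = sv$phi[[3]],
               phi_nir = sv$phi[[4]], baseline = sv$baseline, fx = sv$fx)
  })
  sm <- shap_summary(do.call(rbind, rows), feats)
  imp <- sm$importance
  expect_identical(imp$feature[imp$rank == 1], "z_blue")
  expect_true(all(imp$mean_abs_phi[imp$feature != "z_blue"] < 1e-10))
})

test_that("Type II sums of squares equal the RSS-difference oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    d <- data.frame(y = rlnorm(n),
                    f1 = sample(letters[1:3], n, replace = TRUE),
                    f2 = sample(c("u", "v"), n, replace = TRUE,
                                prob = c(0.7, 0.3)),
                    f3 = sample(LETTERS[1:3], n, replace = TRUE))
    got <- anova_type2(d, "y", c("f1", "f2", "f3"))
    oracle <- type2_ss_oracle(d, "y", c("f1", "f2", "f3"))
    for (f in c("f1", "f2", "f3")) {
      expect_equal(got$sum_sq[got$term == f], oracle$sum_sq[oracle$term == f],
                   tolerance = 1e-8)
      expect_identical(got$df[got$term == f], oracle$df[oracle$term == f])
    }
    expect_equal(got$sum_sq[got$term == "Residuals"], oracle$rss_full[1],
                 tolerance = 1e-8)
  }
})

test_that("on balanced designs Type II equals sequential Type I", {
  set.seed(22)
  d <- expand.grid(f1 = letters[1:3], f2 = c("u", "v"), rep = 1:10)
  d$y <- rlnorm(nrow(d))
  got <- anova_type2(d, "y", c("f1", "f2"))
  fit <- lm(log(y) ~ f1 + f2, data = d)
  seq1 <- anova(fit)
  for (f in c("f1", "f2")) {
    expect_equal(got$sum_sq[got$term == f], seq1[f, "Sum Sq"], tolerance = 1e-10)
  }
  # and in the single-factor case it is the classical one-way between-group SS
  one <- anova_type2(d, "y", "f1")
  expect_equal(one$sum_sq[one$term == "f1"],
               anova(lm(log(y) ~ f1, d))["f1", "Sum Sq"], tolerance = 1e-10)
})

test_that("ANOVA input contracts are enforced", {
  d <- data.frame(y = c(1, 2, 0.5, 3), f1 = c("a", "a", "b", "b"))
  expect_error(anova_type2(data.frame(y = c(-1, 1, 2, 3), f1 = d$f1), "y", "f1"),
               "positive")
  expect_error(anova_type2(data.frame(y = d$y, f1 = "a"), "y", "f1"), "levels")
  # aliased factors are reported
  d2 <- data.frame(y = rlnorm(20), f1 = rep(c("a", "b"), 10),
                   f2 = rep(c("x", "y"), 10))
  expect_error(anova_type2(d2, "y", c("f1", "f2")), "aliased")
})

test_that("null-factor p-values are calibrated at alpha = 0.05", {
  set.seed(77)
  reps <- 400
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- data.frame(y = rlnorm(60),
                    f1 = sample(letters[1:3], 60, replace = TRUE),
                    f2 = sample(c("u", "v"), 60, replace = TRUE))
    p[i] <- anova_type2(d, "y", c("f1", "f2"))$p_value[1]
  }
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("the NCP profile summarizes strata and boundary bands", {
  d <- data.frame(tp_ugL = c(10, 20, 40, 100, 5, 200),
                  color_pcu = c(5, 18, 25, 3, 80, 40),
                  correct = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  prof <- ncp_misclassification_profile(d)
  mis <- prof$summary[prof$summary$stratum == "misclassified", ]
  expect_equal(mis$tp_median, 20)
  expect_equal(c(mis$tp_min, mis$tp_max), c(10, 40))
  # boundary bands: misclassified rows at 20, 40 ug/L and 18, 25 PCU are near
  bf <- prof$band_fraction
  expect_equal(bf$frac_near_boundary[bf$stratum == "misclassified"], 2 / 3)
  expect_equal(bf$frac_near_boundary[bf$stratum == "correct"], 0)
  # all-correct input: no misclassified stratum
  prof2 <- ncp_misclassification_profile(d[d$correct, ])
  expect_false("misclassified" %in% prof2$summary$stratum)
  # boundary-concentrated noise shows up as a higher near-boundary fraction
  set.seed(5)
  n <- 400
  near <- data.frame(tp_ugL = runif(n, 25, 35), color_pcu = runif(n, 16, 24),
                     correct = runif(n) < 0.4)
  far <- data.frame(tp_ugL = c(runif(n, 0, 10), runif(n, 60, 100)),
                    color_pcu = c(runif(n, 0, 5), runif(n, 40, 80)),
                    correct = runif(2 * n) < 0.95)
  prof3 <- ncp_misclassification_profile(rbind(near, far))
  bf3 <- prof3$band_fraction
  expect_gt(bf3$frac_near_boundary[bf3$stratum == "misclassified"],
            bf3$frac_near_boundary[bf3$stratum == "correct"])
})

test_that("group proportions count, difference and filter correctly", {
  pred <- data.frame(group = "G1", year = 2007L,
                     state = c("oligo", "oligo", "eu/mixo", "dys"))
  ref <- pred
  gp <- group_proportions(pred, ref, min_lakes = 10)
  expect_true(all(gp$table$diff == 0))
  expect_equal(sort(gp$table$prop_pred, decreasing = TRUE), c(0.5, 0.25, 0.25))
  # the 4-lake group is excluded by the min_lakes filter
  expect_null(gp$by_state_filtered)
  # differing sources produce signed differences that sum to zero per group
  ref2 <- data.frame(group = "G1", year = 2007L,
                     state = c("oligo", "dys", "dys", "dys"))
  gp2 <- group_proportions(pred, ref2)
  expect_equal(sum(gp2$table$diff), 0)
  expect_equal(gp2$table$diff[gp2$table$state == "dys"], 0.25 - 0.75)
})
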