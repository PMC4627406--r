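# Feed-forward network: analytic gradients, forward pass, training
# behaviour, the hidden-width sweep and the holdout split.

make_221 <- function(seed = 1) {
  set.seed(seed)
  list(W1 = matrix(runif(4, -0.5, 0.5), 2, 2), b1 = runif(2, -0.5, 0.5),
       w2 = runif(2, -0.5, 0.5), b2 = runif(1, -0.5, 0.5))
}

test_that("backprop gradients match central finite differences", {
  set.seed(8)
  X <- matrix(rbinom(10, 1, 0.5), 5, 2)
  y <- c(0, 1, 1, 0, 1)
  p <- make_221()
  pack <- function(p) c(p$W1, p$b1, p$w2, p$b2)
  unpack <- function(v) list(W1 = matrix(v[1:4], 2, 2), b1 = v[5:6],
                             w2 = v[7:8], b2 = v[9])
  mse_at <- function(v) {
    q <- unpack(v)
    g <- ann_gradient(q$W1, q$b1, q$w2, q$b2, X, y)
    g$mse
  }
  g <- ann_gradient(p$W1, p$b1, p$w2, p$b2, X, y)
  analytic <- c(g$gW1, g$gb1, g$gw2, g$gb2)
  v0 <- pack(p)
  h <- 1e-5
  numeric_g <- vapply(seq_along(v0), function(i) {
    e <- replace(numeric(length(v0)), i, h)
    (mse_at(v0 + e) - mse_at(v0 - e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(analytic - numeric_g) / pmax(abs(numeric_g), 1e-8)), 1e-6)
})

test_that("the forward pass matches hand-computed matrix arithmetic", {
  p <- make_221(2)
  model <- structure(c(p, list(config = ann_config(2), features = c("f1", "f2"),
                               best_epoch = 0L,
                               training_mse_trace = numeric(0),
                               slice_mse_trace = NULL)),
                     class = "ann_model")
  x <- c(1, 0)
  sg <- function(z) 1 / (1 + exp(-z))
  h1 <- sg(p$W1[1, 1] * x[1] + p$W1[2, 1] * x[2] + p$b1[1])
  h2 <- sg(p$W1[1, 2] * x[1] + p$W1[2, 2] * x[2] + p$b1[2])
  o <- sg(h1 * p$w2[1] + h2 * p$w2[2] + p$b2)
  expect_equal(ann_predict(model, matrix(x, 1, 2)), o, tolerance = 1e-12)
})

test_that("a zero-weight model outputs 0.5 and predictions are row-order invariant", {
  model <- structure(list(W1 = matrix(0, 3, 2), b1 = c(0, 0), w2 = c(0, 0),
                          b2 = 0, config = ann_config(2),
                          features = paste0("f", 1:3), best_epoch = 0L,
                          training_mse_trace = numeric(0),
                          slice_mse_trace = NULL),
                     class = "ann_model")
  X <- matrix(rbinom(15, 1, 0.5), 5, 3)
  expect_equal(ann_predict(model, X), rep(0.5, 5))
  p <- make_221(3)
  m2 <- structure(c(p, list(config = ann_config(2), features = NULL,
                            best_epoch = 0L, training_mse_trace = numeric(0),
                            slice_mse_trace = NULL)),
                  class = "ann_model")
  X2 <- matrix(rbinom(12, 1, 0.5), 6, 2)
  perm <- sample(6)
  expect_equal(ann_predict(m2, X2)[perm], ann_predict(m2, X2[perm, ]))
  expect_error(ann_predict(m2, X), "mismatch")
})

test_that("training drives MSE below 0.01 on a linearly separable toy", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)[rep(1:4, 10), ]
  y <- X[, 1]
  fit <- ann_train(X, y, ann_config(hidden_neurons = 3, max_epochs = 500,
                                    early_stop_frac = 0, seed = 4))
  expect_lt(tail(fit$training_mse_trace, 1), 0.01)
})

test_that("the MSE trace is non-increasing at a small learning rate", {
  set.seed(9)
  X <- matrix(rbinom(60, 1, 0.5), 20, 3)
  y <- rbinom(20, 1, 0.5)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  fit <- ann_train(X, y, ann_config(hidden_neurons = 2, learning_rate = 0.01,
                                    momentum = 0, max_epochs = 100,
                                    early_stop_frac = 0, seed = 5))
  expect_true(all(diff(fit$training_mse_trace) <= 1e-12))
})

test_that("identical seeds give identical weights; single-class input errors", {
  X <- matrix(rbinom(40, 1, 0.5), 20, 2)
  y <- rep(c(0, 1), 10)
  cfg <- ann_config(hidden_neurons = 4, max_epochs = 50, seed = 6)
  a <- ann_train(X, y, cfg)
  b <- ann_train(X, y, cfg)
  expect_identical(a$W1, b$W1)
  expect_identical(a$w2, b$w2)
  expect_error(ann_train(X, rep(1, 20), cfg), "single class")
  expect_error(ann_train(X[1:5, ], y, cfg), "align")
})

test_that("epoch selection reports the slice-MSE minimizer", {
  set.seed(10)
  X <- matrix(rbinom(200, 1, 0.5), 50, 4)
  y <- as.integer(xor(X[, 1], X[, 2]))
  fit <- ann_train(X, y, ann_config(hidden_neurons = 4, max_epochs = 80,
                                    early_stop_frac = 0.2, seed = 7))
  expect_equal(fit$best_epoch, which.min(fit$slice_mse_trace))
})

test_that("model text serialization round-trips predictions exactly", {
  X <- matrix(rbinom(60, 1, 0.5), 20, 3)
  y <- rep(c(0, 1), 10)
  fit <- ann_train(X, y, ann_config(hidden_neurons = 3, max_epochs = 30,
                                    seed = 8))
  f <- tempfile(fileext = ".txt")
  write_ann_model(fit, f)
  back <- read_ann_model(f)
  expect_equal(back$W1, fit$W1, tolerance = 1e-15)
  expect_equal(ann_predict(back, X), ann_predict(fit, X), tolerance = 1e-15)
})

test_that("holdout split is stratified, exhaustive and reproducible", {
  y <- rep(c(0, 1), c(40, 60))
  sp <- holdout_split(y, 0.85, seed = 9)
  expect_length(sp$train, 85)
  expect_length(sp$validation, 15)
  expect_setequal(c(sp$train, sp$validation), seq_along(y))
  expect_length(intersect(sp$train, sp$validation), 0)
  # stratification: validation has 15 % of each class
  expect_equal(sum(y[sp$validation] == 1), 9)
  expect_identical(sp, holdout_split(y, 0.85, seed = 9))
  expect_false(identical(sp, holdout_split(y, 0.85, seed = 10)))
  expect_error(holdout_split(y, 1.2), "train_fraction")
})

test_that("the hidden sweep scores every fold and picks the argmax", {
  set.seed(11)
  X <- matrix(rbinom(120, 1, 0.5), 30, 4)
  y <- rep(c(0, 1), 15)
  sw <- sweep_hidden(X, y, sizes = 3, k = 2,
                     base_config = ann_config(1, max_epochs = 30,
                                              early_stop_frac = 0),
                     seed = 10)
  expect_equal(nrow(sw$table), 1)
  expect_equal(sw$best_hidden, 3)
  expect_false(is.na(sw$table$mean_auc))
  # fold assignment partitions the pool, stratified
  expect_length(sw$folds, 30)
  expect_setequal(unique(sw$folds), 1:2)
  for (f in 1:2) expect_setequal(unique(y[sw$folds == f]), c(0, 1))
  expect_error(sweep_hidden(X, y, sizes = 2, k = 40), "k exceeds")
})

test_that("sweeping widths never scores below the width-1 candidate", {
  set.seed(12)
  co <- generate_cohort(synthetic_config(
    n_patients = 200, seed = 13,
    effect_sizes = c(dDimer = 2, FC = 2, Shockindex = 2, PO2 = 2, Age = 2)))
  fm <- feature_matrix(build_incidence(co, warn_gaps = FALSE))
  sw <- sweep_hidden(fm$X, fm$y, sizes = c(1, 4, 8), k = 3,
                     base_config = ann_config(1, max_epochs = 60),
                     seed = 11)
  expect_gte(max(sw$table$mean_auc), sw$table$mean_auc[sw$table$hidden == 1])
  expect_equal(sw$best_hidden,
               sw$table$hidden[which.max(sw$table$mean_auc)])
})

test_that("informative descriptors outside the backcloth outscore those inside", {
  # plant all the diagnostic signal in five variables, then declare the
  # *uninformative* descriptors to be the connected backcloth set: the
  # unconnected (signal-bearing) set must classify better
  eff <- c(dDimer = 2, FC = 2, Shockindex = 2, PO2 = 2, Age = 2)
  aucs <- sapply(1:3, function(s) {
    co <- generate_cohort(synthetic_config(n_patients = 600, seed = 300 + s,
                                           effect_sizes = eff))
    inc <- build_incidence(co, warn_gaps = FALSE)
    informative <- descriptor_names(names(eff))
    fake_plateau <- structure(
      list(members = c(setdiff(inc$descriptors, informative),
                       "Final diagnosis[1]"), empty = FALSE),
      class = "plateau_report")
    sets <- split_feature_sets(fake_plateau, inc$descriptors)
    sp <- holdout_split(inc$labels, 0.85, seed = s)
    auc_for <- function(desc) {
      fm <- feature_matrix(inc, desc)
      fit <- ann_train(fm$X[sp$train, ], fm$y[sp$train],
                       ann_config(hidden_neurons = 5, max_epochs = 120,
                                  seed = s))
      roc_auc(ann_predict(fit, fm$X[sp$validation, ]),
              fm$y[sp$validation])$auc
    }
    c(connected = auc_for(sets$connected),
      unconnected = auc_for(sets$unconnected))
  })
  expect_gt(mean(aucs["unconnected", ]), mean(aucs["connected", ]))
})

test_that("a union feature set is no worse than either planted subset", {
  eff <- c(dDimer = 2, FC = 2, Shockindex = 2, PO2 = 2, Age = 2)
  deltas <- sapply(1:3, function(s) {
    co <- generate_cohort(synthetic_config(n_patients = 500, seed = 400 + s,
                                           effect_sizes = eff))
    inc <- build_incidence(co, warn_gaps = FALSE)
    informative <- descriptor_names(names(eff))
    rest <- setdiff(inc$descriptors, informative)
    sp <- holdout_split(inc$labels, 0.85, seed = s)
    auc_for <- function(desc) {
      fm <- feature_matrix(inc, desc)
      fit <- ann_train(fm$X[sp$train, ], fm$y[sp$train],
                       ann_config(hidden_neurons = 5, max_epochs = 120,
                                  seed = s))
      roc_auc(ann_predict(fit, fm$X[sp$validation, ]),
              fm$y[sp$validation])$auc
    }
    auc_for(c(informative, rest)) - max(auc_for(informative), auc_for(rest))
  })
  expect_gt(mean(deltas), -0.05)
})
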