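test_that("hashed encoder is deterministic, seeded and unit-normalized", {
  enc <- hashed_encoder(dim = 64, seed = 3)
  X1 <- encode_text(enc, c("ozone inhibits il6", "a b c"))
  X2 <- encode_text(enc, c("ozone inhibits il6", "a b c"))
  expect_identical(X1, X2)
  expect_equal(dim(X1), c(2L, 64L))
  expect_equal(unname(sqrt(rowSums(X1^2))), c(1, 1), tolerance = 1e-12)
  # a different hash seed relocates tokens
  X3 <- encode_text(hashed_encoder(dim = 64, seed = 4), c("ozone inhibits il6", "a b c"))
  expect_false(identical(X1, X3))
  expect_error(encode_text(enc, c("ok", "")), "empty")
})

test_that("predict_probs applies a sigmoid head to the context vector", {
  inst <- make_instances(c("alpha beta", "gamma delta"))
  # zero weights give probability one half everywhere
  zero_state <- structure(list(
    encoder = hashed_encoder(dim = 16, seed = 1),
    W = matrix(0, nrow = 17, ncol = 13, dimnames = list(NULL, relation_types())),
    uses_features = FALSE, projection = NULL,
    config = list(), n_train = 0, final_loss = NA
  ), class = "dti_classifier")
  P <- predict_probs(zero_state, inst)
  expect_equal(unname(P), matrix(0.5, 2, 13))
  # identical instances give identical rows
  inst2 <- make_instances(c("same text", "same text"))
  P2 <- predict_probs(zero_state, inst2)
  expect_equal(P2[1, ], P2[2, ])

  # hand-computed sigmoid through a toy 1-dim encoder
  toy <- custom_encoder("toy", 1, function(texts) matrix(nchar(texts), ncol = 1))
  st <- structure(list(
    encoder = toy,
    W = matrix(c(0.5, -0.2, rep(0, 24)), nrow = 2, ncol = 13,
               dimnames = list(NULL, relation_types())),
    uses_features = FALSE, projection = NULL,
    config = list(), n_train = 0, final_loss = NA
  ), class = "dti_classifier")
  P3 <- predict_probs(st, make_instances("abcd")) # nchar = 4
  expect_equal(P3[1, 1], 1 / (1 + exp(-(0.5 - 0.2 * 4))))
  expect_equal(unname(P3[1, 2]), 0.5) # zero column
})

test_that("focal loss matches hand computation and reduces to BCE", {
  # perfectly classified positives and negatives contribute exactly zero
  expect_equal(focal_loss(1, 1), 0)
  expect_equal(focal_loss(0, 0), 0)
  # hand-computed single positive term at p = 0.5, gamma = 0.5
  expect_equal(focal_loss(0.5, 1, gamma = 0.5, eps = 1e-6),
               sqrt(0.5) * -log(0.5 + 1e-6), tolerance = 1e-12)
  # gamma = 0, eps = 0 equals an independently written BCE oracle
  set.seed(31)
  p <- runif(1000, 0.01, 0.99)
  y <- rbinom(1000, 1, 0.5)
  bce_oracle <- function(p, y) -sum(ifelse(y == 1, log(p), log(1 - p)))
  expect_equal(focal_loss(p, y, gamma = 0, eps = 0), bce_oracle(p, y), tolerance = 1e-9)
  # non-negative, and monotone decreasing in p for positive terms
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, focal_loss, numeric(1), labels = 1)
  expect_true(all(ls >= 0))
  expect_true(all(diff(ls) < 0))
  expect_error(focal_loss(c(0.5, 0.5), 1), "shape")
})

test_that("analytic focal gradient matches a numerical gradient", {
  set.seed(32)
  p <- runif(20, 0.05, 0.95)
  y <- rbinom(20, 1, 0.5)
  z <- log(p / (1 - p))
  for (gamma in c(0, 0.5, 2)) {
    g <- dtirex:::focal_loss_grad_z(p, y, gamma, 1e-6)
    g_num <- vapply(seq_along(z), function(i) {
      h <- 1e-6
      zp <- z; zp[i] <- zp[i] + h
      zm <- z; zm[i] <- zm[i] - h
      (focal_loss(stats::plogis(zp), y, gamma, 1e-6) -
         focal_loss(stats::plogis(zm), y, gamma, 1e-6)) / (2 * h)
    }, numeric(1))
    expect_equal(g, g_num, tolerance = 1e-6)
  }
})

test_that("fuse_features concatenates context and descriptor blocks", {
  cls <- matrix(rnorm(16), nrow = 2, ncol = 8)
  feats <- matrix(rnorm(2 * 576), nrow = 2)
  expect_identical(fuse_features(cls, mode = "none"), cls)
  expect_equal(dim(fuse_features(cls, feats, mode = "concat")), c(2L, 584L))
  pr <- feature_projection(576, 32, seed = 5)
  expect_equal(dim(fuse_features(cls, feats, mode = "concat", projection = pr)),
               c(2L, 40L))
  expect_error(fuse_features(cls, feats[1, , drop = FALSE], mode = "concat"), "align")
})

test_that("training is seed-deterministic and zero epochs returns the init", {
  texts <- c("xxinhibitor drug gene", "neutral drug gene", "xxagonist drug gene")
  labs <- list("INHIBITOR", character(), "AGONIST")
  inst <- make_instances(texts, labs)
  m1 <- train_relation_classifier(inst, hashed_encoder(32, 1), seed = 9, epochs = 50)
  m2 <- train_relation_classifier(inst, hashed_encoder(32, 1), seed = 9, epochs = 50)
  expect_identical(m1$W, m2$W)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  m3 <- train_relation_classifier(inst, hashed_encoder(32, 1), seed = 10, epochs = 50)
  expect_false(identical(m1$W, m3$W))

  m0 <- train_relation_classifier(inst, hashed_encoder(32, 1), seed = 9, epochs = 0)
  init <- dtirex:::withr_seed(9, matrix(rnorm(33 * 13, sd = 0.01), nrow = 33,
                                        dimnames = list(NULL, relation_types())))
  expect_equal(unname(m0$W), unname(init))

  expect_error(train_relation_classifier(inst[0, ], hashed_encoder(32, 1)), "empty")
  expect_equal(ncol(m1$W), 13)
  expect_s3_class(glance(m1), "tbl_df")
  expect_equal(nrow(tidy(m1)), 33 * 13)
})

test_that("a separable trigger corpus is fit to high training micro-F1", {
  cfg <- synthetic_corpus_config(n_docs = 60, trigger_strength = 1, seed = 17)
  corp <- generate_corpus(cfg)
  inst <- generate_instances(corp$documents, corp$entities, corp$relations)
  m <- train_relation_classifier(inst, hashed_encoder(512, 1), seed = 1, epochs = 600)
  pred <- apply_thresholds(predict_probs(m, inst), inst)
  rep <- evaluate_predictions(corp$relations, pred)
  expect_gte(rep$micro$f1, 95)
})
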