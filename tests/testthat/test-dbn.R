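test_that("RBM energy follows the bilinear form", {
  ly <- structure(list(W = matrix(1, 1, 1), a = 0, b = 0), class = "rbm_layer")
  expect_equal(rbm_energy(ly, 1, 1), -1)
  expect_equal(rbm_energy(ly, 0, 0), 0)

  ly0 <- structure(list(W = matrix(0, 3, 2), a = rep(0, 3), b = rep(0, 2)),
                   class = "rbm_layer")
  for (v in list(c(0, 0, 0), c(1, 1, 0), c(1, 1, 1))) {
    expect_equal(rbm_energy(ly0, v, c(1, 0)), 0)
  }
  withr::with_seed(51, {
    ly2 <- rbm_layer(3, 2)
    expect_equal(rbm_energy(ly2, c(0, 0, 0), c(0, 0)), 0)
    v <- c(1, 0, 1); h <- c(1, 1)
    expect_equal(rbm_energy(ly2, v, h),
                 -sum(ly2$a * v) - sum(ly2$b * h) - as.numeric(v %*% ly2$W %*% h))
  })
  expect_error(rbm_energy(ly0, c(1, 0), c(1, 0)),
               class = "histodbn_structural_error")
})

test_that("conditional probabilities stay in (0,1) and are 0.5 at zero weights", {
  ly <- structure(list(W = matrix(0, 4, 3), a = rep(0, 4), b = rep(0, 3)),
                  class = "rbm_layer")
  batch <- matrix(0, 5, 4)
  ph <- histodbn:::rbm_hidden_probs(ly, batch)
  expect_true(all(ph == 0.5))
  withr::with_seed(52, {
    ly2 <- rbm_layer(4, 3)
    p <- histodbn:::rbm_hidden_probs(ly2, matrix(runif(20), 5, 4))
    expect_true(all(p > 0 & p < 1))
  })
})

test_that("CD updates respect the zero-rate identity and batch symmetry", {
  withr::with_seed(53, {
    ly <- rbm_layer(3, 2)
    same <- cd_update(ly, matrix(runif(9), 3, 3), k = 1, learning_rate = 0)
    expect_equal(same$W, ly$W)
    expect_equal(same$a, ly$a)
    expect_error(cd_update(ly, matrix(0, 2, 3), k = 0),
                 class = "histodbn_parameter_error")
    expect_error(cd_update(ly, matrix(0, 2, 5)),
                 class = "histodbn_structural_error")
  })
})

test_that("mean CD-1 update direction agrees with the exact enumerated gradient", {
  withr::with_seed(54, {
    cos_sims <- sapply(1:40, function(rep) {
      ly <- rbm_layer(2, 2, init_sd = 0.5)
      batch <- matrix(sample(0:1, 8, replace = TRUE), 4, 2)
      exact <- oracle_rbm_gradient(ly$W, ly$a, ly$b, batch)
      dW <- matrix(0, 2, 2)
      for (s in 1:100) {
        up <- cd_update(ly, batch, k = 1, learning_rate = 1)
        dW <- dW + (up$W - ly$W)
      }
      dW <- dW / 100
      sum(dW * exact$W) / sqrt(sum(dW^2) * sum(exact$W^2))
    })
    expect_gt(mean(cos_sims), 0)
    expect_gt(mean(cos_sims > 0), 0.8)  # almost always aligned
  })
})

test_that("greedy pretraining reduces reconstruction cross-entropy on bars", {
  D <- bars_data(n = 80, side = 8, seed = 1)
  cfg <- train_config(epochs = 20, batch_size = 10, learning_rate = 0.1, seed = 1)
  m <- dbn_model(c(64, 16), seed = 1)
  m <- greedy_pretrain(m, D, cfg)
  log1 <- m$pretrain_log
  expect_lt(log1$recon_error[log1$epoch == 20], log1$recon_error[log1$epoch == 1])

  # zero epochs leave the model untouched
  m0 <- dbn_model(c(64, 16), seed = 1)
  expect_identical(greedy_pretrain(m0, D, train_config(epochs = 0, seed = 1)), m0)

  # same seed, same weights
  mA <- greedy_pretrain(dbn_model(c(64, 16), seed = 1), D, cfg)
  mB <- greedy_pretrain(dbn_model(c(64, 16), seed = 1), D, cfg)
  expect_identical(mA$layers, mB$layers)

  expect_error(greedy_pretrain(m, D[, 1:10], cfg),
               class = "histodbn_structural_error")
})

test_that("layer sizes chain through the stack", {
  m <- dbn_model(c(10, 6, 3), seed = 2)
  expect_equal(dim(m$layers[[1]]$W), c(10, 6))
  expect_equal(dim(m$layers[[2]]$W), c(6, 3))
  expect_error(dbn_model(10), class = "histodbn_parameter_error")
})

test_that("up-down fine-tuning drives a separable toy to zero training error", {
  toy <- separable_binary_toy(30, seed = 0)
  cfg <- train_config(epochs = 10, finetune_epochs = 20, seed = 0)
  m <- dbn_fit(toy$x, toy$y, hidden_sizes = c(8, 4), config = cfg)
  expect_equal(dplyr::last(m$finetune_log$train_error_rate), 0)

  # fine-tuning does not increase the training error of the pretrained model
  first <- m$finetune_log$train_error_rate[1]
  expect_lte(dplyr::last(m$finetune_log$train_error_rate), first)

  # zero fine-tune epochs leave the model unchanged
  m1 <- dbn_model(c(2, 8, 4), classes = c("benign", "malignant"), seed = 0)
  cfg0 <- train_config(epochs = 0, finetune_epochs = 0, seed = 0)
  expect_identical(up_down_finetune(m1, toy$x, toy$y, cfg0), m1)

  # same seed twice gives an identical classifier head
  mA <- dbn_fit(toy$x, toy$y, hidden_sizes = c(8, 4), config = cfg)
  expect_identical(m$head, mA$head)
})

test_that("prediction yields normalized scores and honours a zero head", {
  toy <- separable_binary_toy(10, seed = 3)
  m <- dbn_model(c(2, 6, 4), classes = c("benign", "malignant"), seed = 3)
  m$head$W <- matrix(0, 4, 2)  # zero head: exactly uniform scores
  p <- predict(m, toy$x, type = "prob", scaled = TRUE)
  expect_true(all(p == 0.5))

  withr::with_seed(55, {
    m2 <- dbn_model(c(2, 6, 4), classes = c("benign", "malignant"), seed = 4)
    p2 <- predict(m2, matrix(runif(20), 10, 2), type = "prob", scaled = TRUE)
    expect_lt(max(abs(rowSums(p2) - 1)), 1e-9)
  })
  expect_error(predict(m, matrix(0, 2, 5), scaled = TRUE),
               class = "histodbn_structural_error")
})

test_that("a single training example is memorized", {
  x <- matrix(c(1, 0, 1, 0), 2, 2)
  y <- c("benign", "malignant")
  cfg <- train_config(epochs = 5, finetune_epochs = 150, batch_size = 2,
                      dropout = 0, seed = 1)
  m <- dbn_fit(x, y, hidden_sizes = c(4, 3), config = cfg)
  expect_equal(as.character(predict(m, x)), y)
})

test_that("the greedy bound never exceeds the exact log-likelihood", {
  # two-layer DBN with enumerable states: log p(x) >= the variational bound
  # built from the recognition posterior Q(h|x)
  sig <- function(z) 1 / (1 + exp(-z))
  withr::with_seed(56, {
    for (rep in 1:10) {
      nv <- 3; nh1 <- 3; nh2 <- 2
      W1 <- matrix(rnorm(nv * nh1), nv, nh1); a1 <- rnorm(nv); b1 <- rnorm(nh1)
      W2 <- matrix(rnorm(nh1 * nh2), nh1, nh2); a2 <- rnorm(nh1); b2 <- rnorm(nh2)
      H1 <- all_binary_states(nh1); H2 <- all_binary_states(nh2)
      # top RBM marginal p(h1) by enumeration
      en <- sapply(seq_len(nrow(H1)), function(i) {
        sum(sapply(seq_len(nrow(H2)), function(j) {
          exp(sum(a2 * H1[i, ]) + sum(b2 * H2[j, ]) +
                as.numeric(H1[i, ] %*% W2 %*% H2[j, ]))
        }))
      })
      p_h1 <- en / sum(en)
      x <- sample(0:1, nv, replace = TRUE)
      # generative conditional p(x | h1), factorized sigmoid
      p_x_h1 <- sapply(seq_len(nrow(H1)), function(i) {
        pv <- sig(as.numeric(W1 %*% H1[i, ]) + a1)
        prod(ifelse(x == 1, pv, 1 - pv))
      })
      log_px <- log(sum(p_h1 * p_x_h1))
      # recognition posterior Q(h1 | x), factorized sigmoid
      qh <- sig(as.numeric(x %*% W1) + b1)
      Q <- sapply(seq_len(nrow(H1)), function(i) {
        prod(ifelse(H1[i, ] == 1, qh, 1 - qh))
      })
      bound <- sum(Q * (log(p_h1) + log(pmax(p_x_h1, 1e-300)))) -
        sum(Q * log(pmax(Q, 1e-300)))
      expect_lte(bound, log_px + 1e-10)
    }
  })
})

test_that("model tidiers summarise training history", {
  toy <- separable_binary_toy(10, seed = 6)
  cfg <- train_config(epochs = 3, finetune_epochs = 3, seed = 6)
  m <- dbn_fit(toy$x, toy$y, hidden_sizes = c(4, 3), config = cfg)
  td <- tidy(m)
  expect_true(all(c("pretrain", "finetune") %in% unique(td$stage)))
  g <- glance(m)
  expect_true(g$pretrained && g$finetuned)
  expect_s3_class(autoplot(m), "ggplot")
})
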