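#' Restricted Boltzmann machine layer
#'
#' One bipartite energy-based layer: visible bias `a`, hidden bias `b`, and a
#' `visible x hidden` weight matrix `W`.  Weights are initialized from
#' N(0, init_sd^2) using the current RNG state ([dbn_model()] seeds it); the
#' default is the Xavier scale `1/sqrt(n_visible)`, which keeps the hidden
#' pre-activations at unit order so that both contrastive divergence and the
#' supervised fine-tuning gradients have signal from the first epoch.
#'
#' @param n_visible,n_hidden Unit counts (>= 1).
#' @param init_sd Weight initialization standard deviation.
#' @return An `rbm_layer`.
#' @export
rbm_layer <- function(n_visible, n_hidden, init_sd = 1 / sqrt(n_visible)) {
  structure(list(W = matrix(rnorm(n_visible * n_hidden, sd = init_sd),
                            n_visible, n_hidden),
                 a = numeric(n_visible), b = numeric(n_hidden)),
            class = "rbm_layer")
}

#' RBM energy
#'
#' `E(v, h) = -a'v - b'h - v'Wh`; lower energy corresponds to higher
#' unnormalized probability under the layer's Boltzmann distribution.
#'
#' @param layer An [rbm_layer()].
#' @param v,h Binary vectors of visible/hidden states.
#' @return Finite scalar energy.
#' @examples
#' ly <- structure(list(W = matrix(1), a = 0, b = 0), class = "rbm_layer")
#' rbm_energy(ly, 1, 1)  # -1
#' @export
rbm_energy <- function(layer, v, h) {
  if (length(v) != nrow(layer$W) || length(h) != ncol(layer$W)) {
    abort("State lengths do not match the layer.", class = "histodbn_structural_error")
  }
  -sum(layer$a * v) - sum(layer$b * h) - as.numeric(v %*% layer$W %*% h)
}

# batch conditionals; V is n x visible, H is n x hidden
rbm_hidden_probs <- function(layer, V) sigmoid(V %*% layer$W +
                                               rep(layer$b, each = nrow(V)))
rbm_visible_probs <- function(layer, H) sigmoid(H %*% t(layer$W) +
                                                rep(layer$a, each = nrow(H)))
sample_bernoulli <- function(P) {
  out <- (matrix(runif(length(P)), nrow(P), ncol(P)) < P) * 1
  out
}

#' Contrastive-divergence weight update
#'
#' CD-k: the positive phase uses the data, the negative phase the k-th Gibbs
#' reconstruction.  `Delta W = eta * (<v h'>_data - <v h'>_recon) / n`, with
#' the analogous bias updates.  Sampling uses the current RNG state; seed it
#' for reproducibility (the training drivers do).
#'
#' @param layer An [rbm_layer()].
#' @param batch `n x visible` matrix with entries in `[0, 1]` (treated as
#'   Bernoulli probabilities).
#' @param k Number of Gibbs alternations (>= 1).
#' @param learning_rate Step size eta.
#' @return The updated layer.
#' @export
cd_update <- function(layer, batch, k = 1, learning_rate = 0.01) {
  if (k < 1) abort("`k` must be >= 1.", class = "histodbn_parameter_error")
  if (ncol(batch) != nrow(layer$W)) {
    abort("Batch width does not match visible size.", class = "histodbn_structural_error")
  }
  n <- nrow(batch)
  ph0 <- rbm_hidden_probs(layer, batch)
  h <- sample_bernoulli(ph0)
  v <- batch
  for (step in seq_len(k)) {
    pv <- rbm_visible_probs(layer, h)
    v <- sample_bernoulli(pv)
    ph <- rbm_hidden_probs(layer, v)
    if (step < k) h <- sample_bernoulli(ph)
  }
  eta <- learning_rate / n
  layer$W <- layer$W + eta * (t(batch) %*% ph0 - t(v) %*% ph)
  layer$a <- layer$a + eta * colSums(batch - v)
  layer$b <- layer$b + eta * colSums(ph0 - ph)
  layer
}

#' DBN training configuration
#'
#' Defaults follow the reference settings of the classification experiments:
#' learning rate 0.01, dropout 0.5, batch size 5; the epoch counts are
#' exposed so desk-scale runs can shorten them.
#'
#' @param cd_steps Gibbs alternations per CD update (>= 1).
#' @param epochs Pretraining epochs per layer (>= 0; 0 leaves the model
#'   untouched).
#' @param finetune_epochs Up-down fine-tuning epochs (>= 0).
#' @param batch_size Minibatch size.
#' @param learning_rate Step size for CD and the wake/sleep deltas; also the
#'   Adamax rate for the classifier head.
#' @param dropout Dropout probability applied to the head input during
#'   fine-tuning only.
#' @param seed Integer seed; training is reproducible given it.
#' @return A `train_config`.
#' @export
train_config <- function(cd_steps = 1, epochs = 15, finetune_epochs = 15,
                         batch_size = 5, learning_rate = 0.01, dropout = 0.5,
                         seed = 1) {
  if (cd_steps < 1 || batch_size < 1 || learning_rate <= 0) {
    abort("cd_steps, batch_size, learning_rate must be positive.",
          class = "histodbn_parameter_error")
  }
  if (epochs < 0 || finetune_epochs < 0) {
    abort("Epoch counts must be >= 0.", class = "histodbn_parameter_error")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("dropout must lie in [0, 1).", class = "histodbn_parameter_error")
  }
  structure(list(cd_steps = as.integer(cd_steps), epochs = as.integer(epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Deep belief network model
#'
#' A stack of RBM layers plus a softmax head over the top-layer hidden
#' probabilities.  The head is initialized at the Xavier scale (a zero head
#' yields exactly uniform class scores, but blocks the supervised gradient
#' path for many epochs).  After
#' [up_down_finetune()] the stack is untied into recognition (upward) and
#' generative (downward) parameters, Hinton-style, with the top layer kept as
#' an undirected RBM extended by label connections.
#'
#' @param layer_sizes Integer vector of unit counts, visible first, e.g.
#'   `c(32, 64, 32)`.
#' @param n_classes Number of classes for the head (default 2).
#' @param classes Optional class labels (length `n_classes`).
#' @param seed Seed for weight initialization.
#' @return A `dbn_model`.
#' @export
dbn_model <- function(layer_sizes, n_classes = 2, classes = NULL, seed = 42) {
  if (length(layer_sizes) < 2) {
    abort("Need at least one RBM layer (two sizes).", class = "histodbn_parameter_error")
  }
  top <- layer_sizes[length(layer_sizes)]
  init <- withr::with_seed(seed, {
    layers <- purrr::map(seq_len(length(layer_sizes) - 1L), function(i) {
      rbm_layer(layer_sizes[i], layer_sizes[i + 1L])
    })
    head_W <- matrix(rnorm(top * n_classes, sd = 1 / sqrt(top)), top, n_classes)
    list(layers = layers, head_W = head_W)
  })
  structure(list(
    layers = init$layers, layer_sizes = as.integer(layer_sizes),
    head = list(W = init$head_W, b = numeric(n_classes)),
    label_W = NULL, label_bias = NULL,  # top-RBM label pathway, set by finetune
    rec = NULL, gen = NULL,             # untied directed weights, set by finetune
    scaler = NULL, classes = classes, n_classes = as.integer(n_classes),
    pretrain_log = NULL, finetune_log = NULL, seed = as.integer(seed)
  ), class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  cat("<dbn_model> layers ", paste(x$layer_sizes, collapse = "-"),
      " + ", x$n_classes, "-way head",
      if (!is.null(x$rec)) " (fine-tuned)" else "", "\n", sep = "")
  invisible(x)
}

#' Greedy layer-wise pretraining
#'
#' Trains the first RBM on the data by contrastive divergence, then each
#' subsequent RBM on the hidden-probability transform of its predecessor —
#' the classic greedy stacking that makes the deep network trainable.
#' Deterministic per `config$seed`.  Appends a `pretrain_log` tibble
#' (`layer`, `epoch`, `recon_error` = mean reconstruction cross-entropy).
#'
#' @param model A [dbn_model()].
#' @param data `n x visible` matrix with entries in `[0, 1]`.
#' @param config A [train_config()].
#' @return The pretrained model.
#' @export
greedy_pretrain <- function(model, data, config) {
  if (ncol(data) != model$layer_sizes[1]) {
    abort("Data width does not match the first visible size.",
          class = "histodbn_structural_error")
  }
  if (config$epochs == 0L) return(model)
  withr::with_seed(substream_seed(config$seed, "pretrain"), {
    logs <- list()
    input <- data
    for (li in seq_along(model$layers)) {
      layer <- model$layers[[li]]
      for (ep in seq_len(config$epochs)) {
        idx <- sample.int(nrow(input))
        for (start in seq(1, nrow(input), by = config$batch_size)) {
          rows <- idx[start:min(start + config$batch_size - 1L, nrow(input))]
          layer <- cd_update(layer, input[rows, , drop = FALSE],
                             k = config$cd_steps,
                             learning_rate = config$learning_rate)
        }
        pv <- rbm_visible_probs(layer, rbm_hidden_probs(layer, input))
        ce <- -mean(input * log(pmax(pv, 1e-12)) +
                      (1 - input) * log(pmax(1 - pv, 1e-12)))
        logs[[length(logs) + 1L]] <-
          tibble::tibble(layer = li, epoch = ep, recon_error = ce)
      }
      model$layers[[li]] <- layer
      input <- rbm_hidden_probs(layer, input)
    }
    model$pretrain_log <- dplyr::bind_rows(logs)
    model
  })
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  Y
}

# upward pass to the top-layer hidden probabilities (recognition path)
top_hidden_probs <- function(model, X) {
  L <- length(model$layers)
  a <- X
  if (L > 1L) {
    for (li in seq_len(L - 1L)) {
      w <- if (!is.null(model$rec)) model$rec[[li]] else model$layers[[li]]
      a <- sigmoid(a %*% w$W + rep(w$b, each = nrow(a)))
    }
  }
  top <- model$layers[[L]]
  sigmoid(a %*% top$W + rep(top$b, each = nrow(a)))
}

#' Up-down (wake-sleep) fine-tuning
#'
#' Unties the pretrained stack into recognition and generative parameters and
#' refines them with the two-pass up-down procedure: the wake phase drives a
#' sampled recognition pass upward and updates the generative (top-down)
#' weights to reconstruct each layer below; the top layer — an undirected RBM
#' whose visible units are extended with the class labels — takes a CD step;
#' the sleep phase drives a generative pass downward and updates the
#' recognition (bottom-up) weights.  Jointly, the supervised pathway — the
#' deterministic recognition pass into the softmax head — is trained with the
#' Adamax rule by backpropagating the classification cross-entropy through
#' the head, the top layer and the recognition weights, with dropout on the
#' head input.  This supervised pressure is what cures the underfitting of a
#' greedily trained stack: contrastive divergence alone leaves small-weight
#' layers near-uninformative on low-dimensional inputs, while the generative
#' wake/sleep updates keep the stack's layer-wise reconstructions honest
#' during the supervised refinement.  Appends a `finetune_log` tibble
#' (`epoch`, `train_error_rate`, `train_loss`, optionally validation
#' columns).
#'
#' @param model A pretrained [dbn_model()] (an unpretrained model is accepted
#'   but flagged in the log).
#' @param data `n x visible` matrix in `[0, 1]`.
#' @param labels Class labels, length `n`.
#' @param config A [train_config()]; `config$finetune_epochs` controls the
#'   number of passes (0 returns the model unchanged).
#' @param optimizer An [adamax_state()] for the head (default built from
#'   `config$learning_rate`).
#' @param val_data,val_labels Optional held-out features/labels; when given,
#'   per-epoch validation error and loss are added to the log.
#' @return The fine-tuned model.
#' @export
up_down_finetune <- function(model, data, labels, config,
                             optimizer = adamax_state(learning_rate = config$learning_rate),
                             val_data = NULL, val_labels = NULL) {
  if (ncol(data) != model$layer_sizes[1]) {
    abort("Data width does not match the first visible size.",
          class = "histodbn_structural_error")
  }
  if (config$finetune_epochs == 0L) return(model)
  classes <- model$classes %||% sort(unique(as.character(labels)))
  model$classes <- classes
  L <- length(model$layers)
  head_loss <- function(X, lab) {
    P <- predict(model, X, type = "prob", scaled = TRUE)
    Y <- one_hot(lab, classes)
    -mean(rowSums(Y * log(pmax(P, 1e-12))))
  }
  withr::with_seed(substream_seed(config$seed, "finetune"), {
    if (is.null(model$rec) && L > 1L) {
      model$rec <- purrr::map(model$layers[seq_len(L - 1L)],
                              function(ly) list(W = ly$W, b = ly$b))
      model$gen <- purrr::map(model$layers[seq_len(L - 1L)],
                              function(ly) list(W = ly$W, a = ly$a))
    }
    if (is.null(model$label_W)) {
      model$label_W <- matrix(0, length(classes), ncol(model$layers[[L]]$W))
      model$label_bias <- numeric(length(classes))
    }
    eta <- config$learning_rate
    keep <- 1 - config$dropout
    logs <- list()
    flagged <- is.null(model$pretrain_log)
    for (ep in seq_len(config$finetune_epochs)) {
      idx <- sample.int(nrow(data))
      for (start in seq(1, nrow(data), by = config$batch_size)) {
        rows <- idx[start:min(start + config$batch_size - 1L, nrow(data))]
        x <- data[rows, , drop = FALSE]
        y <- one_hot(labels[rows], classes)
        n <- nrow(x)
        # ---- wake: recognition pass upward, generative updates downward
        states <- list(x)
        if (L > 1L) {
          for (li in seq_len(L - 1L)) {
            p <- sigmoid(states[[li]] %*% model$rec[[li]]$W +
                           rep(model$rec[[li]]$b, each = n))
            states[[li + 1L]] <- sample_bernoulli(p)
            prev <- sigmoid(states[[li + 1L]] %*% t(model$gen[[li]]$W) +
                              rep(model$gen[[li]]$a, each = n))
            model$gen[[li]]$W <- model$gen[[li]]$W +
              eta / n * t(states[[li]] - prev) %*% states[[li + 1L]]
            model$gen[[li]]$a <- model$gen[[li]]$a +
              eta * colMeans(states[[li]] - prev)
          }
        }
        # ---- top RBM with label units: one CD step
        top <- model$layers[[L]]
        v <- states[[L]]
        ph0 <- sigmoid(v %*% top$W + y %*% model$label_W + rep(top$b, each = n))
        h <- sample_bernoulli(ph0)
        pv <- sigmoid(h %*% t(top$W) + rep(top$a, each = n))
        v1 <- sample_bernoulli(pv)
        plab <- softmax_rows(h %*% t(model$label_W) +
                               rep(model$label_bias, each = n))
        ph1 <- sigmoid(v1 %*% top$W + plab %*% model$label_W +
                         rep(top$b, each = n))
        top$W <- top$W + eta / n * (t(v) %*% ph0 - t(v1) %*% ph1)
        top$a <- top$a + eta * colMeans(v - v1)
        top$b <- top$b + eta * colMeans(ph0 - ph1)
        model$label_W <- model$label_W +
          eta / n * (t(y) %*% ph0 - t(plab) %*% ph1)
        model$label_bias <- model$label_bias + eta * colMeans(y - plab)
        model$layers[[L]] <- top
        # ---- sleep: generative pass downward, recognition updates upward
        if (L > 1L) {
          down <- sample_bernoulli(sigmoid(h %*% t(top$W) + rep(top$a, each = n)))
          for (li in rev(seq_len(L - 1L))) {
            below <- sample_bernoulli(
              sigmoid(down %*% t(model$gen[[li]]$W) +
                        rep(model$gen[[li]]$a, each = n)))
            q <- sigmoid(below %*% model$rec[[li]]$W +
                           rep(model$rec[[li]]$b, each = n))
            model$rec[[li]]$W <- model$rec[[li]]$W +
              eta / n * t(below) %*% (down - q)
            model$rec[[li]]$b <- model$rec[[li]]$b + eta * colMeans(down - q)
            down <- below
          }
        }
        # ---- supervised pathway: Adamax backprop through recognition stack
        acts <- list(x)
        if (L > 1L) {
          for (li in seq_len(L - 1L)) {
            acts[[li + 1L]] <- sigmoid(acts[[li]] %*% model$rec[[li]]$W +
                                         rep(model$rec[[li]]$b, each = n))
          }
        }
        top <- model$layers[[L]]
        hp <- sigmoid(acts[[L]] %*% top$W + rep(top$b, each = n))
        mask <- matrix(runif(length(hp)) < keep, n, ncol(hp)) / keep
        hd <- hp * mask
        P <- softmax_rows(hd %*% model$head$W + rep(model$head$b, each = n))
        dZ <- (P - y) / n
        params <- list(head_W = model$head$W, head_b = model$head$b,
                       top_W = top$W, top_b = top$b)
        grads <- list(head_W = t(hd) %*% dZ, head_b = colSums(dZ))
        dhp <- (dZ %*% t(model$head$W)) * mask * hp * (1 - hp)
        grads$top_W <- t(acts[[L]]) %*% dhp
        grads$top_b <- colSums(dhp)
        if (L > 1L) {
          da <- dhp %*% t(top$W)
          for (li in rev(seq_len(L - 1L))) {
            dz <- da * acts[[li + 1L]] * (1 - acts[[li + 1L]])
            grads[[paste0("rec", li, "_W")]] <- t(acts[[li]]) %*% dz
            grads[[paste0("rec", li, "_b")]] <- colSums(dz)
            params[[paste0("rec", li, "_W")]] <- model$rec[[li]]$W
            params[[paste0("rec", li, "_b")]] <- model$rec[[li]]$b
            if (li > 1L) da <- dz %*% t(model$rec[[li]]$W)
          }
        }
        stepped <- adamax_step_list(optimizer, params, grads)
        optimizer <- stepped$state
        model$head$W <- stepped$params$head_W
        model$head$b <- stepped$params$head_b
        model$layers[[L]]$W <- stepped$params$top_W
        model$layers[[L]]$b <- stepped$params$top_b
        if (L > 1L) {
          for (li in seq_len(L - 1L)) {
            model$rec[[li]]$W <- stepped$params[[paste0("rec", li, "_W")]]
            model$rec[[li]]$b <- stepped$params[[paste0("rec", li, "_b")]]
          }
        }
      }
      pred <- predict(model, data, type = "class", scaled = TRUE)
      row <- tibble::tibble(
        epoch = ep,
        train_error_rate = fitness_error_rate(pred, labels),
        train_loss = head_loss(data, labels),
        unpretrained = flagged
      )
      if (!is.null(val_data)) {
        row$val_error_rate <- fitness_error_rate(
          predict(model, val_data, type = "class", scaled = TRUE), val_labels)
        row$val_loss <- head_loss(val_data, val_labels)
      }
      logs[[length(logs) + 1L]] <- row
    }
    model$finetune_log <- dplyr::bind_rows(logs)
    model
  })
}

#' Predict classes and scores
#'
#' Deterministic forward pass: recognition weights up to the top hidden
#' probabilities, then the softmax head.  Scores sum to 1 per row.
#'
#' @param object A `dbn_model`.
#' @param newdata `n x visible` feature matrix; the model's stored min-max
#'   scaler (if any) is applied unless `scaled = TRUE`.
#' @param type `"class"` for labels, `"prob"` for the score matrix.
#' @param scaled Set `TRUE` when `newdata` is already on the model's `[0, 1]`
#'   training scale.
#' @param ... Unused.
#' @return Labels (factor/character) or an `n x n_classes` score matrix.
#' @export
predict.dbn_model <- function(object, newdata, type = c("class", "prob"),
                              scaled = FALSE, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!scaled && !is.null(object$scaler)) {
    newdata <- apply_scaler(newdata, object$scaler)
  }
  if (ncol(newdata) != object$layer_sizes[1]) {
    abort("Feature width does not match the model.", class = "histodbn_structural_error")
  }
  hp <- top_hidden_probs(object, newdata)
  P <- softmax_rows(hp %*% object$head$W + rep(object$head$b, each = nrow(hp)))
  if (type == "prob") {
    colnames(P) <- object$classes %||% paste0("class", seq_len(ncol(P)))
    return(P)
  }
  cls <- object$classes %||% paste0("class", seq_len(ncol(P)))
  factor(cls[max.col(P, ties.method = "first")], levels = cls)
}

fit_scaler <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  list(lo = lo, span = pmax(hi - lo, 1e-12))
}
apply_scaler <- function(X, scaler) {
  clamp(sweep(sweep(X, 2, scaler$lo, "-"), 2, scaler$span, "/"), 0, 1)
}

#' Fit a DBN classifier on real-valued features
#'
#' Convenience driver: min-max scales the feature columns to `[0, 1]` (stored
#' with the model and re-applied at prediction), greedily pretrains the stack
#' and runs up-down fine-tuning.
#'
#' @param features `n x d` numeric matrix.
#' @param labels Class labels, length `n`.
#' @param hidden_sizes Hidden-layer widths (default `c(64, 32)`).
#' @param config A [train_config()].
#' @return A fitted `dbn_model`.
#' @export
dbn_fit <- function(features, labels, hidden_sizes = c(64, 32),
                    config = train_config()) {
  features <- as.matrix(features)
  classes <- levels(factor(labels))
  model <- dbn_model(c(ncol(features), hidden_sizes),
                     n_classes = length(classes), classes = classes,
                     seed = config$seed)
  model$scaler <- fit_scaler(features)
  X <- apply_scaler(features, model$scaler)
  model <- greedy_pretrain(model, X, config)
  up_down_finetune(model, X, labels, config)
}
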