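# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# per-pixel median with symmetric (reflect) padding, plain sort
oracle_median_filter <- function(m, window) {
  r <- (window - 1) / 2
  n <- nrow(m); p <- ncol(m)
  ri <- c(r:1, 1:n, n:(n - r + 1))
  ci <- c(r:1, 1:p, p:(p - r + 1))
  pm <- m[ri, ci, drop = FALSE]
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      vals <- sort(as.vector(pm[i:(i + 2 * r), j:(j + 2 * r)]))
      out[i, j] <- vals[(length(vals) + 1) / 2]
    }
  }
  out
}

# direct convolution by quadruple loop; zero same-padding; x: C x H x W,
# W: Cout x Cin x k x k
oracle_conv2d <- function(x, W, b = NULL) {
  dx <- dim(x); dw <- dim(W)
  k <- dw[3]; r <- (k - 1) / 2
  H <- dx[2]; Wd <- dx[3]
  out <- array(0, c(dw[1], H, Wd))
  for (co in seq_len(dw[1])) {
    for (i in seq_len(H)) {
      for (j in seq_len(Wd)) {
        acc <- if (is.null(b)) 0 else b[co]
        for (ci in seq_len(dw[2])) {
          for (di in seq_len(k)) {
            for (dj in seq_len(k)) {
              ii <- i + di - 1 - r; jj <- j + dj - 1 - r
              if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
                acc <- acc + x[ci, ii, jj] * W[co, ci, di, dj]
              }
            }
          }
        }
        out[co, i, j] <- acc
      }
    }
  }
  out
}

all_binary_states <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# exact log-likelihood gradient of a small RBM by full enumeration
oracle_rbm_gradient <- function(W, a, b, batch) {
  nv <- nrow(W); nh <- ncol(W)
  sig <- function(z) 1 / (1 + exp(-z))
  # positive phase: E_{h|v}[v h'] averaged over the batch
  ph <- sig(batch %*% W + matrix(b, nrow(batch), nh, byrow = TRUE))
  pos_W <- t(batch) %*% ph / nrow(batch)
  pos_a <- colMeans(batch)
  pos_b <- colMeans(ph)
  # model phase: enumerate p(v, h)
  Vs <- all_binary_states(nv); Hs <- all_binary_states(nh)
  energies <- matrix(0, nrow(Vs), nrow(Hs))
  for (i in seq_len(nrow(Vs))) {
    for (j in seq_len(nrow(Hs))) {
      v <- Vs[i, ]; h <- Hs[j, ]
      energies[i, j] <- -sum(a * v) - sum(b * h) - as.numeric(v %*% W %*% h)
    }
  }
  p <- exp(-energies); p <- p / sum(p)
  neg_W <- matrix(0, nv, nh); neg_a <- numeric(nv); neg_b <- numeric(nh)
  for (i in seq_len(nrow(Vs))) {
    for (j in seq_len(nrow(Hs))) {
      neg_W <- neg_W + p[i, j] * outer(Vs[i, ], Hs[j, ])
      neg_a <- neg_a + p[i, j] * Vs[i, ]
      neg_b <- neg_b + p[i, j] * Hs[j, ]
    }
  }
  list(W = pos_W - neg_W, a = pos_a - neg_a, b = pos_b - neg_b)
}

# independent implementation of the five report metrics from a 2x2 table
oracle_metrics <- function(tp, fn, fp, tn) {
  total <- tp + fn + fp + tn
  mcc_den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  c(accuracy = 100 * (tp + tn) / total,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    f_score = 100 * 2 * tp / (2 * tp + fp + fn),
    mcc = 100 * (tp * tn - fp * fn) / mcc_den)
}

# toy data builders ----------------------------------------------------------

separable_binary_toy <- function(n_per_class = 30, seed = 0) {
  withr::with_seed(seed, {
    raw <- rbind(matrix(rnorm(n_per_class * 2, -1.5, 0.5), n_per_class, 2),
                 matrix(rnorm(n_per_class * 2, 1.5, 0.5), n_per_class, 2))
    list(x = (raw > 0) * 1,
         y = rep(c("benign", "malignant"), each = n_per_class))
  })
}

bars_data <- function(n = 60, side = 8, seed = 1) {
  withr::with_seed(seed, {
    t(sapply(seq_len(n), function(i) {
      img <- matrix(0, side, side)
      img[sample(side, 2), ] <- 1
      as.vector(img)
    }))
  })
}
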