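# Attentive tabular classifier: K sequential decision steps, each with an
# input-dependent softmax feature mask relaxed by a prior (features attended
# at earlier steps are discounted by `relaxation`), a masked ReLU feature
# transformer, and an additive contribution to the logit. The masked input is
# rescaled by p so a uniform mask leaves feature scale unchanged. Loss is
# class-weighted cross-entropy plus an entropy sparsity penalty on the masks.
# Trained full-vectorized with Adam; gradients flow through the full prior
# chain and are checked against finite differences in the test suite.

att_init <- function(p, d, K) {
  par <- list()
  for (k in seq_len(K)) {
    par[[paste0("Wa", k)]] <- matrix(stats::rnorm(p * p, 0, 0.05), p, p)
    par[[paste0("ba", k)]] <- rep(0, p)
    par[[paste0("W1", k)]] <- matrix(stats::rnorm(p * d, 0, sqrt(2 / p)), p, d)
    par[[paste0("b1", k)]] <- rep(0, d)
    par[[paste0("w2", k)]] <- matrix(stats::rnorm(d, 0, 0.1), d, 1)
  }
  par$b0 <- 0
  par
}

row_softmax <- function(A) {
  E <- exp(A - apply(A, 1, max))
  E / rowSums(E)
}

att_forward <- function(par, X, K, relaxation, keep = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  prior <- matrix(1, n, p)
  logit <- rep(par$b0, n)
  cache <- if (keep) vector("list", K) else NULL
  for (k in seq_len(K)) {
    A <- X %*% par[[paste0("Wa", k)]]
    A <- sweep(A, 2, par[[paste0("ba", k)]], "+")
    S <- row_softmax(A)
    U <- S * prior
    r <- rowSums(U)
    M <- U / r
    Z <- X * M * p
    pre <- sweep(Z %*% par[[paste0("W1", k)]], 2, par[[paste0("b1", k)]], "+")
    H <- pmax(pre, 0)
    logit <- logit + as.vector(H %*% par[[paste0("w2", k)]])
    if (keep) cache[[k]] <- list(S = S, prior = prior, r = r, M = M, Z = Z, H = H)
    prior <- prior * (relaxation - M)
  }
  list(logit = logit, cache = cache)
}

att_loss_grad <- function(par, X, y, w, K, relaxation, sparsity) {
  eps <- 1e-8
  n <- nrow(X)
  fw <- att_forward(par, X, K, relaxation, keep = TRUE)
  prob <- stats::plogis(fw$logit)
  sw <- sum(w)
  loss <- sum(w * (-(y * log(prob + eps) + (1 - y) * log(1 - prob + eps)))) / sw
  grad <- vector("list", length(par))
  names(grad) <- names(par)
  dlogit <- w * (prob - y) / sw
  grad$b0 <- sum(dlogit)
  p <- ncol(X)
  ent_scale <- sparsity / (n * K)
  for (k in seq_len(K)) {
    loss <- loss + ent_scale * sum(-fw$cache[[k]]$M * log(fw$cache[[k]]$M + eps))
  }
  dprior <- matrix(0, n, p)  # gradient flowing into prior_{k+1}
  for (k in rev(seq_len(K))) {
    cc <- fw$cache[[k]]
    dH <- tcrossprod(dlogit, par[[paste0("w2", k)]][, 1])  # n x d
    dH[cc$H <= 0] <- 0
    grad[[paste0("w2", k)]] <- crossprod(cc$H, dlogit)
    grad[[paste0("W1", k)]] <- crossprod(cc$Z, dH)
    grad[[paste0("b1", k)]] <- colSums(dH)
    dZ <- tcrossprod(dH, par[[paste0("W1", k)]])           # n x p
    dM <- dZ * X * p +
      ent_scale * (-log(cc$M + eps) - cc$M / (cc$M + eps)) -
      dprior * cc$prior                 # prior_{k+1} = prior_k * (relax - M_k)
    dU <- (dM - rowSums(dM * cc$M)) / cc$r
    dS <- dU * cc$prior
    dprior <- dU * cc$S + dprior * (relaxation - cc$M)
    dA <- cc$S * (dS - rowSums(dS * cc$S))
    grad[[paste0("Wa", k)]] <- crossprod(X, dA)
    grad[[paste0("ba", k)]] <- colSums(dA)
  }
  list(loss = loss, grad = grad)
}

att_val_loss <- function(par, X, y, w, K, relaxation) {
  eps <- 1e-8
  prob <- stats::plogis(att_forward(par, X, K, relaxation)$logit)
  sum(w * (-(y * log(prob + eps) + (1 - y) * log(1 - prob + eps)))) / sum(w)
}

# early-stopping monitor: negative validation AUROC (discrimination is the
# primary outcome); falls back to weighted loss when only one class is held out
att_monitor <- function(par, X, y, w, K, relaxation) {
  if (length(unique(y)) == 2) {
    prob <- stats::plogis(att_forward(par, X, K, relaxation)$logit)
    -auroc(prob, y)
  } else {
    att_val_loss(par, X, y, w, K, relaxation)
  }
}

fit_attentive <- function(X, y, config, seed, groups = NULL) {
  K <- config$n_steps
  d <- config$width
  p <- ncol(X)
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  w_all <- ifelse(y == 1, config$class_weight_ca, 1)

  withr::with_seed(seed, {
    # validation split for early stopping; grouped (e.g. by patient) when
    # groups are supplied, so the monitor measures generalization to unseen
    # subjects rather than interpolation within them
    n <- nrow(Xs)
    val_idx <- integer(0)
    if (config$val_frac > 0 && n >= 20) {
      if (!is.null(groups)) {
        pos_groups <- unique(groups[y == 1])
        neg_groups <- setdiff(unique(groups), pos_groups)
        pick <- function(g) {
          n_val <- floor(config$val_frac * length(g))
          if (n_val >= 1 && length(g) >= 2) sample(g, n_val) else character(0)
        }
        val_groups <- c(pick(pos_groups), pick(neg_groups))
        val_idx <- which(groups %in% val_groups)
      } else {
        for (cls in c(0, 1)) {
          idx <- which(y == cls)
          n_val <- floor(config$val_frac * length(idx))
          if (n_val >= 1) val_idx <- c(val_idx, sample(idx, n_val))
        }
      }
      # both classes must remain on each side, else fall back to no split
      if (length(val_idx) &&
          (length(unique(y[val_idx])) < 2 || length(unique(y[-val_idx])) < 2)) {
        val_idx <- integer(0)
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]; wtr <- w_all[tr_idx]
    Xva <- Xs[val_idx, , drop = FALSE]; yva <- y[val_idx]; wva <- w_all[val_idx]

    par <- att_init(p, d, K)
    m1 <- lapply(par, function(v) v * 0)
    m2 <- lapply(par, function(v) v * 0)
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
    lr <- config$learning_rate
    step <- 0L
    best <- list(loss = Inf, par = par, epoch = 0L)
    wait <- 0L
    epochs_run <- 0L
    for (epoch in seq_len(config$epochs)) {
      epochs_run <- epoch
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1, nrow(Xtr), by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1, nrow(Xtr))]
        if (length(rows) < 2) next
        lg <- att_loss_grad(par, Xtr[rows, , drop = FALSE], ytr[rows],
                            wtr[rows], K, config$relaxation, config$sparsity)
        step <- step + 1L
        for (nm in names(par)) {
          g <- lg$grad[[nm]]
          m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g
          m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g * g
          mhat <- m1[[nm]] / (1 - b1^step)
          vhat <- m2[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] -
            lr * (mhat / (sqrt(vhat) + adam_eps) + config$weight_decay * par[[nm]])
        }
      }
      monitor <- if (length(val_idx)) {
        att_monitor(par, Xva, yva, wva, K, config$relaxation)
      } else {
        att_val_loss(par, Xtr, ytr, wtr, K, config$relaxation)
      }
      if (monitor < best$loss - 1e-6) {
        best <- list(loss = monitor, par = par, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    list(par = best$par, mu = mu, sg = sg, K = K,
         relaxation = config$relaxation, best_epoch = best$epoch,
         epochs_run = epochs_run, val_loss = best$loss)
  })
}

predict_attentive <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sg, "/")
  stats::plogis(att_forward(fit$par, Xs, fit$K, fit$relaxation)$logit)
}

explain_attentive <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sg, "/")
  fw <- att_forward(fit$par, Xs, fit$K, fit$relaxation, keep = TRUE)
  masks <- lapply(fw$cache, function(cc) {
    m <- cc$M
    colnames(m) <- colnames(X)
    m
  })
  agg <- matrix(0, nrow(X), ncol(X))
  for (k in seq_len(fit$K)) {
    eta <- rowSums(fw$cache[[k]]$H)  # nonnegative step contribution
    agg <- agg + eta * fw$cache[[k]]$M
  }
  rs <- rowSums(agg)
  zero <- rs <= 0
  agg[!zero, ] <- agg[!zero, , drop = FALSE] / rs[!zero]
  if (any(zero)) agg[zero, ] <- 1 / ncol(X)
  colnames(agg) <- colnames(X)
  list(masks = masks, importance = agg)
}
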