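# Fully connected neural-network comparator.
#
# A five-layer perceptron (input, three hidden layers, scalar output) mapping
# the eight impedance feature parameters to one intrinsic property, trained
# with mini-batch stochastic gradient descent on a mean-squared-error loss.
# One network is trained per target (C_sm, sigma_cyto, R_leak). Written in
# base R matrix code; the network is small enough that this trains in
# seconds. Serves as the data-driven baseline the physics-based solver is
# compared against: accurate in distribution, degrading under population
# shift.

FEATURE_COLS <- c("peak_amp_f1", "peak_phase_f1", "peak_amp_f2", "peak_phase_f2",
                  "base_amp_f1", "base_phase_f1", "base_amp_f2", "base_phase_f2")

#' FCNN configuration
#'
#' Five layers in total: the 8-feature input, three hidden layers and a
#' scalar output. Loss is mean squared error, optimised by mini-batch
#' stochastic gradient descent.
#'
#' @param hidden Sizes of the three hidden layers.
#' @param lr Learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 50).
#' @param momentum SGD momentum coefficient.
#' @param val_fraction Fraction of the training set held out for the logged
#'   validation loss (seeded shuffle).
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @return An object of class `"fcnn_config"`.
#' @export
fcnn_config <- function(hidden = c(64L, 64L, 64L), lr = 1e-3, batch_size = 32L,
                        epochs = 50L, momentum = 0.9, val_fraction = 0.1,
                        seed = 1L) {
  stopifnot(length(hidden) == 3, all(hidden >= 1), lr > 0, batch_size >= 1,
            epochs >= 1, momentum >= 0, momentum < 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(hidden = as.integer(hidden), lr = lr,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 momentum = momentum, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "fcnn_config")
}

relu <- function(x) x * (x > 0)

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    # He initialisation for ReLU layers
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                 sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

mlp_forward <- function(net, X) {
  acts <- list(X)
  a <- X
  for (l in seq_along(net)) {
    z <- a %*% net[[l]]$W + rep(net[[l]]$b, each = nrow(a))
    a <- if (l < length(net)) relu(z) else z
    acts[[l + 1L]] <- a
  }
  acts
}

# one SGD(+momentum) step on a mini-batch; returns updated net and velocity
mlp_step <- function(net, vel, X, y, lr, momentum) {
  acts <- mlp_forward(net, X)
  m <- nrow(X)
  delta <- 2 * (acts[[length(acts)]] - y) / m      # d(MSE)/d(output)
  for (l in rev(seq_along(net))) {
    gW <- crossprod(acts[[l]], delta)
    gb <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net[[l]]$W)) * (acts[[l]] > 0)
    }
    vel[[l]]$W <- momentum * vel[[l]]$W - lr * gW
    vel[[l]]$b <- momentum * vel[[l]]$b - lr * gb
    net[[l]]$W <- net[[l]]$W + vel[[l]]$W
    net[[l]]$b <- net[[l]]$b + vel[[l]]$b
  }
  list(net = net, vel = vel)
}

train_one_net <- function(X, y, cfg, seed) {
  with_seed(seed, {
    n <- nrow(X)
    n_val <- floor(cfg$val_fraction * n)
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    sizes <- c(ncol(X), cfg$hidden, 1L)
    net <- mlp_init(sizes)
    vel <- lapply(net, function(l) list(W = 0 * l$W, b = 0 * l$b))
    loss <- matrix(NA_real_, cfg$epochs, 2,
                   dimnames = list(NULL, c("train", "val")))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (s in seq(1, nrow(Xtr), by = cfg$batch_size)) {
        b <- ord[s:min(s + cfg$batch_size - 1L, nrow(Xtr))]
        st <- mlp_step(net, vel, Xtr[b, , drop = FALSE],
                       matrix(ytr[b]), cfg$lr, cfg$momentum)
        net <- st$net; vel <- st$vel
      }
      pred_tr <- mlp_forward(net, Xtr)[[length(net) + 1L]]
      loss[ep, "train"] <- mean((pred_tr - ytr)^2)
      if (length(val_idx))
        loss[ep, "val"] <- mean((mlp_forward(net, X[val_idx, , drop = FALSE])[[
          length(net) + 1L]] - y[val_idx])^2)
      if (!is.finite(loss[ep, "train"]))
        stop(sprintf("non-finite training loss at epoch %d (lr too high?)", ep))
    }
    list(net = net, loss = loss)
  })
}

#' Train the FCNN predictor on solver-labelled cells
#'
#' Trains three independent networks of identical structure, one per target
#' (`C_sm`, `sigma_cyto`, `R_leak`), on the eight impedance feature
#' parameters. Labels are the output of the physics-based solver on the same
#' events (the solver plays the role of ground truth). Features and targets
#' are z-score standardised with training-set statistics; predictions are
#' returned in original units. Fully reproducible from the config seed.
#'
#' @param features Feature data.frame (the eight columns of
#'   [detect_cells()] output).
#' @param labels Data.frame with columns `C_sm`, `sigma_cyto`, `R_leak`
#'   (solver output), one row per feature row.
#' @param config An [fcnn_config()].
#' @return An object of class `"ifc_fcnn"`: per-target networks, loss
#'   histories, standardisation statistics and the config.
#' @export
fcnn_train <- function(features, labels, config = fcnn_config()) {
  stopifnot(all(FEATURE_COLS %in% names(features)),
            all(c("C_sm", "sigma_cyto", "R_leak") %in% names(labels)),
            nrow(features) == nrow(labels))
  if (nrow(features) < config$batch_size)
    stop("need at least one full batch of labelled examples")
  X <- as.matrix(features[, FEATURE_COLS])
  if (any(!is.finite(X))) stop("non-finite feature values")
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[x_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  targets <- c("C_sm", "sigma_cyto", "R_leak")
  nets <- list()
  for (ti in seq_along(targets)) {
    y <- labels[[targets[ti]]]
    y_mean <- mean(y); y_sd <- stats::sd(y)
    if (y_sd == 0) y_sd <- 1
    fit <- train_one_net(Xs, (y - y_mean) / y_sd, config,
                         seed = config$seed + ti)
    nets[[targets[ti]]] <- c(fit, list(y_mean = y_mean, y_sd = y_sd))
  }
  structure(list(nets = nets, x_mean = x_mean, x_sd = x_sd, config = config,
                 n_train = nrow(features)),
            class = "ifc_fcnn")
}

#' Predict intrinsic properties with a trained FCNN
#'
#' Deterministic, order-preserving forward pass of the three networks.
#' Feature rows with non-finite entries yield `NA` predictions rather than
#' aborting the batch.
#'
#' @param object An `"ifc_fcnn"` from [fcnn_train()].
#' @param features Feature data.frame with the eight impedance columns.
#' @param ... Unused.
#' @return Data.frame with columns `C_sm`, `sigma_cyto`, `R_leak` in
#'   original units, one row per input row.
#' @export
predict.ifc_fcnn <- function(object, features, ...) {
  X <- as.matrix(features[, FEATURE_COLS])
  bad <- !is.finite(rowSums(X))
  X[bad, ] <- 0
  Xs <- sweep(sweep(X, 2, object$x_mean), 2, object$x_sd, "/")
  out <- lapply(object$nets, function(nt) {
    p <- mlp_forward(nt$net, Xs)[[length(nt$net) + 1L]]
    p <- as.vector(p) * nt$y_sd + nt$y_mean
    p[bad] <- NA_real_
    p
  })
  as.data.frame(out)
}

#' @export
print.ifc_fcnn <- function(x, ...) {
  cat(sprintf("FCNN predictor: 8 -> %s -> 1 per target, trained on %d cells\n",
              paste(x$config$hidden, collapse = " -> "), x$n_train))
  fin <- vapply(x$nets, function(nt) nt$loss[nrow(nt$loss), "train"], numeric(1))
  cat("  final training MSE (standardised units):",
      paste(sprintf("%s %.3g", names(fin), fin), collapse = ", "), "\n")
  invisible(x)
}

#' Plot FCNN loss curves
#'
#' @param x An `"ifc_fcnn"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ifc_fcnn <- function(x, ...) {
  L <- vapply(x$nets, function(nt) nt$loss[, "train"],
              numeric(nrow(x$nets[[1]]$loss)))
  graphics::matplot(L, type = "l", lty = 1, log = "y",
                    xlab = "epoch", ylab = "training MSE (standardised)", ...)
  graphics::legend("topright", colnames(L), lty = 1, col = seq_len(ncol(L)))
  invisible(x)
}
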