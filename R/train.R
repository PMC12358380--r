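# Parameter-tree utilities: the model parameters are a nested list whose
# leaves are numeric vectors/matrices. Flattening to a single vector powers
# the Adam update, gradient clipping and finite-difference checks.

flatten_params <- function(par) unlist(par, use.names = FALSE)

relist_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      lapply(x, walk)
    } else {
      n <- length(x)
      v <- vec[pos + seq_len(n)]
      pos <<- pos + n
      if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
    }
  }
  walk(skeleton)
}


# Teacher-forced loss (and optionally gradients) of one trajectory:
# predictions at t+1 are made from the OBSERVED state at t; the loss is the
# mean squared error over the (T-1) x N prediction grid. Dropout (inverted,
# on the graph-stage output) is applied when `dropout > 0`, drawing masks
# from the current RNG stream. Gradients come back both as a flat vector
# (`gflat`, optimization path) and relisted to the parameter tree
# (`grads`).
forecaster_traj_grad <- function(model, traj, dropout = 0,
                                 want_grad = TRUE) {
  states <- traj$states
  inputs <- traj$inputs
  T_ <- nrow(states)
  if (T_ < 2L) stop("trajectory must have at least two rows", call. = FALSE)
  N <- model$n_glands
  ctx <- forecaster_compile(model)
  carry <- zero_carry(model)
  caches <- if (want_grad) vector("list", T_ - 1L)
  preds <- matrix(0, T_ - 1L, N)
  for (t in seq_len(T_ - 1L)) {
    mask <- if (dropout > 0)
      matrix((stats::runif(N * model$d) >= dropout) / (1 - dropout),
             N, model$d)
    cc <- forecaster_step_cached(model, states[t, ], inputs[t, ], carry,
                                 drop_mask = mask, ctx = ctx)
    carry <- cc$carry
    preds[t, ] <- cc$pred
    if (want_grad) caches[[t]] <- cc
  }
  targets <- states[-1L, , drop = FALSE]
  loss <- mean((preds - targets)^2)
  if (!want_grad) return(list(loss = loss, preds = preds))

  scale <- 2 / ((T_ - 1L) * N)
  gflat <- numeric(length(flatten_params(model$par)))
  dH <- matrix(0, N, model$d_hidden)
  dC <- matrix(0, N, model$d_hidden)
  for (t in rev(seq_len(T_ - 1L))) {
    dpred <- scale * (preds[t, ] - targets[t, ])
    bk <- forecaster_step_backward(model, caches[[t]], dpred, dH, dC,
                                   ctx = ctx)
    gflat <- gflat + unlist(bk$grads, use.names = FALSE)
    dH <- bk$dHprev
    dC <- bk$dCprev
  }
  list(loss = loss, preds = preds, gflat = gflat)
}

#' Training configuration
#'
#' Optimization defaults for the forecaster: adaptive-moment (Adam) updates
#' from an initial learning rate of 5e-4 decayed by a factor 0.85 every 10
#' epochs, up to 150 epochs with early stopping after 15 epochs without
#' validation improvement, mini-batches of 32 trajectories, dropout 0.4 on
#' the graph-stage outputs, a 70/15/15 train/validation/test split, gradient
#' clipping at global norm 5, and a fixed seed of 42.
#'
#' @param learning_rate initial Adam step size.
#' @param lr_decay multiplicative decay factor.
#' @param lr_decay_every epochs between decays.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs).
#' @param batch_size trajectories per mini-batch.
#' @param dropout dropout rate on graph-stage outputs, in `[0, 1)`.
#' @param seed RNG seed governing split, shuffling and dropout.
#' @param split percentage split `c(train, validation, test)` summing to 100.
#' @param clip_norm global gradient-norm clip.
#' @param window optional fixed window length (in transitions): each
#'   training trajectory is cut into non-overlapping windows of this many
#'   one-step transitions, and mini-batches draw `batch_size` windows. This
#'   mirrors the fixed-length-window protocol common for recurrent
#'   sequence training and multiplies the number of adaptive-moment updates
#'   per epoch at small trajectory counts. `NULL` (default) trains on whole
#'   trajectories. Validation always uses whole trajectories.
#' @return an object of class `"training_config"`.
#' @export
training_config <- function(learning_rate = 5e-4, lr_decay = 0.85,
                            lr_decay_every = 10L, max_epochs = 150L,
                            patience = 15L, batch_size = 32L,
                            dropout = 0.4, seed = 42L,
                            split = c(70, 15, 15), clip_norm = 5,
                            window = NULL) {
  stopifnot(learning_rate > 0, lr_decay > 0, lr_decay_every >= 1,
            max_epochs >= 0, patience >= 1, batch_size >= 1,
            dropout >= 0, dropout < 1, clip_norm > 0,
            is.null(window) || window >= 2)
  if (length(split) != 3L || abs(sum(split) - 100) > 1e-9)
    stop("split must be three percentages summing to 100", call. = FALSE)
  structure(list(learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 seed = as.integer(seed), split = split,
                 clip_norm = clip_norm,
                 window = if (!is.null(window)) as.integer(window)),
            class = "training_config")
}

# Deterministic train/validation/test index split.
split_dataset <- function(n, split, seed) {
  idx <- with_local_seed(seed, sample.int(n))
  n_train <- max(1L, floor(n * split[1] / 100))
  n_val <- max(1L, floor(n * split[2] / 100))
  if (n_train + n_val >= n) {
    n_train <- max(1L, n - 2L)
    n_val <- 1L
  }
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[-seq_len(n_train + n_val)])
}

#' Train a forecaster
#'
#' Teacher-forced one-step-ahead training of a [forecaster_init()] model by
#' mini-batch adaptive-moment gradient descent on the mean squared error,
#' with learning-rate decay, global gradient clipping, early stopping on the
#' validation loss and restoration of the best-validation parameters. Fully
#' deterministic given `config$seed`.
#'
#' @param model a [forecaster_init()] model.
#' @param dataset list of [hormone_trajectory()] objects (`>= 2`).
#' @param config a [training_config()].
#' @return `list(model, history, split)`: the fitted model, a per-epoch
#'   data frame of learning rate and train/validation losses, and the index
#'   split used.
#' @export
train_forecaster <- function(model, dataset, config = training_config()) {
  if (!is.list(dataset) || length(dataset) < 2L)
    stop("dataset must contain at least two trajectories", call. = FALSE)
  sp <- split_dataset(length(dataset), config$split, config$seed)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train = numeric(), val = numeric())
  if (config$max_epochs == 0L)
    return(list(model = model, history = history, split = sp))

  # training units: whole trajectories, or fixed-length windows of
  # `config$window` transitions cut from each training trajectory
  train_units <- if (is.null(config$window)) {
    dataset[sp$train]
  } else {
    w <- config$window
    unlist(lapply(sp$train, function(i) {
      traj <- dataset[[i]]
      T_ <- nrow(traj$states)
      starts <- seq(1L, max(T_ - w, 1L), by = w)
      lapply(starts, function(s) {
        rows <- s:min(s + w, T_)
        list(states = traj$states[rows, , drop = FALSE],
             inputs = traj$inputs[rows, , drop = FALSE])
      })
    }), recursive = FALSE)
  }

  skeleton <- model$par
  theta <- flatten_params(skeleton)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step_count <- 0L
  best_val <- Inf
  best_theta <- theta
  stall <- 0L

  val_loss <- function() {
    mean(vapply(sp$val, function(i)
      forecaster_traj_grad(model, dataset[[i]], dropout = 0,
                           want_grad = FALSE)$loss, numeric(1)))
  }

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$learning_rate *
        config$lr_decay^((epoch - 1L) %/% config$lr_decay_every)
      order <- sample.int(length(train_units))
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      epoch_losses <- numeric(0)
      for (batch in batches) {
        gsum <- numeric(length(theta))
        lsum <- 0
        for (i in batch) {
          res <- forecaster_traj_grad(model, train_units[[i]],
                                      dropout = config$dropout)
          gsum <- gsum + res$gflat
          lsum <- lsum + res$loss
        }
        g <- gsum / length(batch)
        lbatch <- lsum / length(batch)
        if (!is.finite(lbatch))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        gn <- sqrt(sum(g^2))
        if (gn > config$clip_norm) g <- g * (config$clip_norm / gn)
        step_count <- step_count + 1L
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mhat <- m / (1 - beta1^step_count)
        vhat <- v / (1 - beta2^step_count)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
        model$par <- relist_params(theta, skeleton)
        epoch_losses <- c(epoch_losses, lbatch)
      }
      vl <- val_loss()
      history <- rbind(history,
                       data.frame(epoch = epoch, lr = lr,
                                  train = mean(epoch_losses), val = vl))
      if (vl < best_val - 1e-12) {
        best_val <- vl
        best_theta <- theta
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  model$par <- relist_params(best_theta, skeleton)
  list(model = model, history = history, split = sp)
}
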