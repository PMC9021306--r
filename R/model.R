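# User-facing model interface: configuration, network construction,
# training (Adam, mean squared error), and prediction, in single-channel
# and paired two-channel (+ baseline glucose) form.

#' Configuration of the 1-D CNN glucose regressor
#'
#' The reference architecture is five convolution units (kernel length 3,
#' same padding, ReLU, max-pooling of size 2) with 256, 256, 512, 1024 and
#' 2048 filters, a flatten step, an optional merge of the preceding
#' round's measured glucose as one extra scalar input (two-channel, paired
#' mode only), batch normalization, a ReLU dense layer and a linear output
#' unit; mean squared error loss with the Adam optimizer. At full scale
#' this has roughly one hundred million trainable parameters; `scale`
#' divides all filter counts and the dense width so the same architecture
#' runs on a desktop CPU in seconds.
#'
#' @param channels 1 (single round) or 2 (paired adjacent rounds).
#' @param conv_filters Filter counts of the five convolution units at full
#'   scale.
#' @param kernel_len Convolution kernel length in samples (default 3).
#' @param pool_size Max-pooling size (default 2).
#' @param dense_width Width of the hidden dense layer at full scale
#'   (default 4096).
#' @param epochs Training epochs (default 30, at most 1000).
#' @param batch_size Mini-batch size (default 3000, capped at the sample
#'   count during training).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param scale Integer divisor applied to `conv_filters` and
#'   `dense_width` for desk-scale runs (default 1 = full scale).
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling.
#' @param use_baseline_bgl Merge the preceding round's measured glucose
#'   after the flatten step; defaults to `TRUE` iff `channels == 2`.
#' @param baseline_scale Multiplier applied to the baseline glucose before
#'   the merge (default 1, i.e. raw mg/dl; set 0.01 to condition it).
#' @param target_scaling Standardize the regression target to zero mean
#'   and unit variance during training and invert at prediction (default
#'   `TRUE`); affects conditioning only, not the reported scale.
#' @param input_len Length of each input vector (default 406).
#' @return An object of class `model_config`. The effective (scaled)
#'   filter counts and dense width are stored as `filters_eff` and
#'   `dense_eff`.
#' @export
model_config <- function(channels = 1, conv_filters = c(256, 256, 512, 1024, 2048),
                         kernel_len = 3, pool_size = 2, dense_width = 4096,
                         epochs = 30, batch_size = 3000,
                         learning_rate = 1e-3, scale = 1, seed = 1L,
                         use_baseline_bgl = (channels == 2),
                         baseline_scale = 1, target_scaling = TRUE,
                         input_len = 406) {
  stopifnot(channels %in% c(1, 2), scale >= 1, epochs >= 1, epochs <= 1000,
            batch_size >= 1, learning_rate > 0, kernel_len >= 1,
            pool_size == 2, input_len >= 2^length(conv_filters),
            all(conv_filters >= 1), dense_width >= 1)
  if (use_baseline_bgl && channels != 2)
    stop("baseline glucose merge requires the paired two-channel input")
  structure(list(
    channels = as.integer(channels), conv_filters = conv_filters,
    kernel_len = as.integer(kernel_len), pool_size = as.integer(pool_size),
    dense_width = dense_width, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    scale = scale, seed = as.integer(seed),
    use_baseline_bgl = use_baseline_bgl, baseline_scale = baseline_scale,
    target_scaling = target_scaling, input_len = as.integer(input_len),
    filters_eff = pmax(1L, as.integer(round(conv_filters / scale))),
    dense_eff = max(1L, as.integer(round(dense_width / scale)))
  ), class = "model_config")
}

#' Trainable parameter count of a configuration
#'
#' Computed analytically from the configuration without allocating any
#' weights, so the full-scale architecture can be audited cheaply.
#'
#' @param config A [model_config()].
#' @return Total number of trainable parameters (convolution and dense
#'   weights and biases, batch-norm scale and shift).
#' @export
count_params <- function(config) {
  stopifnot(inherits(config, "model_config"))
  total <- 0
  c_in <- config$channels
  len <- config$input_len
  for (f in config$filters_eff) {
    total <- total + config$kernel_len * c_in * f + f
    c_in <- f
    len <- len %/% config$pool_size
  }
  flat <- len * c_in + as.integer(config$use_baseline_bgl)
  total <- total + 2 * flat                       # batch-norm gamma, beta
  total <- total + flat * config$dense_eff + config$dense_eff
  total + config$dense_eff + 1
}

#' Build an untrained network
#'
#' Allocates He-initialized weights for the architecture described by the
#' configuration. Initialization is deterministic given `config$seed`.
#'
#' @param config A [model_config()].
#' @return An object of class `dc_network` holding the layer weights, the
#'   Adam state, and an empty training history.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  layers <- list()
  c_in <- config$channels
  len <- config$input_len
  for (f in config$filters_eff) {
    fan_in <- config$kernel_len * c_in
    layers[[length(layers) + 1]] <- list(
      type = "conv",
      W = matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f),
      b = numeric(f))
    c_in <- f
    len <- len %/% config$pool_size
  }
  flat <- len * c_in + as.integer(config$use_baseline_bgl)
  layers[[length(layers) + 1]] <- list(
    type = "bn", gamma = rep(1, flat), beta = numeric(flat),
    running_mean = numeric(flat), running_var = rep(1, flat))
  layers[[length(layers) + 1]] <- list(
    type = "dense",
    W = matrix(stats::rnorm(flat * config$dense_eff, 0, sqrt(2 / flat)),
               flat, config$dense_eff),
    b = numeric(config$dense_eff))
  layers[[length(layers) + 1]] <- list(
    type = "dense",
    W = matrix(stats::rnorm(config$dense_eff, 0, sqrt(2 / config$dense_eff)),
               config$dense_eff, 1),
    b = 0)
  opt <- lapply(layers, function(ly) {
    ps <- intersect(names(ly), c("W", "b", "gamma", "beta"))
    stats::setNames(lapply(ps, function(p) list(m = 0, v = 0)), ps)
  })
  structure(list(config = config, layers = layers, opt = opt, t = 0L,
                 train_calls = 0L, y_center = 0, y_scale = 1,
                 history = data.frame()),
            class = "dc_network")
}

#' @export
print.dc_network <- function(x, ...) {
  cat(sprintf("<dc_network> %d-channel, filters %s, dense %d, %s params, trained %d epochs\n",
              x$config$channels,
              paste(x$config$filters_eff, collapse = "/"),
              x$config$dense_eff,
              format(count_params(x$config), big.mark = ","),
              nrow(x$history)))
  invisible(x)
}

# Stack a sample_set into the (n, L, C) input array + baseline + target.
.samples_to_arrays <- function(net, samples) {
  cfg <- net$config
  x_now <- samples$x_now
  n <- nrow(x_now)
  if (is.null(n) || n == 0) stop("sample set is empty")
  if (ncol(x_now) != cfg$input_len)
    stop("input vectors have length ", ncol(x_now), ", expected ",
         cfg$input_len)
  x <- array(0, c(n, cfg$input_len, cfg$channels))
  x[, , 1] <- x_now
  if (cfg$channels == 2) {
    if (is.null(samples$x_prev))
      stop("two-channel model requires paired samples (x_prev)")
    x[, , 2] <- samples$x_prev
  }
  if (any(!is.finite(x))) stop("non-finite values in model input")
  list(x = x, baseline = samples$baseline, y = samples$target, n = n)
}

#' Train a network on a sample set
#'
#' Runs mini-batch gradient descent with Adam on the mean squared error
#' between predicted and reference glucose, for `epochs` epochs (taken
#' from the configuration unless overridden). Training is deterministic
#' for a fixed seed on one CPU. Calling `train_model()` again on the same
#' network continues from the current weights, which is how accumulated
#' multi-round training is expressed.
#'
#' @param net A [build_network()] result (or an already trained network).
#' @param samples A `sample_set` ([build_il_samples()],
#'   [build_dl_samples()], [concat_samples()]).
#' @param epochs Number of epochs; defaults to the configuration value.
#' @param val_samples Optional held-out `sample_set`; its loss is recorded
#'   per epoch in the history.
#' @return The trained network, with `history` extended by one row per
#'   epoch (`epoch`, `train_loss`, optionally `val_loss`; losses in
#'   (mg/dl)^2 on the original scale).
#' @export
train_model <- function(net, samples, epochs = NULL,
                        val_samples = NULL) {
  stopifnot(inherits(net, "dc_network"))
  cfg <- net$config
  if (is.null(epochs)) epochs <- cfg$epochs
  dat <- .samples_to_arrays(net, samples)
  if (any(!is.finite(dat$y))) stop("non-finite regression targets")

  if (cfg$target_scaling && net$train_calls == 0L) {
    net$y_center <- mean(dat$y)
    net$y_scale <- stats::sd(dat$y)
    if (!is.finite(net$y_scale) || net$y_scale <= 0) net$y_scale <- 1
  }
  y <- (dat$y - net$y_center) / net$y_scale

  set.seed(cfg$seed + 7919L * net$train_calls)
  net$train_calls <- net$train_calls + 1L
  bs <- min(cfg$batch_size, dat$n)
  momentum <- 0.1

  for (e in seq_len(epochs)) {
    ord <- sample.int(dat$n)
    starts <- seq(1, dat$n, by = bs)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1, dat$n)]
      xb <- dat$x[idx, , , drop = FALSE]
      bb <- if (!is.null(dat$baseline)) dat$baseline[idx]
      fw <- .nn_forward(net, xb, bb, training = TRUE)
      err <- fw$pred - y[idx]
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", e)
      ep_loss <- ep_loss + loss * length(idx)
      # update batch-norm running statistics
      bni <- length(cfg$filters_eff) + 1L
      net$layers[[bni]]$running_mean <-
        (1 - momentum) * net$layers[[bni]]$running_mean + momentum * fw$bn$mu
      net$layers[[bni]]$running_var <-
        (1 - momentum) * net$layers[[bni]]$running_var + momentum * fw$bn$v
      grads <- .nn_backward(net, fw, 2 * err / length(idx))
      net <- .adam_step(net, grads, cfg$learning_rate)
    }
    row <- data.frame(epoch = nrow(net$history) + 1L,
                      train_loss = ep_loss / dat$n * net$y_scale^2)
    if (!is.null(val_samples)) {
      vp <- predict_model(net, val_samples)
      row$val_loss <- mean((vp - val_samples$target)^2)
    }
    net$history <- rbind(net$history, row)
  }
  net
}

#' Predict glucose for a sample set
#'
#' Side-effect-free forward pass using the stored batch-norm running
#' statistics; returns one prediction (mg/dl) per sample.
#'
#' @param net A trained `dc_network`.
#' @param samples A `sample_set`.
#' @return Numeric vector of predicted glucose values in mg/dl.
#' @export
predict_model <- function(net, samples) {
  stopifnot(inherits(net, "dc_network"))
  dat <- .samples_to_arrays(net, samples)
  fw <- .nn_forward(net, dat$x, dat$baseline, training = FALSE)
  fw$pred * net$y_scale + net$y_center
}

#' Aggregate per-window predictions into one replicate prediction
#'
#' A replicate's recording yields many windows, hence many per-window
#' predictions; the replicate-level prediction is their median, which is
#' robust to occasional outlier windows and invariant to sample order.
#'
#' @param net A trained `dc_network`.
#' @param samples `sample_set` holding the windows of one (round,
#'   replicate); must be non-empty.
#' @return A single predicted glucose value in mg/dl.
#' @export
predict_replicate <- function(net, samples) {
  if (length(samples$target) == 0) stop("no samples for this replicate")
  stats::median(predict_model(net, samples))
}
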