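# Q-network: fully connected ReLU network with per-layer dropout, written as
# plain matrix algebra with manual backpropagation and an Adam optimizer.
# Default geometry is input 128 -> 512 -> 256 -> 128 -> |A| with dropout
# (0.3, 0.4, 0.3) on the hidden layers; desk-scale runs use a reduced spec.

#' Q-network architecture specification
#'
#' @param input_dim Width the state vector is zero-padded (or truncated) to.
#' @param hidden_dims Integer vector of hidden-layer widths.
#' @param dropout_rates Per-hidden-layer dropout rates (same length as
#'   `hidden_dims`).
#' @param output_dim Number of actions `|A|`.
#' @return A list of class `network_spec`.
#' @examples
#' network_spec(output_dim = 60)
#' @export
network_spec <- function(input_dim = 128L,
                         hidden_dims = c(512L, 256L, 128L),
                         dropout_rates = c(0.3, 0.4, 0.3),
                         output_dim = 60L) {
  if (length(dropout_rates) != length(hidden_dims)) {
    abort("`dropout_rates` must match `hidden_dims` in length",
          class = "loadctrl_config_error")
  }
  if (any(c(input_dim, hidden_dims, output_dim) <= 0)) {
    abort("all network dimensions must be positive", class = "loadctrl_config_error")
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 dropout_rates = as.numeric(dropout_rates),
                 output_dim = as.integer(output_dim)),
            class = "network_spec")
}

#' Reduced desk-scale network specification
#'
#' A small Q-network (input 32, hidden 64/32, light dropout) for laptop-scale
#' experiments and calibration runs.
#'
#' @param output_dim Number of actions.
#' @return A `network_spec`.
#' @export
reduced_network_spec <- function(output_dim = 60L) {
  network_spec(input_dim = 32L, hidden_dims = c(64L, 32L),
               dropout_rates = c(0.1, 0.1), output_dim = output_dim)
}

layer_dims <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_dims, spec$output_dim)
  list(ins = dims[-length(dims)], outs = dims[-1])
}

#' Number of trainable parameters of a network spec
#'
#' Sum over dense layers of `(fan_in + 1) * fan_out` (weights plus biases).
#'
#' @param spec A [network_spec()].
#' @return Integer parameter count.
#' @export
network_n_params <- function(spec) {
  d <- layer_dims(spec)
  sum((d$ins + 1L) * d$outs)
}

#' Initialize network parameters
#'
#' He-scaled Gaussian weights, zero biases, drawn from `stream`.
#'
#' @param spec A [network_spec()].
#' @param stream An [rng_stream()].
#' @return A list of `(W, b)` layers of class `network_params`.
#' @export
network_init <- function(spec, stream) {
  d <- layer_dims(spec)
  params <- purrr::map2(d$ins, d$outs, function(fi, fo) {
    W <- with_stream(stream,
                     matrix(rnorm(fi * fo, sd = sqrt(2 / fi)), fi, fo))
    list(W = W, b = numeric(fo))
  })
  structure(params, class = "network_params")
}

# Forward pass. X: n x input_dim matrix. mode "train" applies inverted
# dropout using masks drawn from `stream`; "eval" is deterministic.
mlp_forward <- function(spec, params, X, mode = c("eval", "train"),
                        stream = NULL) {
  mode <- match.arg(mode)
  n_hidden <- length(spec$hidden_dims)
  acts <- list(X)            # acts[[l]] is the input to layer l
  masks <- vector("list", n_hidden)
  H <- X
  n <- nrow(X)
  for (l in seq_along(params)) {
    Z <- H %*% params[[l]]$W
    Z <- Z + rep(params[[l]]$b, each = n)   # add bias by column
    if (l <= n_hidden) {
      H <- pmax(Z, 0)
      rate <- spec$dropout_rates[l]
      if (mode == "train" && rate > 0) {
        keep <- 1 - rate
        m <- with_stream(stream,
                         matrix(rbinom(length(H), 1, keep), nrow(H), ncol(H))) / keep
        H <- H * m
        masks[[l]] <- m
      }
      acts[[l + 1]] <- H
    } else {
      H <- Z               # linear output layer
    }
  }
  list(out = H, acts = acts, masks = masks)
}

# Backward pass for the squared-error head. dOut: n x output_dim gradient of
# the loss w.r.t. the network output. Returns per-layer gradients.
mlp_backward <- function(spec, params, cache, dOut) {
  n_hidden <- length(spec$hidden_dims)
  grads <- vector("list", length(params))
  delta <- dOut
  for (l in rev(seq_along(params))) {
    A_in <- cache$acts[[l]]
    grads[[l]] <- list(W = crossprod(A_in, delta), b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(params[[l]]$W)
      prev <- cache$acts[[l]]        # post-activation of layer l-1
      if (!is.null(cache$masks[[l - 1]])) delta <- delta * cache$masks[[l - 1]]
      delta <- delta * (prev > 0)
    }
  }
  grads
}

#' Q-value forward pass for one state or a batch
#'
#' Pads (or truncates) state features to the spec's input width, then runs the
#' network. Dropout is active only in `"train"` mode; `"eval"` mode is
#' deterministic.
#'
#' @param spec A [network_spec()].
#' @param params A `network_params` list.
#' @param state An `env_state`, a numeric feature vector, or a matrix with one
#'   state per row.
#' @param mode `"eval"` or `"train"`.
#' @param stream [rng_stream()] for dropout masks (train mode).
#' @return A list with `q` (matrix n x |A|) and `greedy` (integer vector of
#'   argmax actions, lowest index on ties).
#' @export
q_forward <- function(spec, params, state, mode = c("eval", "train"),
                      stream = NULL) {
  mode <- match.arg(mode)
  X <- states_to_matrix(state, spec$input_dim)
  fw <- mlp_forward(spec, params, X, mode = mode, stream = stream)
  greedy <- max.col(fw$out, ties.method = "first")
  list(q = fw$out, greedy = as.integer(greedy))
}

states_to_matrix <- function(state, input_dim) {
  feat <- if (inherits(state, "env_state")) matrix(state$features, 1)
  else if (is.matrix(state)) state
  else matrix(as.numeric(state), 1)
  if (ncol(feat) > input_dim) {
    feat <- feat[, seq_len(input_dim), drop = FALSE]
  } else if (ncol(feat) < input_dim) {
    feat <- cbind(feat, matrix(0, nrow(feat), input_dim - ncol(feat)))
  }
  feat
}

# ---- parameter-vector helpers ----------------------------------------------

params_map2 <- function(a, b, f) {
  out <- purrr::map2(a, b, function(la, lb) list(W = f(la$W, lb$W), b = f(la$b, lb$b)))
  class(out) <- class(a)
  out
}

params_map <- function(a, f) {
  out <- purrr::map(a, function(la) list(W = f(la$W), b = f(la$b)))
  class(out) <- class(a)
  out
}

params_sqnorm <- function(params) {
  sum(vapply(params, function(l) sum(l$W^2) + sum(l$b^2), numeric(1)))
}

grad_global_norm <- function(grads) sqrt(params_sqnorm(grads))

#' Soft (Polyak) target-network update
#'
#' `target <- tau * main + (1 - tau) * target`, elementwise over every weight
#' and bias. With a frozen main network, `k` repeated updates give
#' `target = main * (1 - (1 - tau)^k) + target0 * (1 - tau)^k`.
#'
#' @param main_params,target_params `network_params` with matching shapes.
#' @param tau Blend factor in (0, 1].
#' @return Updated target parameters.
#' @examples
#' # scalar intuition: main = 1, target = 0, tau = 0.001 -> 0.001
#' @export
soft_update <- function(main_params, target_params, tau = 0.001) {
  check_range(tau, "tau", lo = 1e-12, hi = 1)
  if (length(main_params) != length(target_params)) {
    abort("parameter lists differ in length", class = "loadctrl_invalid_input")
  }
  for (l in seq_along(main_params)) {
    if (!identical(dim(main_params[[l]]$W), dim(target_params[[l]]$W))) {
      abort("parameter shapes do not match", class = "loadctrl_invalid_input")
    }
  }
  params_map2(main_params, target_params, function(m, t) tau * m + (1 - tau) * t)
}

# Adam optimizer -------------------------------------------------------------

adam_init <- function(params) {
  list(m = params_map(params, function(x) x * 0),
       v = params_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- params_map2(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- params_map2(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (l in seq_along(params)) {
    params[[l]]$W <- params[[l]]$W -
      lr * (opt$m[[l]]$W / bc1) / (sqrt(opt$v[[l]]$W / bc2) + eps)
    params[[l]]$b <- params[[l]]$b -
      lr * (opt$m[[l]]$b / bc1) / (sqrt(opt$v[[l]]$b / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- checkpoint serialization (plain JSON, text-only) -----------------------

#' Save a trained agent checkpoint as JSON
#'
#' @param agent A trained agent (see [train_agent()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(agent, path) {
  payload <- list(
    spec = unclass(agent$spec),
    params = purrr::map(agent$params, function(l) {
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load an agent checkpoint saved by [save_checkpoint()]
#'
#' @param path File path.
#' @return A list with `spec` and `params` usable with [q_forward()].
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, payload$spec)
  params <- purrr::map(seq_len(nrow_safe(payload$params)), function(l) {
    entry <- if (is.data.frame(payload$params)) payload$params[l, ] else payload$params[[l]]
    W <- matrix(unlist(entry$W), unlist(entry$dim)[1], unlist(entry$dim)[2])
    list(W = W, b = as.numeric(unlist(entry$b)))
  })
  class(params) <- "network_params"
  list(spec = spec, params = params)
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
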