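#' Bidirectional LSTM model configuration
#'
#' The classifier reshapes the flat feature vector into a short sequence,
#' runs one forward and one backward LSTM pass, concatenates the final
#' forward and initial backward hidden states and maps them through a
#' single linear output unit; a sigmoid turns the score into a malignancy
#' probability.
#'
#' @param feature_length Length of the input feature vector `E`.
#' @param hidden_size Hidden units per direction.
#' @param timesteps Number of sequence steps the feature vector is chunked
#'   into (row-wise, zero-padded).
#' @param threshold Decision threshold on the probability; ties (`p ==
#'   threshold`) are called malignant.
#' @param weight_bound Half-width `w_max` of the search box used when the
#'   parameters are tuned by the swarm optimizer.
#' @return An object of class `chstm_config`.
#' @export
chstm_config <- function(feature_length, hidden_size = 8L, timesteps = 8L,
                         threshold = 0.5, weight_bound = 2) {
  feature_length <- as.integer(feature_length)
  hidden_size <- as.integer(hidden_size)
  timesteps <- as.integer(timesteps)
  if (feature_length < 1L) stopf("feature_length must be >= 1")
  if (hidden_size < 1L || timesteps < 1L)
    stopf("hidden_size and timesteps must be >= 1")
  assert_scalar_num(threshold, "threshold", 0, 1)
  assert_scalar_num(weight_bound, "weight_bound", lower = .Machine$double.xmin)
  step_dim <- as.integer(ceiling(feature_length / timesteps))
  structure(list(feature_length = feature_length, hidden_size = hidden_size,
                 timesteps = timesteps, step_dim = step_dim,
                 threshold = threshold, weight_bound = weight_bound),
            class = "chstm_config")
}

#' Number of free parameters of the model
#'
#' Four gate blocks per direction, each mapping the concatenation
#' `[h_prev, x_t]` to the hidden size with a bias, plus the linear output
#' layer on the concatenated final states.
#'
#' @param config A [chstm_config()].
#' @return Integer parameter count.
#' @export
chstm_param_count <- function(config) {
  h <- config$hidden_size
  d <- config$step_dim
  per_gate <- h * (h + d) + h
  2L * 4L * per_gate + (2L * h + 1L)
}

# Fixed flattening layout: for each direction (forward, backward), gates in
# the order Q (forget), I (input), P (output), X (candidate), each as the
# weight matrix column-major then the bias; finally output weights and bias.
chstm_unflatten <- function(param_vector, config) {
  h <- config$hidden_size
  d <- config$step_dim
  np <- chstm_param_count(config)
  if (length(param_vector) != np)
    stopf("parameter vector has length %d, expected %d", length(param_vector), np)
  pos <- 0L
  take <- function(n) {
    out <- param_vector[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  direction <- function() {
    g <- lapply(1:4, function(.) {
      w <- matrix(take(h * (h + d)), h, h + d)
      b <- take(h)
      list(w = w, b = b)
    })
    names(g) <- c("Q", "I", "P", "X")
    g
  }
  fwd <- direction()
  bwd <- direction()
  w_out <- take(2L * h)
  b_out <- take(1L)
  list(forward = fwd, backward = bwd, w_out = w_out, b_out = b_out)
}

chstm_flatten <- function(params, config) {
  dir_vec <- function(g) unlist(lapply(g, function(p) c(as.numeric(p$w), p$b)))
  c(dir_vec(params$forward), dir_vec(params$backward),
    params$w_out, params$b_out)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' One LSTM cell step
#'
#' Computes the three sigmoid gates and the tanh candidate from the
#' concatenation `[h_prev, x_t]`, then
#' `c_t = Q_t * c_prev + I_t * X~_t` (element-wise) and
#' `h_t = P_t * tanh(c_t)`. `Q` acts as the forget gate (it multiplies the
#' previous cell state), `I` as the input gate and `P` as the output gate.
#'
#' @param x_t Input vector for this step.
#' @param h_prev,c_prev Previous hidden and cell state vectors.
#' @param gates One direction's gate list (elements `Q`, `I`, `P`, `X`,
#'   each with `w` and `b`).
#' @return List with `h` and `c`.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, gates) {
  z <- c(h_prev, x_t)
  q <- sigmoid(as.numeric(gates$Q$w %*% z) + gates$Q$b)
  i <- sigmoid(as.numeric(gates$I$w %*% z) + gates$I$b)
  p <- sigmoid(as.numeric(gates$P$w %*% z) + gates$P$b)
  xc <- tanh(as.numeric(gates$X$w %*% z) + gates$X$b)
  ct <- q * c_prev + i * xc
  if (any(!is.finite(ct))) stopf("numerical overflow in the cell state")
  list(h = p * tanh(ct), c = ct)
}

#' Encode a flat feature vector as a sequence
#'
#' Pads `E` with `pad` up to `timesteps * step_dim` values and chunks it
#' row-wise: step `t` holds elements
#' `E[(t-1) * step_dim + 1 : t * step_dim]`.
#'
#' @param E Numeric vector.
#' @param timesteps,step_dim Sequence geometry.
#' @param pad Padding value (default 0).
#' @return A `timesteps x step_dim` matrix, one row per step.
#' @export
encode_as_sequence <- function(E, timesteps, step_dim, pad = 0) {
  v <- as.numeric(E)
  total <- timesteps * step_dim
  if (length(v) > total)
    stopf("feature vector of length %d does not fit %d x %d", length(v),
          timesteps, step_dim)
  matrix(c(v, rep(pad, total - length(v))), timesteps, step_dim, byrow = TRUE)
}

#' Bidirectional forward computation
#'
#' Runs the forward direction left to right and the backward direction
#' right to left from zero initial states, concatenates the forward state
#' at the last step with the backward state at the first step, and applies
#' the linear output layer.
#'
#' @param sequence `T x step_dim` matrix (or list of step vectors).
#' @param params Parameter list from `chstm_unflatten()` (see
#'   [train_chstm()] for the usual entry point).
#' @return List with `score` (scalar), `hidden_forward` and
#'   `hidden_backward` (`T x hidden` matrices).
#' @export
bilstm_forward <- function(sequence, params) {
  if (is.list(sequence) && !is.matrix(sequence))
    sequence <- do.call(rbind, sequence)
  if (!is.matrix(sequence) || nrow(sequence) < 1L)
    stopf("sequence must be a non-empty matrix")
  tt <- nrow(sequence)
  h <- length(params$forward$Q$b)
  hf <- matrix(0, tt, h)
  hb <- matrix(0, tt, h)
  state <- list(h = numeric(h), c = numeric(h))
  for (t in seq_len(tt)) {
    state <- lstm_cell_step(sequence[t, ], state$h, state$c, params$forward)
    hf[t, ] <- state$h
  }
  state <- list(h = numeric(h), c = numeric(h))
  for (t in rev(seq_len(tt))) {
    state <- lstm_cell_step(sequence[t, ], state$h, state$c, params$backward)
    hb[t, ] <- state$h
  }
  s <- c(hf[tt, ], hb[1, ])
  list(score = sum(params$w_out * s) + params$b_out,
       hidden_forward = hf, hidden_backward = hb)
}

# Batched scores for a feature matrix (rows = samples); same arithmetic as
# bilstm_forward, vectorized across samples for training speed.
chstm_scores <- function(params, features, config) {
  n <- nrow(features)
  h <- config$hidden_size
  tt <- config$timesteps
  d <- config$step_dim
  total <- tt * d
  padded <- cbind(features, matrix(0, n, total - ncol(features)))
  step_mat <- function(t) padded[, ((t - 1L) * d + 1L):(t * d), drop = FALSE]
  run_dir <- function(gates, order) {
    hs <- matrix(0, n, h)
    cs <- matrix(0, n, h)
    first <- matrix(0, n, h)
    for (t in order) {
      z <- cbind(hs, step_mat(t))
      q <- sigmoid(z %*% t(gates$Q$w) + rep(gates$Q$b, each = n))
      i <- sigmoid(z %*% t(gates$I$w) + rep(gates$I$b, each = n))
      p <- sigmoid(z %*% t(gates$P$w) + rep(gates$P$b, each = n))
      xc <- tanh(z %*% t(gates$X$w) + rep(gates$X$b, each = n))
      cs <- q * cs + i * xc
      hs <- p * tanh(cs)
    }
    hs
  }
  hf_last <- run_dir(params$forward, seq_len(tt))
  hb_first <- run_dir(params$backward, rev(seq_len(tt)))
  as.numeric(cbind(hf_last, hb_first) %*% params$w_out + params$b_out)
}

#' Classify feature vectors
#'
#' @param model A `chstm_model` from [train_chstm()], or a list with
#'   `params`, `config` and optionally `center`/`scale` standardization.
#' @param features Numeric matrix (rows = samples) or one-row tibble /
#'   vector matching the model's feature length.
#' @return Tibble with `probability` and `label`
#'   (`"malignant"` iff `probability >= threshold`).
#' @export
chstm_predict <- function(model, features) {
  if (is.null(model$params)) stopf("model is not configured")
  if (inherits(features, "data.frame")) features <- as.matrix(features)
  if (is.vector(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$config$feature_length)
    stopf("feature length %d does not match model (%d)", ncol(features),
          model$config$feature_length)
  if (!is.null(model$center))
    features <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  p <- sigmoid(chstm_scores(model$params, features, model$config))
  tibble::tibble(probability = p,
                 label = ifelse(p >= model$config$threshold,
                                "malignant", "benign"))
}

#' Accuracy fitness of a flattened parameter candidate
#'
#' Unflattens the candidate into gate weights and biases, scores the given
#' set and returns the classification accuracy in \[0, 1\] — the quantity
#' the swarm optimizer maximizes during training.
#'
#' @param param_vector Flattened parameters (length
#'   [chstm_param_count()]).
#' @param features Numeric matrix of (already standardized) features.
#' @param labels Character or factor vector (`"benign"` / `"malignant"`).
#' @param config A [chstm_config()].
#' @return Accuracy in \[0, 1\].
#' @export
fitness_of_candidate <- function(param_vector, features, labels, config) {
  if (nrow(features) == 0L) stopf("empty evaluation set")
  params <- chstm_unflatten(param_vector, config)
  p <- sigmoid(chstm_scores(params, features, config))
  pred <- ifelse(p >= config$threshold, "malignant", "benign")
  mean(pred == as.character(labels))
}

#' Train the classifier with the cnidaria-herd optimizer
#'
#' Standardizes the features on the training portion of a seeded
#' stratified split, then lets [cho_optimize()] maximize the training
#' accuracy of the flattened gate parameters over the box
#' `[-w_max, w_max]^P`. No gradients are used anywhere. The held-out
#' portion is only evaluated once, on the returned best parameters.
#'
#' @param features Numeric matrix or tibble, one row per candidate region.
#' @param labels Vector of `"benign"` / `"malignant"` labels.
#' @param cho A [cho_config()] controlling the optimizer run.
#' @param model_config A [chstm_config()] (built from the data when
#'   `NULL`).
#' @param split Fraction of samples in the training portion.
#' @param seed Seed for the stratified split.
#' @return An object of class `chstm_model`: `params`, `config`, the
#'   standardization `center`/`scale`, `trace` (optimizer history),
#'   `train_accuracy`, `val_accuracy`, `val_baseline` (majority-class
#'   share of the held-out portion) and the index split.
#' @export
train_chstm <- function(features, labels,
                        cho = cho_config(pop_size = 20L, t_max = 50L),
                        model_config = NULL, split = 0.8, seed = 1L) {
  if (inherits(features, "data.frame")) features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stopf("features and labels are not aligned")
  if (length(unique(labels)) < 2L)
    stopf("degenerate labels: both classes must be present")
  if (is.null(model_config))
    model_config <- chstm_config(feature_length = ncol(features))

  idx <- with_seed(seed, {
    tr <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      n_tr <- max(1L, round(length(ix) * split))
      sample(ix, n_tr)
    }), use.names = FALSE)
    sort(tr)
  })
  val <- setdiff(seq_along(labels), idx)
  if (length(val) == 0L) stopf("split leaves no held-out samples")

  center <- colMeans(features[idx, , drop = FALSE])
  scale <- apply(features[idx, , drop = FALSE], 2, sd)
  scale[scale < 1e-12] <- 1
  std <- sweep(sweep(features, 2, center), 2, scale, "/")

  np <- chstm_param_count(model_config)
  b <- model_config$weight_bound
  bounds <- cho_bounds(rep(-b, np), rep(b, np))
  objective <- function(v)
    fitness_of_candidate(v, std[idx, , drop = FALSE], labels[idx], model_config)
  opt <- cho_optimize(objective, bounds, cho)

  params <- chstm_unflatten(opt$best_position, model_config)
  val_p <- sigmoid(chstm_scores(params, std[val, , drop = FALSE], model_config))
  val_pred <- ifelse(val_p >= model_config$threshold, "malignant", "benign")
  structure(list(params = params, config = model_config,
                 center = center, scale = scale,
                 param_vector = opt$best_position,
                 trace = opt$history,
                 train_accuracy = opt$best_fitness,
                 val_accuracy = mean(val_pred == labels[val]),
                 val_baseline = max(table(labels[val])) / length(val),
                 train_index = idx, val_index = val),
            class = "chstm_model")
}

#' @export
print.chstm_model <- function(x, ...) {
  cat("<chstm_model>\n")
  cat(sprintf("  hidden %d, %d steps of %d, %d parameters\n",
              x$config$hidden_size, x$config$timesteps, x$config$step_dim,
              chstm_param_count(x$config)))
  cat(sprintf("  train accuracy %.3f | held-out accuracy %.3f (baseline %.3f)\n",
              x$train_accuracy, x$val_accuracy, x$val_baseline))
  invisible(x)
}

#' Serialize / restore a trained model as JSON
#'
#' The schema stores the architecture and the flattened parameter vector;
#' it is versioned so later readers can detect layout changes.
#'
#' @param model A `chstm_model`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `read_chstm()` returns the restored model.
#' @export
write_chstm <- function(model, path) {
  stopifnot(inherits(model, "chstm_model"))
  obj <- list(schema = "nodulekit/chstm-model/1",
              config = unclass(model$config),
              center = model$center, scale = model$scale,
              param_vector = model$param_vector,
              train_accuracy = model$train_accuracy,
              val_accuracy = model$val_accuracy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chstm
#' @export
read_chstm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "nodulekit/chstm-model/1"))
    stopf("unrecognized model schema: %s", obj$schema %||% "<none>")
  cfg <- do.call(chstm_config, obj$config[c("feature_length", "hidden_size",
                                            "timesteps", "threshold",
                                            "weight_bound")])
  structure(list(params = chstm_unflatten(obj$param_vector, cfg),
                 config = cfg, center = obj$center, scale = obj$scale,
                 param_vector = obj$param_vector,
                 train_accuracy = obj$train_accuracy,
                 val_accuracy = obj$val_accuracy),
            class = "chstm_model")
}
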