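# broom-style tidiers and autoplot methods for the fitted objects

#' @export
tidy.cho_result <- function(x, ...) x$history

#' @export
glance.cho_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 iterations = x$config$t_max,
                 pop_size = x$config$pop_size,
                 evaluations = x$evaluations,
                 dimensions = x$bounds$dim)
}

#' @export
autoplot.cho_result <- function(object, ...) {
  ggplot(object$history, aes(x = .data$iteration)) +
    geom_line(aes(y = .data$best_fitness), linewidth = 0.7) +
    geom_line(aes(y = .data$mean_fitness), linetype = "dashed",
              colour = "grey50") +
    labs(x = "iteration", y = "fitness",
         title = "Swarm convergence (solid: elitist best, dashed: mean)") +
    theme_minimal()
}

#' @export
tidy.fcm_partition <- function(x, ...) {
  centers <- x$centers
  tibble::tibble(cluster = seq_len(nrow(centers)),
                 center = lapply(seq_len(nrow(centers)),
                                 function(i) centers[i, ]),
                 total_membership = colSums(x$memberships))
}

#' @export
glance.fcm_partition <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$memberships),
                 n_clusters = nrow(x$centers),
                 fuzzifier = x$config$fuzzifier,
                 iterations = x$iterations,
                 converged = x$converged,
                 objective = x$objective_history[length(x$objective_history)])
}

#' @export
autoplot.fcm_partition <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_history),
                       objective = object$objective_history)
  ggplot(df, aes(x = .data$iteration, y = .data$objective)) +
    geom_line() +
    labs(x = "iteration", y = "weighted squared error",
         title = "Fuzzy C-means objective") +
    theme_minimal()
}

#' @export
tidy.chstm_model <- function(x, ...) x$trace

#' @export
glance.chstm_model <- function(x, ...) {
  tibble::tibble(n_parameters = chstm_param_count(x$config),
                 hidden_size = x$config$hidden_size,
                 timesteps = x$config$timesteps,
                 train_accuracy = x$train_accuracy,
                 val_accuracy = x$val_accuracy,
                 val_baseline = x$val_baseline)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_sample

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(TP = x$counts["TP"], FP = x$counts["FP"],
                 TN = x$counts["TN"], FN = x$counts["FN"],
                 accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity)
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tibble::tibble(
    truth = c("malignant", "malignant", "benign", "benign"),
    predicted = c("malignant", "benign", "malignant", "benign"),
    n = as.numeric(object$counts[c("TP", "FN", "FP", "TN")]))
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    coord_equal() +
    labs(title = "Confusion matrix (malignant = positive)") +
    theme_minimal()
}

#' Plot a phantom sample
#'
#' Renders the slice with ggplot2; nodule outlines are overlaid from the
#' ground-truth masks.
#'
#' @param object A `phantom_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_sample <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$row, df$col)]
  gg <- ggplot(df, aes(x = .data$col, y = .data$row,
                       fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(option = "B") +
    coord_equal(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    labs(title = sprintf("Phantom (seed %d): %s", object$seed,
                         paste(object$labels, collapse = ", "))) +
    theme_minimal()
  gg
}
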