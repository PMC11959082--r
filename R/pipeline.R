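#' Pipeline configuration
#'
#' Nested configuration for the full detection chain. Unknown keys in any
#' block are rejected; the assembled object is stamped with a schema
#' version.
#'
#' @param preprocess List overriding [segment_lobes()] parameters
#'   (`erosion_radius`, `closing_radius`, `keep_k`).
#' @param fcm List overriding [fcm_config()] fields.
#' @param features List overriding [texture_config()] fields.
#' @param classifier List overriding [chstm_config()] fields other than
#'   `feature_length` (`hidden_size`, `timesteps`, `threshold`,
#'   `weight_bound`).
#' @param cho List overriding [cho_config()] fields.
#' @param phantom List overriding [phantom_config()] fields.
#' @param min_gap_factor Detection guard of [segment_nodules()].
#' @param match_iou IoU at or above which a predicted nodule mask is
#'   matched to a ground-truth mask.
#' @param use_backbone Whether per-pixel backbone channels join the
#'   segmentation features.
#' @param seed Global seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = list(), fcm = list(),
                            features = list(), classifier = list(),
                            cho = list(), phantom = list(),
                            min_gap_factor = 2.5, match_iou = 0.3,
                            use_backbone = FALSE, seed = 7L) {
  check_keys <- function(given, allowed, block) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stopf("unknown key(s) in '%s' block: %s", block,
            paste(bad, collapse = ", "))
    given
  }
  preprocess <- modifyList(list(erosion_radius = 2, closing_radius = 10,
                                keep_k = 2),
                           check_keys(preprocess,
                                      c("erosion_radius", "closing_radius",
                                        "keep_k"), "preprocess"))
  fcm <- check_keys(fcm, c("n_clusters", "fuzzifier", "tolerance",
                           "max_iter", "seed"), "fcm")
  features <- check_keys(features, c("ltp_threshold", "histogram_bins"),
                         "features")
  classifier <- check_keys(classifier, c("hidden_size", "timesteps",
                                         "threshold", "weight_bound"),
                           "classifier")
  cho <- check_keys(cho, c("pop_size", "t_max", "foraging_speed",
                           "trial_factor_scale", "sensitive_factor",
                           "recursive_range", "diffusion_max", "epsilon",
                           "inertia", "target_effect", "seed"), "cho")
  phantom <- check_keys(phantom, names(formals(phantom_config)), "phantom")
  structure(list(schema = "nodulekit/pipeline-config/1",
                 preprocess = preprocess,
                 fcm = do.call(fcm_config, fcm),
                 features = do.call(texture_config, features),
                 classifier = classifier,
                 cho = do.call(cho_config,
                               modifyList(list(pop_size = 20L, t_max = 50L),
                                          cho)),
                 phantom = do.call(phantom_config, phantom),
                 min_gap_factor = min_gap_factor, match_iou = match_iou,
                 use_backbone = use_backbone, seed = as.integer(seed)),
            class = "pipeline_config")
}

mask_iou <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(0)
  inter / uni
}

mask_dice <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  tot <- sum(a) + sum(b)
  if (tot == 0) return(0)
  2 * inter / tot
}

# Split a nodule segmentation mask into connected candidate regions,
# dropping specks below min_area.
candidate_regions <- function(mask, min_area = 9L) {
  lab <- label_components(mask)
  n <- max(lab)
  out <- list()
  for (i in seq_len(n)) {
    m <- (lab == i) * 1
    if (sum(m) >= min_area) out[[length(out) + 1L]] <- m
  }
  out
}

#' Detect and describe nodule candidates in one slice
#'
#' Runs lobe segmentation, ROI masking, fuzzy C-means nodule segmentation
#' and per-candidate feature extraction; when a trained model is given,
#' each candidate is classified.
#'
#' @param image Numeric matrix (grayscale slice).
#' @param config A [pipeline_config()].
#' @param model Optional `chstm_model`.
#' @return A list with `lobe_mask`, `roi`, `segmentation`, `candidates`
#'   (list of masks) and `detections` (tibble of features plus
#'   `probability`/`label` when a model is supplied).
#' @export
detect_nodules <- function(image, config = pipeline_config(), model = NULL) {
  pp <- config$preprocess
  lobe <- segment_lobes(image, pp$erosion_radius, pp$closing_radius, pp$keep_k)
  roi <- extract_roi(image, lobe)
  seg <- segment_nodules(roi, lobe, config$fcm,
                         backbone = if (config$use_backbone)
                           backbone_pixel_channels else NULL,
                         min_gap_factor = config$min_gap_factor)
  cands <- candidate_regions(seg$mask)
  feats <- lapply(cands, function(m)
    extract_features(roi, m, config$features))
  det <- if (length(feats)) dplyr::bind_rows(feats) else tibble::tibble()
  if (!is.null(model) && nrow(det)) {
    pred <- chstm_predict(model, det)
    det <- dplyr::bind_cols(det, pred)
  }
  list(lobe_mask = lobe, roi = roi, segmentation = seg,
       candidates = cands, detections = det)
}

#' Classification metrics from aligned label vectors
#'
#' Confusion counts and the three headline metrics with malignant as the
#' positive class: accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`. A ratio with an empty denominator is
#' reported as `NA`, never as 0.
#'
#' @param truth,predicted Equal-length vectors of
#'   `"benign"` / `"malignant"` labels.
#' @return An object of class `eval_report`: `counts` (TP, FP, TN, FN),
#'   `accuracy`, `sensitivity`, `specificity`, `per_sample` tibble.
#' @examples
#' evaluate_detections(c("malignant", "benign"), c("malignant", "malignant"))
#' @export
evaluate_detections <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) == 0L) stopf("empty inputs")
  if (length(truth) != length(predicted))
    stopf("label vectors are not aligned")
  tp <- sum(truth == "malignant" & predicted == "malignant")
  fn <- sum(truth == "malignant" & predicted == "benign")
  tn <- sum(truth == "benign" & predicted == "benign")
  fp <- sum(truth == "benign" & predicted == "malignant")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 accuracy = ratio(tp + tn, tp + fp + tn + fn),
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 per_sample = tibble::tibble(truth = truth,
                                             predicted = predicted,
                                             correct = truth == predicted)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  cat(sprintf("  accuracy %.3f | sensitivity %s | specificity %s\n",
              x$accuracy,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.3f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.3f", x$specificity))))
  invisible(x)
}

#' Scaled-down end-to-end detection experiment
#'
#' The package's reference experiment: generate `n` phantom slices, run
#' every image through lobe segmentation, ROI masking and fuzzy C-means
#' nodule segmentation, extract per-candidate descriptors, match each
#' candidate to ground truth by mask IoU to inherit its label, train the
#' classifier with the swarm optimizer on a stratified split, and score
#' the held-out portion. The whole run is a pure function of
#' `config$seed`.
#'
#' @param n Number of phantom slices.
#' @param config A [pipeline_config()].
#' @return An object of class `nodule_experiment`: `features` (tibble with
#'   labels), `model` (`chstm_model`), `report` (`eval_report` on the
#'   held-out portion), `segmentation_dice` (per matched candidate),
#'   `n_unmatched`, and the manifest.
#' @export
run_experiment <- function(n = 100L, config = pipeline_config()) {
  manifest <- generate_dataset(n, config$phantom, seed = config$seed)
  samples <- attr(manifest, "samples")
  feats <- list()
  labels <- character(0)
  dice <- numeric(0)
  unmatched <- 0L
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    res <- detect_nodules(sm$image, config)
    for (m in res$candidates) {
      ious <- vapply(sm$nodule_masks, function(g) mask_iou(m, g), numeric(1))
      if (length(ious) && max(ious) >= config$match_iou) {
        j <- which.max(ious)
        feats[[length(feats) + 1L]] <-
          extract_features(res$roi, m, config$features)
        labels <- c(labels, sm$labels[j])
        dice <- c(dice, mask_dice(m, sm$nodule_masks[[j]]))
      } else {
        unmatched <- unmatched + 1L
      }
    }
  }
  if (!length(feats)) stopf("no candidate matched the ground truth")
  features <- dplyr::bind_rows(feats)
  model <- train_chstm(features, labels, cho = config$cho,
                       seed = child_seed(config$seed, 1))
  val <- model$val_index
  pred <- chstm_predict(model, features[val, , drop = FALSE])
  report <- evaluate_detections(labels[val], pred$label)
  structure(list(features = dplyr::mutate(features, label = labels),
                 model = model, report = report,
                 segmentation_dice = dice, n_unmatched = unmatched,
                 manifest = manifest, config = config),
            class = "nodule_experiment")
}

#' @export
print.nodule_experiment <- function(x, ...) {
  cat("<nodule_experiment>\n")
  cat(sprintf("  candidates: %d matched, %d unmatched | mean Dice %.3f\n",
              nrow(x$features), x$n_unmatched, mean(x$segmentation_dice)))
  cat(sprintf("  held-out accuracy %.3f (baseline %.3f)\n",
              x$model$val_accuracy, x$model$val_baseline))
  invisible(x)
}

#' Run the pipeline over images and write a structured report
#'
#' @param images A list of numeric matrices, a character vector of image
#'   paths, or a single matrix.
#' @param config A [pipeline_config()].
#' @param model Optional trained `chstm_model`.
#' @param report_path Optional path for the JSON report.
#' @return A tibble with one row per detection (image index, candidate
#'   index, area, probability and label when a model is given), also
#'   serialized to `report_path` when requested.
#' @export
run_pipeline <- function(images, config = pipeline_config(), model = NULL,
                         report_path = NULL) {
  if (is.matrix(images)) images <- list(images)
  if (is.character(images)) images <- lapply(images, read_gray_image)
  rows <- list()
  for (i in seq_along(images)) {
    res <- tryCatch(detect_nodules(images[[i]], config, model),
                    error = function(e)
                      stopf("stage failure on image %d: %s", i,
                            conditionMessage(e)))
    if (!length(res$candidates)) next
    for (k in seq_along(res$candidates)) {
      row <- tibble::tibble(image = i, candidate = k,
                            area = sum(res$candidates[[k]]))
      if (!is.null(model))
        row <- dplyr::bind_cols(row, res$detections[k, c("probability", "label")])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows)
         else tibble::tibble(image = integer(0), candidate = integer(0),
                             area = numeric(0))
  if (!is.null(report_path)) {
    jsonlite::write_json(list(schema = "nodulekit/report/1",
                              n_images = length(images),
                              detections = out),
                         report_path, auto_unbox = TRUE, digits = NA)
  }
  out
}
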