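#' Pixel confusion matrix
#'
#' @param pred,truth Integer label arrays of identical shape with values in
#'   `{0, ..., n_classes - 1}`.
#' @param n_classes Number of classes including background.
#' @return An `n_classes x n_classes` integer matrix; rows are true classes,
#'   columns predicted classes.
#' @export
confusion_matrix <- function(pred, truth, n_classes = 3L) {
  if (length(pred) == 0L) stop("empty masks")
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("prediction and truth shapes differ")
  p <- as.integer(pred); t <- as.integer(truth)
  if (any(p < 0L) || any(p >= n_classes) || any(t < 0L) || any(t >= n_classes))
    stop("labels must lie in {0, ..., ", n_classes - 1L, "}")
  cm <- matrix(tabulate(t * n_classes + p + 1L, nbins = n_classes^2),
               n_classes, n_classes, byrow = TRUE)
  dimnames(cm) <- list(truth = 0:(n_classes - 1L), pred = 0:(n_classes - 1L))
  cm
}

#' Mean intersection over union
#'
#' Mean over classes of `TP / (TP + FP + FN)`. Classes absent from both the
#' prediction and the truth (an empty union, 0/0) are excluded from the mean
#' rather than scored, which avoids biasing small tiles.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return mIoU in `[0, 1]`.
#' @export
miou <- function(cm) {
  tp <- diag(cm)
  union <- rowSums(cm) + colSums(cm) - tp
  present <- union > 0
  if (!any(present)) stop("no class present in prediction or truth")
  mean(tp[present] / union[present])
}

#' Overall accuracy
#'
#' Fraction of all pixels classified correctly: `trace(cm) / sum(cm)`, the
#' multi-class generalization of `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm Confusion matrix.
#' @return OA in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  s <- sum(cm)
  if (s == 0) stop("empty confusion matrix")
  sum(diag(cm)) / s
}

#' Macro-averaged recall
#'
#' Per-class `TP / (TP + FN)` averaged over the classes present in the truth
#' (classes with no true pixels are excluded from the macro mean).
#'
#' @param cm Confusion matrix.
#' @param averaging Only `"macro"` is implemented.
#' @return Recall in `[0, 1]`.
#' @export
recall <- function(cm, averaging = "macro") {
  stopifnot(identical(averaging, "macro"))
  pos <- rowSums(cm)
  present <- pos > 0
  if (!any(present)) stop("truth contains no pixels")
  mean(diag(cm)[present] / pos[present])
}

# Aggregate confusion matrix and metrics of a model over a list of tiles
# (micro aggregation of counts over the whole split, not per-tile averages).
evaluate_tiles <- function(model, tiles, batch_size = 4L) {
  K <- model$config$num_classes
  cm <- matrix(0L, K, K)
  idx <- split(seq_along(tiles),
               ceiling(seq_along(tiles) / batch_size))
  for (b in idx) {
    hwd <- dim(tiles[[b[1]]]$image)
    x <- array(0, c(hwd[1], hwd[2], hwd[3], length(b)))
    y <- array(0L, c(hwd[1], hwd[2], length(b)))
    for (j in seq_along(b)) {
      x[, , , j] <- tiles[[b[j]]]$image
      y[, , j] <- tiles[[b[j]]]$mask
    }
    pred <- predict(model, x, type = "class")
    if (length(dim(pred)) == 2L) dim(pred) <- c(dim(pred), 1L)
    cm <- cm + confusion_matrix(pred, y, K)
  }
  list(cm = cm, miou = miou(cm), oa = overall_accuracy(cm),
       recall = recall(cm))
}

#' Evaluate a trained network on a tile set
#'
#' Computes the aggregated confusion matrix over all tiles and the derived
#' mIoU, overall accuracy and macro recall, plus per-class IoU and recall.
#'
#' @param object An `agrinet_fit` or `agrinet_model`.
#' @param tiles List of [tile_pair()] objects.
#' @param ids Optional tile ids to evaluate (e.g. a manifest's `val_ids`).
#' @return A list with `cm`, `miou`, `oa`, `recall`, `per_class`.
#' @export
evaluate_agrinet <- function(object, tiles, ids = NULL) {
  model <- if (inherits(object, "agrinet_fit")) object$model else object
  if (!is.null(ids)) {
    all_ids <- vapply(tiles, function(t) t$tile_id, character(1))
    tiles <- tiles[match(ids, all_ids)]
    if (anyNA(match(ids, all_ids))) stop("unknown tile ids requested")
  }
  r <- evaluate_tiles(model, tiles)
  tp <- diag(r$cm)
  union <- rowSums(r$cm) + colSums(r$cm) - tp
  r$per_class <- data.frame(
    class = seq_len(nrow(r$cm)) - 1L,
    iou = ifelse(union > 0, tp / union, NA_real_),
    recall = ifelse(rowSums(r$cm) > 0, tp / rowSums(r$cm), NA_real_))
  r
}
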