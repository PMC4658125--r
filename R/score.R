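#' Score predicted boxes against ground truth
#'
#' A formal scoring harness for segmentation output: predictions are matched
#' one-to-one to ground-truth boxes greedily on descending IoU (ties broken
#' by reading order, i.e. row order of the inputs), a pair counting as a true
#' positive when its IoU reaches the threshold. Unmatched predictions are
#' false positives (a box where there is no specimen); unmatched truths are
#' false negatives (a specimen without a box) — the two quantities a human
#' refiner has to correct.
#'
#' @param pred Predicted boxes: a tibble with normalized `x0, y0, x1, y1`.
#' @param truth Ground truth in the same form (the `truth` element of a
#'   fixture works directly).
#' @param iou_threshold Minimum IoU for a match, in `(0, 1]` (default 0.5).
#' @return A `seg_eval` object: counts `tp`, `fp`, `fn`, rates `precision`
#'   and `recall`, the threshold, and a `matches` tibble
#'   (`pred`, `truth`, `iou`).
#' @export
score_segmentation <- function(pred, truth, iou_threshold = 0.5) {
  if (!(iou_threshold > 0 && iou_threshold <= 1))
    stop_param("`iou_threshold` must be in (0, 1]")
  pred <- as_tibble(pred); truth <- as_tibble(truth)
  iou <- iou_matrix(pred, truth)
  cand <- which(iou >= iou_threshold, arr.ind = TRUE)
  matches <- tibble(pred = integer(), truth = integer(), iou = double())
  if (nrow(cand)) {
    vals <- iou[cand]
    ord <- order(-vals, cand[, 1], cand[, 2])
    used_p <- logical(nrow(pred)); used_t <- logical(nrow(truth))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      matches <- bind_rows(matches, tibble(pred = i, truth = j, iou = vals[k]))
    }
    matches <- arrange(matches, .data$pred)
  }
  tp <- nrow(matches)
  fp <- nrow(pred) - tp
  fn <- nrow(truth) - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0L) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0L) tp / (tp + fn) else 1,
    iou_threshold = iou_threshold, matches = matches,
    n_pred = nrow(pred), n_truth = nrow(truth)),
    class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("<seg_eval> tp %d, fp %d, fn %d | precision %.3f, recall %.3f (IoU >= %.2f)\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$iou_threshold))
  invisible(x)
}

#' @export
glance.seg_eval <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn,
         precision = x$precision, recall = x$recall,
         iou_threshold = x$iou_threshold,
         n_pred = x$n_pred, n_truth = x$n_truth)
}

#' @export
tidy.seg_eval <- function(x, ...) {
  pred_rows <- tibble(role = rep("pred", x$n_pred), index = seq_len(x$n_pred)) |>
    dplyr::left_join(x$matches, by = c(index = "pred")) |>
    mutate(status = ifelse(is.na(.data$truth), "fp", "tp"),
           matched = .data$truth) |>
    select("role", "index", "matched", "iou", "status")
  truth_rows <- tibble(role = rep("truth", x$n_truth), index = seq_len(x$n_truth)) |>
    dplyr::left_join(x$matches, by = c(index = "truth")) |>
    mutate(status = ifelse(is.na(.data$pred), "fn", "tp"),
           matched = .data$pred) |>
    select("role", "index", "matched", "iou", "status")
  bind_rows(pred_rows, truth_rows)
}
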