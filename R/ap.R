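## Instance-segmentation average precision ---------------------------------

#' Average precision of an instance segmentation against ground truth
#'
#' For each IoU threshold `tau`, ground-truth and predicted instances are
#' matched one-to-one greedily in descending IoU order (ties broken by
#' ascending `(gt_id, pred_id)`), considering only pairs with IoU >= tau;
#' greedy matching equals optimal matching whenever IoUs are distinct.
#' `AP = TP / (TP + FP + FN)`. IoU is computed on voxel sets; background (0)
#' is never matched. The result is invariant to instance relabelling and to
#' axis transposition applied to both inputs, and non-increasing in `tau`.
#'
#' @param gt,pred integer label arrays of identical shape (0 = background).
#' @param iou_thresholds IoU thresholds in (0, 1).
#' @return data.frame with one row per threshold: `threshold`, `ap`, `tp`,
#'   `fp`, `fn`; attribute `"match_tables"` holds, per threshold, the matched
#'   `(gt_id, pred_id, iou)` pairs.
#' @export
average_precision <- function(gt, pred, iou_thresholds = seq(0.5, 0.95, 0.05)) {
  gt <- vol_data(gt)
  pred <- vol_data(pred)
  check_same_shape(gt, pred)
  if (any(gt != round(gt)) || any(pred != round(pred)))
    stop("labels must be non-negative integers", call. = FALSE)
  if (min(gt) < 0 || min(pred) < 0)
    stop("labels must be non-negative integers", call. = FALSE)
  stopifnot(all(iou_thresholds > 0), all(iou_thresholds < 1))
  g <- as.integer(gt)
  p <- as.integer(pred)
  n_gt <- length(unique(g[g > 0L]))
  n_pr <- length(unique(p[p > 0L]))
  pairs <- pair_ious(g, p)
  rows <- list()
  tables <- list()
  for (tau in iou_thresholds) {
    cand <- pairs[pairs$iou >= tau, , drop = FALSE]
    cand <- cand[order(-cand$iou, cand$gt_id, cand$pred_id), , drop = FALSE]
    used_g <- integer(0)
    used_p <- integer(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!(cand$gt_id[i] %in% used_g) && !(cand$pred_id[i] %in% used_p)) {
        keep[i] <- TRUE
        used_g <- c(used_g, cand$gt_id[i])
        used_p <- c(used_p, cand$pred_id[i])
      }
    }
    matched <- cand[keep, , drop = FALSE]
    tp <- nrow(matched)
    fp <- n_pr - tp
    fn <- n_gt - tp
    ap <- if (tp + fp + fn == 0L) 1 else tp / (tp + fp + fn)
    rows[[length(rows) + 1L]] <-
      data.frame(threshold = tau, ap = ap, tp = tp, fp = fp, fn = fn)
    tables[[length(tables) + 1L]] <- matched
  }
  out <- do.call(rbind, rows)
  names(tables) <- as.character(iou_thresholds)
  attr(out, "match_tables") <- tables
  out
}

# IoU of every overlapping (gt, pred) instance pair
pair_ious <- function(g, p) {
  area_g <- tabulate(g[g > 0L], nbins = max(g, 1L))
  area_p <- tabulate(p[p > 0L], nbins = max(p, 1L))
  sel <- g > 0L & p > 0L
  if (!any(sel))
    return(data.frame(gt_id = integer(0), pred_id = integer(0),
                      iou = numeric(0)))
  tab <- table(gt = g[sel], pred = p[sel])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, , drop = FALSE]
  gt_id <- as.integer(df$gt)
  pred_id <- as.integer(df$pred)
  inter <- df$Freq
  union <- area_g[gt_id] + area_p[pred_id] - inter
  data.frame(gt_id = gt_id, pred_id = pred_id, iou = inter / union)
}
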