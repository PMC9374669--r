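#' Match detections to ground truth at one IoU threshold
#'
#' Greedy one-to-one matching in descending confidence order: each detection
#' claims its best-IoU still-unmatched ground-truth box and is a true
#' positive iff that IoU meets the threshold; every other detection is a
#' false positive, every unclaimed ground truth a false negative.
#'
#' @param dets detection box data.frame (any order; sorted internally by
#'   descending score).
#' @param gts ground-truth box data.frame.
#' @param iou_threshold match threshold in (0, 1\].
#' @return list with `score` (sorted descending), `tp` / `fp` logical
#'   vectors aligned to it, `fn` count and `n_gt`.
#' @export
match_detections <- function(dets, gts, iou_threshold) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0)
    return(list(score = numeric(), tp = logical(), fp = logical(),
                fn = ng, n_gt = ng))
  ord <- order(-dets$score, seq_len(nd))
  dets <- dets[ord, , drop = FALSE]
  tp <- rep(FALSE, nd)
  taken <- rep(FALSE, max(ng, 1L))
  if (ng > 0) {
    M <- iou_matrix(dets, gts)
    for (i in seq_len(nd)) {
      free <- which(!taken[seq_len(ng)])
      if (length(free) == 0) break
      j <- free[which.max(M[i, free])]
      if (M[i, j] >= iou_threshold) {
        tp[i] <- TRUE
        taken[j] <- TRUE
      }
    }
  }
  list(score = dets$score, tp = tp, fp = !tp, fn = ng - sum(tp), n_gt = ng)
}

#' Average precision from per-image matches
#'
#' Detections from all images are pooled and ranked globally by confidence
#' (micro-averaging); the precision envelope is integrated over all recall
#' points (all-point interpolation, the COCO convention).
#'
#' @param matches list of [match_detections()] results, one per image, all
#'   computed at the same IoU threshold.
#' @param iou_threshold the threshold they were computed at (recorded in the
#'   result).
#' @return an `wce_eval_result`: list with `ap`, `iou_threshold`,
#'   `precision_curve`, `recall_curve`, `n_images`, `n_gt_boxes`.
#' @export
average_precision <- function(matches, iou_threshold = NA_real_) {
  n_gt <- sum(vapply(matches, `[[`, numeric(1), "n_gt"))
  if (n_gt == 0)
    stop("average precision is undefined with zero ground-truth boxes")
  score <- unlist(lapply(matches, `[[`, "score"))
  tp <- unlist(lapply(matches, `[[`, "tp"))
  ord <- order(-score, seq_along(score))
  tp <- tp[ord]
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  if (length(tp) == 0) {
    ap <- 0
  } else {
    penv <- rev(cummax(rev(precision)))
    ap <- sum(diff(c(0, recall)) * penv)
  }
  structure(list(ap = ap, iou_threshold = iou_threshold,
                 precision_curve = precision, recall_curve = recall,
                 n_images = length(matches), n_gt_boxes = n_gt),
            class = "wce_eval_result")
}

#' @export
print.wce_eval_result <- function(x, ...) {
  cat(sprintf("<wce_eval_result> AP_%s = %.4f (%d images, %d gt boxes)\n",
              ifelse(is.na(x$iou_threshold), "?",
                     format(round(100 * x$iou_threshold))),
              x$ap, x$n_images, x$n_gt_boxes))
  invisible(x)
}

#' Evaluate a detector on annotated frames
#'
#' Runs the full pipeline (forward, decode, NMS — no confidence cut, so the
#' whole ranked list enters the precision-recall curve) on every frame and
#' reports AP at each requested IoU threshold, e.g. AP_25 and AP_50.
#'
#' @param network a `wce_network`.
#' @param frames list of annotated images (see [generate_frame()]).
#' @param config a [head_config()] whose `image_size` matches the frames.
#' @param iou_thresholds numeric vector of thresholds n/100.
#' @return named list of `wce_eval_result`, names `AP_25` etc.
#' @export
evaluate_detector <- function(network, frames, config = head_config(),
                              iou_thresholds = c(0.25, 0.5)) {
  dets <- lapply(frames, function(f)
    detect_polyps(network, f$pixels, config, apply_threshold = FALSE))
  setNames(lapply(iou_thresholds, function(th) {
    matches <- lapply(seq_along(frames), function(i)
      match_detections(dets[[i]], frames[[i]]$boxes, th))
    average_precision(matches, th)
  }), paste0("AP_", round(100 * iou_thresholds)))
}
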