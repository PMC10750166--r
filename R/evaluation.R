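#' IoU matrix between ground-truth and predicted instances
#'
#' Computes intersection-over-union over voxel sets for every (ground truth,
#' prediction) instance pair via a sparse joint histogram of co-occurring
#' labels — no per-pair voxel scans.
#'
#' @param gt,pred [label_volume()]s of identical shape (2D slices are
#'   accepted as single-slice volumes).
#' @return Numeric matrix with rownames = gt ids, colnames = pred ids,
#'   entries in `[0, 1]`.
#' @export
iou_matrix <- function(gt, pred) {
  stopifnot(inherits(gt, "label_volume"), inherits(pred, "label_volume"))
  check_same_shape(gt$labels, pred$labels)
  g <- as.vector(gt$labels)
  p <- as.vector(pred$labels)
  keep <- g > 0L | p > 0L
  g <- g[keep]; p <- p[keep]
  gids <- sort(unique(g[g > 0L]))
  pids <- sort(unique(p[p > 0L]))
  M <- matrix(0, length(gids), length(pids),
              dimnames = list(as.character(gids), as.character(pids)))
  if (!length(gids) || !length(pids)) return(M)
  sz_g <- stats::setNames(tabulate(match(g, gids), nbins = length(gids)), gids)
  sz_p <- stats::setNames(tabulate(match(p, pids), nbins = length(pids)), pids)
  both <- g > 0L & p > 0L
  if (any(both)) {
    key <- paste(g[both], p[both])
    inter <- table(key)
    parts <- do.call(rbind, strsplit(names(inter), " ", fixed = TRUE))
    gi <- parts[, 1]; pj <- parts[, 2]
    ious <- as.numeric(inter) /
      (sz_g[gi] + sz_p[pj] - as.numeric(inter))
    M[cbind(gi, pj)] <- ious
  }
  M
}

#' One-to-one instance matching above an IoU threshold
#'
#' Finds a maximum-cardinality one-to-one matching among pairs with
#' `IoU > iou_threshold` (strict). Pairs are preferred in order of descending
#' IoU, ties broken by ascending (gt id, pred id); a final augmenting-path
#' pass guarantees maximum cardinality. At thresholds above 0.5 each instance
#' can exceed the threshold with at most one partner, so greedy and maximum
#' matching coincide.
#'
#' @param iou Matrix from [iou_matrix()].
#' @param iou_threshold Threshold in `[0, 1)`; default 0.5, the standard
#'   operating point of the instance-matched Jaccard metric.
#' @return An object of class `match_result`: `pairs` (data.frame `gt_id`,
#'   `pred_id`, `iou`), counts `n_tp`, `n_fp`, `n_fn`, and the threshold.
#' @export
match_instances <- function(iou, iou_threshold = 0.5) {
  if (!is.matrix(iou)) stop("`iou` must be a matrix", call. = FALSE)
  if (iou_threshold < 0 || iou_threshold >= 1)
    stop("`iou_threshold` must be in [0, 1)", call. = FALSE)
  n_gt <- nrow(iou); n_pred <- ncol(iou)
  gids <- if (is.null(rownames(iou))) as.character(seq_len(n_gt)) else rownames(iou)
  pids <- if (is.null(colnames(iou))) as.character(seq_len(n_pred)) else colnames(iou)
  cand <- which(iou > iou_threshold, arr.ind = TRUE)
  gmatch <- rep(NA_integer_, n_gt)  # gt row -> pred col
  pmatch <- rep(NA_integer_, n_pred)
  if (nrow(cand)) {
    # rows/cols are already in ascending id order, so index order = id order
    o <- order(-iou[cand], cand[, 1], cand[, 2], method = "radix")
    cand <- cand[o, , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1]; c <- cand[k, 2]
      if (is.na(gmatch[r]) && is.na(pmatch[c])) {
        gmatch[r] <- c; pmatch[c] <- r
      }
    }
    # augmenting paths to reach maximum cardinality (matters only < 0.5)
    adj <- split(cand[, 2], cand[, 1])
    for (r in seq_len(n_gt)) {
      if (!is.na(gmatch[r])) next
      visited <- rep(FALSE, n_pred)
      try_augment <- function(row) {
        for (c in adj[[as.character(row)]]) {
          if (visited[c]) next
          visited[c] <<- TRUE
          if (is.na(pmatch[c]) || try_augment(pmatch[c])) {
            gmatch[row] <<- c; pmatch[c] <<- row
            return(TRUE)
          }
        }
        FALSE
      }
      if (!is.null(adj[[as.character(r)]])) try_augment(r)
    }
  }
  matched <- which(!is.na(gmatch))
  pairs <- data.frame(
    gt_id = as.integer(gids[matched]),
    pred_id = as.integer(pids[gmatch[matched]]),
    iou = iou[cbind(matched, gmatch[matched])]
  )
  pairs <- pairs[order(-pairs$iou, pairs$gt_id, pairs$pred_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 n_tp = nrow(pairs),
                 n_fp = n_pred - nrow(pairs),
                 n_fn = n_gt - nrow(pairs),
                 n_gt = n_gt, n_pred = n_pred,
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (IoU > %.2f)\n",
              x$n_tp, x$n_fp, x$n_fn, x$iou_threshold))
  invisible(x)
}

#' Instance-matched Jaccard index
#'
#' `TP / (TP + FP + FN)` after one-to-one matching of instances at
#' `IoU > iou_threshold` — the segmentation-quality statistic used to assess
#' nucleus segmentation models. Two volumes with no instances at all score 1.
#'
#' @param gt,pred [label_volume()]s of identical shape.
#' @param iou_threshold Matching threshold, default 0.5.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_index <- function(gt, pred, iou_threshold = 0.5) {
  mr <- match_instances(iou_matrix(gt, pred), iou_threshold)
  denom <- mr$n_tp + mr$n_fp + mr$n_fn
  if (denom == 0L) return(1)
  mr$n_tp / denom
}

#' Evaluate a dataset of ground-truth / prediction pairs
#'
#' Scores each pair with [jaccard_index()] and summarises the per-image
#' scores (mean, sd, median, IQR) — the reporting format used for
#' segmentation test sets (e.g. "0.78 +/- 0.07").
#'
#' @param gt_list,pred_list Equal-length lists of [label_volume()]s.
#' @param iou_threshold Matching threshold, default 0.5.
#' @param image_ids Optional identifiers; defaults to `img_1 ...`.
#' @return An object of class `evaluation_report`: `per_image` data.frame
#'   (`image_id`, `n_gt`, `n_pred`, `tp`, `fp`, `fn`, `jaccard`) and
#'   `summary` (mean, sd, median, iqr, n_images).
#' @export
evaluate_dataset <- function(gt_list, pred_list, iou_threshold = 0.5,
                             image_ids = NULL) {
  if (length(gt_list) != length(pred_list))
    stop("gt_list and pred_list must have equal length", call. = FALSE)
  if (is.null(image_ids)) image_ids <- paste0("img_", seq_along(gt_list))
  rows <- mapply(function(gt, pred, id) {
    mr <- match_instances(iou_matrix(gt, pred), iou_threshold)
    denom <- mr$n_tp + mr$n_fp + mr$n_fn
    data.frame(image_id = id, n_gt = mr$n_gt, n_pred = mr$n_pred,
               tp = mr$n_tp, fp = mr$n_fp, fn = mr$n_fn,
               jaccard = if (denom == 0L) 1 else mr$n_tp / denom)
  }, gt_list, pred_list, image_ids, SIMPLIFY = FALSE)
  per_image <- do.call(rbind, rows)
  rownames(per_image) <- NULL
  s <- per_image$jaccard
  structure(list(
    per_image = per_image,
    summary = data.frame(mean = mean(s), sd = stats::sd(s),
                         median = stats::median(s), iqr = stats::IQR(s),
                         n_images = length(s))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d image(s): Jaccard %.3f +/- %.3f (median %.3f)\n",
              x$summary$n_images, x$summary$mean,
              if (is.na(x$summary$sd)) 0 else x$summary$sd, x$summary$median))
  invisible(x)
}

#' Write an evaluation report as CSV
#' @param report An [evaluate_dataset()] result.
#' @param path Output CSV path (columns image_id, n_gt, n_pred, tp, fp, fn,
#'   jaccard).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  utils::write.csv(report$per_image, path, row.names = FALSE)
  invisible(path)
}
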