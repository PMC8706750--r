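# coerce LabelMask / SegmentationMap / matrix to a bare label matrix
.asLabels <- function(x) {
  if (is(x, "LabelMask") || is(x, "SegmentationMap")) return(x@labels)
  if (is.matrix(x)) return(x)
  .stopf("expected a LabelMask, SegmentationMap or integer matrix")
}

#' Contingency table between ground truth and segmentation
#'
#' Cross-tabulates ground-truth classes (rows) against segmentation regions
#' (columns) over the ground-truth-labeled pixels only; pixels with
#' ground-truth label 0 are excluded, matching partially labeled benchmark
#' ground truths.
#'
#' @param truth ground-truth labels (0 = unlabeled).
#' @param seg segmentation labels.
#' @return An integer matrix with one row per ground-truth class.
#' @export
contingencyTable <- function(truth, seg) {
  g <- .asLabels(truth); s <- .asLabels(seg)
  if (!all(dim(g) == dim(s)))
    .stopf("ground truth (%s) and segmentation (%s) shapes differ",
           paste(dim(g), collapse = "x"), paste(dim(s), collapse = "x"))
  keep <- g > 0
  if (!any(keep)) .stopf("ground truth contains no labeled pixels")
  unclass(table(truth = g[keep], segment = s[keep]))
}

#' Rand index between ground truth and segmentation
#'
#' Fraction of pixel pairs (over ground-truth-labeled pixels) on which the
#' two partitions agree: co-clustered in both, or separated in both.
#' Computed through the contingency-table identity
#' `RI = (n_s + n_d) / choose(n, 2)` with
#' `n_s = sum choose(n_ij, 2)` and
#' `n_d = choose(n, 2) - sum choose(a_i, 2) - sum choose(b_j, 2) + n_s`.
#'
#' @inheritParams contingencyTable
#' @return A scalar in `[0, 1]`; 1 iff the partitions coincide.
#' @examples
#' randIndex(matrix(c(1, 1, 2, 2), 1), matrix(c(1, 2, 1, 2), 1))  # 4/6
#' @export
randIndex <- function(truth, seg) {
  tab <- contingencyTable(truth, seg)
  n <- sum(tab)
  if (n < 2) .stopf("the Rand index needs at least 2 labeled pixels")
  ns <- sum(choose(tab, 2))
  total <- choose(n, 2)
  nd <- total - sum(choose(rowSums(tab), 2)) -
    sum(choose(colSums(tab), 2)) + ns
  (ns + nd) / total
}

#' Overall accuracy
#'
#' Each ground-truth class is credited with its best-overlapping
#' segmentation region: `OA = sum_i max_j #(g_i & s_j) / n`.  Invariant to
#' relabeling of the segmentation, and suited to segmentations with fewer
#' regions than ground-truth classes.
#'
#' @inheritParams contingencyTable
#' @return A scalar in `[0, 1]`.
#' @export
overallAccuracy <- function(truth, seg) {
  tab <- contingencyTable(truth, seg)
  sum(apply(tab, 1L, max)) / sum(tab)
}

#' Purity
#'
#' Each segmentation region is credited with its dominant ground-truth
#' class: `Purity = sum_j max_i #(s_j & g_i) / n` (the column-max of the
#' contingency table) - how much each segment tends to contain a sole
#' class.
#'
#' @inheritParams contingencyTable
#' @return A scalar in `[0, 1]`.
#' @export
purity <- function(truth, seg) {
  tab <- contingencyTable(truth, seg)
  sum(apply(tab, 2L, max)) / sum(tab)
}

#' All segmentation quality measures at once
#'
#' @inheritParams contingencyTable
#' @return A list with `rand_index`, `overall_accuracy`, `purity` and the
#'   `contingency_table`.
#' @export
evaluateSegmentation <- function(truth, seg) {
  list(rand_index = randIndex(truth, seg),
       overall_accuracy = overallAccuracy(truth, seg),
       purity = purity(truth, seg),
       contingency_table = contingencyTable(truth, seg))
}
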