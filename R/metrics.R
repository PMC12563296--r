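#' Classification / partition agreement metrics
#'
#' Accuracy is the fraction of exact label matches. NMI and ARI are
#' permutation-invariant partition agreement scores (computed through
#' igraph and mclust respectively). Macro-F1 averages the per-class F1 over
#' the classes present in the true labels, counting an undefined class F1
#' (no predictions and no members) as 0.
#'
#' @param truth,pred integer label vectors of equal length.
#' @return a single number.
#' @name agreement-metrics
NULL

#' @rdname agreement-metrics
#' @export
accuracy_score <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  mean(truth == pred)
}

#' @rdname agreement-metrics
#' @export
nmi_score <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(unique(truth)) == 1L && length(unique(pred)) == 1L) return(1)
  igraph::compare(as.integer(factor(truth)), as.integer(factor(pred)),
                  method = "nmi")
}

#' @rdname agreement-metrics
#' @export
ari_score <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  mclust::adjustedRandIndex(truth, pred)
}

#' @rdname agreement-metrics
#' @param average `"macro"` (default), `"micro"` or `"weighted"`.
#' @export
f1_score <- function(truth, pred, average = c("macro", "micro", "weighted")) {
  stopifnot(length(truth) == length(pred))
  average <- match.arg(average)
  classes <- sort(unique(truth))
  if (average == "micro") return(mean(truth == pred))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  if (average == "macro") return(mean(f1))
  w <- as.numeric(table(factor(truth, levels = classes)))
  sum(f1 * w) / sum(w)
}
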