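#' Precision-recall evaluation of an edge ranking
#'
#' Ranks all candidate (regulator, target) pairs of an importance or
#' posterior matrix by decreasing score and evaluates them against a
#' ground-truth edge set. The area under the precision-recall curve is
#' computed as average precision (precision summed at each recovered
#' true edge); the no-skill baseline is the density of true edges among
#' candidate pairs.
#'
#' @param scores regulators x targets numeric matrix.
#' @param truth a [gt_network] or data.frame with `source`/`target`.
#' @return List with `aupr`, `baseline` (true-edge density), `n_true`,
#'   `n_candidates`.
#' @export
edge_ranking_aupr <- function(scores, truth) {
  te <- if (inherits(truth, "gt_network")) truth$edges else truth
  regs <- rownames(scores)
  tgts <- colnames(scores)
  src <- rep(regs, times = length(tgts))
  tgt <- rep(tgts, each = length(regs))
  off <- src != tgt
  key <- paste(src, tgt, sep = "\r")[off]
  s <- as.vector(scores)[off]
  pos <- key %in% paste(te$source, te$target, sep = "\r")
  n_true <- sum(pos)
  if (n_true == 0L) stop("no true edge lies among the candidate pairs")
  ord <- order(-s)
  pos <- pos[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  list(aupr = sum(prec[pos]) / n_true,
       baseline = n_true / length(pos),
       n_true = n_true,
       n_candidates = length(pos))
}
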