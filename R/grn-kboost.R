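#' Kernel principal-component features of one expression vector
#'
#' Builds an RBF (Gaussian) kernel Gram matrix over samples from a single
#' gene's expression vector, double-centers it, and returns the top
#' eigenvectors scaled by the square root of their eigenvalues — the
#' kernel-PCA feature block used as the regression basis by
#' [infer_kboost()]. A zero-variance input yields an all-zero block.
#'
#' @param values numeric expression vector (one value per sample, >= 2
#'   samples).
#' @param n_components number of components (<= number of samples).
#' @param bandwidth RBF bandwidth h in exp(-(x_i - x_j)^2 / (2 h^2));
#'   defaults to the median non-zero pairwise distance.
#' @return Numeric matrix, samples x `n_components`; columns beyond the
#'   rank of the centered Gram matrix are zero.
#' @export
kernel_features <- function(values, n_components, bandwidth = NULL) {
  n <- length(values)
  if (n < 2L) stop("at least 2 samples required")
  if (n_components > n) stop("'n_components' cannot exceed the sample count")
  if (n_components < 1L) stop("'n_components' must be positive")
  out <- matrix(0, nrow = n, ncol = n_components)
  if (sd(values) == 0) return(out)
  d <- abs(outer(values, values, "-"))
  if (is.null(bandwidth)) {
    dv <- d[upper.tri(d)]
    dv <- dv[dv > 0]
    bandwidth <- if (length(dv)) median(dv) else 1
  }
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  k <- exp(-d^2 / (2 * bandwidth^2))
  # double-centering: J K J with J = I - 11'/n
  kc <- sweep(k, 1, rowMeans(k))
  kc <- sweep(kc, 2, colMeans(kc))
  eg <- eigen(kc, symmetric = TRUE)
  keep <- seq_len(n_components)
  ev <- pmax(eg$values[keep], 0)
  out[] <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev), n_components)
  out
}

#' Infer edge posteriors by kernel-PCA gradient boosting
#'
#' For each target gene, a greedy boosting loop over candidate
#' regulators: every round fits a least-squares regression of the current
#' residual on each candidate's kernel-PCA features, scores candidates by
#' BIC, converts the scores to model posteriors by Bayesian model
#' averaging under a uniform prior (no prior regulatory knowledge), adds
#' `shrinkage` times the best candidate's fit to the running prediction,
#' and accumulates the posterior weights. The final column for a target
#' is the accumulated weight normalized to sum to 1 over its candidates.
#'
#' Samples are treated as exchangeable: the time-course ordering is
#' deliberately ignored. The procedure has no random element, so output
#' is deterministic.
#'
#' @param expr an [expression_set] with at least 4 samples.
#' @param regulators candidate regulator genes.
#' @param n_components kernel-PCA components per regulator; default
#'   min(5, n_samples - 1).
#' @param bandwidth RBF bandwidth; default per-regulator median pairwise
#'   distance.
#' @param boosting_rounds greedy rounds per target (default 3).
#' @param shrinkage learning rate in (0, 1] (default 0.5).
#' @return Posterior matrix, regulators x targets; each non-degenerate
#'   column sums to 1 (a zero-variance target gives an all-zero column; a
#'   single-candidate target gives that candidate posterior 1).
#' @export
infer_kboost <- function(expr, regulators, n_components = NULL,
                         bandwidth = NULL, boosting_rounds = 3,
                         shrinkage = 0.5) {
  if (!inherits(expr, "expr_set")) stop("'expr' must be an expr_set")
  if (!all(regulators %in% rownames(expr$values)))
    stop("all regulators must be present in the expression matrix")
  n <- ncol(expr$values)
  if (n < 4L) stop("at least 4 samples required")
  if (shrinkage <= 0 || shrinkage > 1) stop("'shrinkage' must be in (0, 1]")
  if (boosting_rounds < 1) stop("'boosting_rounds' must be positive")
  n_components <- n_components %||% min(5L, n - 1L)
  targets <- rownames(expr$values)
  # kernel feature blocks depend only on the regulator, so cache them
  feats <- lapply(regulators, function(r)
    kernel_features(expr$values[r, ], n_components, bandwidth))
  names(feats) <- regulators
  qrs <- lapply(feats, function(f) qr(cbind(1, f)))

  post <- matrix(0, nrow = length(regulators), ncol = length(targets),
                 dimnames = list(regulators, targets))
  for (g in targets) {
    cands <- setdiff(regulators, g)
    if (length(cands) == 0L) next
    if (length(cands) == 1L) {
      post[cands, g] <- 1
      next
    }
    y <- expr$values[g, ]
    if (sd(y) == 0) next
    r <- y - mean(y)
    ss_total <- sum(r^2)
    acc <- stats::setNames(numeric(length(cands)), cands)
    for (round in seq_len(boosting_rounds)) {
      rss0 <- sum(r^2)
      bic <- numeric(length(cands))
      fitted <- vector("list", length(cands))
      for (ci in seq_along(cands)) {
        q <- qrs[[cands[ci]]]
        fv <- qr.fitted(q, r)
        rss <- max(sum((r - fv)^2), 1e-10 * rss0, 1e-300)
        bic[ci] <- n * log(rss / n) + q$rank * log(n)
        fitted[[ci]] <- fv
      }
      w <- exp(-0.5 * (bic - min(bic)))
      w <- w / sum(w)
      best <- which.min(bic)
      # a round's vote counts in proportion to the share of the original
      # variance its best model explains, so rounds that mostly fit
      # residual noise cannot dilute the posterior
      round_gain <- (rss0 - sum((r - fitted[[best]])^2)) / ss_total
      acc <- acc + max(round_gain, 1e-12) * w
      r <- r - shrinkage * fitted[[best]]
    }
    post[cands, g] <- acc / sum(acc)
  }
  post
}

#' Select per-target top regulators from a posterior matrix
#'
#' For each target, emits an edge from every candidate regulator
#' attaining the column's maximum posterior (ties produce multiple
#' edges); edge weight is the posterior and the sign is `regulating`
#' (the boosting run is unsigned). All-zero columns produce no edge.
#'
#' @param post posterior matrix from [infer_kboost()].
#' @param tol tie tolerance on the posterior (default 1e-12).
#' @return A [grn] whose node set is the union of regulators and targets.
#' @export
select_top_regulators <- function(post, tol = 1e-12) {
  if (length(post) == 0L) stop("empty posterior matrix")
  if (any(post < -tol) || any(post > 1 + tol))
    stop("posteriors must lie in [0, 1]")
  src <- character()
  tgt <- character()
  w <- numeric()
  for (j in seq_len(ncol(post))) {
    m <- max(post[, j])
    if (m <= 0) next
    hit <- which(post[, j] >= m - tol)
    src <- c(src, rownames(post)[hit])
    tgt <- c(tgt, rep(colnames(post)[j], length(hit)))
    w <- c(w, post[hit, j])
  }
  grn(data.frame(source = src, target = tgt, weight = w,
                 sign = "regulating", stringsAsFactors = FALSE),
      nodes = sort(unique(c(rownames(post), colnames(post)))),
      provenance = list(engine = "kboost"))
}

#' Kernel-boosting inference returning a network
#'
#' Convenience wrapper: [infer_kboost()] followed by
#' [select_top_regulators()], with parameters recorded in provenance.
#'
#' @inheritParams infer_kboost
#' @param tol tie tolerance for the argmax selection.
#' @return A [grn].
#' @export
infer_kboost_grn <- function(expr, regulators, n_components = NULL,
                             bandwidth = NULL, boosting_rounds = 3,
                             shrinkage = 0.5, tol = 1e-12) {
  post <- infer_kboost(expr, regulators, n_components = n_components,
                       bandwidth = bandwidth,
                       boosting_rounds = boosting_rounds,
                       shrinkage = shrinkage)
  net <- select_top_regulators(post, tol = tol)
  net$provenance <- list(engine = "kboost",
                         n_components = n_components %||%
                           min(5L, ncol(expr$values) - 1L),
                         boosting_rounds = boosting_rounds,
                         shrinkage = shrinkage)
  net
}
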