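# Enzymatic-reaction likeness: ordered compound pairs featurized by the
# meet / positive-difference algebra and classified with an L1-regularized
# squared-hinge linear SVM (the LIBLINEAR L1R-L2-loss objective,
#   min_w ||w||_1 + C * sum_i max(0, 1 - y_i (w.x_i + b))^2,
# solved by proximal gradient / FISTA with an unpenalized intercept).

#' Number of ordered compound pairs
#'
#' @param n number of compounds.
#' @return numeric(1), n(n-1).
#' @examples
#' countOrderedPairs(6922)  # 47907162
#' @export
countOrderedPairs <- function(n) as.numeric(n) * (as.numeric(n) - 1)

#' Enumerate labeled candidate pairs
#'
#' All n(n-1) ordered pairs of distinct compounds; pairs listed in
#' \code{positives} get label +1 (both directions are distinct examples and
#' must be listed separately if both are positive), everything else -1.
#' Optionally subsamples the negatives to \code{negRatio} negatives per
#' positive (seeded).
#'
#' @param ids character vector of unique compound identifiers.
#' @param positives data.frame with columns \code{id1}, \code{id2} of
#'   positive ordered pairs.
#' @param negRatio optional numeric: negatives kept per positive.
#' @param seed integer seed used when subsampling.
#' @return data.frame with columns \code{id1}, \code{id2}, \code{label}.
#' @export
enumerateCandidatePairs <- function(ids, positives, negRatio = NULL, seed = 1L) {
  if (anyDuplicated(ids)) .stopf("compound ids must be unique")
  unknown <- setdiff(c(positives$id1, positives$id2), ids)
  if (length(unknown)) {
    .stopf("positive pair references unknown compound(s): %s",
           paste(unique(unknown), collapse = ", "))
  }
  if (nrow(positives) && anyDuplicated(paste(positives$id1, positives$id2))) {
    .stopf("duplicate positive pairs")
  }
  grid <- expand.grid(id1 = ids, id2 = ids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$id1 != grid$id2, , drop = FALSE]
  pos_key <- paste(positives$id1, positives$id2, sep = "\r")
  key <- paste(grid$id1, grid$id2, sep = "\r")
  grid$label <- ifelse(key %in% pos_key, 1L, -1L)
  if (!is.null(negRatio)) {
    neg_idx <- which(grid$label == -1L)
    n_keep <- min(length(neg_idx), ceiling(negRatio * sum(grid$label == 1L)))
    keep <- .with_seed(seed, sample(neg_idx, n_keep))
    grid <- grid[sort(c(which(grid$label == 1L), keep)), , drop = FALSE]
  }
  rownames(grid) <- NULL
  grid
}

# evaluate expr with a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pair-feature design matrix
#'
#' @param pairs data.frame with \code{id1}, \code{id2} (and optionally
#'   \code{label}).
#' @param descriptors named list of \code{\link{KcfsDescriptor}} objects
#'   covering every id.
#' @param mode "diff-common" or "diff-only".
#' @param space a \code{\link{FeatureSpace}}.
#' @return numeric matrix, one row per pair.
#' @export
pairFeatureMatrix <- function(pairs, descriptors, mode, space) {
  missing_ids <- setdiff(unique(c(pairs$id1, pairs$id2)), names(descriptors))
  if (length(missing_ids)) {
    .stopf("no descriptor for compound(s): %s", paste(missing_ids, collapse = ", "))
  }
  proj <- lapply(descriptors, projectDescriptor, space = space)
  D <- length(space@keys)
  n <- nrow(pairs)
  X <- matrix(0, n, if (mode == "diff-common") 3L * D else 2L * D)
  for (i in seq_len(n)) {
    va <- proj[[pairs$id1[i]]]
    vb <- proj[[pairs$id2[i]]]
    fwd <- pmax(va - vb, 0)
    rev_ <- pmax(vb - va, 0)
    X[i, ] <- if (mode == "diff-common") c(pmin(va, vb), fwd, rev_)
              else c(fwd, rev_)
  }
  pre <- if (mode == "diff-common") c("common:", "fwd:", "rev:") else c("fwd:", "rev:")
  colnames(X) <- as.vector(vapply(pre, function(p) paste0(p, space@keys),
                                  character(D)))
  X
}

#' Train a linear SVM with squared-hinge loss
#'
#' Minimizes \code{penalty(w) + C * sum(max(0, 1 - y f(x))^2)} with
#' \code{f(x) = w.x + b}; the penalty is \code{||w||_1} (default, sparse) or
#' \code{0.5 ||w||_2^2}. Solved by FISTA with a power-iteration Lipschitz
#' estimate; deterministic for fixed data order.
#'
#' @param X numeric design matrix.
#' @param y labels in \{-1, +1\} (or a logical vector).
#' @param C loss weight (larger = less regularization).
#' @param penalty "l1" or "l2".
#' @param maxit,tol iteration cap and relative objective tolerance.
#' @param mode stored pair-feature mode tag (bookkeeping only).
#' @return an \code{\link{SvmModel}}.
#' @export
trainLinearSvm <- function(X, y, C = 1, penalty = c("l1", "l2"),
                           maxit = 2000L, tol = 1e-9, mode = "diff-common") {
  penalty <- match.arg(penalty)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) .stopf("training data must contain both classes")
  stopifnot(all(y %in% c(-1, 1)), nrow(X) == length(y))
  d <- ncol(X)
  Xa <- cbind(X, 1)  # unpenalized intercept column
  # Lipschitz constant of the smooth part: 2C * lambda_max(Xa'Xa)
  v <- rep(1 / sqrt(d + 1), d + 1)
  for (it in 1:30) {
    v <- crossprod(Xa, Xa %*% v)
    v <- v / sqrt(sum(v^2))
  }
  lam <- as.numeric(crossprod(v, crossprod(Xa, Xa %*% v)))
  L <- 2 * C * lam + if (penalty == "l2") 1 else 0
  step <- 1 / L
  w <- numeric(d + 1)
  z <- w
  t_acc <- 1
  obj <- function(w) {
    m <- pmax(0, 1 - y * as.numeric(Xa %*% w))
    pen <- if (penalty == "l1") sum(abs(w[seq_len(d)]))
           else 0.5 * sum(w[seq_len(d)]^2)
    pen + C * sum(m^2)
  }
  grad_smooth <- function(w) {
    m <- pmax(0, 1 - y * as.numeric(Xa %*% w))
    g <- -2 * C * as.numeric(crossprod(Xa, y * m))
    if (penalty == "l2") g <- g + c(w[seq_len(d)], 0)
    g
  }
  prev_obj <- obj(w)
  for (it in seq_len(maxit)) {
    g <- grad_smooth(z)
    w_new <- z - step * g
    if (penalty == "l1") {
      wi <- w_new[seq_len(d)]
      w_new[seq_len(d)] <- sign(wi) * pmax(abs(wi) - step, 0)
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    z <- w_new + ((t_acc - 1) / t_new) * (w_new - w)
    w <- w_new
    t_acc <- t_new
    if (it %% 20L == 0L) {
      cur <- obj(w)
      if (abs(prev_obj - cur) <= tol * max(1, abs(prev_obj))) break
      prev_obj <- cur
    }
  }
  wt <- w[seq_len(d)]
  names(wt) <- colnames(X)
  new("SvmModel", w = wt, bias = w[d + 1L], cost = C, penalty = penalty,
      mode = mode)
}

#' Decision values for pair-feature rows
#'
#' @param model an \code{\link{SvmModel}}.
#' @param X design matrix with the model's feature columns.
#' @return numeric vector of scores \code{X w + b}.
#' @export
scorePairs <- function(model, X) {
  stopifnot(is(model, "SvmModel"))
  if (ncol(X) != length(model@w)) {
    .stopf("feature-space mismatch: model has %d features, matrix has %d columns",
           length(model@w), ncol(X))
  }
  as.numeric(X %*% model@w) + model@bias
}

#' Area under the ROC curve (trapezoidal)
#'
#' @param scores numeric prediction scores.
#' @param labels +1/-1 (or logical) true labels.
#' @return numeric(1) AUC.
#' @export
aucROC <- function(scores, labels) {
  pos <- labels %in% c(1, TRUE)
  if (!any(pos) || all(pos)) .stopf("both classes required for AUC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' Step-wise area (precision at each achieved recall level, summed over
#' recall increments).
#'
#' @inheritParams aucROC
#' @return numeric(1) AUPR.
#' @export
auPR <- function(scores, labels) {
  pos <- labels %in% c(1, TRUE)
  if (!any(pos)) .stopf("positives required for AUPR")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p)
  n_seen <- seq_along(p)
  last <- !duplicated(grp, fromLast = TRUE)
  prec <- tp[last] / n_seen[last]
  rec <- tp[last] / sum(pos)
  sum(diff(c(0, rec)) * prec)
}

#' Weighted-Jaccard baseline score for compound pairs
#'
#' A no-learning reference: the score of an ordered pair is the weighted
#' Jaccard similarity of the two compound descriptors.
#'
#' @param pairs data.frame with \code{id1}, \code{id2}.
#' @param descriptors named list of \code{\link{KcfsDescriptor}} objects.
#' @return numeric vector of scores in [0, 1].
#' @export
baselineScore <- function(pairs, descriptors) {
  vapply(seq_len(nrow(pairs)), function(i) {
    weightedJaccard(descriptors[[pairs$id1[i]]], descriptors[[pairs$id2[i]]])
  }, numeric(1))
}

#' Cross-validated reaction-likeness prediction
#'
#' Seeded 5-fold cross-validation over labeled ordered pairs: each pair is
#' assigned to exactly one test fold; the descriptor feature space is fixed
#' once from the whole compound corpus (matching the fixed vector dimension
#' of the published experiments; labels play no part in it), a model is
#' trained per fold (with inner selection over \code{Cgrid} on a held-out
#' fifth of the training pairs by AUPR when the grid has more than one
#' value) and test pairs are scored. Pooled scores yield the reported AUC
#' and AUPR.
#'
#' @param pairs data.frame with \code{id1}, \code{id2}, \code{label}.
#' @param descriptors named list of \code{\link{KcfsDescriptor}} objects.
#' @param mode "diff-common" or "diff-only".
#' @param folds number of folds (>= 2).
#' @param Cgrid numeric vector of candidate C values.
#' @param penalty "l1" or "l2".
#' @param seed integer seed for the fold shuffle.
#' @param cap optional feature-space cap.
#' @return list with \code{auc}, \code{aupr}, \code{scores}, \code{labels},
#'   \code{fold} assignments and the selected \code{C} per fold.
#' @export
crossValidate <- function(pairs, descriptors, mode = "diff-common",
                          folds = 5L, Cgrid = 1, penalty = "l1", seed = 1L,
                          cap = NULL) {
  if (folds < 2L) .stopf("folds must be >= 2")
  n <- nrow(pairs)
  fold <- .with_seed(seed, sample(rep_len(seq_len(folds), n)))
  if (any(tapply(pairs$label, fold, function(l) sum(l == 1L)) == 0)) {
    .stopf("a fold has no positive pairs; use a larger dataset or fewer folds")
  }
  scores <- numeric(n)
  sel_C <- numeric(folds)
  space <- featureSpace(descriptors, cap = cap)
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    Xtr <- pairFeatureMatrix(pairs[tr, ], descriptors, mode, space)
    ytr <- pairs$label[tr]
    Cbest <- Cgrid[1]
    if (length(Cgrid) > 1L) {
      inner <- .with_seed(seed + f, sample(rep_len(seq_len(5L), length(tr))))
      val <- inner == 1L
      if (sum(ytr[val] == 1L) > 0L && length(unique(ytr[!val])) == 2L) {
        best_aupr <- -Inf
        for (Cc in Cgrid) {
          m <- trainLinearSvm(Xtr[!val, , drop = FALSE], ytr[!val], C = Cc,
                              penalty = penalty, mode = mode)
          a <- auPR(scorePairs(m, Xtr[val, , drop = FALSE]), ytr[val])
          if (a > best_aupr) { best_aupr <- a; Cbest <- Cc }
        }
      }
    }
    sel_C[f] <- Cbest
    model <- trainLinearSvm(Xtr, ytr, C = Cbest, penalty = penalty, mode = mode)
    Xte <- pairFeatureMatrix(pairs[te, ], descriptors, mode, space)
    scores[te] <- scorePairs(model, Xte)
  }
  list(auc = aucROC(scores, pairs$label),
       aupr = auPR(scores, pairs$label),
       scores = scores, labels = pairs$label, fold = fold, C = sel_C)
}
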