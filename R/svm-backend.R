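#' Linear support vector machine (C-SVM)
#'
#' Fits a linear soft-margin C-parameterised SVM by dual coordinate descent.
#' Multi-class problems are handled one-vs-one with majority voting; ties are
#' broken in favour of the lowest class index. The intercept is obtained
#' through an augmented constant feature and is therefore weakly regularised,
#' as in the liblinear formulation.
#'
#' @param x numeric matrix, exemplars in rows, features in columns.
#' @param y class labels (coerced to integer codes of `sort(unique(y))`).
#' @param cost soft-margin cost parameter C (default 1, the standard
#'   field default for linear ERP decoding).
#' @param tol convergence tolerance on the projected dual gradient.
#' @param max_iter maximum number of coordinate-descent epochs.
#' @return an object of class `linear_svm` with per-pair weight vectors
#'   (`w`, features x pairs), intercepts `b`, the class codes, and the pair
#'   table. Binary fits expose `weights(fit)` as a single vector.
#' @seealso [linear_svr()]
#' @export
linear_svm <- function(x, y, cost = 1, tol = 1e-3, max_iter = 2000) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), cost > 0)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  code <- match(y, classes)
  pairs <- utils::combn(length(classes), 2)
  d <- ncol(x)
  W <- matrix(0, d, ncol(pairs))
  b <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i1 <- pairs[1, p]; i2 <- pairs[2, p]
    sel <- code == i1 | code == i2
    xs <- cbind(x[sel, , drop = FALSE], 1)      # augmented bias feature
    ys <- ifelse(code[sel] == i1, 1, -1)        # lower class index -> +1
    fit <- .dcd_svc(xs, ys, cost, tol, max_iter)
    W[, p] <- fit$w[seq_len(d)]
    b[p] <- fit$w[d + 1L]
  }
  structure(list(w = W, b = b, pairs = pairs, classes = classes,
                 cost = cost, n_features = d),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "vote", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$n_features)
  scores <- newdata %*% object$w + matrix(object$b, nrow(newdata), length(object$b), byrow = TRUE)
  if (type == "decision") return(scores)
  nc <- length(object$classes)
  votes <- matrix(0L, nrow(newdata), nc)
  for (p in seq_len(ncol(object$pairs))) {
    i1 <- object$pairs[1, p]; i2 <- object$pairs[2, p]
    win <- ifelse(scores[, p] >= 0, i1, i2)     # boundary goes to lower index
    votes[cbind(seq_len(nrow(newdata)), win)] <- votes[cbind(seq_len(nrow(newdata)), win)] + 1L
  }
  if (type == "vote") return(votes)
  object$classes[apply(votes, 1, which.max)]    # which.max ties -> lowest index
}

#' Linear support vector regression (epsilon-SVR)
#'
#' Fits linear epsilon-insensitive support vector regression (L1 loss) by
#' dual coordinate descent, in the standard C-parameterised formulation.
#'
#' @inheritParams linear_svm
#' @param y numeric response, one value per exemplar.
#' @param cost cost parameter C; the field default for ERP regression is 0.1.
#' @param epsilon width of the insensitive tube (default 0.1).
#' @return object of class `linear_svr` with `w` (feature weights) and `b`.
#' @export
linear_svr <- function(x, y, cost = 0.1, epsilon = 0.1, tol = 1e-4, max_iter = 2000) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), cost > 0, epsilon >= 0)
  d <- ncol(x)
  xs <- cbind(x, 1)
  fit <- .dcd_svr(xs, as.numeric(y), cost, epsilon, tol, max_iter)
  structure(list(w = fit$w[seq_len(d)], b = fit$w[d + 1L],
                 cost = cost, epsilon = epsilon, n_features = d),
            class = "linear_svr")
}

#' @export
predict.linear_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$w + object$b)
}

#' Extract the primal weight vector of a linear fit
#'
#' @param fit a `linear_svm` (binary) or `linear_svr` fit.
#' @return numeric vector of feature weights (intercept excluded).
#' @export
weights_of <- function(fit) {
  if (inherits(fit, "linear_svr")) return(fit$w)
  if (inherits(fit, "linear_svm")) {
    if (ncol(fit$w) == 1L) return(drop(fit$w))
    return(fit$w)
  }
  stop("not a linear_svm / linear_svr fit", call. = FALSE)
}
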