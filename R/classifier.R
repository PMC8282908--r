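#' Fit a linear support vector machine with a signed decision score
#'
#' Thin wrapper around `e1071::svm` (libsvm) with a linear kernel and fixed
#' cost 1 (no per-fold tuning, for determinism inside leave-one-out loops).
#' The fitted hyperplane is extracted as a weight vector and offset so the
#' decision value `x . w - b` is cheap to evaluate; the sign convention is
#' fixed so positive scores indicate the positive (target) class.
#'
#' @param x Feature matrix `[n x p]`.
#' @param y Vector coercible to a 2-level factor; the level named `"pos"`
#'   (or the first level otherwise) is the positive class.
#' @param cost Soft-margin constant `C` (default 1).
#' @return A list of class `linear_classifier` with `w`, `b`, `levels`.
#' @export
fit_linear_classifier <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  f <- factor(y)
  if (nlevels(f) != 2) stop("need exactly 2 classes")
  if ("pos" %in% levels(f)) f <- stats::relevel(f, "pos")
  fit <- e1071::svm(x, f, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- fit$rho
  s <- drop(x %*% w) - b
  # libsvm's internal +1 class is the first label it encounters, not the
  # first factor level; orient so the positive class scores higher
  if (mean(s[f == levels(f)[1]]) < mean(s[f != levels(f)[1]])) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, levels = levels(f)), class = "linear_classifier")
}

#' Signed decision values of a linear classifier
#'
#' @param clf A `linear_classifier`.
#' @param x Feature matrix (or single feature vector).
#' @return Numeric vector of signed scores; positive means the positive
#'   class.
#' @export
decision_values <- function(clf, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  drop(x %*% clf$w) - clf$b
}
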