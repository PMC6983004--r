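## Training objective: focal classification loss + smooth-L1 box regression.

#' Focal loss
#'
#' Sum over contributing anchor-class entries of
#' `-alpha_t (1 - p_t)^gamma log(p_t)`, with `p_t = p` where `y = 1` and
#' `1 - p` where `y = 0`, and `alpha_t = alpha` for positives,
#' `1 - alpha` for negatives, normalised by the number of positive entries
#' (floored at 1). With `gamma = 0, alpha = 0.5` this is exactly half the
#' binary cross-entropy under the same normalisation. Entries labelled
#' ignore must be excluded before calling.
#'
#' @param p predicted probabilities in (0,1); values outside are clamped to
#'   `[1e-7, 1 - 1e-7]` with a warning.
#' @param y binary targets (0/1), same shape as `p`.
#' @param alpha,gamma focal parameters; defaults 0.25 and 2.
#' @param normalizer optional explicit divisor; default
#'   `max(1, sum(y == 1))`.
#' @return Scalar loss.
#' @export
focalLoss <- function(p, y, alpha = 0.25, gamma = 2, normalizer = NULL) {
  if (any(p <= 0) || any(p >= 1)) {
    warning("probabilities outside (0,1) clamped to [1e-7, 1-1e-7]")
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  }
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  norm <- if (is.null(normalizer)) max(1, sum(y == 1)) else normalizer
  sum(-at * (1 - pt)^gamma * log(pt)) / norm
}

# loss and gradient w.r.t. logits for training; labels y in {0,1}, an
# `exclude` mask drops ignore entries; everything divided by `norm`.
focalLossGrad <- function(z, y, alpha, gamma, norm, exclude = NULL) {
  p <- 1 / (1 + exp(-z))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  term <- -at * (1 - pt)^gamma * log(pt)
  # d/dz with s = +1 for y=1 and -1 for y=0 (dp_t/dz = s * p_t(1-p_t)):
  # dL/dz = -at * s * (1-pt)^gamma * [ (1-pt) - gamma * pt * log(pt) ]
  s <- ifelse(y == 1, 1, -1)
  grad <- -at * s * (1 - pt)^gamma * ((1 - pt) - gamma * pt * log(pt))
  if (!is.null(exclude)) { term[exclude] <- 0; grad[exclude] <- 0 }
  list(loss = sum(term) / norm, grad = grad / norm)
}

#' Box regression loss over positive anchors
#'
#' Default mode is the standard smooth-L1 (Huber with delta 1) applied per
#' offset coordinate, summed per anchor and averaged over positive anchors.
#' `"focal_as_stated"` has no defined continuous form and raises an error
#' rather than inventing semantics.
#'
#' @param pred,target numeric n x 4 matrices of offsets for the positive
#'   anchors (zero rows allowed).
#' @param mode `"smooth_l1"` (default) or `"focal_as_stated"`.
#' @return Scalar loss; 0 when there are no positive anchors.
#' @export
regressionLoss <- function(pred, target, mode = c("smooth_l1", "focal_as_stated")) {
  mode <- match.arg(mode)
  if (mode == "focal_as_stated")
    stop("regression_mode 'focal_as_stated' is intentionally unimplemented: ",
         "a focal loss has no standard form for continuous regression ",
         "targets; use 'smooth_l1'")
  pred <- rbind(pred); target <- rbind(target)
  n <- nrow(pred)
  if (is.null(n) || n == 0L) return(0)
  e <- pred - target
  l <- ifelse(abs(e) < 1, 0.5 * e^2, abs(e) - 0.5)
  sum(l) / n
}

# gradient of the above w.r.t. pred (same normalisation)
regressionLossGrad <- function(pred, target) {
  n <- nrow(pred)
  if (is.null(n) || n == 0L) return(list(loss = 0, grad = pred * 0))
  e <- pred - target
  l <- ifelse(abs(e) < 1, 0.5 * e^2, abs(e) - 0.5)
  g <- ifelse(abs(e) < 1, e, sign(e))
  list(loss = sum(l) / n, grad = g / n)
}

#' Total training loss
#'
#' Unweighted sum of the classification and regression components.
#'
#' @param cls_loss,reg_loss finite scalars.
#' @return Their sum.
#' @export
totalLoss <- function(cls_loss, reg_loss) {
  if (!is.finite(cls_loss) || !is.finite(reg_loss))
    stop(sprintf("non-finite loss component (cls=%g, reg=%g); training diverged",
                 cls_loss, reg_loss))
  cls_loss + reg_loss
}

#' Loss configuration
#'
#' @param alpha focal class weight in (0,1); default 0.25.
#' @param gamma focal focusing exponent >= 0; default 2.
#' @param regression_mode see [regressionLoss()].
#' @return list of class `"LossConfig"`.
#' @export
lossConfig <- function(alpha = 0.25, gamma = 2.0,
                       regression_mode = c("smooth_l1", "focal_as_stated")) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(alpha = alpha, gamma = gamma,
                 regression_mode = match.arg(regression_mode)),
            class = "LossConfig")
}
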