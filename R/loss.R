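#' Count-derived class weights
#'
#' As specified, each class weight is proportional to its instance count
#' (`alpha_i = Count_i / sum(Count)`). Because that up-weights the majority
#' class, the conventional inverse-frequency weighting is available through
#' `weighting = "inverse"` (`alpha_i` proportional to `1 / Count_i`,
#' normalized; zero-count classes get the largest weight among observed
#' classes).
#'
#' @param counts Non-negative per-class counts, at least one positive.
#' @param weighting `"printed"` (proportional to counts) or `"inverse"`.
#' @return Numeric vector of weights summing to 1, named like `counts`.
#' @export
class_weights <- function(counts, weighting = c("printed", "inverse")) {
  weighting <- match.arg(weighting)
  if (any(counts < 0) || sum(counts) == 0) {
    rlang::abort("counts must be non-negative with a positive total")
  }
  w <- if (weighting == "printed") {
    counts / sum(counts)
  } else {
    inv <- ifelse(counts > 0, 1 / counts, NA_real_)
    inv[is.na(inv)] <- max(inv, na.rm = TRUE)
    inv / sum(inv)
  }
  stats::setNames(as.numeric(w), names(counts))
}

#' Multi-class focal loss
#'
#' For an instance with true class y and predicted probability
#' `p_t = p[y]`, the default (`focal_form = "true_class"`) loss is
#' `-alpha_y * (1 - p_t)^gamma * log(p_t)`; the batch loss is the mean over
#' instances. `focal_form = "printed_sum"` uses
#' `-(sum_i alpha_i / m) * (1 - p_t)^gamma * log(p_t)`, a constant
#' rescaling when the weights sum to 1. Probabilities of 0 are clamped to
#' 1e-12 with a warning.
#'
#' @param prob Numeric matrix `n x m` of class probabilities (or a single
#'   probability row).
#' @param labels Integer class indices in `1..m` (or a factor whose level
#'   order matches the columns of `prob`).
#' @param alpha Numeric class weights of length m.
#' @param gamma Focusing parameter (default 2).
#' @param focal_form `"true_class"` or `"printed_sum"`.
#' @return The scalar batch loss.
#' @export
multi_focal_loss <- function(prob, labels, alpha, gamma = 2,
                             focal_form = c("true_class", "printed_sum")) {
  focal_form <- match.arg(focal_form)
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1L)
  if (is.factor(labels)) labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(prob), length(alpha) == ncol(prob),
            gamma >= 0)
  pt <- prob[cbind(seq_len(nrow(prob)), labels)]
  if (any(pt <= 0)) {
    rlang::warn("clamping zero probabilities to 1e-12")
    pt <- pmax(pt, 1e-12)
  }
  coef <- if (focal_form == "true_class") {
    alpha[labels]
  } else {
    rep(sum(alpha) / length(alpha), length(labels))
  }
  mean(-coef * (1 - pt)^gamma * log(pt))
}

# AD focal loss from a 1 x m score node: softmax -> pick true class ->
# focal modulation. Returns a 1 x 1 node.
focal_loss_ad <- function(scores, y, alpha, gamma = 2,
                          focal_form = "true_class") {
  p <- ad_softmax_rows(scores)
  pt <- ad_clamp_min(ad_pick(p, 1L, y), 1e-12)
  om <- ad_sub(ad_const(matrix(1, 1L, 1L)), pt)
  coef <- if (focal_form == "true_class") {
    alpha[y]
  } else {
    sum(alpha) / length(alpha)
  }
  ad_scale(ad_mul(ad_pow(om, gamma), ad_log(pt)), -coef)
}
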