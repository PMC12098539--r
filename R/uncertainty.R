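# Transformation-based uncertainty estimation: Monte-Carlo dropout entropy of
# the teacher's averaged prediction, a seven-transform agreement confidence
# map, the boolean masks derived from both, and the masked consistency loss.

#' Monte-Carlo predictive entropy of the teacher
#'
#' Runs `T` stochastic forward passes (dropout active), averages the softmax
#' probabilities per pixel, and returns the entropy of the averaged
#' distribution (natural logarithm).
#'
#' @param model a `semiseg_model` (teacher)
#' @param image H x W x C array
#' @param T number of Monte-Carlo passes (>= 1)
#' @param params optional parameter override (the teacher's EMA values)
#' @return H x W entropy map, bounded by `log(n_classes)`
#' @export
mc_entropy <- function(model, image, T = 8L, params = model$params) {
  if (T < 1L) stop("T must be >= 1")
  probs <- NULL
  for (t in seq_len(T)) {
    p <- predict_probs(model, image, dropout = TRUE, params = params)
    probs <- if (is.null(probs)) p else probs + p
  }
  probs <- probs / T
  entropy_map(probs)
}

# per-pixel entropy of a probability array (0 log 0 = 0)
entropy_map <- function(probs) {
  pl <- probs * log(pmax(probs, .Machine$double.xmin))
  pl[probs == 0] <- 0
  -apply(pl, c(1, 2), sum)
}

#' Entropy-based confidence mask
#'
#' @param q_e H x W entropy map
#' @param xi_e entropy threshold (> 0); pixels with `q_e < xi_e` (strictly)
#'   are marked confident
#' @return H x W logical matrix
#' @export
entropy_mask <- function(q_e, xi_e) {
  if (xi_e <= 0) stop("xi_e must be positive")
  q_e < xi_e
}

#' Transformation-agreement confidence maps
#'
#' For each of the `M` transformations in `suite`: transform the image, run a
#' deterministic teacher pass, invert the prediction, and take the arg-max
#' class per pixel. `Q_T[i, j, c]` is the fraction of transformations voting
#' class `c` at that pixel (values in `{0, 1/M, ..., 1}`).
#'
#' @param model a `semiseg_model` (teacher); dropout is kept off
#' @param image H x W x C array
#' @param suite list of `transform_spec` from [transform_suite()]
#' @param params optional parameter override
#' @return H x W x n_classes array of vote fractions
#' @export
transform_confidence <- function(model, image, suite, params = model$params) {
  M <- length(suite)
  d <- dim(image)
  nc <- model$config$n_classes
  votes <- array(0, c(d[1], d[2], nc))
  for (spec in suite) {
    ti <- apply_transform(spec, image)
    p <- predict_probs(model, ti, dropout = FALSE, params = params)
    p <- invert_on_prediction(spec, p)
    cls <- argmax_class(p)
    for (c in seq_len(nc)) votes[, , c] <- votes[, , c] + (cls == c)
  }
  votes / M
}

# per-pixel arg-max class (1-based; first class wins ties)
argmax_class <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first"), d[1], d[2])
}

#' Transformation-confidence mask
#'
#' Marks a pixel confident when its strongest class was voted by a fraction
#' of transformations strictly greater than `xi_t`.
#'
#' @param q_t H x W x n_classes vote-fraction array from
#'   [transform_confidence()]
#' @param xi_t agreement threshold in `(0, 1]`
#' @return H x W logical matrix
#' @export
transform_mask <- function(q_t, xi_t) {
  if (xi_t <= 0 || xi_t > 1) stop("xi_t must be in (0, 1]")
  apply(q_t, c(1, 2), max) > xi_t
}

#' Combined uncertainty maps for one tile
#'
#' Convenience wrapper computing the entropy map (`T` Monte-Carlo passes),
#' the transformation-confidence maps, both masks, and their pixel-wise AND.
#'
#' @inheritParams mc_entropy
#' @param suite list of `transform_spec`
#' @param xi_e entropy threshold
#' @param xi_t agreement threshold
#' @return an `uncertainty_maps` list: `Q_e`, `Q_T`, `mask_E`, `mask_T`,
#'   `mask`
#' @export
uncertainty_maps <- function(model, image, suite, xi_e, xi_t, T = 8L,
                             params = model$params) {
  q_e <- mc_entropy(model, image, T = T, params = params)
  q_t <- transform_confidence(model, image, suite, params = params)
  m_e <- entropy_mask(q_e, xi_e)
  m_t <- transform_mask(q_t, xi_t)
  structure(list(Q_e = q_e, Q_T = q_t, mask_E = m_e, mask_T = m_t,
                 mask = m_e & m_t),
            class = "uncertainty_maps")
}

# autodiff path of the masked consistency loss; p_s may be a graph node
ag_consistency_loss <- function(p_s, p_t, mask) {
  p_s <- as_ag(p_s)
  d <- dim(ag_value(p_s))
  m <- sum(mask)
  if (m == 0) return(ag_const(0))
  mrep <- array(rep(as.numeric(mask), times = d[3]), d)
  diff <- ag_sub(p_s, ag_const(ag_value(as_ag(p_t))))
  ag_div(ag_sum(ag_mul(ag_mul(diff, diff), ag_const(mrep))), ag_const(m))
}

#' Masked consistency loss
#'
#' Mean over masked pixels of the squared Euclidean distance between the
#' student's and teacher's per-pixel probability vectors. An all-zero mask
#' contributes 0 (guarded; no division by zero).
#'
#' @param p_s student probabilities, H x W x n_classes
#' @param p_t teacher probabilities, same shape
#' @param mask H x W logical or 0/1 matrix
#' @return scalar loss
#' @export
consistency_loss <- function(p_s, p_t, mask) {
  if (!all(dim(ag_value(as_ag(p_s))) == dim(ag_value(as_ag(p_t)))))
    stop("student and teacher predictions must share a shape")
  ag_no_grad(ag_value(ag_consistency_loss(p_s, p_t, mask)))
}
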