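# Multi-scale class-prototype contrastive learning: 1x1 projection heads per
# decoder scale, probability-weighted class prototypes, an InfoNCE-style
# prototype loss per scale (implemented exactly as the printed five-term
# form), and the weighted multi-scale combination.

#' Contrastive-learning configuration
#'
#' @param D number of decoder scales used (finest first)
#' @param beta per-scale loss weights, finest first; must sum to 1
#' @param tau InfoNCE temperature
#' @param C_out projection channel count
#' @param symmetric_denominator add the (Q_ca, V_ca) same-class term to the
#'   denominator (textbook-InfoNCE variant); the printed five-term form omits
#'   it, so the default is `FALSE`
#' @return a `contrastive_config` list
#' @export
contrastive_config <- function(D = 3L, beta = c(0.6, 0.3, 0.1), tau = 0.1,
                               C_out = 64L, symmetric_denominator = FALSE) {
  if (length(beta) != D) stop("beta must have length D")
  if (abs(sum(beta) - 1) > 1e-9) stop("beta must sum to 1")
  if (tau <= 0) stop("tau must be positive")
  structure(list(D = as.integer(D), beta = beta, tau = tau,
                 C_out = as.integer(C_out),
                 symmetric_denominator = isTRUE(symmetric_denominator)),
            class = "contrastive_config")
}

#' Project a feature map with a scale's 1x1 head
#'
#' @param feature_map H_d x W_d x C_d array (or graph node)
#' @param w,b projection parameters: `w` a (C_d x C_out) matrix (1x1-conv
#'   weight in im2col layout), `b` length C_out
#' @return projected map with `C_out` channels, spatial size unchanged
#' @export
project_features <- function(feature_map, w, b) {
  out <- ag_conv2d(as_ag(feature_map), as_ag(w), as_ag(b), 1L)
  if (is_ag(feature_map) || is_ag(w)) out else ag_value(out)
}

# autodiff path: probability-weighted mean feature vector of one class
ag_prototype <- function(projected, class_prob) {
  num <- ag_chan_sum(ag_mul_spatial(projected, class_prob))
  den <- ag_sum(class_prob)
  ag_div(num, den)
}

#' Class prototypes at one scale
#'
#' Probability-weighted average of projected feature vectors per class:
#' `Q_c = sum_n F'_n * P_c,n / sum_n P_c,n`. A class with zero total
#' probability mass yields an absent (`NULL`) prototype.
#'
#' @param projected H x W x C_out array of projected features
#' @param class_probs H x W x 2 per-pixel class probabilities (background
#'   first, tumor second)
#' @return list with `bg` and `ca` prototype vectors (length C_out) or `NULL`
#'   when the class mass is zero
#' @export
class_prototype <- function(projected, class_probs) {
  pr <- as_ag(projected)
  grad_in <- is_ag(projected) || is_ag(class_probs)
  get_proto <- function(c) {
    pc_val <- ag_value(as_ag(class_probs))[, , c]
    if (sum(pc_val) == 0) return(NULL)
    pc <- if (is_ag(class_probs)) ag_slice_c(class_probs, c) else ag_const(pc_val)
    proto <- ag_prototype(pr, pc)
    if (grad_in) proto else ag_value(proto)
  }
  list(bg = get_proto(1L), ca = get_proto(2L))
}

#' Prototype contrastive loss at one scale
#'
#' InfoNCE-style loss on the four prototypes with cosine similarity and
#' temperature `tau`, exactly in the printed five-term form:
#' numerator `exp(s(Qbg,Vbg)/tau) + exp(s(Qca,Vca)/tau)`; denominator
#' `exp(s(Qbg,Vbg)/tau) + exp(s(Qbg,Qca)/tau) + exp(s(Qbg,Vca)/tau) +
#'  exp(s(Vbg,Qca)/tau) + exp(s(Vbg,Vca)/tau)`.
#' With all four prototypes identical this is `-log(2/5)`.
#'
#' @param q_bg,q_ca teacher prototypes (treated as constants)
#' @param v_bg,v_ca student prototypes (may be graph nodes)
#' @param tau temperature
#' @param symmetric_denominator add `exp(s(Qca,Vca)/tau)` to the denominator
#' @return scalar loss (graph node if the inputs are nodes)
#' @export
scale_loss <- function(q_bg, q_ca, v_bg, v_ca, tau = 0.1,
                       symmetric_denominator = FALSE) {
  if (is.null(q_bg) || is.null(q_ca) || is.null(v_bg) || is.null(v_ca))
    stop("all four prototypes must be present")
  q_bg <- as_ag(ag_value(as_ag(q_bg)))  # teacher prototypes are constants
  q_ca <- as_ag(ag_value(as_ag(q_ca)))
  v_bg <- as_ag(v_bg); v_ca <- as_ag(v_ca)
  e <- function(a, b) ag_exp(ag_div(ag_cosine(a, b), tau))
  num <- ag_add(e(q_bg, v_bg), e(q_ca, v_ca))
  den <- ag_add(ag_add(ag_add(ag_add(e(q_bg, v_bg), e(q_bg, q_ca)),
                              e(q_bg, v_ca)), e(v_bg, q_ca)), e(v_bg, v_ca))
  if (symmetric_denominator) den <- ag_add(den, e(q_ca, v_ca))
  loss <- ag_neg(ag_log(ag_div(num, den)))
  if (is_ag_node(v_bg) || is_ag_node(v_ca)) loss else ag_value(loss)
}

# does this node carry gradient state (vs a plain wrapped constant)?
is_ag_node <- function(x) is_ag(x) && x$requires_grad

#' Weighted multi-scale combination
#'
#' @param per_scale_losses numeric vector (or list of graph nodes), finest
#'   scale first
#' @param beta weights, same length, summing to 1
#' @return weighted sum
#' @export
multiscale_loss <- function(per_scale_losses, beta) {
  if (length(per_scale_losses) != length(beta))
    stop("per-scale losses and beta lengths differ")
  if (abs(sum(beta) - 1) > 1e-9) stop("beta must sum to 1")
  if (is.list(per_scale_losses)) {
    total <- ag_const(0)
    for (d in seq_along(beta))
      total <- ag_add(total, ag_mul(as_ag(per_scale_losses[[d]]), beta[d]))
    total
  } else {
    sum(per_scale_losses * beta)
  }
}

# Full multi-scale contrastive loss for one unlabeled tile (autodiff path).
# Teacher quantities are constants; student quantities are graph nodes.
# Per-scale class probabilities are the seg-head softmax average-pooled down
# to scale d (differentiable on the student side), so the prototype weights
# reflect the actual segmentation. Scales where either model lacks a class's
# probability mass are skipped and the remaining beta weights renormalized.
ag_mscl_loss <- function(student_feats, teacher_feats, student_probs,
                         teacher_probs, params, teacher_values, ccfg) {
  D <- ccfg$D
  losses <- vector("list", D)
  usable <- logical(D)
  s_probs <- student_probs
  t_probs <- as_ag(teacher_probs)
  for (d in seq_len(D)) {
    if (d > 1L) {
      s_probs <- ag_avgpool2(s_probs)
      t_probs <- ag_avgpool2(t_probs)
    }
    sf <- student_feats[[d]]
    tf <- teacher_feats[[d]]
    s_proj <- ag_conv2d(sf, params[[sprintf("proj%d.w", d)]],
                        params[[sprintf("proj%d.b", d)]], 1L)
    tfv <- ag_value(as_ag(tf))
    t_proj <- ag_no_grad(ag_value(ag_conv2d(tfv,
                                            teacher_values[[sprintf("proj%d.w", d)]],
                                            teacher_values[[sprintf("proj%d.b", d)]], 1L)))
    t_probs_v <- ag_value(t_probs)
    tmass <- apply(t_probs_v, 3, sum)
    smass <- apply(ag_value(s_probs), 3, sum)
    if (any(tmass == 0) || any(smass == 0)) next
    qp <- class_prototype(t_proj, t_probs_v)
    vbg <- ag_prototype(s_proj, ag_slice_c(s_probs, 1L))
    vca <- ag_prototype(s_proj, ag_slice_c(s_probs, 2L))
    losses[[d]] <- scale_loss(qp$bg, qp$ca, vbg, vca, tau = ccfg$tau,
                              symmetric_denominator = ccfg$symmetric_denominator)
    usable[d] <- TRUE
  }
  if (!any(usable)) return(ag_const(0))
  b <- ccfg$beta[usable] / sum(ccfg$beta[usable])
  multiscale_loss(losses[usable], b)
}
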