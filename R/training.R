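# Mean-teacher semi-supervised training loop: EMA teacher updates, Gaussian
# ramp-up weighting, entropy/agreement threshold schedules, loss assembly
# (supervised Dice+CE, masked consistency, multi-scale contrastive) and SGD
# with momentum on the student only.

#' Training configuration
#'
#' Defaults follow the reference protocol: SGD with learning rate 0.01 and
#' momentum 0.9, EMA decay 0.99, 100 epochs, batch size 1 for both labeled
#' and unlabeled tiles.
#'
#' @param alpha_ema EMA decay of the teacher parameters, in `[0, 1]`
#' @param lambda weight of the unsupervised loss term (the ramp-up factor
#'   additionally scales it)
#' @param lr SGD learning rate
#' @param momentum SGD momentum coefficient
#' @param epochs training epochs
#' @param T_mc Monte-Carlo dropout passes for the entropy estimate
#' @param xi_t transformation-agreement threshold (constant over training)
#' @param patch_grid patch grid of the transform suite
#' @param seed integer seed controlling initialization and all stochastic
#'   draws of the run
#' @return a `train_config` list
#' @export
train_config <- function(alpha_ema = 0.99, lambda = 1.0, lr = 0.01,
                         momentum = 0.9, epochs = 100L, T_mc = 8L,
                         xi_t = 0.5, patch_grid = 4L, seed = 1L) {
  if (alpha_ema < 0 || alpha_ema > 1) stop("alpha_ema must be in [0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  if (lr <= 0 || momentum < 0 || momentum >= 1) stop("invalid optimizer settings")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(alpha_ema = alpha_ema, lambda = lambda, lr = lr,
                 momentum = momentum, epochs = as.integer(epochs),
                 T_mc = as.integer(T_mc), xi_t = xi_t,
                 patch_grid = as.integer(patch_grid),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Exponential-moving-average update of the teacher parameters
#'
#' `theta_T <- alpha * theta_T + (1 - alpha) * theta_S`, element-wise for
#' every parameter.
#'
#' @param teacher_values named list of teacher parameter arrays
#' @param student_params congruent named list (graph leaves or arrays)
#' @param alpha EMA decay
#' @return updated named list of teacher values
#' @export
ema_update <- function(teacher_values, student_params, alpha) {
  if (!identical(names(teacher_values), names(student_params)))
    stop("teacher and student parameter collections are not congruent")
  out <- teacher_values
  for (nm in names(out)) {
    sv <- ag_value(student_params[[nm]])
    if (!identical(dim(out[[nm]]), dim(sv)) ||
        length(out[[nm]]) != length(sv))
      stop("parameter shape mismatch at ", nm)
    out[[nm]] <- alpha * out[[nm]] + (1 - alpha) * sv
  }
  out
}

#' Gaussian ramp-up weight
#'
#' `omega(t) = 0.001 * exp(-5 * (1 - t / t_max)^2)`; rises monotonically to
#' its ceiling 0.001 at `t = t_max`.
#'
#' @param t current iteration, `0 <= t <= t_max`
#' @param t_max total iterations (> 0)
#' @return scalar weight
#' @export
rampup_weight <- function(t, t_max) {
  if (t_max <= 0) stop("t_max must be positive")
  0.001 * exp(-5 * (1 - t / t_max)^2)
}

#' Uncertainty-threshold schedule
#'
#' The entropy threshold ramps from `0.75 * log(2)` to `log(2)` following the
#' same Gaussian ramp shape as the unsupervised weight (normalized so the
#' endpoints are exact); the agreement threshold stays constant.
#'
#' @param t current iteration
#' @param t_max total iterations
#' @param xi_t constant transformation-agreement threshold
#' @return list with `xi_e` and `xi_t`
#' @export
threshold_schedule <- function(t, t_max, xi_t = 0.5) {
  if (t_max <= 0) stop("t_max must be positive")
  g <- function(u) exp(-5 * (1 - u / t_max)^2)
  frac <- (g(t) - g(0)) / (1 - g(0))
  list(xi_e = 0.75 * log(2) + 0.25 * log(2) * frac, xi_t = xi_t)
}

# autodiff supervised loss: mean of cross-entropy and Dice loss
ag_supervised_loss <- function(logits, labels, eps = 1e-5) {
  d <- dim(ag_value(as_ag(logits)))
  nc <- d[3]
  if (!all(labels %in% 0:(nc - 1L)))
    stop("labels contain classes outside 0..", nc - 1L)
  npix <- d[1] * d[2]
  onehot <- array(0, d)
  for (c in seq_len(nc)) onehot[, , c] <- labels == (c - 1L)
  ls <- ag_logsoftmax_c(logits)
  ce <- ag_neg(ag_div(ag_sum(ag_mul(ls, ag_const(onehot))), npix))
  p_fg <- ag_slice_c(ag_exp(ls), nc)   # tumor = last class
  y <- (labels == (nc - 1L)) * 1
  inter <- ag_sum(ag_mul(p_fg, ag_const(y)))
  dice <- ag_div(ag_add(ag_mul(inter, 2), eps),
                 ag_add(ag_add(ag_sum(p_fg), sum(y)), eps))
  ag_mul(ag_add(ce, ag_sub(1, dice)), 0.5)
}

#' Supervised segmentation loss
#'
#' Average of pixel-wise cross-entropy and the Dice loss on the softmax
#' tumor probability (smoothing `eps`).
#'
#' @param logits H x W x n_classes array of seg-head outputs
#' @param labels H x W matrix of class indices (0 = background, 1 = tumor)
#' @param eps Dice smoothing constant
#' @return scalar loss
#' @export
supervised_loss <- function(logits, labels, eps = 1e-5) {
  ag_no_grad(ag_value(ag_supervised_loss(logits, labels, eps)))
}

#' Initialize the mean-teacher training state
#'
#' The teacher starts as an exact copy of the student.
#'
#' @param model a `semiseg_model` (the student)
#' @param t_max total number of iterations of the planned run
#' @return a `train_state` list
#' @export
init_train_state <- function(model, t_max) {
  structure(list(teacher = param_values(model$params),
                 velocity = lapply(model$params, function(p) ag_value(p) * 0),
                 t = 0L, t_max = t_max),
            class = "train_state")
}

sgd_step <- function(params, velocity, lr, momentum) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    velocity[[nm]] <- momentum * velocity[[nm]] + p$grad
    p$value <- p$value - lr * velocity[[nm]]
  }
  velocity
}

#' One mean-teacher training step
#'
#' Computes the supervised loss on the labeled tile; on the unlabeled tile
#' computes the combined uncertainty mask, the masked consistency loss and
#' the multi-scale contrastive loss; backpropagates the total through the
#' student only; applies SGD with momentum and then the EMA teacher update.
#'
#' @param model the student `semiseg_model`
#' @param state a `train_state`
#' @param labeled an `image_sample` with a mask
#' @param unlabeled an `image_sample` (mask ignored), or `NULL` for a purely
#'   supervised step
#' @param tcfg a [train_config()]
#' @param ccfg a [contrastive_config()]
#' @return list with the updated `state` and a `breakdown` row (all loss
#'   components, the ramp-up weight and thresholds, and the mask occupancy)
#' @export
train_step <- function(model, state, labeled, unlabeled, tcfg,
                       ccfg = contrastive_config()) {
  if (is.null(labeled) || is.null(labeled$mask)) stop("labeled batch is empty")
  t <- state$t + 1L
  omega <- rampup_weight(t, state$t_max)
  th <- threshold_schedule(t, state$t_max, tcfg$xi_t)
  fp_l <- model_forward(model, labeled$image, dropout = TRUE)
  l_s <- ag_supervised_loss(fp_l$logits, labeled$mask)
  mask_frac <- NA_real_
  if (!is.null(unlabeled) && tcfg$lambda > 0) {
    q_e <- mc_entropy(model, unlabeled$image, T = tcfg$T_mc,
                      params = state$teacher)
    suite <- transform_suite(seed = sample.int(.Machine$integer.max, 1L),
                             patch_grid = tcfg$patch_grid)
    q_t <- transform_confidence(model, unlabeled$image, suite,
                                params = state$teacher)
    mask <- entropy_mask(q_e, th$xi_e) & transform_mask(q_t, th$xi_t)
    mask_frac <- mean(mask)
    fp_t <- ag_no_grad(model_forward(model, unlabeled$image, dropout = FALSE,
                                     params = state$teacher))
    p_t <- ag_no_grad(ag_value(ag_softmax_c(fp_t$logits)))
    fp_s <- model_forward(model, unlabeled$image, dropout = TRUE)
    p_s <- ag_softmax_c(fp_s$logits)
    l_csy <- ag_consistency_loss(p_s, p_t, mask)
    l_mscl <- ag_mscl_loss(fp_s$decoder_feats, fp_t$decoder_feats,
                           p_s, p_t, model$params, state$teacher, ccfg)
  } else {
    l_csy <- ag_const(0)
    l_mscl <- ag_const(0)
  }
  l_u <- ag_mul(ag_add(l_csy, l_mscl), omega)
  l_total <- ag_add(l_s, ag_mul(l_u, tcfg$lambda))
  ag_zero_grad(model$params)
  ag_backward(l_total)
  state$velocity <- sgd_step(model$params, state$velocity, tcfg$lr,
                             tcfg$momentum)
  state$teacher <- ema_update(state$teacher, model$params, tcfg$alpha_ema)
  state$t <- t
  breakdown <- data.frame(t = t,
                          L_s = ag_value(l_s),
                          L_csy = ag_value(l_csy),
                          L_mscl = ag_value(l_mscl),
                          omega = omega,
                          L_u = ag_value(l_u),
                          L_total = ag_value(l_total),
                          xi_e = th$xi_e, xi_t = th$xi_t,
                          mask_frac = mask_frac)
  list(state = state, breakdown = breakdown)
}

#' Train a model on a labeled/unlabeled/validation split
#'
#' Runs the mean-teacher loop for `tcfg$epochs` epochs with per-step batch
#' parity (one labeled and one unlabeled tile per iteration), logs every loss
#' component, evaluates the validation Dice score each epoch and returns the
#' parameters of the epoch with the highest validation DSC.
#'
#' @param samples list of `image_sample` (must cover all split ids)
#' @param split list with character vectors `labeled`, `unlabeled`, `val`
#' @param mcfg a [model_config()]
#' @param tcfg a [train_config()]
#' @param ccfg a [contrastive_config()]
#' @param boundary build the full boundary-aware model (`TRUE`) or the plain
#'   backbone (`FALSE`)
#' @param val_every validate (and consider checkpointing) every `val_every`
#'   epochs; lets studies with different epoch lengths keep an equal
#'   model-selection budget
#' @param verbose print one line per epoch
#' @return a `semiseg_fit`: `model` (student, final weights), `best_params`
#'   (values at the best validation epoch), `best_dsc`, `history` (per-epoch
#'   validation DSC), `log` (per-step loss breakdowns), and the config echo
#' @export
fit_semiseg <- function(samples, split, mcfg = model_config(),
                        tcfg = train_config(), ccfg = contrastive_config(),
                        boundary = TRUE, val_every = 1L, verbose = FALSE) {
  if (length(split$labeled) == 0L) stop("no labeled data in split")
  by_id <- stats::setNames(samples, vapply(samples, function(s) s$id, character(1)))
  missing <- setdiff(unlist(split[c("labeled", "unlabeled", "val")]), names(by_id))
  if (length(missing) > 0L) stop("split refers to unknown ids: ",
                                 paste(missing, collapse = ", "))
  with_seed(tcfg$seed, {
    model <- if (boundary) build_model(mcfg, seed = sample.int(1e6, 1L))
             else build_backbone(mcfg, seed = sample.int(1e6, 1L))
    n_lab <- length(split$labeled)
    n_unl <- length(split$unlabeled)
    semi <- n_unl > 0L && tcfg$lambda > 0
    steps <- if (semi) max(n_lab, n_unl) else n_lab
    t_max <- tcfg$epochs * steps
    state <- init_train_state(model, t_max)
    log <- list()
    history <- data.frame(epoch = integer(0), val_dsc = numeric(0))
    best_dsc <- -Inf
    best_params <- param_values(model$params)
    for (ep in seq_len(tcfg$epochs)) {
      lab_order <- split$labeled[sample.int(n_lab)]
      unl_order <- if (semi) split$unlabeled[sample.int(n_unl)] else character(0)
      for (s in seq_len(steps)) {
        lab <- by_id[[lab_order[((s - 1L) %% n_lab) + 1L]]]
        unl <- if (semi) by_id[[unl_order[((s - 1L) %% n_unl) + 1L]]] else NULL
        res <- train_step(model, state, lab, unl, tcfg, ccfg)
        state <- res$state
        log[[length(log) + 1L]] <- res$breakdown
      }
      if (ep %% val_every != 0L && ep != tcfg$epochs) next
      val_dsc <- validation_dsc(model, by_id[split$val])
      history <- rbind(history, data.frame(epoch = ep, val_dsc = val_dsc))
      if (!is.na(val_dsc) && val_dsc > best_dsc) {
        best_dsc <- val_dsc
        best_params <- param_values(model$params)
      }
      if (verbose)
        message(sprintf("epoch %d/%d  val DSC %.4f", ep, tcfg$epochs, val_dsc))
    }
    structure(list(model = model, best_params = best_params,
                   best_dsc = best_dsc, history = history,
                   log = do.call(rbind, log),
                   config = list(model = mcfg, train = tcfg,
                                 contrastive = ccfg, boundary = boundary)),
              class = "semiseg_fit")
  })
}

# mean validation DSC at full resolution with arg-max predictions
validation_dsc <- function(model, val_samples, params = model$params) {
  if (length(val_samples) == 0L) return(NA_real_)
  vals <- vapply(val_samples, function(s) {
    pred <- predict_mask(model, s$image, params = params)
    metric_dsc(pred, s$mask)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Predict a binary tumor mask for one tile
#'
#' Deterministic forward pass followed by per-pixel arg-max.
#'
#' @inheritParams model_forward
#' @return H x W integer matrix in `{0, 1}`
#' @export
predict_mask <- function(model, image, params = model$params) {
  p <- predict_probs(model, image, dropout = FALSE, params = params)
  cls <- argmax_class(p) - 1L
  matrix(as.integer(cls), nrow(cls), ncol(cls))
}
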