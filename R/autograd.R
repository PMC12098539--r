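# Tape-based reverse-mode automatic differentiation on dense numeric arrays.
# Nodes are environments so gradients accumulate by reference; the graph is
# built eagerly as ops execute and freed when the step's nodes go out of scope.

.ag <- new.env(parent = emptyenv())
.ag$grad_enabled <- TRUE
.ag$next_id <- 0L

#' Evaluate an expression with gradient recording disabled
#'
#' Used for teacher-model forward passes and any inference path: ops executed
#' inside return constant nodes with no parents, so no graph is retained.
#'
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  expr
}

new_ag <- function(value, parents = list(), backfn = NULL, requires_grad = FALSE,
                   is_leaf = length(parents) == 0L && is.null(backfn)) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$requires_grad <- requires_grad
  e$is_leaf <- is_leaf
  e$grad <- NULL
  .ag$next_id <- .ag$next_id + 1L
  e$id <- .ag$next_id
  class(e) <- "ag_tensor"
  e
}

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor", if (is.null(d)) paste0("len ", length(x$value)) else paste(d, collapse = "x"),
      if (x$requires_grad) "grad" else "const", ">\n")
  invisible(x)
}

is_ag <- function(x) inherits(x, "ag_tensor")

# Trainable leaf.
ag_param <- function(value) new_ag(value, requires_grad = TRUE)

# Constant (no gradient ever flows into it).
ag_const <- function(value) new_ag(value)

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

ag_value <- function(x) if (is_ag(x)) x$value else x

# Create an op node. `backfn(g)` must return a list of gradients aligned with
# `parents` (entries for constant parents may be NULL). If recording is off or
# no parent needs a gradient the graph edge is dropped.
ag_op <- function(value, parents, backfn) {
  rg <- .ag$grad_enabled &&
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  if (!rg) return(new_ag(value))
  new_ag(value, parents = parents, backfn = backfn, requires_grad = TRUE,
         is_leaf = FALSE)
}

#' Backpropagate from a scalar node
#'
#' Accumulates gradients into every reachable node with `requires_grad = TRUE`.
#'
#' @param node terminal `ag_tensor` (typically the scalar loss)
#' @param grad seed gradient; defaults to 1 for scalars
#' @keywords internal
ag_backward <- function(node, grad = NULL) {
  stopifnot(is_ag(node))
  if (is.null(grad)) {
    stopifnot(length(node$value) == 1L)
    grad <- 1
  }
  # iterative topological sort (post-order DFS)
  topo <- vector("list", 256L); nt <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(n = node, i = 0L)); ns <- 1L
  assign(as.character(node$id), TRUE, envir = visited)
  while (ns > 0L) {
    fr <- stack[[ns]]
    if (fr$i < length(fr$n$parents)) {
      stack[[ns]]$i <- fr$i + 1L
      p <- fr$n$parents[[fr$i + 1L]]
      key <- as.character(p$id)
      if (p$requires_grad && !p$is_leaf && is.null(visited[[key]])) {
        assign(key, TRUE, envir = visited)
        ns <- ns + 1L
        stack[[ns]] <- list(n = p, i = 0L)
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- fr$n
      ns <- ns - 1L
    }
  }
  node$grad <- grad
  for (k in seq(nt, 1L)) {
    n <- topo[[k]]
    if (is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$requires_grad || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (!n$is_leaf) n$grad <- NULL  # free intermediate gradients
  }
  invisible(node)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- elementwise primitives ---------------------------------------------

# reduce gradient g to the shape of parent value v (scalar broadcast case)
.shrink <- function(g, v) if (length(v) == 1L) sum(g) else g

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value + b$value, list(a, b),
        function(g) list(.shrink(g, a$value), .shrink(g, b$value)))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value - b$value, list(a, b),
        function(g) list(.shrink(g, a$value), .shrink(-g, b$value)))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value * b$value, list(a, b),
        function(g) list(.shrink(g * b$value, a$value),
                         .shrink(g * a$value, b$value)))
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value / b$value, list(a, b),
        function(g) list(.shrink(g / b$value, a$value),
                         .shrink(-g * a$value / b$value^2, b$value)))
}

ag_neg <- function(a) {
  a <- as_ag(a)
  ag_op(-a$value, list(a), function(g) list(-g))
}

ag_exp <- function(a) {
  a <- as_ag(a)
  v <- exp(a$value)
  ag_op(v, list(a), function(g) list(g * v))
}

ag_log <- function(a) {
  a <- as_ag(a)
  ag_op(log(a$value), list(a), function(g) list(g / a$value))
}

ag_sqrt <- function(a) {
  a <- as_ag(a)
  v <- sqrt(a$value)
  ag_op(v, list(a), function(g) list(g / (2 * v)))
}

ag_sum <- function(a) {
  a <- as_ag(a)
  ag_op(sum(a$value), list(a),
        function(g) list(array(g, dim(a$value) %||% length(a$value))))
}

ag_mean <- function(a) {
  a <- as_ag(a)
  n <- length(a$value)
  ag_op(mean(a$value), list(a),
        function(g) list(array(g / n, dim(a$value) %||% length(a$value))))
}

ag_relu <- function(a) {
  a <- as_ag(a)
  keep <- a$value > 0
  ag_op(a$value * keep, list(a), function(g) list(g * keep))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  v <- 1 / (1 + exp(-a$value))
  ag_op(v, list(a), function(g) list(g * v * (1 - v)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# concatenate numeric vectors
ag_cat <- function(xs) {
  xs <- lapply(xs, as_ag)
  lens <- vapply(xs, function(x) length(x$value), integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_op(unlist(lapply(xs, function(x) as.numeric(x$value))), xs,
        function(g) lapply(seq_along(xs), function(j) g[starts[j]:ends[j]]))
}

# subset a vector node (scatter gradient back)
ag_subset <- function(x, idx) {
  x <- as_ag(x)
  n <- length(x$value)
  ag_op(x$value[idx], list(x), function(g) {
    gx <- numeric(n)
    gx[idx] <- g
    list(gx)
  })
}

# dense layer on a vector: t(W) x + b, W is (in x out)
ag_dense <- function(x, w, b) {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  v <- drop(crossprod(w$value, as.numeric(x$value))) + b$value
  ag_op(v, list(x, w, b),
        function(g) list(drop(w$value %*% g),
                         outer(as.numeric(x$value), g),
                         g))
}
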