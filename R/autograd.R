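## Minimal reverse-mode autograd on dense arrays.
##
## Nodes are environments carrying `value` (array, dim = c(H, W, N, C) for
## feature maps), optional `parents` and a `bwd` closure mapping the node's
## upstream gradient to a list of parent gradients. No external deep
## learning framework is available in the target environment, so the engine
## is part of the package; it is exercised by finite-difference tests.

.gcu <- new.env(parent = emptyenv())
.gcu$grad_enabled <- TRUE

#' Evaluate an expression with gradient recording disabled
#'
#' Inside `ag_no_grad()` all tensor operations skip caching and graph
#' construction, which makes inference-mode forward passes cheaper.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
ag_no_grad <- function(expr) {
  old <- .gcu$grad_enabled
  .gcu$grad_enabled <- FALSE
  on.exit(.gcu$grad_enabled <- old)
  expr
}

grad_on <- function() isTRUE(.gcu$grad_enabled)

#' Create an autograd tensor node
#'
#' @param value numeric array.
#' @param parents list of parent nodes the value was computed from.
#' @param bwd function(grad) returning a list of gradients, one per parent
#'   (NULL entries allowed for parents that need no gradient).
#' @param requires logical; whether gradients must flow through this node.
#' @return an object of class `ag_node`.
#' @export
ag_node <- function(value, parents = list(), bwd = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$bwd <- bwd
  e$requires <- requires
  class(e) <- "ag_node"
  e
}

#' Create a trainable parameter node
#'
#' @param value numeric array of initial values.
#' @param name optional identifier used in serialized checkpoints.
#' @return an `ag_node` with `is_param = TRUE` and Adam state slots.
#' @export
ag_param <- function(value, name = NULL) {
  e <- ag_node(value, requires = TRUE)
  e$is_param <- TRUE
  e$name <- name
  e$adam_m <- NULL
  e$adam_v <- NULL
  e
}

is_param <- function(x) isTRUE(x$is_param)

## Wrap raw arrays as constant leaves so ops can mix arrays and nodes.
as_node <- function(x) if (inherits(x, "ag_node")) x else ag_node(x)

## Helper used by every op: build a result node, recording the graph only
## when gradients are enabled and some parent needs them.
ag_op <- function(value, parents, bwd_factory) {
  req <- grad_on() && any(vapply(parents, function(p) isTRUE(p$requires),
                                 logical(1)))
  if (!req) return(ag_node(value))
  ag_node(value, parents = parents, bwd = bwd_factory(), requires = TRUE)
}

## Reverse-topological traversal accumulating gradients. Gradients of
## non-parameter intermediates are freed as soon as they are consumed.
#' Backpropagate a gradient from a node through the recorded graph
#'
#' @param root `ag_node` to start from.
#' @param grad gradient of the objective with respect to `root$value`
#'   (same shape).
#' @export
ag_backward <- function(root, grad) {
  stopifnot(inherits(root, "ag_node"))
  if (!isTRUE(root$requires)) return(invisible(NULL))
  ## iterative DFS topological sort over nodes that require grad; visited
  ## bookkeeping is a per-call token written onto the node environments
  .gcu$visit_token <- if (is.null(.gcu$visit_token)) 1L else .gcu$visit_token + 1L
  token <- .gcu$visit_token
  order <- vector("list", 0L)
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    if (top$stage == 1L) {
      if (identical(nd$.vtok, token)) next
      nd$.vtok <- token
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (isTRUE(p$requires) && !identical(p$.vtok, token)) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      order[[length(order) + 1L]] <- nd
    }
  }
  root$grad <- grad
  for (i in rev(seq_along(order))) {
    nd <- order[[i]]
    g <- nd$grad
    if (is.null(g) || is.null(nd$bwd)) next
    pg <- nd$bwd(g)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!isTRUE(p$requires) || is.null(pg[[j]])) next
      p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
    }
    if (!is_param(nd)) nd$grad <- NULL
    nd$bwd <- NULL  # drop cached activations early
  }
  invisible(NULL)
}

#' Zero the gradients of a list of parameters
#' @param params list of `ag_param` nodes.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## --- Adam ------------------------------------------------------------------

#' One Adam update over a list of parameters
#'
#' Standard Adam with bias correction; state (first/second moments, step
#' counter) lives on the parameter nodes themselves so it serializes with
#' checkpoints.
#'
#' @param params list of `ag_param` nodes with populated `$grad`.
#' @param state environment holding the step counter `t` (created on first
#'   use if missing fields).
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @export
adam_step <- function(params, state, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state$t)) state$t <- 0L
  state$t <- state$t + 1L
  t <- state$t
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$adam_m)) {
      p$adam_m <- g * 0
      p$adam_v <- g * 0
    }
    ## fused in-place update (value, moments mutated directly)
    k_adam(p$value, p$adam_m, p$adam_v, g, lr, beta1, beta2, eps, c1, c2)
  }
  invisible(NULL)
}
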