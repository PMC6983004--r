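## A minimal reverse-mode tape over the Rcpp convolution primitives.
## Values are H x W x C arrays; parameters live in a named list shared by
## all nodes that reference them, so weight sharing (e.g. detector heads
## applied at every pyramid level) accumulates gradients naturally.

newTape <- function(params) {
  tp <- new.env(parent = emptyenv())
  tp$params <- params
  tp$vals <- list()
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

.tp_push <- function(tp, node, val) {
  tp$n <- tp$n + 1L
  id <- tp$n
  node$out <- id
  tp$nodes[[id]] <- node
  tp$vals[[id]] <- val
  id
}

tpInput <- function(tp, x) .tp_push(tp, list(op = "input"), x)

tpConv <- function(tp, id, pname, stride = 1L, pad = 1L) {
  force(id)
  p <- tp$params[[pname]]
  x <- tp$vals[[id]]
  fw <- cpp_conv_fw(x, p$W, p$b, p$kh, p$kw, stride, pad)
  .tp_push(tp, list(op = "conv", x = id, pname = pname, stride = stride,
                    pad = pad, cols = fw$cols, xdims = dim(x)), fw$out)
}

tpReLU <- function(tp, id) {
  force(id)
  x <- tp$vals[[id]]
  .tp_push(tp, list(op = "relu", x = id, mask = x > 0), pmax(x, 0))
}

tpMaxPool <- function(tp, id, k = 3L, stride = 2L, pad = 1L) {
  force(id)
  x <- tp$vals[[id]]
  fw <- cpp_maxpool_fw(x, k, stride, pad)
  .tp_push(tp, list(op = "maxpool", x = id, idx = fw$idx, xdims = dim(x)),
           fw$out)
}

tpAdd <- function(tp, a, b) {
  force(a); force(b)
  .tp_push(tp, list(op = "add", a = a, b = b), tp$vals[[a]] + tp$vals[[b]])
}

tpUpsample2 <- function(tp, id) {
  force(id)
  .tp_push(tp, list(op = "upsample2", x = id),
           cpp_upsample2_fw(tp$vals[[id]]))
}

# seeds: named list mapping node id (as character) -> gradient array.
# Returns list(param_grads = named list(W=, b=), input_grads = by id).
tpBackward <- function(tp, seeds) {
  d <- vector("list", tp$n)
  for (nm in names(seeds)) {
    id <- as.integer(nm)
    d[[id]] <- if (is.null(d[[id]])) seeds[[nm]] else d[[id]] + seeds[[nm]]
  }
  pg <- list()
  acc <- function(cur, g) if (is.null(cur)) g else cur + g
  for (id in rev(seq_len(tp$n))) {
    g <- d[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    switch(node$op,
      input = NULL,
      conv = {
        p <- tp$params[[node$pname]]
        bw <- cpp_conv_bw(g, node$cols, p$W, node$xdims[1], node$xdims[2],
                          node$xdims[3], p$kh, p$kw, node$stride, node$pad)
        if (is.null(pg[[node$pname]])) {
          pg[[node$pname]] <- list(W = bw$dW, b = as.numeric(bw$db))
        } else {
          pg[[node$pname]]$W <- pg[[node$pname]]$W + bw$dW
          pg[[node$pname]]$b <- pg[[node$pname]]$b + as.numeric(bw$db)
        }
        d[[node$x]] <- acc(d[[node$x]], bw$dx)
      },
      relu = { d[[node$x]] <- acc(d[[node$x]], g * node$mask) },
      maxpool = {
        d[[node$x]] <- acc(d[[node$x]],
                           cpp_maxpool_bw(g, node$idx, node$xdims[1],
                                          node$xdims[2], node$xdims[3]))
      },
      add = {
        d[[node$a]] <- acc(d[[node$a]], g)
        d[[node$b]] <- acc(d[[node$b]], g)
      },
      upsample2 = { d[[node$x]] <- acc(d[[node$x]], cpp_upsample2_bw(g)) },
      stop("unknown op: ", node$op))
    d[[id]] <- NULL # free
  }
  list(param_grads = pg, input_grads = d)
}

## parameter construction / optimisation ------------------------------------

# He-initialised convolution parameter stored as (Cout x Cin*kh*kw) matrix.
makeConvParam <- function(c_in, c_out, k, bias_init = 0, gain = 2) {
  fan_in <- c_in * k * k
  list(W = matrix(rnorm(c_out * fan_in, sd = sqrt(gain / fan_in)),
                  nrow = c_out),
       b = rep(bias_init, c_out), kh = as.integer(k), kw = as.integer(k))
}

newAdamState <- function(params) {
  st <- lapply(params, function(p)
    list(mW = matrix(0, nrow(p$W), ncol(p$W)), vW = matrix(0, nrow(p$W), ncol(p$W)),
         mb = numeric(length(p$b)), vb = numeric(length(p$b))))
  attr(st, "t") <- 0L
  st
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  t <- attr(state, "t") + 1L
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  attr(state, "t") <- t
  list(params = params, state = state)
}
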