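# Minimal CNN layer zoo with hand-written backward passes.
#
# A feature map is list(x = matrix[(N*H*W) x C], n, h, w): one row per
# spatial location (image-major, then row-major y, then x), one column per
# channel. Convolution is im2col (C++ kernel) followed by one BLAS GEMM, so
# the whole network runs at matrix-multiply speed on a single CPU core.

fm <- function(x, n, h, w) {
  list(x = x, n = as.integer(n), h = as.integer(h), w = as.integer(w))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1   # running <- (1 - m) * running + m * batch
LEAKY_SLOPE <- 0.1   # Darknet convention

conv_pad <- function(k) (k - 1L) %/% 2L

init_cbl_params <- function(cin, cout, k) {
  fan_in <- cin * k * k
  list(W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                  fan_in, cout),
       gamma = rep(1, cout), beta = rep(0, cout),
       running_mean = rep(0, cout), running_var = rep(1, cout))
}

init_conv_params <- function(cin, cout, k, obj_channels = integer(0)) {
  fan_in <- cin * k * k
  b <- rep(0, cout)
  # bias the objectness logits toward "background" at init so early training
  # is not dominated by a sea of confident false positives
  b[obj_channels] <- -4
  list(W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(1 / fan_in)),
                  fan_in, cout),
       b = b)
}

# ---- forward ops -----------------------------------------------------------

cbl_forward <- function(node, p, input, training) {
  k <- node$k; stride <- node$stride; pad <- conv_pad(k)
  patches <- im2col_cpp(input$x, input$n, input$h, input$w, k, stride, pad)
  z <- patches %*% p$W
  oh <- (input$h + 2 * pad - k) %/% stride + 1L
  ow <- (input$w + 2 * pad - k) %/% stride + 1L
  if (training) {
    mu <- colMeans(z)
    v <- pmax(colMeans(z^2) - mu^2, 0)
    istd <- 1 / sqrt(v + BN_EPS)
    zhat <- col_scale_add_cpp(z, istd, -mu * istd)
    p$running_mean <- (1 - BN_MOMENTUM) * p$running_mean + BN_MOMENTUM * mu
    m <- nrow(z)
    unbias <- if (m > 1) m / (m - 1) else 1
    p$running_var <- (1 - BN_MOMENTUM) * p$running_var + BN_MOMENTUM * v * unbias
  } else {
    istd <- 1 / sqrt(p$running_var + BN_EPS)
    zhat <- col_scale_add_cpp(z, istd, -p$running_mean * istd)
  }
  y <- col_scale_add_cpp(zhat, p$gamma, p$beta)
  neg <- y < 0
  y[neg] <- y[neg] * LEAKY_SLOPE
  list(out = fm(y, input$n, oh, ow),
       cache = list(input = input, patches = patches, zhat = zhat,
                    istd = istd, neg = neg, training = training),
       params = p)
}

cbl_backward <- function(node, p, cache, dy) {
  dy[cache$neg] <- dy[cache$neg] * LEAKY_SLOPE
  zhat <- cache$zhat; istd <- cache$istd
  dgamma <- colSums(dy * zhat)
  dbeta <- colSums(dy)
  dzhat <- col_scale_add_cpp(dy, p$gamma, numeric(ncol(dy)))
  if (cache$training) {
    # standard batchnorm backward in normalized coordinates
    dz <- bn_center_scale_cpp(dzhat, zhat, colMeans(dzhat),
                              colMeans(dzhat * zhat), istd)
  } else {
    dz <- col_scale_add_cpp(dzhat, istd, numeric(ncol(dzhat)))
  }
  input <- cache$input
  k <- node$k; stride <- node$stride; pad <- conv_pad(k)
  patches <- cache$patches
  dW <- crossprod(patches, dz)
  dpatch <- tcrossprod(dz, p$W)
  dx <- col2im_cpp(dpatch, input$n, input$h, input$w, ncol(input$x),
                   k, stride, pad)
  list(dinput = fm(dx, input$n, input$h, input$w),
       grads = list(W = dW, gamma = dgamma, beta = dbeta))
}

conv_forward <- function(node, p, input) {
  k <- node$k; stride <- node$stride; pad <- conv_pad(k)
  ones <- rep(1, length(p$b))
  if (k == 1L && stride == 1L) {
    z <- col_scale_add_cpp(input$x %*% p$W, ones, p$b)
    return(list(out = fm(z, input$n, input$h, input$w),
                cache = list(input = input)))
  }
  patches <- im2col_cpp(input$x, input$n, input$h, input$w, k, stride, pad)
  z <- col_scale_add_cpp(patches %*% p$W, ones, p$b)
  oh <- (input$h + 2 * pad - k) %/% stride + 1L
  ow <- (input$w + 2 * pad - k) %/% stride + 1L
  list(out = fm(z, input$n, oh, ow),
       cache = list(input = input, patches = patches))
}

conv_backward <- function(node, p, cache, dy) {
  input <- cache$input
  k <- node$k; stride <- node$stride; pad <- conv_pad(k)
  if (k == 1L && stride == 1L) {
    dW <- crossprod(input$x, dy)
    dx <- tcrossprod(dy, p$W)
    return(list(dinput = fm(dx, input$n, input$h, input$w),
                grads = list(W = dW, b = colSums(dy))))
  }
  dW <- crossprod(cache$patches, dy)
  dpatch <- tcrossprod(dy, p$W)
  dx <- col2im_cpp(dpatch, input$n, input$h, input$w, ncol(input$x),
                   k, stride, pad)
  list(dinput = fm(dx, input$n, input$h, input$w),
       grads = list(W = dW, b = colSums(dy)))
}

# ---- graph builder / executor ----------------------------------------------

graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()     # topological order by construction
  env$channels <- list()  # node name -> output channels
  add <- function(node) {
    env$nodes[[node$name]] <- node
    env$channels[[node$name]] <- node$cout
    node$name
  }
  env$input <- function(name, channels) {
    add(list(name = name, op = "input", inputs = character(0),
             cout = channels))
  }
  env$cbl <- function(name, input, cout, k = 3L, stride = 1L) {
    add(list(name = name, op = "cbl", inputs = input,
             cin = env$channels[[input]], cout = cout,
             k = as.integer(k), stride = as.integer(stride)))
  }
  env$conv <- function(name, input, cout, k = 1L, obj_channels = integer(0)) {
    add(list(name = name, op = "conv", inputs = input,
             cin = env$channels[[input]], cout = cout,
             k = as.integer(k), stride = 1L, obj_channels = obj_channels))
  }
  env$add_node <- function(name, a, b) {
    stopifnot(env$channels[[a]] == env$channels[[b]])
    add(list(name = name, op = "add", inputs = c(a, b),
             cout = env$channels[[a]]))
  }
  env$upsample <- function(name, input) {
    add(list(name = name, op = "upsample", inputs = input,
             cout = env$channels[[input]]))
  }
  env$concat <- function(name, a, b) {
    add(list(name = name, op = "concat", inputs = c(a, b),
             cout = env$channels[[a]] + env$channels[[b]],
             split = env$channels[[a]]))
  }
  env
}

init_graph_params <- function(nodes) {
  params <- new.env(parent = emptyenv())
  for (node in nodes) {
    if (node$op == "cbl") {
      assign(node$name, init_cbl_params(node$cin, node$cout, node$k),
             envir = params)
    } else if (node$op == "conv") {
      assign(node$name, init_conv_params(node$cin, node$cout, node$k,
                                         node$obj_channels), envir = params)
    }
  }
  params
}

graph_forward <- function(nodes, params, input_fm, training = FALSE,
                          keep_cache = FALSE) {
  vals <- list()
  caches <- if (keep_cache) list() else NULL
  for (node in nodes) {
    out <- switch(node$op,
      input = input_fm,
      cbl = {
        p <- get(node$name, envir = params)
        r <- cbl_forward(node, p, vals[[node$inputs]], training)
        if (training) assign(node$name, r$params, envir = params)
        if (keep_cache) caches[[node$name]] <- r$cache
        r$out
      },
      conv = {
        p <- get(node$name, envir = params)
        r <- conv_forward(node, p, vals[[node$inputs]])
        if (keep_cache) caches[[node$name]] <- r$cache
        r$out
      },
      add = {
        a <- vals[[node$inputs[1]]]; b <- vals[[node$inputs[2]]]
        fm(a$x + b$x, a$n, a$h, a$w)
      },
      upsample = {
        a <- vals[[node$inputs]]
        fm(upsample2_cpp(a$x, a$n, a$h, a$w), a$n, 2L * a$h, 2L * a$w)
      },
      concat = {
        a <- vals[[node$inputs[1]]]; b <- vals[[node$inputs[2]]]
        stopifnot(a$h == b$h, a$w == b$w)
        fm(cbind(a$x, b$x), a$n, a$h, a$w)
      },
      stop(sprintf("unknown op %s", node$op)))
    vals[[node$name]] <- out
  }
  list(values = vals, caches = caches)
}

# Backward over the recorded forward pass. `grad_map` holds output-node
# gradients (same matrix shape as the node's fm$x). Returns an environment
# of parameter gradients keyed by node name.
graph_backward <- function(nodes, params, fwd, grad_map) {
  grads <- new.env(parent = emptyenv())
  gvals <- grad_map  # node name -> accumulated gradient matrix
  acc <- function(name, g) {
    gvals[[name]] <<- if (is.null(gvals[[name]])) g else gvals[[name]] + g
  }
  for (i in rev(seq_along(nodes))) {
    node <- nodes[[i]]
    dy <- gvals[[node$name]]
    if (is.null(dy) || node$op == "input") next
    switch(node$op,
      cbl = {
        p <- get(node$name, envir = params)
        r <- cbl_backward(node, p, fwd$caches[[node$name]], dy)
        assign(node$name, r$grads, envir = grads)
        acc(node$inputs, r$dinput$x)
      },
      conv = {
        p <- get(node$name, envir = params)
        r <- conv_backward(node, p, fwd$caches[[node$name]], dy)
        assign(node$name, r$grads, envir = grads)
        acc(node$inputs, r$dinput$x)
      },
      add = {
        acc(node$inputs[1], dy)
        acc(node$inputs[2], dy)
      },
      upsample = {
        a <- fwd$values[[node$inputs]]
        acc(node$inputs, downsum2_cpp(dy, a$n, a$h, a$w))
      },
      concat = {
        split <- node$split
        acc(node$inputs[1], dy[, seq_len(split), drop = FALSE])
        acc(node$inputs[2], dy[, split + seq_len(ncol(dy) - split),
                               drop = FALSE])
      })
    gvals[[node$name]] <- NULL  # free
  }
  grads
}
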