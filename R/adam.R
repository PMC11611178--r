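# Adam optimizer over an arbitrary nested list of numeric arrays.
# Updates run in place (C++ kernel) on parameter/state arrays that this
# package allocates itself; elements named in `skip` (structural constants
# like the kernel width) are left untouched.

adam_init <- function(params, skip = "kernel") {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk)
    else array(0, dim = dim(p) %||% length(p))
  }
  p <- params[setdiff(names(params), skip)]
  list(m = lapply(p, walk), v = lapply(p, walk), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      skip = "kernel") {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        key <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i] else i
        walk(p[[key]], g[[key]], m[[key]], v[[key]])
      }
    } else {
      cpp_adam_inplace(p, m, v, g, lr, weight_decay,
                       beta1, beta2, eps, t)
    }
    invisible(NULL)
  }
  keep <- setdiff(names(params), skip)
  walk(params[keep], grads[keep], state$m, state$v)
  list(params = params, state = state)
}
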