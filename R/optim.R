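# Adam optimizer over a named list of numeric arrays.
# Returns an environment holding first/second moment estimates and the
# step counter; step() applies one update in place and returns the
# updated parameter list.
adamInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim(as.array(p))))
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adamStep <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  params
}

# plain SGD with classical momentum (the optimizer of the original
# fixed-unit-scale deep-embedding-clustering setup; the collapse failure
# mode it exhibits depends on unnormalized gradient magnitudes)
sgdInit <- function(params, lr = 1e-2, momentum = 0.9) {
  st <- new.env(parent = emptyenv())
  st$vel <- lapply(params, function(p) array(0, dim(as.array(p))))
  st$lr <- lr; st$momentum <- momentum
  st
}

sgdStep <- function(st, params, grads) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$vel[[nm]] <- st$momentum * st$vel[[nm]] - st$lr * g
    params[[nm]] <- params[[nm]] + st$vel[[nm]]
  }
  params
}
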