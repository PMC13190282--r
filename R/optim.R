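# Adam optimizer over a named parameter list, with decoupled weight decay
# and a trainable mask. State lives in an environment so repeated steps do
# not copy the moment estimates.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) p * 0)
  e$v <- lapply(params, function(p) p * 0)
  e$t <- 0L
  e$lr <- lr
  e$beta1 <- beta1
  e$beta2 <- beta2
  e$eps <- eps
  e$wd <- weight_decay
  e
}

adam_step <- function(opt, params, grads, trainable, lr = NULL) {
  lr <- lr %||% opt$lr
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    if (!isTRUE(trainable[[nm]])) next
    gr <- grads[[nm]]
    if (is.null(gr)) next
    wd <- if (grepl("_W$", nm)) opt$wd else 0
    upd <- .cpp_adam_update(params[[nm]], opt$m[[nm]], opt$v[[nm]], gr,
                            lr, opt$beta1, opt$beta2, opt$eps, wd, bc1, bc2)
    attributes(upd) <- attributes(params[[nm]])
    params[[nm]] <- upd
  }
  params
}
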