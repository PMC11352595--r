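#' @keywords internal
"_PACKAGE"

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic code in the package funnels
# through this so seeds never leak across stages.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Round half away from zero
#'
#' Metric tables are conventionally reported with half-up rounding
#' (93.525 -> 93.53), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Row-wise softmax with max-shift stabilization.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Cross-entropy of one logit vector against an integer class index.
ce_loss <- function(logits, y) {
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  lse - logits[y]
}

l2norm <- function(x) sqrt(sum(x * x))

# ---- Adam optimizer over a named list of numeric arrays -------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}

# Gaussian init scaled for a layer with `fan_in` inputs.
ginit <- function(nrow, ncol, fan_in = nrow) {
  matrix(stats::rnorm(nrow * ncol, sd = 1 / sqrt(fan_in)), nrow, ncol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
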