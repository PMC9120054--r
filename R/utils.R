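#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm pchisq pt qt rbinom rlnorm rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-(region, metric) stream derived from a master seed, so
# permutation results are independent of execution order. Kept < 2^31.
derive_seed <- function(seed, region_index = 0L, metric = "strength") {
  metric_id <- match(metric, c("strength", "betweenness", "clustering",
                               "volume", "edge", "symptom"))
  if (is.na(metric_id)) metric_id <- 7L
  s <- (as.numeric(seed) %% 2147483647)
  ((s * 48271 + as.numeric(region_index) * 7919 + metric_id * 104729) %%
      2147483629) + 1
}

log_msg <- function(...) {
  message(sprintf("[limbconn] %s", sprintf(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
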