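#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois quantile
#' @importFrom utils read.csv write.csv head tail
NULL

abort_config <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-stage seed from a global seed so pipeline stages are
# independently reproducible. Kept strictly below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(generate = 101L, augment = 211L, split = 307L, train = 401L,
               kfold = 503L, explain = 601L)
  off <- offsets[[stage]]
  as.integer((abs(as.numeric(seed)) * 7919 + off) %% 2147483629)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Sigmoid with output clamped away from exact 0/1 so the downstream
# log-ratio similarity kernel never sees a degenerate distance.
sigmoid_safe <- function(x) {
  y <- 1 / (1 + exp(-x))
  pmin(pmax(y, 1e-7), 1 - 1e-7)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}
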