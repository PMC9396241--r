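#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm runif rbinom setNames quantile kmeans lm coef
#'   predict aggregate sd var
#' @importFrom utils head tail
NULL

# Internal error helpers so every contract violation carries a class that
# tests can assert on.
stop_contract <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "tepredict_contract_error")
}

stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "tepredict_config_error")
}

stop_missing_data <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "tepredict_missing_data_error")
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop_config("`%s` must be a finite number in [%s, %s]", name, lo, hi)
  }
  invisible(x)
}

# Deterministic per-eye random streams: a small string hash folded with the
# cohort seed so cohorts are reproducible under eye reordering. Kept below
# .Machine$integer.max.
eye_seed <- function(seed, eye_id) {
  h <- 0
  for (k in utf8ToInt(as.character(eye_id))) {
    h <- (h * 31 + k) %% 2147483563
  }
  as.integer((h + (as.numeric(seed) * 2654435) %% 2147483563) %% 2147483563)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_eye_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

biomarkers_fluid <- function() c("irf", "srf", "ped", "hrf")
biomarkers_all <- function() c("irf", "srf", "ped", "hrf", "pr")
zones_all <- function() c("central", "para", "peri")
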