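#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

dd_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "durddm_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_domain <- function(msg) dd_stop(msg, "durddm_domain_error")
stop_validation <- function(msg) dd_stop(msg, "durddm_validation_error")
stop_config <- function(msg) dd_stop(msg, "durddm_config_error")

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded helpers do
#' not disturb an enclosing simulation.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit integer stream seed derived from a master seed and a
# label, so each pipeline stage gets its own reproducible stream
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}
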