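# Internal helpers shared across the package.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so library functions never perturb ambient
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

clamp0 <- function(x) {
  x[x < 0] <- 0
  x
}

stop_user <- function(...) {
  stop(mccims_error(paste0(...), class = "mccims_user_error"))
}

mccims_error <- function(message, class) {
  structure(
    class = c(class, "mccims_error", "error", "condition"),
    list(message = message, call = NULL)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replicate-pad a matrix by `kr` rows / `kc` cols on each side (nearest-value
# edge extension used by all 2D filters).
pad_replicate <- function(x, kr, kc) {
  nr <- nrow(x)
  nc <- ncol(x)
  ri <- c(rep(1L, kr), seq_len(nr), rep(nr, kr))
  ci <- c(rep(1L, kc), seq_len(nc), rep(nc, kc))
  x[ri, ci, drop = FALSE]
}
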