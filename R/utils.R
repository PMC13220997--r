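# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' then restores the caller's RNG state, so seeded operations never disturb
#' the surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; stays inside 32-bit integer range for
# any master seed the user supplies.
derive_seed <- function(master, k) {
  as.integer((abs(as.double(master)) %% 1e9 + 104729 * as.double(k)) %%
               2147483646) + 1L
}

ltx_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("leaftex_", class), "leaftex_error",
                                "error", "condition")))
}

ltx_validation_error <- function(fmt, ...) ltx_stop("validation_error", fmt, ...)
ltx_io_error <- function(fmt, ...) ltx_stop("io_error", fmt, ...)

# Clamp to the 8-bit gray range and round to integers.
clamp8 <- function(x) {
  storage.mode(x) <- "double"
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Spearman rank correlation with average-rank tie handling
#'
#' Thin wrapper over [stats::cor()] used for all rank-stability diagnostics.
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  stats::cor(x, y, method = "spearman")
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    ltx_validation_error("%s is missing required column(s): %s", what,
                         paste(miss, collapse = ", "))
}
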