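#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators are pure
#' functions of their arguments and never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Per-module seed offsets so that adding a generator never perturbs another's
# stream when all are driven from one global seed.
seed_offset <- function(seed, module) {
  offs <- c(sst = 101L, diet = 202L, echogram = 303L, lengths = 404L,
            energetics = 505L, pipeline = 606L)
  if (!module %in% names(offs)) stop("unknown module: ", module)
  (as.integer(seed) + offs[[module]]) %% .Machine$integer.max
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
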