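#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent substream seeds from one master seed
#'
#' All stochastic stages of the pipeline draw their own seed from the single
#' user-facing seed, so stages stay reproducible independently of how many
#' random numbers earlier stages consumed. The caller's RNG state is left
#' untouched.
#'
#' @param seed master integer seed.
#' @param n number of substream seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  sample.int(2147483645L, n)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates, and restores the previous RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Internal logger: messages go to stderr; a pipeline run can additionally tee
# them into run.log via the `komix.log_con` option.
komix_log <- function(fmt, ...) {
  txt <- sprintf(fmt, ...)
  con <- getOption("komix.log_con", NULL)
  if (!is.null(con)) writeLines(txt, con)
  message(txt)
  invisible(txt)
}

komix_stop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Collapse a character vector for an error message, capping length.
id_list <- function(ids, max = 10L) {
  ids <- as.character(ids)
  if (length(ids) > max) {
    paste0(paste(ids[seq_len(max)], collapse = ", "), ", ... (", length(ids), " total)")
  } else {
    paste(ids, collapse = ", ")
  }
}
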