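# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Tissue groups a sample annotation may use; order fixed so reports are stable.
TISSUE_GROUPS <- c("peripheral_blood", "normal_prostate", "prostate_cancer",
                   "other_normal", "other_cancer")

# Roles a qMSP well may carry.
PLATE_ROLES <- c("unknown", "standard", "pos_ctrl", "neg_ctrl_wga",
                 "neg_ctrl_water")

# qMSP reference assays: DNA input normalization and bisulfite-conversion QC.
REFERENCE_TARGETS <- c("ALUC4", "MYOD1")

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "methmark_error", "error"),
                      call = sys.call(-1)))
}
abort_config <- function(msg) abort(msg, "methmark_config_error")
abort_format <- function(msg) abort(msg, "methmark_format_error")
abort_degenerate <- function(msg) abort(msg, "methmark_degenerate_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x, min = 0L) {
  is_scalar_number(x) && x >= min && x == round(x)
}

#' Evaluate an expression under a fixed random seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded generator calls never shift an enclosing random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a named substream seed from a single user seed, so that adding one
# generator call does not shift another generator's stream. Result < 2^31.
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 2147483587 * 48271 + h) %% 2147483587) + 1L
}

# Collapse a character vector into "a, b, c" for messages.
oxford <- function(x) paste(x, collapse = ", ")

# stopifnot-style column check with a format error listing ALL missing names.
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_format(sprintf("%s is missing required column(s): %s",
                         what, oxford(missing)))
  }
  invisible(df)
}
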