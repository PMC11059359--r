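# Internal helpers shared across modules.

#' Evaluate an expression under a seed without touching global RNG state
#'
#' The generators take `seed` as an explicit parameter; this wrapper restores
#' the caller's `.Random.seed` afterwards so no global state leaks.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_preserved_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stop() with a class so tests can assert on error kinds
rs_error <- function(msg, class) {
  stop(structure(
    class = c(class, "revscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

param_error <- function(msg) rs_error(msg, "revscreen_parameter_error")
format_error <- function(msg) rs_error(msg, "revscreen_format_error")
io_error <- function(msg) rs_error(msg, "revscreen_io_error")

# stage logging to stderr; silenced via options(revscreen.quiet = TRUE)
log_msg <- function(...) {
  if (!isTRUE(getOption("revscreen.quiet", TRUE))) {
    message("[revscreen] ", sprintf(...))
  }
  invisible(NULL)
}

check_expression_matrix <- function(mat, what = "matrix") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    param_error(sprintf("%s must be a numeric matrix", what))
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    param_error(sprintf("%s must have gene rownames and sample colnames", what))
  }
  if (anyDuplicated(rownames(mat))) {
    param_error(sprintf("%s has duplicated gene ids", what))
  }
  if (anyNA(mat)) param_error(sprintf("%s contains missing values", what))
  invisible(mat)
}

check_design <- function(design, mat = NULL) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "group") %in% names(design))) {
    param_error("design must be a data.frame with columns sample_id and group")
  }
  if (!all(design$group %in% c("control", "case"))) {
    param_error("design groups must be 'control' or 'case'")
  }
  if (!is.null(mat)) {
    if (!setequal(design$sample_id, colnames(mat))) {
      param_error("design sample_ids do not match matrix columns")
    }
  }
  invisible(design)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
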