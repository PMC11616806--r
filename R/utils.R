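# Internal helpers: dotted-path access into the nested parameter list and a
# small validation-issue collector used to report all problems at once.

path_parts <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Read a value from a parameter set by dotted path
#'
#' Paths address leaves of the nested parameter list, e.g.
#' `"utilities.lvad_baseline"` or `"complications.gib.prob"`.
#'
#' @param params A parameter set (see [default_parameters()]).
#' @param path Dotted path string.
#' @return The value stored at `path`.
#' @export
#' @examples
#' param_get(default_parameters(), "discounting.annual_discount")
param_get <- function(params, path) {
  out <- tryCatch(purrr::chuck(params, !!!as.list(path_parts(path))),
                  error = function(e) NULL)
  if (is.null(out)) {
    abort(sprintf("unknown parameter path '%s'", path))
  }
  out
}

#' Replace a value in a parameter set by dotted path
#'
#' @inheritParams param_get
#' @param value Replacement value.
#' @return A modified copy of `params`; the input is not changed.
#' @export
param_set <- function(params, path, value) {
  param_get(params, path) # errors on unknown paths
  purrr::assign_in(params, as.list(path_parts(path)), value)
}

new_issues <- function() {
  env <- new.env(parent = emptyenv())
  env$issues <- character()
  env
}

add_issue <- function(env, path, msg) {
  env$issues <- c(env$issues, sprintf("%s: %s", path, msg))
  invisible(env)
}

stop_if_issues <- function(env, context) {
  if (length(env$issues)) {
    abort(c(sprintf("invalid %s (%d problem%s)", context, length(env$issues),
                    if (length(env$issues) > 1L) "s" else ""),
            setNames(env$issues, rep("x", length(env$issues)))))
  }
  invisible(TRUE)
}

check_prob <- function(env, x, path) {
  if (!is.numeric(x) || anyNA(x)) {
    add_issue(env, path, "must be numeric and non-missing")
  } else if (any(x < 0 | x > 1)) {
    add_issue(env, path, sprintf("probability outside [0, 1] (got %s)",
                                 paste(signif(x[x < 0 | x > 1], 4), collapse = ", ")))
  }
  invisible(env)
}

check_nonneg <- function(env, x, path) {
  if (!is.numeric(x) || anyNA(x)) {
    add_issue(env, path, "must be numeric and non-missing")
  } else if (any(x < 0)) {
    add_issue(env, path, "must be non-negative")
  }
  invisible(env)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
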