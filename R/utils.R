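`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop_empty <- function(msg) {
  stop(structure(class = c("jpeg_empty_data", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_fraction <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single number in [0, 1]", name))
  invisible(x)
}

# Drop rank-deficient columns of a design matrix (keeps the pivoted
# full-rank subset), warning with the dropped column names.
drop_collinear <- function(X, warn = TRUE, label = "covariate") {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    if (warn)
      warning(sprintf("dropping %d collinear %s column(s): %s",
                      length(drop), label,
                      paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, -drop, drop = FALSE]
  }
  X
}
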