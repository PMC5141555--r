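# numerically safe row-wise helpers used throughout the EM machinery

# log(sum(exp(M[i, ]))) per row; tolerates -Inf entries (rows of all -Inf
# return -Inf, never NaN)
.row_logsumexp <- function(M) {
  m <- apply(M, 1L, max)
  fin <- is.finite(m)
  out <- m
  if (any(fin)) {
    Mf <- M[fin, , drop = FALSE] - m[fin]
    out[fin] <- m[fin] + log(rowSums(exp(Mf)))
  }
  out
}

# row-wise softmax with max subtraction for stability
.softmax_rows <- function(E) {
  E <- E - apply(E, 1L, max)
  P <- exp(E)
  P / rowSums(P)
}

.clip <- function(x, bound) pmin(pmax(x, -bound), bound)

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, class = "poismix_error") {
  if (!isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}
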