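#' Aggregate per-replicate statistics
#'
#' Arithmetic mean and sample standard deviation across replicates. Accepts
#' a numeric vector (one scalar per replicate), a matrix with replicates in
#' columns, or a list of congruently named/indexed numeric vectors. With a
#' single replicate the sd is reported as 0 and flagged.
#'
#' @param x Numeric vector, matrix (statistics x replicates), or list of
#'   named numeric vectors (one per replicate).
#' @return data.frame with `mean`, `sd`, `n` and `single_replicate`; row
#'   names/`statistic` column preserved for matrix/list input.
#' @export
aggregate_replicates <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    nms <- lapply(x, names)
    lens <- vapply(x, length, integer(1))
    if (length(unique(lens)) != 1) {
      stop("replicate index mismatch: unequal statistic counts")
    }
    if (!is.null(nms[[1]])) {
      same <- vapply(nms, function(n) identical(n, nms[[1]]), logical(1))
      if (!all(same)) stop("replicate index mismatch: names differ")
    }
    x <- do.call(cbind, x)
  }
  if (is.matrix(x)) {
    n <- ncol(x)
    out <- data.frame(statistic = rownames(x) %||% seq_len(nrow(x)),
                      mean = rowMeans(x),
                      sd = if (n > 1) apply(x, 1, stats::sd) else 0,
                      n = n, single_replicate = n == 1,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  n <- length(x)
  data.frame(mean = mean(x), sd = if (n > 1) stats::sd(x) else 0,
             n = n, single_replicate = n == 1)
}
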