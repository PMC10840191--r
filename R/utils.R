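# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    .stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

.check_prob <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || !hi_ok)
    .stopf("'%s' must be a probability in [0,%s)", name, if (allow_one) "1]" else "1")
  invisible(as.numeric(x))
}

# Jaccard similarity between two sets.
.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# z-score matrix rows; rows with zero variance become all-zero.
.zscore_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}
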