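#' Patch landscape
#'
#' A set of habitat patches on a rectangular grid, each with a resource
#' input rate (quality) and a consumer count. Consumers are omniscient and
#' move instantaneously, so the grid coordinates are cosmetic bookkeeping:
#' there is no neighbourhood structure and distance plays no role.
#'
#' @param quality Numeric vector of per-patch resource input rates, all
#'   strictly positive; length must equal `n_rows * n_cols`.
#' @param n_rows,n_cols Grid dimensions. Defaults describe a single row.
#' @param count Integer vector of per-patch consumer counts (recycled if
#'   scalar), all non-negative.
#' @return An object of class `patch_landscape` with fields `n_rows`,
#'   `n_cols`, `quality`, `count`.
#' @examples
#' patch_landscape(c(12, 6))
#' patch_landscape(runif(49, 1, 10), n_rows = 7, n_cols = 7)
#' @export
patch_landscape <- function(quality, n_rows = 1L, n_cols = length(quality),
                            count = 0L) {
  quality <- as.numeric(quality)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be at least 1")
  P <- n_rows * n_cols
  if (length(quality) != P)
    stop(sprintf("`quality` has length %d but the grid has %d patches",
                 length(quality), P))
  if (any(!is.finite(quality)) || any(quality <= 0))
    stop("all patch qualities must be finite and strictly positive")
  count <- rep_len(as.integer(count), P)
  if (any(is.na(count)) || any(count < 0))
    stop("all patch counts must be non-negative integers")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, quality = quality, count = count),
    class = "patch_landscape"
  )
}

#' @export
print.patch_landscape <- function(x, ...) {
  cat(sprintf("Patch landscape: %d x %d grid (%d patches), %d consumers\n",
              x$n_rows, x$n_cols, length(x$quality), sum(x$count)))
  cat(sprintf("  quality: [%g, %g], total input %g\n",
              min(x$quality), max(x$quality), sum(x$quality)))
  invisible(x)
}

#' Number of patches
#' @param x A `patch_landscape` or `ifd_state`.
#' @return Integer patch count.
#' @export
n_patches <- function(x) length(as_landscape(x)$quality)

# accept a state or a landscape wherever only patches matter
as_landscape <- function(x) {
  if (inherits(x, "ifd_state")) x$landscape
  else if (inherits(x, "patch_landscape")) x
  else stop("expected a `patch_landscape` or `ifd_state`")
}

#' Draw a random patch landscape
#'
#' Qualities are drawn independently from a configurable distribution
#' (default: continuous uniform on \[1, 10\], which makes intake ties
#' between distinct patches a measure-zero event); counts start at zero.
#'
#' @param n_rows,n_cols Grid dimensions (default 7 x 7 = 49 patches).
#' @param quality_fn Function of one argument `n` returning `n` positive
#'   qualities, or `NULL` for the default `runif(n, 1, 10)`.
#' @param quality Optional explicit quality vector overriding `quality_fn`.
#' @return A [patch_landscape()].
#' @examples
#' set.seed(1)
#' generate_landscape()                       # 49 patches, U[1,10]
#' generate_landscape(2, 2, function(n) rep(5, n))  # degenerate at 5
#' @export
generate_landscape <- function(n_rows = 7L, n_cols = 7L, quality_fn = NULL,
                               quality = NULL) {
  P <- as.integer(n_rows) * as.integer(n_cols)
  if (is.null(quality)) {
    quality_fn <- quality_fn %||% function(n) stats::runif(n, 1, 10)
    quality <- quality_fn(P)
  }
  if (any(!is.finite(quality)) || any(quality <= 0))
    stop("quality distribution produced non-positive or non-finite values")
  patch_landscape(quality, n_rows, n_cols, count = 0L)
}

#' Read / write a landscape as CSV
#'
#' Plain comma-separated UTF-8 files with a header row and columns
#' `patch_id, row, col, quality, count`; patch ids are 1-based row-major.
#'
#' @param x A `patch_landscape` or `ifd_state` (the embedded landscape is
#'   written).
#' @param path File path.
#' @return `write_landscape()` returns `path` invisibly; `read_landscape()`
#'   returns a [patch_landscape()].
#' @export
write_landscape <- function(x, path) {
  L <- as_landscape(x)
  P <- length(L$quality)
  id <- seq_len(P)
  df <- data.frame(
    patch_id = id,
    row = (id - 1L) %/% L$n_cols + 1L,
    col = (id - 1L) %% L$n_cols + 1L,
    quality = L$quality,
    count = L$count
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("patch_id", "row", "col", "quality", "count")
  if (!all(need %in% names(df)))
    stop("landscape CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$patch_id), , drop = FALSE]
  if (!identical(as.integer(df$patch_id), seq_len(nrow(df))))
    stop("patch_id must be the contiguous sequence 1..P")
  patch_landscape(df$quality, n_rows = max(df$row), n_cols = max(df$col),
                  count = df$count)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
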