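#' Place a cohort of embryos on a square dish grid
#'
#' Embryos are arranged row-major on the smallest square grid with at least
#' `n` cells (a 2 x 2, 3 x 3, ... layout, partially filled when `n` is not a
#' perfect square). Immediate neighbours are the occupied cells at Chebyshev
#' distance 1 (Moore neighbourhood, up to 8) and "neighbour's neighbours" the
#' occupied cells at Chebyshev distance 2 (up to 16); a von Neumann variant
#' uses Manhattan distances instead. There is no wraparound: the dish has
#' edges, so boundary embryos have fewer signaling partners.
#'
#' @param n Number of embryos (>= 1).
#' @param topology `"moore"` (default) or `"von_neumann"`.
#' @return An object of class `cohort_grid` with elements `n`, `side`,
#'   `layout` (tibble: `embryo`, `row`, `col`, 0-based coordinates), `nb` and
#'   `nn` (lists of neighbour index vectors) and sparse adjacency matrices
#'   `W_nb`, `W_nn`.
#' @examples
#' g <- cohort_grid(9)
#' lengths(g$nb)[5] # centre embryo has 8 immediate neighbours
#' @export
cohort_grid <- function(n, topology = c("moore", "von_neumann")) {
  topology <- match.arg(topology)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be a positive integer.")
  side <- as.integer(ceiling(sqrt(n)))
  row <- (seq_len(n) - 1L) %/% side
  col <- (seq_len(n) - 1L) %% side
  D <- if (topology == "moore") {
    pmax(abs(outer(row, row, "-")), abs(outer(col, col, "-")))
  } else {
    abs(outer(row, row, "-")) + abs(outer(col, col, "-"))
  }
  W_nb <- Matrix(D == 1L, sparse = TRUE) * 1
  W_nn <- Matrix(D == 2L, sparse = TRUE) * 1
  nb <- lapply(seq_len(n), function(i) which(D[i, ] == 1L))
  nn <- lapply(seq_len(n), function(i) which(D[i, ] == 2L))
  structure(
    list(n = n, side = side, topology = topology,
         layout = tibble(embryo = seq_len(n), row = row, col = col),
         nb = nb, nn = nn, W_nb = W_nb, W_nn = W_nn),
    class = "cohort_grid"
  )
}

#' @export
print.cohort_grid <- function(x, ...) {
  cat(sprintf("<cohort_grid> %d embryos on a %dx%d grid (%s neighbourhood)\n",
              x$n, x$side, x$side, x$topology))
  invisible(x)
}
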