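# Shared helpers: validation, classed errors, small geometry utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed wavetrack error
#'
#' All package errors carry a subclass (e.g. "wavetrack_validation_error")
#' so callers and tests can distinguish failure modes.
#'
#' @param message error message.
#' @param class error subclass, prefixed with "wavetrack_".
#' @param ... fields attached to the condition.
#' @keywords internal
wt_stop <- function(message, class, ...) {
  cond <- structure(
    class = c(paste0("wavetrack_", class), "wavetrack_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    wt_stop(sprintf("'%s' must be a single positive finite number", name),
            "validation_error", field = name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    wt_stop(sprintf("'%s' must be finite and non-negative", name),
            "validation_error", field = name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || x < min || x != round(x))
    wt_stop(sprintf("'%s' must be an integer >= %d", name, min),
            "validation_error", field = name)
  invisible(as.integer(x))
}

#' Moving-average smoothing with edge shrinkage
#'
#' Centred moving average; near the ends the window shrinks so the output
#' has the same length as the input and no padding bias.
#' @param x numeric vector.
#' @param window odd integer window length; 1 returns x unchanged.
#' @keywords internal
moving_average <- function(x, window) {
  window <- check_count(window, "window")
  if (window == 1L) return(x)
  h <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Signed polygon area by the shoelace formula
#' @param xy two-column matrix of vertices (closed or open ring).
#' @return absolute area in the units of the vertices squared.
#' @keywords internal
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Even-odd point-in-polygon test
#'
#' Ray casting with the even-odd rule; points exactly on a horizontal edge
#' follow the usual half-open convention.
#'
#' @param px,py point coordinates (vectors).
#' @param poly two-column matrix of polygon vertices.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Simple-polygon check (no self intersection)
#' @keywords internal
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1L), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (k in (i + 2):n) {
      if (i == 1 && k == n) next  # adjacent through the closing edge
      if (inter(seg[i, ], seg[k, ])) return(FALSE)
    }
  }
  TRUE
}

#' Label 8-connected (or 4-connected) foreground components
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, H, W)
  if (length(idx) == 0) return(out)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  pos <- integer(H * W)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  co <- ((idx - 1L) %/% H) + 1L
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    r2 <- r + s[1]; c2 <- co + s[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- mask[nb]
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, pos[nb[hit]])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

#' Bilinear interpolation of a matrix at fractional (row, col) positions
#' @param img numeric matrix.
#' @param r,c fractional 1-based row/col coordinates.
#' @keywords internal
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H)
  c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * H + r0
  img[i00] * (1 - fr) * (1 - fc) + img[i00 + 1] * fr * (1 - fc) +
    img[i00 + H] * (1 - fr) * fc + img[i00 + H + 1] * fr * fc
}
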