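## A small vector letter font for logo drawing. Every glyph lives in the
## unit box [0,1] x [0,1] and is a union of filled polygons (strokes and
## elliptic ring segments), so letters can be stretched to an exact height
## in bits without touching device fonts. Round glyphs (O, Q) trace the
## outer ring counter-clockwise and the inner ring clockwise in one
## polygon, so the hole renders under the default nonzero winding rule.

.STROKE <- 0.18

## axis-aligned bar
.gbar <- function(x0, x1, y0, y1) {
  data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

.vbar <- function(x0, y0 = 0, y1 = 1, w = .STROKE) .gbar(x0, x0 + w, y0, y1)
.hbar <- function(y0, x0 = 0, x1 = 1, h = 0.16) .gbar(x0, x1, y0, y0 + h)

## thick segment between two points
.gseg <- function(x1, y1, x2, y2, w = .STROKE) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  px <- -dy / len * w / 2; py <- dx / len * w / 2
  data.frame(x = c(x1 + px, x2 + px, x2 - px, x1 - px),
             y = c(y1 + py, y2 + py, y2 - py, y1 - py))
}

## elliptic ring segment (degrees); full rings get their hole via winding
.gring <- function(cx = 0.5, cy = 0.5, rx = 0.5, ry = 0.5, th = .STROKE,
                   from = 0, to = 360, n = 40) {
  t1 <- seq(from, to, length.out = n) * pi / 180
  t2 <- rev(t1)
  data.frame(
    x = c(cx + rx * cos(t1), cx + (rx - th) * cos(t2)),
    y = c(cy + ry * sin(t1), cy + (ry - th) * sin(t2)))
}

.GLYPHS <- local({
  V <- .vbar; H <- .hbar; S <- .gseg; R <- .gring
  list(
    A = list(S(0.07, 0, 0.5, 1, 0.2), S(0.93, 0, 0.5, 1, 0.2),
             H(0.24, 0.2, 0.8, 0.14)),
    B = list(V(0), H(0.84), H(0.44, 0, 0.92), H(0, 0, 0.92), V(0.82, 0, 1)),
    C = list(R(from = 35, to = 325)),
    D = list(V(0), R(cx = 0.28, rx = 0.68, from = -88, to = 88)),
    E = list(V(0), H(0.84), H(0.44, 0, 0.85), H(0)),
    F = list(V(0), H(0.84), H(0.44, 0, 0.85)),
    G = list(R(from = 35, to = 325), H(0.36, 0.52, 1, 0.14),
             V(0.82, 0.06, 0.44)),
    H = list(V(0), V(0.82), H(0.44)),
    I = list(V(0.41), H(0.84, 0.12, 0.88), H(0, 0.12, 0.88)),
    J = list(H(0.84, 0.2, 1), V(0.58, 0.1, 1), H(0, 0.02, 0.76),
             V(0.02, 0, 0.3)),
    K = list(V(0), S(0.16, 0.52, 0.95, 1), S(0.16, 0.48, 0.95, 0)),
    L = list(V(0), H(0)),
    M = list(V(0), V(0.82), S(0.09, 1, 0.5, 0.4), S(0.91, 1, 0.5, 0.4)),
    N = list(V(0), V(0.82), S(0.09, 1, 0.91, 0)),
    O = list(R(from = 0, to = 360)),
    P = list(V(0), H(0.84, 0, 0.92), H(0.42, 0, 0.92), V(0.78, 0.42, 1)),
    Q = list(R(from = 0, to = 360), S(0.6, 0.32, 0.97, 0, 0.16)),
    R = list(V(0), H(0.84, 0, 0.92), H(0.42, 0, 0.92), V(0.78, 0.42, 1),
             S(0.5, 0.45, 0.95, 0)),
    S = list(H(0.84), V(0, 0.42, 0.95), H(0.42), V(0.82, 0.05, 0.56),
             H(0)),
    T = list(H(0.84), V(0.41)),
    U = list(V(0), V(0.82), H(0)),
    V = list(S(0.08, 1, 0.5, 0, 0.2), S(0.92, 1, 0.5, 0, 0.2)),
    W = list(S(0.05, 1, 0.27, 0), S(0.27, 0, 0.5, 0.6), S(0.5, 0.6, 0.73, 0),
             S(0.73, 0, 0.95, 1)),
    X = list(S(0.05, 0, 0.95, 1), S(0.05, 1, 0.95, 0)),
    Y = list(S(0.08, 1, 0.5, 0.48, 0.2), S(0.92, 1, 0.5, 0.48, 0.2),
             V(0.41, 0, 0.55)),
    Z = list(H(0.84), S(0.88, 0.84, 0.12, 0.16), H(0))
  )
})

## One letter's polygons as a data.frame with a `part` id per polygon.
.letterPolygon <- function(letter) {
  parts <- .GLYPHS[[toupper(letter)]]
  if (is.null(parts)) parts <- list(.gbar(0.1, 0.9, 0, 1))  # fallback block
  do.call(rbind, lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    p$part <- i
    p
  }))
}
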