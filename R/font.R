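# Minimal built-in 5x7 bitmap font covering the characters used in lead
# names (I, V, a, R, L, F, digits 1-6). Rendering text through a bundled
# bitmap keeps label masks pixel-exact without depending on system fonts.

.GLYPHS <- local({
  g <- list(
    "I" = c("11111", "00100", "00100", "00100", "00100", "00100", "11111"),
    "V" = c("10001", "10001", "10001", "10001", "01010", "01010", "00100"),
    "a" = c("00000", "00000", "01110", "00001", "01111", "10001", "01111"),
    "R" = c("11110", "10001", "10001", "11110", "10100", "10010", "10001"),
    "L" = c("10000", "10000", "10000", "10000", "10000", "10000", "11111"),
    "F" = c("11111", "10000", "10000", "11110", "10000", "10000", "10000"),
    "1" = c("00100", "01100", "00100", "00100", "00100", "00100", "01110"),
    "2" = c("01110", "10001", "00001", "00010", "00100", "01000", "11111"),
    "3" = c("11110", "00001", "00001", "01110", "00001", "00001", "11110"),
    "4" = c("00010", "00110", "01010", "10010", "11111", "00010", "00010"),
    "5" = c("11111", "10000", "11110", "00001", "00001", "10001", "01110"),
    "6" = c("00110", "01000", "10000", "11110", "10001", "10001", "01110")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]] == "1")))
  })
})

# Render a label as a binary matrix (1 = ink). `scale` is the integer pixel
# size of one font unit; glyphs are separated by one font unit.
render_label <- function(text, scale = 2) {
  chars <- strsplit(text, "")[[1]]
  glyphs <- lapply(chars, function(ch) {
    g <- .GLYPHS[[ch]]
    if (is.null(g)) stop("character not in built-in font: ", ch)
    g
  })
  h <- 7L
  w <- sum(vapply(glyphs, ncol, 1L)) + length(glyphs) - 1L
  out <- matrix(0L, h, w)
  x <- 1L
  for (g in glyphs) {
    out[, x:(x + ncol(g) - 1L)] <- g
    x <- x + ncol(g) + 1L
  }
  if (scale > 1) {
    out <- out[rep(seq_len(h), each = scale), rep(seq_len(w), each = scale)]
  }
  out
}
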