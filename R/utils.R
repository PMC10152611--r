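# internal helpers shared across renderers and pipelines

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# matrices of x (col) and y (row) coordinates for a raster
coord_grids <- function(x_mm, y_mm) {
  list(x = matrix(x_mm, nrow = length(y_mm), ncol = length(x_mm), byrow = TRUE),
       y = matrix(y_mm, nrow = length(y_mm), ncol = length(x_mm)))
}

# rasterized disk mask on a coordinate grid
disk_mask <- function(x_mm, y_mm, cx, cy, r) {
  g <- coord_grids(x_mm, y_mm)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}
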