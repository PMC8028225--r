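# Shared small fixtures built in code.

# Binary ellipsoid mask on an n^3 grid (semi-axes in voxels, centered).
ball_mask <- function(n, semi_axes) {
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  inside <- ((g$x - ctr) / semi_axes[1])^2 + ((g$y - ctr) / semi_axes[2])^2 +
    ((g$z - ctr) / semi_axes[3])^2 <= 1
  rad_mask(array(inside, c(n, n, n)))
}

const_volume <- function(dim3, value = 0, spacing = c(1, 1, 1)) {
  rad_volume(array(value, dim3), spacing = spacing)
}

full_mask <- function(dim3) rad_mask(array(TRUE, dim3))

# One cached mid-size textured phantom + features, shared across test files.
cached_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- make_tumor_phantom(seed = 7)
    ph
  }
})

cached_features <- local({
  fv <- NULL
  function() {
    if (is.null(fv)) {
      ph <- cached_phantom()
      fv <<- extract_features(ph$volume, ph$mask)
    }
    fv
  }
})
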