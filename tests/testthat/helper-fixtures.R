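# Shared fixtures, built in code at test time.

# A reduced acquisition for fast mechanistic tests: a 16 x 10 grid, an axis
# covering only the GM3/GM2 d18:1 channels, and a two-ion panel.
tiny_panel <- function(window = 0.5) {
  build_panel(list(
    window = window,
    ions = list(
      list(species = "GM3", ceramides = "d18:1", adducts = "[M-H]-"),
      list(species = "GM2", ceramides = "d18:1", adducts = "[M-H]-")
    )
  ))
}

tiny_config <- function(sigma_noise = 0, sigma_gain = 0,
                        fold_table = default_fold_table()) {
  cfg <- default_effect_config(sigma_noise = sigma_noise,
                               sigma_gain = sigma_gain,
                               fold_table = fold_table)
  cfg$nx <- 16L
  cfg$ny <- 10L
  cfg$mz_range <- c(1170, 1430)
  cfg$panel <- tiny_panel()
  cfg$amplitudes <- cfg$amplitudes[cfg$panel$ion]
  cfg$lesion <- list(cx = 4, cy = 4.5, rx = 2, ry = 2.5)
  cfg$midline_x <- 7.5
  cfg
}

# a small continuous-mode image with constant spectra, for geometry tests
flat_image <- function(nx = 6, ny = 6, mz = seq(100, 110, by = 0.5),
                       value = 1) {
  coords <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(ny - 1)))
  msi_image(coords, mz,
            matrix(value, nrow(coords), length(mz)), pitch_um = 100)
}

# independent point-in-polygon oracle: winding number by signed angles
winding_inside <- function(px, py, vx, vy) {
  vapply(seq_along(px), function(i) {
    dx <- vx - px[i]
    dy <- vy - py[i]
    a <- atan2(dy, dx)
    d <- diff(c(a, a[1L]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi  # ~2*pi inside, ~0 outside
  }, logical(1))
}
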