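# Shared numerical helpers: seeded evaluation, array rolling, Fourier
# shifting, bilinear sampling. Convention throughout the package: matrices
# are indexed [y, x] (row = slow axis, column = fast axis); coordinates in
# function arguments are 0-based (x = column, y = row) unless stated.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# circular shift: out[i, j] = m[i - dy, j - dx] (content moves by +dy, +dx)
roll2d <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  dy <- ((dy %% ny) + ny) %% ny
  dx <- ((dx %% nx) + nx) %% nx
  iy <- ((seq_len(ny) - 1 - dy) %% ny) + 1
  ix <- ((seq_len(nx) - 1 - dx) %% nx) + 1
  m[iy, ix, drop = FALSE]
}

# band-limited subpixel translation via the Fourier shift theorem;
# integer shifts reduce to an exact roll
fourier_shift <- function(m, dy, dx) {
  if (dy == round(dy) && dx == round(dx))
    return(roll2d(m, round(dy), round(dx)))
  ny <- nrow(m); nx <- ncol(m)
  fy <- c(0:floor((ny - 1) / 2), -(ceiling((ny - 1) / 2):1)) / ny
  fx <- c(0:floor((nx - 1) / 2), -(ceiling((nx - 1) / 2):1)) / nx
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, nx)) + outer(rep(1, ny), fx * dx)))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (ny * nx)
}

# bilinear sample at 0-based fractional coordinates; outside -> fill
bilinear_sample <- function(m, y, x, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  get_px <- function(yy, xx) {
    ok <- yy >= 0 & yy <= ny - 1 & xx >= 0 & xx <= nx - 1
    v <- rep(fill, length(yy))
    v[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  v00 <- get_px(y0, x0);     v01 <- get_px(y0, x0 + 1)
  v10 <- get_px(y0 + 1, x0); v11 <- get_px(y0 + 1, x0 + 1)
  v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
}

# rotate about the image centre by `theta` radians (counter-clockwise in
# (x, y) pixel coordinates), then translate by (dy, dx); bilinear resampling
rigid_transform_image <- function(m, theta, dy = 0, dx = 0, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  gy <- matrix(0:(ny - 1), ny, nx) - cy
  gx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE) - cx
  # inverse map: source = R(-theta) (target - t)
  ty <- gy - dy; tx <- gx - dx
  sy <- cos(theta) * ty - sin(theta) * tx + cy
  sx <- sin(theta) * ty + cos(theta) * tx + cx
  matrix(bilinear_sample(m, as.vector(sy), as.vector(sx), fill = fill), ny, nx)
}

# cross-correlation C(sy, sx) = sum_xy a(y, x) * b(y + sy, x + sx), computed
# on a zero-padded grid so there is no circular wrap-around. Returns a list
# with the correlation matrix and the lag vectors.
xcorr2d <- function(a, b, max_lag_y, max_lag_x) {
  ny <- nrow(a); nx <- ncol(a)
  py <- ny + max_lag_y; px <- nx + max_lag_x
  pa <- matrix(0, py, px); pb <- matrix(0, py, px)
  pa[1:ny, 1:nx] <- a; pb[1:ny, 1:nx] <- b
  cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE)) / (py * px)
  lag_y <- -max_lag_y:max_lag_y
  lag_x <- -max_lag_x:max_lag_x
  out <- matrix(0, length(lag_y), length(lag_x))
  for (i in seq_along(lag_y)) {
    iy <- ((lag_y[i] %% py) + py) %% py + 1
    for (j in seq_along(lag_x)) {
      ix <- ((lag_x[j] %% px) + px) %% px + 1
      out[i, j] <- cc[iy, ix]
    }
  }
  list(cc = out, lag_y = lag_y, lag_x = lag_x)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
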