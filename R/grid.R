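#' Spatial grid of neuron preferred positions
#'
#' A map of `n` neurons whose preferred positions tile the visual field of
#' extent `v` degrees uniformly, endpoints included: centres run from `-v/2`
#' to `v/2` with spacing `v / (n - 1)`.  Positive positions are in the
#' saccade (rightward) direction.
#'
#' @param n neuron count (>= 2).
#' @param v visual-field extent in degrees (> 0).
#' @return An object of class `lip_grid` with fields `n`, `v`, `centers`,
#'   `spacing`.
#' @export
#' @examples
#' g <- make_grid(40, 160)
#' range(g$centers)   # -80 80
#' g$spacing          # 160/39
make_grid <- function(n = 40, v = 160) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2")
  }
  if (!is.numeric(v) || length(v) != 1 || v <= 0) {
    abort("`v` must be a single positive number of degrees")
  }
  n <- as.integer(n)
  structure(list(n = n, v = v,
                 centers = seq(-v / 2, v / 2, length.out = n),
                 spacing = v / (n - 1)),
            class = "lip_grid")
}

#' @export
print.lip_grid <- function(x, ...) {
  cat(sprintf("<lip_grid> %d neurons over [%g, %g] deg (spacing %.3f deg)\n",
              x$n, -x$v / 2, x$v / 2, x$spacing))
  invisible(x)
}

#' Gaussian connection kernel
#'
#' Dense weight matrix with entries `K * exp(-d^2 / sigma^2)` for the declared
#' distance metric `d`.  For `direction = "horizontal"` or `"vertical"` both
#' source and target are 1-D grids and `d` is the distance in degrees between
#' preferred positions; the two directions only differ in how the resulting
#' matrix is meant to be applied (along rows vs. columns of a 2-D map).  For
#' `direction = "diagonal"` the target must be a 2-D map (a list of two
#' grids); the source indexes the `2n - 1` diagonals and the distance from
#' source diagonal `i` to target cell `(l, m)` is the index distance
#' `i + 1 - (l + m)`, i.e. diagonal `i` is aligned with cells satisfying
#' `l + m = i + 1`.
#'
#' @param source a [make_grid()] object (for diagonal kernels: the diagonal
#'   axis, with `2n - 1` bins).
#' @param target a [make_grid()] object, or for `direction = "diagonal"` a
#'   list of two grids describing the 2-D target.
#' @param K peak gain (> 0).
#' @param sigma kernel width (> 0), in degrees for horizontal/vertical and in
#'   grid-index units for diagonal kernels.
#' @param direction one of `"horizontal"`, `"vertical"`, `"diagonal"`.
#' @param normalize if `TRUE`, rows are rescaled to sum to 1 (smoothing
#'   kernel); `K` is applied after normalisation.
#' @return A list of class `lip_kernel` with the weight `matrix`
#'   (targets x sources) and the declared parameters.
#' @export
#' @examples
#' g <- make_grid(40, 160)
#' k <- gaussian_kernel(g, g, K = 0.02, sigma = 15)
#' k$matrix[1, 1]  # = K at zero distance
gaussian_kernel <- function(source, target, K, sigma,
                            direction = c("horizontal", "vertical",
                                          "diagonal"),
                            normalize = FALSE) {
  direction <- match.arg(direction)
  if (!is.numeric(K) || K <= 0) abort("`K` must be positive")
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be positive")
  if (direction == "diagonal") {
    if (!is.list(target) || length(target) != 2 ||
        !inherits(target[[1]], "lip_grid") ||
        !inherits(target[[2]], "lip_grid")) {
      abort("diagonal kernels require a 2-D target (a list of two grids)")
    }
    nl <- target[[1]]$n
    nm <- target[[2]]$n
    ns <- source$n
    lm <- as.vector(outer(seq_len(nl), seq_len(nm), `+`))   # l + m per cell
    d <- outer(lm, seq_len(ns) + 1, `-`)                    # (l+m) - (i+1)
    w <- exp(-d^2 / sigma^2)
  } else {
    if (!inherits(source, "lip_grid") || !inherits(target, "lip_grid")) {
      abort("horizontal/vertical kernels require 1-D grids")
    }
    d <- outer(target$centers, source$centers, `-`)
    w <- exp(-d^2 / sigma^2)
  }
  if (normalize) w <- w / rowSums(w)
  w <- K * w
  structure(list(matrix = w, K = K, sigma = sigma, direction = direction,
                 normalized = normalize),
            class = "lip_kernel")
}

#' Rate-coded neural population
#'
#' The universal state container of the model: a vector (1-D map) or matrix
#' (2-D map) of non-negative firing rates relaxing toward a drive with a
#' leaky-integrator time constant `tau`.
#'
#' @param grid a [make_grid()] object, or a list of two grids for a 2-D map.
#' @param tau time constant in ms.
#' @param rates optional initial rates (defaults to zeros).
#' @return An object of class `lip_pop` with fields `rates`, `tau`, `grid`.
#' @export
rate_population <- function(grid, tau = 10, rates = NULL) {
  if (inherits(grid, "lip_grid")) {
    shape <- grid$n
    init <- numeric(shape)
  } else if (is.list(grid) && length(grid) == 2) {
    init <- matrix(0, grid[[1]]$n, grid[[2]]$n)
  } else {
    abort("`grid` must be a lip_grid or a list of two lip_grids")
  }
  if (!is.null(rates)) {
    if (!identical(dim(rates), dim(init)) || length(rates) != length(init)) {
      abort("`rates` shape does not match the grid")
    }
    init[] <- rates
    if (any(init < 0)) abort("rates must be non-negative")
  }
  structure(list(rates = init, tau = tau, grid = grid), class = "lip_pop")
}

#' One explicit Euler step of the leaky integrator
#'
#' Advances `tau * dr/dt = drive - r` by `dt` ms:
#' `r <- r + (dt / tau) * (drive - r)`, clipped at zero afterwards so rates
#' stay non-negative.  `dt` must satisfy `dt <= tau / 5` (stability guard for
#' the explicit scheme).
#'
#' @param pop a [rate_population()].
#' @param drive drive array of the same shape as `pop$rates`.
#' @param dt step size in ms.
#' @return The updated population.
#' @export
#' @examples
#' g <- make_grid(5, 8)
#' p <- rate_population(g, tau = 10)
#' p <- euler_step(p, drive = rep(1, 5), dt = 1)
#' p$rates  # all 0.1 after one step from zero
euler_step <- function(pop, drive, dt = 1) {
  if (dt <= 0 || dt > pop$tau / 5) {
    abort("`dt` must be positive and at most tau/5")
  }
  if (length(drive) != length(pop$rates) ||
      !identical(dim(drive), dim(pop$rates))) {
    abort("drive shape does not match population rates")
  }
  r <- pop$rates + (dt / pop$tau) * (drive - pop$rates)
  r[r < 0] <- 0
  pop$rates <- r
  pop
}

# bare-array version used in the simulation inner loop (no validation)
step_rates <- function(r, drive, coef) {
  r <- r + coef * (drive - r)
  r[r < 0] <- 0
  r
}
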