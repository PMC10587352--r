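#' Clark 2Dt dispersal kernel
#'
#' Constructs a Clark 2Dt kernel used both to distance-weight adult
#' neighbourhood densities and to disperse recruits in the null model.
#' The weight at distance `d` (metres) is
#' \deqn{w(d) = (1 + d^2/u)^{-(p+1)}}
#' i.e. the 2Dt density normalised so that `w(0) = 1`: weights join
#' continuously with the unit weight given to adults inside the focal
#' quadrat, and decrease strictly with distance.
#'
#' Either `u` (squared-metre scale) or `mean_distance` must be given; when
#' `mean_distance` is supplied, `u` is solved from the kernel's mean
#' dispersal distance `sqrt(u) * p * Beta(3/2, p - 1/2)` (finite for
#' `p > 1/2`).
#'
#' @param u Scale parameter (m^2), positive.
#' @param p Shape parameter, dimensionless, positive. Default 1 (a heavy,
#'   Cauchy-like tail typical of tree seed shadows).
#' @param mean_distance Mean dispersal distance (m) used to solve for `u`
#'   when `u` is not given.
#' @return An object of class `clark2dt` with elements `u`, `p` and
#'   `mean_distance`.
#' @examples
#' k <- clark2dt(u = 100, p = 1)
#' kernel_weight(10, k) # 0.25
#' @export
clark2dt <- function(u = NULL, p = 1, mean_distance = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop("`p` must be a positive scalar")
  if (is.null(u)) {
    if (is.null(mean_distance))
      stop("supply either `u` or `mean_distance`")
    u <- kernel_scale_for_mean(mean_distance, p)
  }
  if (!is.numeric(u) || length(u) != 1L || u <= 0)
    stop("`u` must be a positive scalar")
  if (is.null(mean_distance)) mean_distance <- kernel_mean_distance(u, p)
  structure(list(u = u, p = p, mean_distance = mean_distance),
            class = "clark2dt")
}

#' @export
print.clark2dt <- function(x, ...) {
  cat(sprintf("Clark 2Dt kernel: u = %.4g m^2, p = %.3g, mean distance = %.4g m\n",
              x$u, x$p, x$mean_distance))
  invisible(x)
}

#' Kernel weight at a distance
#'
#' @param distance Distance in metres from the edge of the focal quadrat;
#'   non-negative, vectorised.
#' @param kernel A [clark2dt()] kernel.
#' @return Weights in (0, 1]; exactly 1 at distance 0.
#' @export
kernel_weight <- function(distance, kernel) {
  stopifnot(inherits(kernel, "clark2dt"))
  if (any(distance < 0)) stop("distance must be non-negative")
  (1 + distance^2 / kernel$u)^(-(kernel$p + 1))
}

#' Mean dispersal distance of a 2Dt kernel
#'
#' The radial density of the 2Dt kernel is
#' `f(r) = (2 p r / u) (1 + r^2/u)^(-(p+1))`, whose mean
#' `sqrt(u) * p * Beta(3/2, p - 1/2)` is finite for `p > 1/2`.
#'
#' @param u,p Kernel parameters.
#' @return Mean distance in metres.
#' @export
kernel_mean_distance <- function(u, p) {
  if (p <= 0.5) stop("mean distance is infinite for p <= 1/2")
  sqrt(u) * p * beta(1.5, p - 0.5)
}

#' Solve the kernel scale for a target mean dispersal distance
#'
#' @param mean_distance Target mean distance (m), positive.
#' @param p Kernel shape, must exceed 1/2.
#' @return The scale `u` (m^2).
#' @export
kernel_scale_for_mean <- function(mean_distance, p = 1) {
  if (!is.numeric(mean_distance) || mean_distance <= 0)
    stop("`mean_distance` must be positive")
  if (p <= 0.5) stop("mean distance is infinite for p <= 1/2")
  (mean_distance / (p * beta(1.5, p - 0.5)))^2
}

#' Sample dispersal distances from a 2Dt kernel
#'
#' Inverse-CDF sampling of the radial distribution
#' `F(r) = 1 - (1 + r^2/u)^(-p)`.
#'
#' @param n Number of draws.
#' @param kernel A [clark2dt()] kernel.
#' @return Vector of `n` non-negative distances (m).
#' @export
sample_kernel_distance <- function(n, kernel) {
  stopifnot(inherits(kernel, "clark2dt"))
  uu <- runif(n)
  sqrt(kernel$u * ((1 - uu)^(-1 / kernel$p) - 1))
}
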