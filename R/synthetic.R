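# Registry of the fourteen relationship families used as the package's
# test-bed. Ten are named classes of the original figure set (trigonometric,
# power, exponential, inverse-proportion and composite functions; taijitu,
# galaxy spiral, heart curve, polygonal line); the remaining four (circle,
# ellipse, cross, two intersecting lines) are standard non-functional test
# shapes completing the set and are reconstructions, not transcriptions.
relationship_registry <- function() {
  list(
    sine = list(kind = "function",
                f = function(u) list(x = 4 * pi * u, y = sin(4 * pi * u))),
    tangent = list(kind = "function",
                   f = function(u) {
                     x <- -1.4 + 2.8 * u
                     list(x = x, y = tan(x))
                   }),
    power = list(kind = "function",
                 f = function(u) {
                   x <- -2 + 4 * u
                   list(x = x, y = x^2)
                 }),
    exponential = list(kind = "function",
                       f = function(u) {
                         x <- 2 * u
                         list(x = x, y = 10^x)
                       }),
    inverse = list(kind = "function",
                   f = function(u) {
                     x <- 0.2 + 2.8 * u
                     list(x = x, y = 1 / x)
                   }),
    composite = list(kind = "function",
                     f = function(u) {
                       x <- 4 * pi * u
                       list(x = x, y = x * sin(x))
                     }),
    polygon = list(kind = "function",
                   f = function(u) {
                     # zigzag polygonal line with vertices at x = 0, .25, .5, .75, 1
                     y <- 1 - abs((u * 4) %% 2 - 1)
                     list(x = u, y = y)
                   }),
    taijitu = list(kind = "figure", f = function(u) taijitu_points(u)),
    galaxy = list(kind = "figure",
                  f = function(u) {
                    arm <- ifelse(u < 0.5, 0, pi)
                    v <- ifelse(u < 0.5, u * 2, (u - 0.5) * 2)
                    th <- 3 * pi * v
                    r <- v
                    list(x = r * cos(th + arm), y = r * sin(th + arm))
                  }),
    heart = list(kind = "figure",
                 f = function(u) {
                   t <- 2 * pi * u
                   list(x = 16 * sin(t)^3 / 17,
                        y = (13 * cos(t) - 5 * cos(2 * t) - 2 * cos(3 * t) -
                               cos(4 * t)) / 17)
                 }),
    circle = list(kind = "figure",
                  f = function(u) {
                    t <- 2 * pi * u
                    list(x = cos(t), y = sin(t))
                  }),
    ellipse = list(kind = "figure",
                   f = function(u) {
                     t <- 2 * pi * u
                     list(x = cos(t), y = 0.5 * sin(t))
                   }),
    cross = list(kind = "figure",
                 f = function(u) {
                   horiz <- u < 0.5
                   v <- ifelse(horiz, u * 2, (u - 0.5) * 2)
                   list(x = ifelse(horiz, 2 * v - 1, 0),
                        y = ifelse(horiz, 0, 2 * v - 1))
                 }),
    two_lines = list(kind = "figure",
                     f = function(u) {
                       pos <- u < 0.5
                       v <- ifelse(pos, u * 2, (u - 0.5) * 2)
                       x <- 2 * v - 1
                       list(x = x, y = ifelse(pos, x, -x))
                     })
  )
}

taijitu_points <- function(u) {
  n <- length(u)
  x <- numeric(n)
  y <- numeric(n)
  outer <- u < 0.5                       # outer circle, radius 1
  t <- 2 * pi * (u[outer] / 0.5)
  x[outer] <- cos(t)
  y[outer] <- sin(t)
  scurve <- u >= 0.5 & u < 0.85          # S-boundary: two half circles r = 1/2
  v <- (u[scurve] - 0.5) / 0.35
  upper <- v < 0.5
  t <- numeric(sum(scurve))
  t[upper] <- pi * (v[upper] * 2) - pi / 2
  t[!upper] <- pi * ((v[!upper] - 0.5) * 2) + pi / 2
  cy <- ifelse(upper, 0.5, -0.5)
  x[scurve] <- 0.5 * cos(t)
  y[scurve] <- cy + 0.5 * sin(t)
  eyes <- u >= 0.85                      # the two dots, radius 0.1
  v <- (u[eyes] - 0.85) / 0.15
  upper <- v < 0.5
  t <- 2 * pi * ifelse(upper, v * 2, (v - 0.5) * 2)
  cy <- ifelse(upper, 0.5, -0.5)
  x[eyes] <- 0.1 * cos(t)
  y[eyes] <- cy + 0.1 * sin(t)
  list(x = x, y = y)
}

#' Registered relationship family names
#'
#' @return Character vector of the 14 family names accepted by
#'   [generate_relationship()].
#' @export
relationship_families <- function() {
  names(relationship_registry())
}

# relative noise amplitudes for levels 0..3, as a fraction of each
# coordinate's range
noise_sigma_levels <- c(0, 0.05, 0.15, 0.30)

#' Generate a synthetic relationship sample
#'
#' Draws `n` points from one of the 14 registered relationship families.
#' Function families sample `x` uniformly over the family's domain and set
#' `y = f(x)`; figure families sample uniformly along their curve. At
#' `noise_level > 0`, centered Gaussian noise with standard deviation
#' `{0.05, 0.15, 0.30}` of the coordinate range is added to `y` (and to `x`
#' for figure families, whose shapes have no privileged axis). Deterministic
#' per seed.
#'
#' @param family One of [relationship_families()].
#' @param noise_level Integer 0 (noiseless) to 3 (heaviest noise).
#' @param n Number of points (default 2000, the original figure sampling
#'   density).
#' @param seed Integer seed.
#' @return A [paired_sample()].
#' @examples
#' s <- generate_relationship("power", noise_level = 0, n = 100, seed = 1)
#' all(s$ys == s$xs^2)
#' @export
generate_relationship <- function(family, noise_level = 0L, n = 2000L,
                                  seed = 1L) {
  reg <- relationship_registry()
  if (!family %in% names(reg)) {
    stop("unknown family '", family, "'; registered families: ",
         paste(names(reg), collapse = ", "))
  }
  stopifnot(noise_level %in% 0:3, n >= 4)
  fam <- reg[[family]]
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  u <- stats::runif(n)
  pts <- fam$f(u)
  x <- pts$x
  y <- pts$y
  if (noise_level > 0L) {
    sigma <- noise_sigma_levels[noise_level + 1L]
    y <- y + stats::rnorm(n, 0, sigma * diff(range(y)))
    if (fam$kind == "figure") {
      x <- x + stats::rnorm(n, 0, sigma * diff(range(x)))
    }
  }
  paired_sample(x, y)
}

#' Independent uniform random cloud
#'
#' `n` points with `x` and `y` independent U(0, 1) — the null model used to
#' calibrate the grid-size budget. Deterministic per seed.
#'
#' @param n Number of points.
#' @param seed Integer seed.
#' @return A [paired_sample()].
#' @export
random_cloud <- function(n, seed = 1L) {
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  paired_sample(stats::runif(n), stats::runif(n))
}

#' Full relationship suite: 14 families at 4 noise levels
#'
#' All 56 family-by-noise combinations, each generated with a distinct seed
#' derived from `seed`.
#'
#' @param n Points per sample.
#' @param seed Base seed.
#' @return List of 56 entries, each a list with `family`, `noise_level`,
#'   `seed` and `sample`.
#' @export
relationship_suite <- function(n = 2000L, seed = 1L) {
  fams <- relationship_families()
  out <- vector("list", length(fams) * 4L)
  k <- 0L
  for (fi in seq_along(fams)) {
    for (lvl in 0:3) {
      k <- k + 1L
      sub_seed <- (seed * 101L + fi * 10L + lvl) %% .Machine$integer.max
      out[[k]] <- list(
        family = fams[fi], noise_level = lvl, seed = sub_seed,
        sample = generate_relationship(fams[fi], lvl, n, sub_seed)
      )
    }
  }
  out
}
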