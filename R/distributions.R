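#' Distribution specifications for Monte Carlo inputs
#'
#' Small declarative specs for the input distributions propagated through
#' the exposure equations. Supported families: `point` (`value`), `normal`
#' (`mean`, `sd`), `lognormal` (`meanlog`/`sdlog`, or arithmetic
#' `mean`/`sd` which are moment-matched), `uniform` (`min`, `max`) and
#' `triangular` (`min`, `mode`, `max`). Optional truncation bounds are
#' enforced by rejection sampling.
#'
#' @param family Distribution family name.
#' @param ... Family parameters (see above).
#' @param lower,upper Optional truncation bounds (`lower < upper`).
#' @return List of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("lognormal", mean = 0.45, sd = 0.15)
#' dist_spec("triangular", min = 0, mode = 1, max = 2)
dist_spec <- function(family = c("point", "normal", "lognormal", "uniform",
                                 "triangular"),
                      ..., lower = NULL, upper = NULL) {
  family <- match.arg(family)
  p <- list(...)
  switch(family,
    point = {
      if (!is.numeric(p[["value"]]) || length(p[["value"]]) != 1) {
        stop("point spec needs a single numeric `value`", call. = FALSE)
      }
    },
    normal = {
      if (is.null(p[["mean"]]) || is.null(p[["sd"]]) || p[["sd"]] <= 0) {
        stop("normal spec needs `mean` and `sd` > 0", call. = FALSE)
      }
    },
    lognormal = {
      if (!is.null(p[["mean"]]) && !is.null(p[["sd"]])) {
        if (p[["mean"]] <= 0 || p[["sd"]] <= 0) {
          stop("lognormal arithmetic `mean` and `sd` must be positive",
               call. = FALSE)
        }
        cv2 <- (p[["sd"]] / p[["mean"]])^2
        p[["sdlog"]] <- sqrt(log(1 + cv2))
        p[["meanlog"]] <- log(p[["mean"]]) - p[["sdlog"]]^2 / 2
      }
      if (is.null(p[["meanlog"]]) || is.null(p[["sdlog"]]) || p[["sdlog"]] <= 0) {
        stop("lognormal spec needs `meanlog`/`sdlog` (or `mean`/`sd`)",
             call. = FALSE)
      }
    },
    uniform = {
      if (is.null(p[["min"]]) || is.null(p[["max"]]) || p[["min"]] >= p[["max"]]) {
        stop("uniform spec needs `min` < `max`", call. = FALSE)
      }
    },
    triangular = {
      if (is.null(p[["min"]]) || is.null(p[["mode"]]) || is.null(p[["max"]]) ||
          p[["min"]] > p[["mode"]] || p[["mode"]] > p[["max"]] || p[["min"]] >= p[["max"]]) {
        stop("triangular spec needs min <= mode <= max with min < max",
             call. = FALSE)
      }
    }
  )
  if (!is.null(lower) && !is.null(upper) && lower >= upper) {
    stop("truncation bounds must satisfy lower < upper", call. = FALSE)
  }
  structure(list(family = family, params = p, lower = lower, upper = upper),
            class = "dist_spec")
}

# run code under a temporary RNG state; the caller's stream is untouched
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

draw_raw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    point = rep(p[["value"]], n),
    normal = rnorm(n, p[["mean"]], p[["sd"]]),
    lognormal = rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    uniform = runif(n, p[["min"]], p[["max"]]),
    triangular = {
      u <- runif(n)
      fc <- (p[["mode"]] - p[["min"]]) / (p[["max"]] - p[["min"]])
      ifelse(u < fc,
             p[["min"]] + sqrt(u * (p[["max"]] - p[["min"]]) * (p[["mode"]] - p[["min"]])),
             p[["max"]] - sqrt((1 - u) * (p[["max"]] - p[["min"]]) * (p[["max"]] - p[["mode"]])))
    }
  )
}

#' Draw from a distribution spec
#'
#' Reproducible given `seed`; truncation bounds are enforced by rejection
#' with a bounded number of attempts.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param seed Optional integer; when given, draws are taken under a local
#'   RNG state and the caller's random stream is left untouched.
#' @param max_rounds Rejection rounds before giving up on truncation.
#' @return Numeric vector of `n` draws.
#' @export
#' @examples
#' draw_dist(dist_spec("point", value = 3), 5)
#' draw_dist(dist_spec("uniform", min = 0, max = 1), 3, seed = 42)
draw_dist <- function(spec, n, seed = NULL, max_rounds = 100L) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  with_local_seed(seed, {
    x <- draw_raw(spec, n)
    lo <- if (is.null(spec$lower)) -Inf else spec$lower
    hi <- if (is.null(spec$upper)) Inf else spec$upper
    if (is.finite(lo) || is.finite(hi)) {
      bad <- which(x < lo | x > hi)
      rounds <- 0L
      while (length(bad) > 0 && rounds < max_rounds) {
        x[bad] <- draw_raw(spec, length(bad))
        bad <- bad[x[bad] < lo | x[bad] > hi]
        rounds <- rounds + 1L
      }
      if (length(bad) > 0) {
        stop("truncation bounds reject essentially all mass for family '",
             spec$family, "'", call. = FALSE)
      }
    }
    x
  })
}
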