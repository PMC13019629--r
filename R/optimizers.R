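#' Configuration of the deflation (Hermitian) stage
#'
#' @param penalty Overlap penalty weight `c` (default 100).
#' @param max_iter Maximum optimization iterations for COBYLA (default 2^9).
#' @param optimizer `"cobyla"` for noiseless runs, `"nft"` (sequential
#'   single-angle sinusoid minimization) for noisy ones.
#' @param f_max Maximum function evaluations for NFT (default 2^11).
#' @param reset_interval NFT re-anchoring interval `R` in parameter updates
#'   (default 32).
#' @return Object of class `deflation_config`.
#' @export
deflation_config <- function(penalty = 100, max_iter = 2^9,
                             optimizer = c("cobyla", "nft"),
                             f_max = 2^11, reset_interval = 32) {
  optimizer <- match.arg(optimizer)
  stopifnot(penalty > 0, max_iter >= 1, f_max >= 3, reset_interval >= 1)
  structure(list(penalty = penalty, max_iter = max_iter,
                 optimizer = optimizer, f_max = f_max,
                 reset_interval = reset_interval),
            class = "deflation_config")
}

#' Sequential sinusoid-fitting (NFT) optimizer
#'
#' Minimizes an objective that, as a function of any single rotation angle
#' with the others held fixed, is an exact sinusoid
#' \eqn{f(\theta) = c_0 + A\cos(\theta - \varphi)} - true of any circuit
#' expectation value, including overlap penalties. Each update evaluates the
#' objective at \eqn{\theta \pm \pi/2}, solves for the sinusoid, and jumps
#' to its minimum \eqn{\varphi + \pi}. Parameters are swept cyclically; the
#' anchor value is re-evaluated every `reset_interval` updates to prevent
#' drift of the accumulated estimate under measurement noise.
#'
#' @param fn Objective function of a parameter vector.
#' @param p0 Starting parameter vector (angles, radians).
#' @param f_max Total function-evaluation budget.
#' @param reset_interval Updates between full re-evaluations of the anchor.
#' @return List with `par`, `value` (best seen), `evals` and `status`.
#' @export
nft_minimize <- function(fn, p0, f_max = 2^11, reset_interval = 32) {
  p <- p0
  evals <- 0
  ev <- function(x) { evals <<- evals + 1; fn(x) }
  f_cur <- ev(p)
  best_p <- p; best_f <- f_cur
  k <- 0; updates <- 0
  m <- length(p)
  while (evals + 2 <= f_max) {
    k <- k %% m + 1
    pp <- p; pp[k] <- p[k] + pi / 2
    f_plus <- ev(pp)
    pp[k] <- p[k] - pi / 2
    f_minus <- ev(pp)
    c0 <- (f_plus + f_minus) / 2
    a_sin <- (f_minus - f_plus) / 2       # A sin(theta_k - phi)
    a_cos <- f_cur - c0                   # A cos(theta_k - phi)
    amp <- sqrt(a_sin^2 + a_cos^2)
    phi <- p[k] - atan2(a_sin, a_cos)
    p[k] <- phi + pi
    f_cur <- c0 - amp                     # sinusoid minimum (model value)
    updates <- updates + 1
    if (updates %% reset_interval == 0 && evals < f_max) f_cur <- ev(p)
    if (f_cur < best_f) { best_f <- f_cur; best_p <- p }
  }
  f_end <- if (evals < f_max) ev(p) else f_cur
  if (f_end < best_f) { best_f <- f_end; best_p <- p }
  list(par = best_p, value = best_f, evals = evals,
       status = if (best_f <= fn(p0) + 1e-12) "ok" else "no-improvement")
}

#' Minimize a deflation-stage objective
#'
#' Dispatches to COBYLA (derivative-free linear-approximation trust region,
#' noiseless default) or to [nft_minimize()] per the configuration, with
#' best-seen bookkeeping so the returned value never exceeds the starting
#' one in exact mode.
#'
#' @param fn Objective function of a parameter vector.
#' @param p0 Starting parameters.
#' @param cfg A [deflation_config()].
#' @return List with `par`, `value`, `evals`, `status`.
#' @export
optimize_parameters <- function(fn, p0, cfg = deflation_config()) {
  best_f <- Inf; best_p <- p0; evals <- 0
  wrapped <- function(x) {
    v <- fn(x)
    evals <<- evals + 1
    if (v < best_f) { best_f <<- v; best_p <<- x }
    v
  }
  if (cfg$optimizer == "cobyla") {
    # every rotation angle is 2*pi-periodic, so the box p0 +/- pi covers
    # the full torus of parameters; the bounds also give COBYLA its
    # length scale (unit initial variable change on angle parameters)
    res <- nloptr::cobyla(p0, wrapped,
                          lower = p0 - pi, upper = p0 + pi,
                          control = list(maxeval = cfg$max_iter))
    f0 <- fn(p0)
    status <- if (best_f <= f0 + 1e-12) "ok" else "no-improvement"
    list(par = best_p, value = best_f, evals = evals, status = status)
  } else {
    nft_minimize(fn, p0, f_max = cfg$f_max,
                 reset_interval = cfg$reset_interval)
  }
}
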