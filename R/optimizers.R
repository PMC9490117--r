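# Design of experiments and bounded global optimizers over the design space.

#' Latin hypercube sample of scaffold designs
#'
#' Space-filling design with exactly one point per equal-width stratum per
#' dimension. The default size is 20 times the number of design variables
#' (60 points for the three pore-size parameters).
#'
#' @param n Number of samples; defaults to `20 * length(bounds$lower)`.
#' @param bounds List with `lower`/`upper` per dimension
#'   (default [design_bounds()]).
#' @param seed RNG seed.
#' @return A tibble with one column per dimension (`x1`, `x2`, ...).
#' @export
lhs_sample <- function(n = NULL, bounds = design_bounds(), seed = 1) {
  d <- length(bounds$lower)
  if (is.null(n)) n <- 20L * d
  stopifnot(n >= 1)
  set.seed(seed)
  U <- lhs::randomLHS(n, d)
  X <- sweep(sweep(U, 2, bounds$upper - bounds$lower, `*`), 2,
             bounds$lower, `+`)
  colnames(X) <- paste0("x", seq_len(d))
  tibble::as_tibble(X)
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

## individual algorithms; all maximize f over box bounds ------------------

pattern_search <- function(f, lower, upper, start, step = NULL,
                           tol = 1e-4, max_iter = 500) {
  x <- clamp(start, lower, upper)
  fx <- f(x)
  if (is.null(step)) step <- (upper - lower) / 4
  iter <- 0
  while (max(step) > tol && iter < max_iter) {
    iter <- iter + 1
    improved <- FALSE
    for (k in seq_along(x)) {
      for (sgn in c(1, -1)) {
        cand <- x
        cand[k] <- clamp(x[k] + sgn * step[k], lower[k], upper[k])
        if (all(cand == x)) next
        fc <- f(cand)
        if (fc > fx) { x <- cand; fx <- fc; improved <- TRUE }
      }
    }
    if (!improved) step <- step / 2
  }
  list(par = x, value = fx, iterations = iter)
}

genetic_algorithm <- function(fbatch, lower, upper, pop = 50,
                              generations = 50, p_mut = 0.2, elite = 2) {
  d <- length(lower)
  P <- matrix(0, pop, d)
  for (k in seq_len(d)) P[, k] <- stats::runif(pop, lower[k], upper[k])
  fit <- fbatch(P)
  for (g in seq_len(generations)) {
    ord <- order(fit, decreasing = TRUE)
    newP <- P[ord[seq_len(elite)], , drop = FALSE]
    while (nrow(newP) < pop) {
      # tournament selection (size 3) of two parents
      pick <- function() {
        cand <- sample.int(pop, 3)
        cand[which.max(fit[cand])]
      }
      pa <- P[pick(), ]; pb <- P[pick(), ]
      w <- stats::runif(d)
      child <- w * pa + (1 - w) * pb
      mut <- stats::runif(d) < p_mut
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, 0.1 * (upper[mut] - lower[mut]))
      newP <- rbind(newP, clamp(child, lower, upper))
    }
    P <- newP
    fit <- fbatch(P)
  }
  best <- which.max(fit)
  list(par = P[best, ], value = fit[best], iterations = generations)
}

particle_swarm <- function(fbatch, lower, upper, pop = 30, iterations = 100,
                           inertia = 0.729, c1 = 1.49445, c2 = 1.49445) {
  d <- length(lower)
  P <- matrix(0, pop, d); V <- matrix(0, pop, d)
  for (k in seq_len(d)) {
    P[, k] <- stats::runif(pop, lower[k], upper[k])
    V[, k] <- stats::runif(pop, -(upper[k] - lower[k]), upper[k] - lower[k]) / 2
  }
  fit <- fbatch(P)
  Pb <- P; fb <- fit
  g <- which.max(fb)
  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(pop * d), pop, d)
    r2 <- matrix(stats::runif(pop * d), pop, d)
    G <- matrix(Pb[g, ], pop, d, byrow = TRUE)
    V <- inertia * V + c1 * r1 * (Pb - P) + c2 * r2 * (G - P)
    P <- P + V
    for (k in seq_len(d)) P[, k] <- clamp(P[, k], lower[k], upper[k])
    fit <- fbatch(P)
    upd <- fit > fb
    Pb[upd, ] <- P[upd, , drop = FALSE]; fb[upd] <- fit[upd]
    g <- which.max(fb)
  }
  list(par = Pb[g, ], value = fb[g], iterations = iterations)
}

#' Optimizer configuration
#'
#' @param algorithm One of `"pattern_search"`, `"genetic"`,
#'   `"particle_swarm"`.
#' @param pattern_start Initial point of the pattern search (mm).
#' @param pso_pop,pso_iter,ga_pop,ga_gen Population sizes and iteration caps.
#' @param loop1_tolerance Surrogate-vs-oracle discrepancy tolerance on the
#'   objective.
#' @param loop1_metric `"absolute"` (default; the objective lives on the
#'   `[0, 1]` bone-fraction scale) or `"relative"` (discrepancy divided by
#'   the oracle value).
#' @param loop1_max_extra,loop2_max_extra Caps on additional oracle calls in
#'   the two framework loops.
#' @param seed RNG seed for the optimizer and sampling.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("particle_swarm", "genetic",
                                           "pattern_search"),
                             pattern_start = c(2.05, 2.05, 1.65),
                             pso_pop = 30, pso_iter = 100,
                             ga_pop = 50, ga_gen = 50,
                             loop1_tolerance = 0.05,
                             loop1_metric = c("absolute", "relative"),
                             loop1_max_extra = 30, loop2_max_extra = 30,
                             seed = 1) {
  algorithm <- match.arg(algorithm)
  loop1_metric <- match.arg(loop1_metric)
  stopifnot(loop1_tolerance > 0)
  structure(list(algorithm = algorithm, pattern_start = pattern_start,
                 pso_pop = pso_pop, pso_iter = pso_iter, ga_pop = ga_pop,
                 ga_gen = ga_gen, loop1_tolerance = loop1_tolerance,
                 loop1_metric = loop1_metric,
                 loop1_max_extra = loop1_max_extra,
                 loop2_max_extra = loop2_max_extra, seed = seed),
            class = "optimizer_config")
}

#' Maximize a surrogate (or any objective) within the design bounds
#'
#' Runs the selected global optimizer — pattern search from the fixed
#' initial point, a generational GA with tournament selection, or global-best
#' PSO — on the surrogate prediction and returns the best point evaluated.
#'
#' @param model A `kriging_model`, or a function taking a design vector.
#' @param config An [optimizer_config()].
#' @param bounds List with `lower`/`upper`.
#' @return List with `par` (design vector), `value` (predicted objective) and
#'   `algorithm`.
#' @export
optimize_surrogate <- function(model, config = optimizer_config(),
                               bounds = design_bounds()) {
  if (is.function(model)) {
    f <- model
    fbatch <- function(X) apply(X, 1, model)
  } else {
    f <- function(x) predict(model, matrix(x, nrow = 1),
                             check_bounds = FALSE)$mean
    fbatch <- function(X) predict(model, X, check_bounds = FALSE)$mean
  }
  set.seed(config$seed)
  res <- switch(config$algorithm,
    pattern_search = pattern_search(f, bounds$lower, bounds$upper,
                                    config$pattern_start),
    genetic = genetic_algorithm(fbatch, bounds$lower, bounds$upper,
                                pop = config$ga_pop,
                                generations = config$ga_gen),
    particle_swarm = particle_swarm(fbatch, bounds$lower, bounds$upper,
                                    pop = config$pso_pop,
                                    iterations = config$pso_iter))
  res$algorithm <- config$algorithm
  res
}
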