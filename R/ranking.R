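## Design selection: logistic per-criterion fitness and the fuzzy-logic
## product objective, plus energy-style ranking.

#' Logistic fitness of a criterion value
#'
#' `f = 1 / (1 + exp((x - mu) / sigma))` for a desirable criterion (lower
#' values are better: f approaches 1 as x falls below the ensemble mean and
#' 0 as it rises above); an undesirable criterion is handled by negating x
#' and mu. `f(mu) = 0.5` always. Values are kept strictly inside (0, 1)
#' (the exponential is saturated at machine-adjacent bounds).
#'
#' @param x Criterion value(s).
#' @param mu,sigma Ensemble mean and standard deviation of the criterion
#'   (`sigma > 0`).
#' @param sense `"desirable"` or `"undesirable"`.
#' @return Fitness value(s) in (0, 1).
#' @export
logistic_fitness <- function(x, mu, sigma, sense = c("desirable", "undesirable")) {
  sense <- match.arg(sense)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (sense == "undesirable") { x <- -x; mu <- -mu }
  z <- (x - mu) / sigma
  f <- stats::plogis(-z)
  pmin(pmax(f, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Ensemble mean and standard deviation of a criterion
#'
#' Population (divide-by-n) standard deviation; a constant ensemble is
#' rejected because the logistic fitness would be undefined.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Named vector `c(mu, sigma)`.
#' @export
ensemble_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2)
    stop("criterion is constant over the ensemble (sigma would be 0)")
  mu <- mean(values)
  c(mu = mu, sigma = sqrt(mean((values - mu)^2)))
}

#' Fuzzy-logic product objective
#'
#' Product of per-criterion fitness terms. Scores near 1 indicate a
#' favorable compromise across all features; any single poor feature drives
#' the product toward 0.
#'
#' @param fitnesses Numeric vector of per-criterion fitness values in (0,1).
#' @return The product objective.
#' @export
objective <- function(fitnesses) {
  if (length(fitnesses) == 0) stop("no fitness terms")
  prod(fitnesses)
}

#' Define a ranking criterion
#'
#' @param name Feature column name in the candidates' `feature_values`.
#' @param sense `"desirable"` (lower is better, e.g. computed energy) or
#'   `"undesirable"` (higher is worse is already the desirable convention;
#'   use undesirable for features where *low* raw values are bad).
#' @param mu,sigma Optional fixed ensemble statistics; computed from the
#'   candidate ensemble when omitted.
#' @return Object of class `criterion`.
#' @export
criterion <- function(name, sense = "desirable", mu = NULL, sigma = NULL) {
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0")
  structure(list(name = name, sense = sense, mu = mu, sigma = sigma),
            class = "criterion")
}

.recipe_key <- function(cand) {
  paste(vapply(names(cand$recipe),
               function(s) as.character(cand$recipe[[s]]), ""),
        collapse = "|")
}

#' Rank design candidates
#'
#' Energy mode sorts ascending by a single named energy-like feature; fuzzy
#' mode computes the logistic fitness of every criterion against the
#' candidate ensemble and sorts descending by the product objective. Ties
#' are broken by lexicographic recipe order; candidates missing a needed
#' feature are excluded with a warning.
#'
#' @param candidates List of `design_candidate` objects carrying
#'   `feature_values`.
#' @param mode `"energy"` or `"fuzzy"`.
#' @param criteria For fuzzy mode, a list of [criterion()] objects; for
#'   energy mode, the single feature name (default `"energy"`).
#' @return The candidates in rank order, with a `report` attribute: a data
#'   frame of feature values, per-criterion fitness and objective.
#' @export
rank_designs <- function(candidates, mode = c("fuzzy", "energy"),
                         criteria = NULL) {
  mode <- match.arg(mode)
  if (length(candidates) == 0) stop("no candidates")
  feat <- function(cand, nm) {
    v <- cand$feature_values[nm]
    if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
  }
  keys <- vapply(candidates, .recipe_key, "")
  if (mode == "energy") {
    nm <- if (is.null(criteria)) "energy" else
      if (is.character(criteria)) criteria[1] else criteria[[1]]$name
    x <- vapply(candidates, feat, 0, nm = nm)
    ok <- !is.na(x)
    if (any(!ok)) warning(sum(!ok), " candidate(s) missing feature '", nm,
                          "' excluded from ranking")
    ord <- order(x[ok], keys[ok])
    out <- candidates[ok][ord]
    attr(out, "report") <- data.frame(recipe = keys[ok][ord],
                                      energy = x[ok][ord])
    return(out)
  }
  if (is.null(criteria) || length(criteria) == 0)
    stop("fuzzy mode requires at least one criterion")
  fmat <- matrix(NA_real_, length(candidates), length(criteria))
  colnames(fmat) <- vapply(criteria, function(cr) cr$name, "")
  xmat <- fmat
  for (j in seq_along(criteria)) {
    cr <- criteria[[j]]
    x <- vapply(candidates, feat, 0, nm = cr$name)
    xmat[, j] <- x
    if (is.null(cr$mu) || is.null(cr$sigma)) {
      st <- ensemble_stats(x)
      cr$mu <- st["mu"]; cr$sigma <- st["sigma"]
    }
    fmat[, j] <- logistic_fitness(x, cr$mu, cr$sigma, cr$sense)
  }
  ok <- stats::complete.cases(xmat)
  if (any(!ok)) warning(sum(!ok), " candidate(s) missing criterion values ",
                        "excluded from ranking")
  O <- apply(fmat[ok, , drop = FALSE], 1, objective)
  ord <- order(-O, keys[ok])
  out <- candidates[ok][ord]
  rep_df <- data.frame(recipe = keys[ok][ord], xmat[ok, , drop = FALSE][ord, , drop = FALSE])
  for (j in seq_along(criteria))
    rep_df[[paste0("f_", colnames(fmat)[j])]] <- fmat[ok, j][ord]
  rep_df$objective <- O[ord]
  attr(out, "report") <- rep_df
  out
}
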