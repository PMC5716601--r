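#' The twelve-member value-function model space
#'
#' Candidate functions assigning a subjective value V(G, D) to a composite
#' offer made of a monetary gain G for the subject and a donation D for a
#' charity (both in euros). The space spans single-dimension rules (Leontief
#' "mini", "maxi"), additive and interactive combinations with optional
#' power transforms, equity-sensitive forms (linear-equity, Fehr-Schmidt
#' inequity aversion), and production functions (Cobb-Douglas and the
#' constant elasticity of substitution family, of which linear, Leontief and
#' Cobb-Douglas are special or limit cases).
#'
#' Parameter domains: weights `alpha`, `beta` are non-negative for weighting
#' models; the CES share `alpha` lies in \[0, 1\]; exponents `delta`,
#' `epsilon` are strictly positive; interaction weights `gamma` and the
#' Fehr-Schmidt envy/guilt coefficients are unconstrained. Each parameter
#' carries a transform ("log", "logit" or "identity") mapping its native
#' domain to an unconstrained scale used by the fitting routines.
#'
#' @return `value_model_space()` returns a list of 12 model specifications,
#'   each a list with elements `id`, `name`, `params` (named character
#'   vector of transforms, one per value parameter) and `fun`.
#' @examples
#' space <- value_model_space()
#' vapply(space, `[[`, "", "name")
#' @export
value_model_space <- function() .model_space

#' @rdname value_model_space
#' @param model A model id (1-12) or name (e.g. `"ces"`).
#' @return `value_model()` returns the single matching specification.
#' @export
value_model <- function(model) {
  if (is.numeric(model)) {
    if (length(model) != 1L || is.na(model) || model < 1 || model > 12)
      stop("model id must be a single integer in 1..12")
    return(.model_space[[as.integer(model)]])
  }
  nm <- match.arg(as.character(model), vapply(.model_space, `[[`, "", "name"))
  .model_space[[match(nm, vapply(.model_space, `[[`, "", "name"))]]
}

# 0^d = 0 for d > 0 is R's native behaviour; transforms keep exponents > 0.
.pow <- function(x, d) x^d

# Numerically stable CES: factor out the larger amount so 100^delta never
# overflows for the large exponents visited by unconstrained optimisation.
.ces_value <- function(alpha, delta, G, D) {
  n <- max(length(G), length(D))
  G <- rep_len(G, n); D <- rep_len(D, n)
  M <- pmax(G, D)
  pos <- M > 0
  V <- numeric(n)
  if (any(pos)) {
    g <- G[pos] / M[pos]
    d <- D[pos] / M[pos]
    inner <- alpha * g^delta + (1 - alpha) * d^delta
    V[pos] <- M[pos] * inner^(1 / delta)
  }
  V
}

.model_space <- list(
  list(id = 1L, name = "mini",
       params = c(alpha = "log", beta = "log"),
       fun = function(p, G, D) pmin(p[["alpha"]] * G, p[["beta"]] * D)),
  list(id = 2L, name = "maxi",
       params = c(alpha = "log", beta = "log"),
       fun = function(p, G, D) pmax(p[["alpha"]] * G, p[["beta"]] * D)),
  list(id = 3L, name = "linear-independent",
       params = c(alpha = "log", beta = "log"),
       fun = function(p, G, D) p[["alpha"]] * G + p[["beta"]] * D),
  list(id = 4L, name = "similarly-nonlinear-independent",
       params = c(alpha = "log", beta = "log", delta = "log"),
       fun = function(p, G, D)
         p[["alpha"]] * .pow(G, p[["delta"]]) + p[["beta"]] * .pow(D, p[["delta"]])),
  list(id = 5L, name = "nonlinear-independent",
       params = c(alpha = "log", beta = "log", delta = "log", epsilon = "log"),
       fun = function(p, G, D)
         p[["alpha"]] * .pow(G, p[["delta"]]) + p[["beta"]] * .pow(D, p[["epsilon"]])),
  list(id = 6L, name = "linear-interactive",
       params = c(alpha = "log", beta = "log", gamma = "identity"),
       fun = function(p, G, D)
         p[["alpha"]] * G + p[["beta"]] * D + p[["gamma"]] * G * D),
  list(id = 7L, name = "similarly-nonlinear-interactive",
       params = c(alpha = "log", beta = "log", gamma = "identity", delta = "log"),
       fun = function(p, G, D) {
         Gd <- .pow(G, p[["delta"]]); Dd <- .pow(D, p[["delta"]])
         p[["alpha"]] * Gd + p[["beta"]] * Dd + p[["gamma"]] * Gd * Dd
       }),
  list(id = 8L, name = "nonlinear-interactive",
       params = c(alpha = "log", beta = "log", gamma = "identity",
                  delta = "log", epsilon = "log"),
       fun = function(p, G, D) {
         Gd <- .pow(G, p[["delta"]]); De <- .pow(D, p[["epsilon"]])
         p[["alpha"]] * Gd + p[["beta"]] * De + p[["gamma"]] * Gd * De
       }),
  list(id = 9L, name = "linear-equity",
       params = c(alpha = "log", beta = "log", gamma = "identity"),
       fun = function(p, G, D)
         p[["alpha"]] * G + p[["beta"]] * D + p[["gamma"]] * abs(G - D)),
  list(id = 10L, name = "fehr-schmidt",
       params = c(alpha = "identity", beta = "identity"),
       fun = function(p, G, D)
         G - p[["alpha"]] * pmax(D - G, 0) - p[["beta"]] * pmax(G - D, 0)),
  list(id = 11L, name = "cobb-douglas",
       params = c(delta = "logit"),
       fun = function(p, G, D) .pow(G, p[["delta"]]) * .pow(D, 1 - p[["delta"]])),
  list(id = 12L, name = "ces",
       params = c(alpha = "logit", delta = "log"),
       fun = function(p, G, D) .ces_value(p[["alpha"]], p[["delta"]], G, D))
)

.check_native <- function(spec, params) {
  for (nm in names(spec$params)) {
    if (is.null(params[[nm]]) || !is.finite(params[[nm]]))
      stop(sprintf("model '%s' requires a finite parameter '%s'",
                   spec$name, nm))
    v <- params[[nm]]
    bad <- switch(spec$params[[nm]],
                  log = v <= 0,
                  logit = v < 0 || v > 1,
                  identity = FALSE)
    if (bad)
      stop(sprintf("parameter '%s' = %g outside its native domain (%s scale)",
                   nm, v, spec$params[[nm]]))
  }
  invisible(TRUE)
}

#' Evaluate a value function over offers
#'
#' @param model Model id or name (see [value_model_space()]).
#' @param params Named list or vector of native-scale parameters.
#' @param gain,donation Numeric vectors of euro amounts (recycled to a
#'   common length); both must be non-negative.
#' @return Numeric vector of utilities.
#' @examples
#' value_function("ces", list(alpha = 0.5, delta = 1), 50, 50)  # 50
#' @export
value_function <- function(model, params, gain, donation) {
  spec <- value_model(model)
  params <- as.list(params)
  .check_native(spec, params)
  if (any(gain < 0, na.rm = TRUE) || any(donation < 0, na.rm = TRUE))
    stop("gain and donation must be non-negative")
  n <- max(length(gain), length(donation))
  spec$fun(params, rep_len(as.numeric(gain), n), rep_len(as.numeric(donation), n))
}

#' Transform parameters between native and unconstrained scales
#'
#' Positive parameters are log-transformed, unit-interval parameters
#' logit-transformed, unconstrained ones left as-is. The round trip
#' native -> unconstrained -> native is the identity.
#'
#' @param model Model id or name.
#' @param params Named numeric vector/list on the source scale.
#' @return Named numeric vector on the target scale.
#' @export
par_to_unconstrained <- function(model, params) {
  spec <- value_model(model)
  out <- vapply(names(spec$params), function(nm) {
    v <- params[[nm]]
    switch(spec$params[[nm]],
           log = log(v), logit = stats::qlogis(v), identity = v)
  }, numeric(1))
  names(out) <- names(spec$params)
  out
}

#' @rdname par_to_unconstrained
#' @export
par_to_native <- function(model, params) {
  spec <- value_model(model)
  out <- vapply(names(spec$params), function(nm) {
    v <- params[[nm]]
    switch(spec$params[[nm]],
           log = exp(v), logit = stats::plogis(v), identity = v)
  }, numeric(1))
  names(out) <- names(spec$params)
  out
}

.apply_transform <- function(v, tr, inverse = FALSE) {
  if (inverse)
    switch(tr, log = exp(v), logit = stats::plogis(v), identity = v)
  else
    switch(tr, log = log(v), logit = stats::qlogis(v), identity = v)
}

#' Discrepancy between CES at delta = 1 and the linear weighting model
#'
#' With unit concavity the CES value collapses to
#' `alpha * G + (1 - alpha) * D`; this returns the sup-norm discrepancy
#' between the two evaluations over a set of offers, a direct check that the
#' linear model is nested in the CES family.
#'
#' @param gain,donation Offer amounts (vectors, recycled).
#' @param alpha CES share parameter in \[0, 1\].
#' @param delta CES concavity, default 1.
#' @return Maximum absolute discrepancy over the offers.
#' @export
ces_linear_residual <- function(gain, donation, alpha, delta = 1) {
  ces <- value_function("ces", list(alpha = alpha, delta = delta),
                        gain, donation)
  lin <- value_function("linear-independent",
                        list(alpha = alpha, beta = 1 - alpha),
                        gain, donation)
  max(abs(ces - lin))
}

#' Serialize the model space as a JSON registry
#'
#' Writes id, name, parameter names and transforms for each of the twelve
#' models.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_registry <- function(path) {
  reg <- lapply(.model_space, function(s)
    list(id = s$id, name = s$name,
         parameters = names(s$params),
         transforms = unname(s$params)))
  jsonlite::write_json(reg, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
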