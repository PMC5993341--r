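# Waiting-time specifications: the distribution of the time a lineage waits
# until it speciates or goes extinct, written in R's random-generator call
# syntax ("rexp(0.5)", "rweibull(0.4,3)", ...), with the leading
# number-of-observations argument implied and never written.

#' Classed error helper
#' @noRd
bh_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "bhtree_error", "error", "condition")))
}

# Family registry: recognized generator names, parameter names in positional
# order, defaults (NA = required), and domain predicates.
.wt_families <- list(
  rexp = list(
    family = "exponential", pars = c("rate"), defaults = c(rate = 1),
    check = function(p) if (p[["rate"]] > 0) TRUE else "rate must be > 0"
  ),
  rweibull = list(
    family = "weibull", pars = c("shape", "scale"), defaults = c(shape = NA, scale = 1),
    check = function(p) if (p[["shape"]] > 0 && p[["scale"]] > 0) TRUE else "shape and scale must be > 0"
  ),
  rgamma = list(
    # positional shape, rate, scale; when a third argument is given the scale
    # overrides the rate (documented quirk of the positional grammar)
    family = "gamma", pars = c("shape", "rate", "scale"),
    defaults = c(shape = NA, rate = 1, scale = NA),
    check = function(p) {
      if (p[["shape"]] <= 0) return("shape must be > 0")
      if (!is.na(p[["scale"]]) && p[["scale"]] <= 0) return("scale must be > 0")
      if (p[["rate"]] <= 0) return("rate must be > 0")
      TRUE
    }
  ),
  runif = list(
    family = "uniform", pars = c("min", "max"), defaults = c(min = 0, max = 1),
    check = function(p) {
      if (p[["min"]] > p[["max"]]) return("lower bound must not exceed upper bound")
      if (p[["max"]] <= 0) return("upper bound must be > 0 (waiting times are positive)")
      TRUE
    }
  ),
  rlnorm = list(
    family = "lognormal", pars = c("meanlog", "sdlog"), defaults = c(meanlog = 0, sdlog = 1),
    check = function(p) if (p[["sdlog"]] >= 0) TRUE else "sdlog must be >= 0"
  ),
  rnorm = list(
    family = "normal-truncated", pars = c("mean", "sd"), defaults = c(mean = 0, sd = 1),
    check = function(p) {
      if (p[["sd"]] < 0) return("sd must be >= 0")
      if (p[["mean"]] <= 0 && p[["sd"]] == 0) return("degenerate normal with non-positive mean")
      TRUE
    }
  ),
  const = list(
    family = "constant", pars = c("value"), defaults = c(value = NA),
    check = function(p) if (p[["value"]] >= 0) TRUE else "constant waiting time must be >= 0"
  )
)

#' Waiting-time specification
#'
#' Parse a distribution-specification string into a validated waiting-time
#' specification. The grammar mirrors how one would invoke the corresponding
#' random-generator function in R, skipping the leading number-of-observations
#' argument: `"rexp(0.5)"` is an exponential waiting time with rate 0.5,
#' `"rweibull(0.4,3)"` a Weibull with shape 0.4 and scale 3. Omitted trailing
#' parameters take the generator's documented defaults (`"rweibull(0.4)"`
#' means scale 1). `const(x)` denotes a point mass at `x` (a deterministic
#' waiting time). For `rgamma` the positional order is shape, rate, scale,
#' with a third argument (scale) overriding the second (rate). `rnorm` draws
#' are truncated to positive values by resampling.
#'
#' Any R function returning a single positive waiting time per call may be
#' supplied instead of a string; it is wrapped as a `custom` spec.
#'
#' @param x A specification string such as `"rexp(0.5)"`, a function, or an
#'   existing `wt_spec` (returned unchanged).
#' @return An object of class `wt_spec` with fields `family`, `params`
#'   (named numeric vector) and `source` (the original string, reproduced by
#'   `format()` so that parsing round-trips exactly).
#' @examples
#' wt_spec("rexp(0.5)")
#' wt_spec("rweibull(0.4)") # scale defaults to 1
#' wt_spec(function() 2 + abs(rnorm(1)))
#' @seealso [wt_draw()]
#' @export
wt_spec <- function(x) {
  if (inherits(x, "wt_spec")) return(x)
  if (is.function(x)) {
    return(structure(
      list(family = "custom", params = numeric(0), fn = x,
           source = "<custom function>"),
      class = "wt_spec"
    ))
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    bh_stop("bhtree_bad_spec", "waiting-time spec must be a single string or a function")
  }
  txt <- trimws(x)
  m <- regmatches(txt, regexec("^([A-Za-z_.][A-Za-z0-9_.]*)\\s*\\(([^()]*)\\)$", txt))[[1]]
  if (length(m) != 3L) {
    bh_stop("bhtree_bad_spec",
            sprintf("cannot parse waiting-time spec '%s': expected name(p1,p2,...)", txt))
  }
  name <- m[2]
  fam <- .wt_families[[name]]
  if (is.null(fam)) {
    bh_stop("bhtree_unknown_family",
            sprintf("unknown waiting-time family '%s' (supported: %s)",
                    name, paste(names(.wt_families), collapse = ", ")))
  }
  argtxt <- trimws(m[3])
  args <- if (nzchar(argtxt)) trimws(strsplit(argtxt, ",", fixed = TRUE)[[1]]) else character(0)
  if (any(!nzchar(args))) {
    bh_stop("bhtree_bad_spec", sprintf("empty parameter in spec '%s'", txt))
  }
  vals <- suppressWarnings(as.numeric(args))
  if (anyNA(vals)) {
    bh_stop("bhtree_bad_spec", sprintf("non-numeric parameter in spec '%s'", txt))
  }
  np <- length(fam$pars)
  if (length(vals) > np) {
    bh_stop("bhtree_bad_arity",
            sprintf("spec '%s': at most %d parameter(s) allowed for %s", txt, np, name))
  }
  params <- fam$defaults
  if (length(vals)) params[seq_along(vals)] <- vals
  # required parameters (defaults NA) must be supplied -- except rgamma's
  # optional trailing scale, which stays NA when absent
  required_missing <- is.na(params) & !(name == "rgamma" & names(params) == "scale")
  if (any(required_missing)) {
    bh_stop("bhtree_bad_arity",
            sprintf("spec '%s': missing required parameter '%s'",
                    txt, names(params)[required_missing][1]))
  }
  ok <- fam$check(params)
  if (!isTRUE(ok)) {
    bh_stop("bhtree_bad_param", sprintf("spec '%s': %s", txt, ok))
  }
  structure(list(family = fam$family, params = params, source = txt),
            class = "wt_spec")
}

#' @export
format.wt_spec <- function(x, ...) x$source

#' @export
print.wt_spec <- function(x, ...) {
  cat("<wt_spec> ", x$source, "  [", x$family, "]\n", sep = "")
  invisible(x)
}

#' Draw waiting times
#'
#' Draws `n` independent waiting times from a specification, each multiplied
#' by a positive scaling factor (the lineage-specific shift factor; 1 means
#' no scaling). Draws that are non-positive or non-finite -- a point mass at
#' zero, a uniform straddling zero, a truncated normal -- are resampled up to
#' 100 times per slot; a slot still degenerate after that raises an error.
#' Draws use R's global random number generator, so results are reproducible
#' under `set.seed()`.
#'
#' @param spec A [wt_spec()] (strings and functions are coerced).
#' @param n Number of draws.
#' @param factor Positive multiplicative scaling factor applied to the draws.
#' @return Numeric vector of `n` strictly positive waiting times.
#' @examples
#' set.seed(1)
#' wt_draw(wt_spec("rexp(0.5)"), 5)
#' wt_draw("const(2)", 3, factor = 0.5) # deterministic: 1 1 1
#' @export
wt_draw <- function(spec, n = 1L, factor = 1) {
  spec <- wt_spec(spec)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    bh_stop("bhtree_bad_factor", "scaling factor must be a single finite positive number")
  }
  x <- wt_raw_draw(spec, n)
  bad <- which(!is.finite(x) | x <= 0)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > 100L) {
      bh_stop("bhtree_degenerate_draw",
              sprintf("spec '%s' produced non-positive/non-finite waiting times in 100 consecutive resamples",
                      spec$source))
    }
    x[bad] <- wt_raw_draw(spec, length(bad))
    bad <- bad[!is.finite(x[bad]) | x[bad] <= 0]
  }
  x * factor
}

#' @noRd
wt_raw_draw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    exponential = stats::rexp(n, rate = p[["rate"]]),
    weibull     = stats::rweibull(n, shape = p[["shape"]], scale = p[["scale"]]),
    gamma       = if (!is.na(p[["scale"]])) {
      stats::rgamma(n, shape = p[["shape"]], scale = p[["scale"]])
    } else {
      stats::rgamma(n, shape = p[["shape"]], rate = p[["rate"]])
    },
    uniform     = stats::runif(n, min = p[["min"]], max = p[["max"]]),
    lognormal   = stats::rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    `normal-truncated` = stats::rnorm(n, mean = p[["mean"]], sd = p[["sd"]]),
    constant    = rep.int(p[["value"]], n),
    custom      = vapply(seq_len(n), function(i) as.numeric(spec$fn())[1], numeric(1)),
    bh_stop("bhtree_unknown_family", sprintf("unknown family '%s'", spec$family))
  )
}
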