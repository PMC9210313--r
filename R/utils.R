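# Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.geomean <- function(x) exp(mean(log(x)))

#' @noRd
#' Log2 ratio with a symmetric pseudo-count so zeros stay finite.
.log2_ratio <- function(num, den, pseudo = 0.5) {
  log2((num + pseudo) / (den + pseudo))
}

#' @noRd
#' Deterministic integer allocation of n items to proportions (largest
#' remainder / Hamilton method). Guarantees sum(out) == n.
.largest_remainder <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0))
  if (sum(props) == 0) return(rep(0L, length(props)))
  props <- props / sum(props)
  raw <- n * props
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' @noRd
#' rnbinom with mean/dispersion parameterization: Var = mu + phi * mu^2.
#' phi = 0 degenerates to Poisson.
.rnb <- function(n, mu, phi) {
  if (phi <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / phi, mu = mu)
}

.inheritance_classes <- c("conserved", "additive", "P1_dominant", "P2_dominant",
                          "overdominant", "underdominant")

.regulatory_classes <- c("conserved", "cis", "trans", "cis_plus_trans",
                         "cis_times_trans", "compensatory")

.regulatory_call_levels <- c(.regulatory_classes, "ambiguous")

#' Closed class vocabularies
#'
#' Category labels used by the inheritance and regulatory-divergence
#' classifiers. `inheritance_classes()` lists the six hybrid expression
#' inheritance modes; `regulatory_classes()` lists the six generative
#' regulatory-divergence modes (the classifier may additionally emit
#' `"ambiguous"` when exactly one of its three tests is significant).
#'
#' @return Character vector of class labels.
#' @export
inheritance_classes <- function() .inheritance_classes

#' @rdname inheritance_classes
#' @export
regulatory_classes <- function() .regulatory_classes
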