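#' Smoothed Heaviside step function
#'
#' `H_k(x) = 1/2 + arctan(k x) / pi`, a smooth approximation of the
#' Heaviside step used by the arbitrium reaction norms. Strictly increasing
#' in `x`, with limits 0 and 1 and `H_k(0) = 1/2` for any slope.
#'
#' @param x Numeric vector.
#' @param k Positive slope; larger values give a sharper step.
#' @return Values in (0, 1), vectorised over `x`.
#' @examples
#' smooth_heaviside(0, 10)   # 0.5
#' smooth_heaviside(2, 1000) # ~1
#' @export
smooth_heaviside <- function(x, k = 10) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive number", call. = FALSE)
  0.5 + atan(k * x) / pi
}

#' Fixed lysis-lysogeny strategy
#'
#' A strategy whose lysogenisation probabilities and reactivation rates do
#' not respond to the arbitrium concentration. Unstarred traits apply in
#' normal cells, starred traits in stressed (SOS-induced) cells.
#'
#' @param phi,phiStar Lysogenisation probabilities in normal / stressed
#'   cells, in \[0, 1\].
#' @param alpha,alphaStar Prophage reactivation rates in normal / stressed
#'   cells (h^-1).
#' @return A `phage_strategy` object with `kind = "fixed"`.
#' @seealso [strategy_plastic()], [evaluate_strategy()]
#' @export
strategy_fixed <- function(phi = 0, phiStar = 0, alpha = 0, alphaStar = 0) {
  chk_prob(phi, "phi"); chk_prob(phiStar, "phiStar")
  chk_rate(alpha, "alpha"); chk_rate(alphaStar, "alphaStar")
  structure(list(kind = "fixed", phi = phi, phiStar = phiStar,
                 alpha = alpha, alphaStar = alphaStar),
            class = "phage_strategy")
}

#' Arbitrium-plastic lysis-lysogeny strategy (reaction norms)
#'
#' A strategy in which reactivation decreases and lysogenisation increases
#' with the arbitrium concentration `A` through smoothed threshold
#' functions:
#' `alpha(A) = alphaMax * (1 - H_k(A/Aalpha - 1))` and
#' `phi(A)   = phiMax  * H_k(A/Aphi - 1)`,
#' with independent norms (starred parameters) in stressed cells. At
#' `A` equal to a threshold the corresponding rate is exactly half its
#' maximum.
#'
#' @param alphaMax,alphaMaxStar Maximal reactivation rates (h^-1).
#' @param phiMax,phiMaxStar Maximal lysogenisation probabilities in
#'   \[0, 1\].
#' @param Aalpha,Aphi,AalphaStar,AphiStar Arbitrium thresholds
#'   (mol ml^-1); must be positive whenever the corresponding maximal rate
#'   is positive (a zero maximum switches the trait off and its threshold
#'   is ignored).
#' @return A `phage_strategy` object with `kind = "plastic"`.
#' @seealso [strategy_fixed()], [evaluate_strategy()], [smooth_heaviside()]
#' @export
strategy_plastic <- function(alphaMax = 0, Aalpha = NA_real_,
                             phiMax = 0, Aphi = NA_real_,
                             alphaMaxStar = 0, AalphaStar = NA_real_,
                             phiMaxStar = 0, AphiStar = NA_real_) {
  chk_rate(alphaMax, "alphaMax"); chk_rate(alphaMaxStar, "alphaMaxStar")
  chk_prob(phiMax, "phiMax"); chk_prob(phiMaxStar, "phiMaxStar")
  chk_thr <- function(mx, thr, nm) {
    if (mx > 0 && (!is.numeric(thr) || length(thr) != 1L || is.na(thr) ||
                   thr <= 0))
      stop("threshold '", nm, "' must be > 0 when its maximal rate is > 0",
           call. = FALSE)
  }
  chk_thr(alphaMax, Aalpha, "Aalpha")
  chk_thr(phiMax, Aphi, "Aphi")
  chk_thr(alphaMaxStar, AalphaStar, "AalphaStar")
  chk_thr(phiMaxStar, AphiStar, "AphiStar")
  structure(list(kind = "plastic", alphaMax = alphaMax, Aalpha = Aalpha,
                 phiMax = phiMax, Aphi = Aphi,
                 alphaMaxStar = alphaMaxStar, AalphaStar = AalphaStar,
                 phiMaxStar = phiMaxStar, AphiStar = AphiStar),
            class = "phage_strategy")
}

chk_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", nm, "' must be a single probability in [0, 1]", call. = FALSE)
}

chk_rate <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop("'", nm, "' must be a single non-negative rate", call. = FALSE)
}

#' @export
print.phage_strategy <- function(x, ...) {
  if (x$kind == "fixed") {
    cat(sprintf(
      "Fixed strategy: phi = %.4g, phiStar = %.4g, alpha = %.4g, alphaStar = %.4g\n",
      x$phi, x$phiStar, x$alpha, x$alphaStar))
  } else {
    cat("Arbitrium-plastic strategy:\n")
    cat(sprintf("  normal:   alphaMax = %.4g (Aalpha = %.4g), phiMax = %.4g (Aphi = %.4g)\n",
                x$alphaMax, x$Aalpha, x$phiMax, x$Aphi))
    cat(sprintf("  stressed: alphaMaxStar = %.4g (AalphaStar = %.4g), phiMaxStar = %.4g (AphiStar = %.4g)\n",
                x$alphaMaxStar, x$AalphaStar, x$phiMaxStar, x$AphiStar))
  }
  invisible(x)
}

#' Evaluate a strategy at given arbitrium concentrations
#'
#' Returns the realised lysogenisation probabilities and reactivation rates
#' of a strategy. Fixed strategies ignore `A`; plastic strategies evaluate
#' their reaction norms at `A`, so reactivation decreases and
#' lysogenisation increases with the signal.
#'
#' @param strategy A `phage_strategy` object.
#' @param A Arbitrium concentration(s), non-negative (mol ml^-1).
#' @param k Slope of the smoothed Heaviside (use the model's `k`).
#' @return A list with numeric components `phi`, `phiStar`, `alpha`,
#'   `alphaStar`, each of the length of `A`.
#' @examples
#' s <- strategy_plastic(alphaMax = 0.02, Aalpha = 0.1,
#'                       phiMax = 0.3, Aphi = 0.05)
#' evaluate_strategy(s, A = 0.1)$alpha  # alphaMax / 2 at the threshold
#' @export
evaluate_strategy <- function(strategy, A, k = 10) {
  stopifnot(inherits(strategy, "phage_strategy"))
  if (any(A < 0)) stop("'A' must be non-negative", call. = FALSE)
  n <- length(A)
  if (strategy$kind == "fixed") {
    return(list(phi = rep(strategy$phi, n),
                phiStar = rep(strategy$phiStar, n),
                alpha = rep(strategy$alpha, n),
                alphaStar = rep(strategy$alphaStar, n)))
  }
  norm_dec <- function(mx, thr) {
    if (mx > 0) mx * (1 - smooth_heaviside(A / thr - 1, k)) else rep(0, n)
  }
  norm_inc <- function(mx, thr) {
    if (mx > 0) mx * smooth_heaviside(A / thr - 1, k) else rep(0, n)
  }
  list(phi = norm_inc(strategy$phiMax, strategy$Aphi),
       phiStar = norm_inc(strategy$phiMaxStar, strategy$AphiStar),
       alpha = norm_dec(strategy$alphaMax, strategy$Aalpha),
       alphaStar = norm_dec(strategy$alphaMaxStar, strategy$AalphaStar))
}
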