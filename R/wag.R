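# Canonical amino-acid ordering used throughout the package (PAML order).
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Letters treated as missing data (never as a 21st state).
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O", "J", "*")

GAP_CHAR <- "-"

# WAG exchangeabilities (Whelan & Goldman 2001), lower triangle of the
# symmetric 20x20 matrix in column-major order over AA_LETTERS.
WAG_RATES <- c(
  0.5515710, 0.5098480, 0.7389980, 1.0270400, 0.9085980, 1.5828500,
  1.4167200, 0.3169540, 0.1933350, 0.3979150, 0.9062650, 0.8934960,
  0.2104940, 1.4385500, 3.3707900, 2.1211100, 0.1131330, 0.2407350,
  2.0060100, 0.6353460, 0.1473040, 0.5281910, 3.0355000, 0.4391570,
  0.5846650, 2.1371500, 0.1869790, 0.4976710, 5.3514200, 0.6831620,
  0.1027110, 0.6794890, 1.2241900, 0.5544130, 1.1639200, 0.3815330,
  0.2518490, 5.4294200, 0.2652560, 1.5436400, 0.9471980, 1.1255600,
  3.9562900, 0.5542360, 0.1315280, 3.0120100, 0.1982210, 0.0961621,
  0.1950810, 3.9742300, 2.0300600, 0.0719167, 1.0860000, 0.1962460,
  0.0302949, 0.6167830, 6.1741600, 0.8655840, 0.9306760, 0.0394370,
  0.0848047, 0.4798550, 0.1037540, 0.0467304, 0.4239840, 1.0717600,
  0.3748660, 0.1297670, 0.3257110, 0.1523350, 0.0988179, 0.0213520,
  0.3066740, 0.2489720, 0.1701350, 0.3842870, 0.0740339, 0.3904820,
  0.3980200, 0.1094040, 1.4076600, 0.5129840, 0.7170700, 0.5438330,
  1.0021400, 5.4694700, 0.3300520, 4.2941100, 0.1139170, 0.8694890,
  3.8949000, 1.5452600, 0.0999208, 0.9333720, 1.0288700, 0.8579280,
  0.2157370, 0.2277100, 0.3012810, 0.5677170, 0.5700250, 0.1273950,
  0.1542630, 2.5844300, 0.3151240, 0.0811339, 0.6823550, 0.7049390,
  0.8227650, 0.1565570, 0.1963030, 0.5887310, 0.2494100, 0.0304501,
  0.0613037, 0.3735580, 0.1741000, 0.0499310, 0.2435700, 1.3418200,
  0.2258330, 0.3369830, 0.1036040, 0.1872470, 0.1381900, 0.4994620,
  0.8904320, 0.4041410, 0.6793710, 0.6961980, 0.7401690, 0.4733070,
  0.2625690, 3.8734400, 0.1183580, 3.1709700, 0.3238320, 4.2574600,
  1.0594700, 0.0999288, 0.3194400, 1.4581600, 0.2124830, 0.4201700,
  7.8213000, 0.2575550, 4.8540200, 2.1151700, 0.4158440, 0.3447390,
  0.3266220, 0.6653090, 0.3986180, 1.8003400, 0.9342760, 0.0888360,
  0.5568960, 0.9671300, 1.3869800, 0.1375050, 0.1332640, 0.3054340,
  1.1906300, 0.1713290, 0.4939050, 1.5161200, 0.5157060, 0.4284370,
  2.0584500, 0.1614440, 0.5459310, 0.1719030, 1.5296400, 6.4542800,
  0.6498920, 1.6132800, 0.7953840, 0.1394050, 0.2160460, 0.3148870,
  4.3780200, 0.5237420, 0.7869930, 0.2327390, 0.1108640, 0.2911480,
  1.3882300, 2.4853900, 0.3653690, 0.3147300)

# WAG stationary amino-acid frequencies (same source), normalized to sum 1.
WAG_FREQS <- c(
  0.0866279086627909, 0.0439720043972004, 0.0390894039089404,
  0.0570451057045106, 0.0193078019307802, 0.0367281036728104,
  0.0580589058058906, 0.0832518083251808, 0.0244313024431302,
  0.0484660048466005, 0.0862090086209009, 0.0620286062028606,
  0.0195027019502702, 0.0384319038431904, 0.0457631045763105,
  0.0695179069517907, 0.0610127061012706, 0.0143859014385901,
  0.0352742035274204, 0.0708956070895607)

#' Build a reversible amino-acid substitution model
#'
#' Assembles the instantaneous rate matrix Q from symmetric exchangeabilities
#' S and stationary frequencies pi: `Q[i,j] = S[i,j] * pi[j]` off-diagonal,
#' diagonal set so rows sum to zero, then globally scaled so the expected
#' substitution rate at stationarity, `-sum(pi * diag(Q))`, equals 1 (branch
#' lengths are therefore expected substitutions per site).  The symmetric
#' eigendecomposition of `diag(sqrt(pi)) Q diag(1/sqrt(pi))` is precomputed so
#' transition matrices can be formed cheaply for any branch length.
#'
#' @param rates numeric vector of the 190 lower-triangle exchangeabilities
#'   (column-major over the canonical residue order), or a full symmetric
#'   20x20 matrix with zero diagonal.
#' @param freqs stationary frequencies; 20 positive values summing to 1.
#' @param name model name (bookkeeping only).
#' @return an object of class `subst_model` with elements `S`, `pi`, `Q`,
#'   and the eigendecomposition used by [transition_matrix()].
#' @export
substitution_model <- function(rates, freqs, name = "custom") {
  if (is.matrix(rates)) {
    S <- rates
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
      stop("exchangeability matrix must be symmetric")
  } else {
    if (length(rates) != 190L)
      stop("need 190 lower-triangle exchangeabilities")
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- rates
    S <- S + t(S)
  }
  if (any(S < 0)) stop("exchangeabilities must be non-negative")
  if (length(freqs) != 20L || any(freqs <= 0))
    stop("freqs must be 20 positive values")
  pi <- freqs / sum(freqs)
  dimnames(S) <- list(AA_LETTERS, AA_LETTERS)
  names(pi) <- AA_LETTERS

  Q <- S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale

  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))          # diag(sq) Q diag(1/sq), symmetric
  B <- (B + t(B)) / 2                  # enforce symmetry numerically
  e <- eigen(B, symmetric = TRUE)
  structure(list(
    name = name, S = S, pi = pi, Q = Q,
    lambda = e$values,
    # P(t) = evec_left %*% diag(exp(lambda t)) %*% evec_right
    evec_left = e$vectors / sq,          # rows scaled by 1/sqrt(pi)
    evec_right = t(e$vectors * sq)       # columns scaled by sqrt(pi), transposed
  ), class = "subst_model")
}

#' The WAG amino-acid model
#'
#' The empirical WAG model with its published exchangeabilities and
#' stationary frequencies, scaled to one expected substitution per site.
#'
#' @return a `subst_model` object.
#' @export
wag_model <- function() {
  substitution_model(WAG_RATES, WAG_FREQS, name = "WAG")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Reversible amino-acid substitution model:", x$name, "\n")
  cat("  expected rate at stationarity:",
      format(-sum(x$pi * diag(x$Q))), "\n")
  invisible(x)
}

#' Discrete gamma rate categories
#'
#' Approximates gamma-distributed among-site rate variation (shape `alpha`,
#' mean 1) by `n_categories` equiprobable categories.  The default `"mean"`
#' method sets each category rate to the conditional mean of the gamma
#' distribution within the category's quantile band (Yang's discrete-gamma);
#' `"median"` uses the band medians rescaled to mean 1.
#'
#' @param alpha gamma shape parameter, > 0.
#' @param n_categories number of rate categories (default 5).
#' @param method `"mean"` or `"median"`.
#' @return object of class `gamma_rates`: list with `alpha`, `rates`
#'   (ascending, mean 1 under equal weights) and `probs` (all `1/K`).
#' @export
discrete_gamma <- function(alpha, n_categories = 5L, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  k <- as.integer(n_categories)
  if (k < 1L) stop("n_categories must be >= 1")
  if (k == 1L) {
    rates <- 1
  } else if (method == "mean") {
    cuts <- stats::qgamma((0:k) / k, shape = alpha, rate = alpha)
    # conditional category means via the incomplete-gamma identity
    upper <- stats::pgamma(cuts[-1L], shape = alpha + 1, rate = alpha)
    lower <- stats::pgamma(cuts[-(k + 1L)], shape = alpha + 1, rate = alpha)
    rates <- k * (upper - lower)
  } else {
    med <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha, rate = alpha)
    rates <- med * k / sum(med)
  }
  structure(list(alpha = alpha, n_categories = k,
                 rates = sort(rates), probs = rep(1 / k, k),
                 method = method),
            class = "gamma_rates")
}

#' @export
print.gamma_rates <- function(x, ...) {
  cat("Discrete gamma rates: alpha =", x$alpha, ",", x$n_categories,
      "equiprobable categories (", x$method, ")\n")
  cat("  rates:", paste(format(x$rates, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param model a `subst_model`.
#' @param t branch length (expected substitutions per site), >= 0.
#' @param rate rate multiplier (e.g. a discrete-gamma category rate), > 0.
#' @return 20x20 row-stochastic matrix; tiny negative entries from the
#'   eigendecomposition are clamped to zero.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a non-negative scalar")
  if (rate <= 0) stop("rate multiplier must be positive")
  P <- model$evec_left %*% (exp(model$lambda * t * rate) * model$evec_right)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_LETTERS, AA_LETTERS)
  P
}

# Mixture transition kernel averaged over gamma categories:
# M(t) = (1/K) sum_k P(t * r_k).  Collapses into the eigenbasis, so it costs
# a single 20x20 reconstruction.  Used heavily by pairwise distances.
mixture_matrix <- function(model, t, gamma = NULL) {
  if (is.null(gamma)) {
    d <- exp(model$lambda * t)
  } else {
    d <- rowMeans(exp(outer(model$lambda * t, gamma$rates)))
  }
  P <- model$evec_left %*% (d * model$evec_right)
  P[P < 0] <- 0
  P
}
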