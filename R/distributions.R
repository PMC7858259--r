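#' Labelled discrete probability distribution
#'
#' Carrier for both an agent's prior preferences over states, P(S), and the
#' policy-conditioned distribution over attainable states, P(S|pi). Labels are
#' state identifiers; probabilities are dimensionless and must sum to one.
#'
#' @param labels Character vector of unique state identifiers.
#' @param probs Numeric vector of probabilities, same length as `labels`,
#'   all non-negative, summing to 1 within `tol`.
#' @param renormalize If `TRUE`, divide `probs` by their sum instead of
#'   requiring normalization on input. Default `FALSE`: distributions are
#'   only renormalized when explicitly requested.
#' @param tol Normalization tolerance on construction (default `1e-9`).
#' @return An object of class `discrete_distribution` with fields `labels`
#'   and `probs`.
#' @examples
#' d <- discrete_distribution(c("a", "b"), c(0.25, 0.75))
#' surprise(d, "a")
#' @export
discrete_distribution <- function(labels, probs, renormalize = FALSE,
                                  tol = 1e-9) {
  labels <- as.character(labels)
  probs <- as.numeric(probs)
  if (length(labels) != length(probs)) {
    stop("`labels` and `probs` must have the same length", call. = FALSE)
  }
  if (length(labels) == 0L) {
    stop("a distribution needs at least one state", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("state labels must be unique", call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("probabilities must be finite and non-negative", call. = FALSE)
  }
  s <- sum(probs)
  if (renormalize) {
    if (s <= 0) stop("cannot renormalize an all-zero vector", call. = FALSE)
    probs <- probs / s
  } else if (abs(s - 1) > tol) {
    stop(sprintf("probabilities sum to %.12g, not 1 (tolerance %g)", s, tol),
         call. = FALSE)
  }
  structure(list(labels = labels, probs = probs),
            class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  cat(sprintf("<discrete_distribution over %d states>\n", length(x$labels)))
  print(stats::setNames(round(x$probs, 6), x$labels))
  invisible(x)
}

#' @export
format.discrete_distribution <- function(x, ...) {
  paste0(x$labels, "=", signif(x$probs, 6), collapse = ", ")
}

is_discrete_distribution <- function(x) inherits(x, "discrete_distribution")

#' Gaussian belief over a continuous state variable
#'
#' Sufficient statistics of a one-dimensional Gaussian density used to model
#' continuous goal-state and attainable-state beliefs.
#'
#' @param mean State coordinate (arbitrary continuous units).
#' @param sd Standard deviation, same units, strictly positive.
#' @return An object of class `gaussian_belief`.
#' @examples
#' goal <- gaussian_belief(3, 1)
#' @export
gaussian_belief <- function(mean, sd) {
  mean <- as.numeric(mean)[1L]
  sd <- as.numeric(sd)[1L]
  if (!is.finite(mean)) stop("`mean` must be finite", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) {
    stop("`sd` must be strictly positive", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief mean=%g sd=%g>\n", x$mean, x$sd))
  invisible(x)
}

#' Surprisal of a realized state, in bits
#'
#' The surprise an agent experiences on reaching `state` is the negative
#' base-2 logarithm of the probability its preference prior assigns to that
#' state. A zero-probability state yields `Inf` (maximal surprise), signalled
#' as a value rather than an error so that rankings over states still work.
#'
#' @param dist A [discrete_distribution()] (the preference prior).
#' @param state A state label present in `dist$labels`.
#' @return Surprisal in bits (non-negative; `Inf` for probability zero).
#' @examples
#' d <- discrete_distribution(c("a", "b"), c(0.5, 0.5))
#' surprise(d, "a")  # 1 bit
#' @export
surprise <- function(dist, state) {
  stopifnot(is_discrete_distribution(dist))
  i <- match(as.character(state)[1L], dist$labels)
  if (is.na(i)) {
    stop(sprintf("unknown state label '%s'", state), call. = FALSE)
  }
  p <- dist$probs[i]
  if (p == 0) Inf else -log2(p)
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' H = -sum p log2 p with the convention 0 * log 0 = 0. Bounded by
#' log2 of the number of states; zero for a point mass.
#'
#' @param dist A [discrete_distribution()].
#' @return Entropy in bits.
#' @export
entropy_bits <- function(dist) {
  stopifnot(is_discrete_distribution(dist))
  p <- dist$probs[dist$probs > 0]
  -sum(p * log2(p))
}

check_same_labels <- function(posterior, prior) {
  if (!identical(posterior$labels, prior$labels)) {
    if (setequal(posterior$labels, prior$labels)) {
      stop("label order differs between posterior and prior; align them first",
           call. = FALSE)
    }
    stop("posterior and prior are over different label sets", call. = FALSE)
  }
}

#' Kullback-Leibler divergence between two discrete distributions, in bits
#'
#' The risk of a policy: D(posterior || prior) = sum over states of
#' posterior(s) * log2(posterior(s)/prior(s)). Non-negative, and zero exactly
#' when the two distributions coincide (Gibbs' inequality). If the posterior
#' puts mass on a state the prior rules out, the divergence is `Inf`,
#' returned as a sentinel value (an infinite-risk policy) rather than raised
#' as an error, so that policy ranking still works.
#'
#' @param posterior A [discrete_distribution()]; the attainable states
#'   P(S|pi).
#' @param prior A [discrete_distribution()] over the same labels in the same
#'   order; the preference prior P(S).
#' @return Divergence in bits (possibly `Inf`).
#' @examples
#' post <- discrete_distribution(c("a", "b"), c(1, 0))
#' pri <- discrete_distribution(c("a", "b"), c(0.5, 0.5))
#' kl_discrete(post, pri)  # 1 bit
#' @export
kl_discrete <- function(posterior, prior) {
  stopifnot(is_discrete_distribution(posterior), is_discrete_distribution(prior))
  check_same_labels(posterior, prior)
  p <- posterior$probs
  q <- prior$probs
  nz <- p > 0
  if (any(q[nz] == 0)) return(Inf)
  sum(p[nz] * (log2(p[nz]) - log2(q[nz])))
}

#' Decompose policy risk into expected-utility and entropy terms
#'
#' The KL risk splits as risk = -EU - H, where
#' EU = sum posterior(s) * log2 prior(s) is the expected utility over
#' outcomes (non-positive; its negative is the cross-entropy) and
#' H is the entropy of the posterior over attainable states. The entropy
#' term is an exploration bonus: at fixed cross-entropy, a policy that keeps
#' more options open (higher H) carries strictly lower risk. Note the
#' identity requires the entropy to be *subtracted* from the cross-entropy.
#'
#' @inheritParams kl_discrete
#' @return A list with components `expected_utility_term` (bits, <= 0, or
#'   `-Inf`), `entropy_term` (bits), and `risk` (bits,
#'   `= -expected_utility_term - entropy_term`), which equals
#'   [kl_discrete()] to within floating-point accuracy.
#' @examples
#' post <- discrete_distribution(letters[1:4], rep(0.25, 4))
#' pri <- discrete_distribution(letters[1:4], c(0.4, 0.3, 0.2, 0.1))
#' decompose_risk(post, pri)
#' @export
decompose_risk <- function(posterior, prior) {
  stopifnot(is_discrete_distribution(posterior), is_discrete_distribution(prior))
  check_same_labels(posterior, prior)
  p <- posterior$probs
  q <- prior$probs
  nz <- p > 0
  h <- entropy_bits(posterior)
  if (any(q[nz] == 0)) {
    return(list(expected_utility_term = -Inf, entropy_term = h, risk = Inf))
  }
  eu <- sum(p[nz] * log2(q[nz]))
  list(expected_utility_term = eu, entropy_term = h, risk = -eu - h)
}

#' Kullback-Leibler divergence between two Gaussian beliefs, in bits
#'
#' Closed form, computed in nats and converted to bits:
#' ln(sd_prior/sd_post) + (sd_post^2 + (mu_post - mu_prior)^2) /
#' (2 sd_prior^2) - 1/2, all divided by ln 2. For equal standard deviations
#' this reduces to (delta mu)^2 / (2 sd^2 ln 2): risk grows quadratically
#' with the distance between the attainable-state mean and the goal mean.
#'
#' @param posterior A [gaussian_belief()] (attainable states).
#' @param prior A [gaussian_belief()] (goal states).
#' @return Divergence in bits.
#' @examples
#' kl_gaussian(gaussian_belief(5.3, 1), gaussian_belief(3, 1))
#' @export
kl_gaussian <- function(posterior, prior) {
  stopifnot(inherits(posterior, "gaussian_belief"),
            inherits(prior, "gaussian_belief"))
  nats <- log(prior$sd / posterior$sd) +
    (posterior$sd^2 + (posterior$mean - prior$mean)^2) / (2 * prior$sd^2) - 0.5
  nats / log(2)
}
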