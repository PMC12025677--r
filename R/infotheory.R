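#' Categorical distribution
#'
#' A finite probability vector, the basic currency of the package: beliefs
#' over hidden states, preference distributions over observations, policy
#' posteriors and capacity-achieving input distributions are all categoricals.
#'
#' @param probs numeric vector of non-negative probabilities summing to 1
#'   (validated to 1e-8, then renormalised exactly so downstream algebraic
#'   identities hold to machine precision).
#' @param labels optional character vector of outcome identifiers.
#' @return An object of class `imotiv_categorical`: the probability vector
#'   with an optional `names` attribute.
#' @export
#' @examples
#' p <- categorical(c(0.5, 0.25, 0.25))
#' entropy(p)
categorical <- function(probs, labels = NULL) {
  probs <- as.numeric(probs)
  stop_not_prob(probs, "categorical 'probs'")
  probs <- probs / sum(probs)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(probs))
    names(probs) <- labels
  }
  structure(probs, class = "imotiv_categorical")
}

#' @export
print.imotiv_categorical <- function(x, ...) {
  cat("<categorical over", length(x), "outcomes>\n")
  print(unclass(x), ...)
  invisible(x)
}

as_categorical <- function(p) {
  if (inherits(p, "imotiv_categorical")) p else categorical(p)
}

#' Joint distribution over two finite variables
#'
#' @param probs numeric matrix of non-negative probabilities; the grand total
#'   must be 1 (validated to 1e-8, then renormalised). Rows index the first
#'   variable X, columns the second variable Y.
#' @return An object of class `imotiv_joint`.
#' @export
joint_distribution <- function(probs) {
  probs <- as.matrix(probs)
  stop_not_prob(as.numeric(probs), "joint 'probs'")
  probs <- probs / sum(probs)
  structure(probs, class = "imotiv_joint")
}

#' Marginals of a joint distribution
#'
#' @param J an [joint_distribution()] object.
#' @param margin 1 for the row variable X, 2 for the column variable Y.
#' @return A [categorical()].
#' @export
marginal <- function(J, margin) {
  stopifnot(inherits(J, "imotiv_joint"), margin %in% c(1, 2))
  categorical(apply(unclass(J), margin, sum))
}

#' Discrete memoryless channel
#'
#' A row-stochastic conditional probability matrix P(Y | X): rows index input
#' symbols, columns output symbols. The capacity of such a channel, over the
#' channel linking an agent's action sequences to a future observation, is
#' the empowerment objective.
#'
#' @param matrix numeric matrix; every row must be a valid probability
#'   vector (each validated to 1e-8 and renormalised).
#' @return An object of class `imotiv_channel`.
#' @export
channel <- function(matrix) {
  m <- as.matrix(matrix)
  for (i in seq_len(nrow(m))) {
    stop_not_prob(m[i, ], sprintf("channel row %d", i))
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  structure(m, class = "imotiv_channel")
}

#' @export
print.imotiv_channel <- function(x, ...) {
  cat("<channel:", nrow(x), "inputs ->", ncol(x), "outputs>\n")
  print(unclass(x), ...)
  invisible(x)
}

# joint P(X, Y) = P(X) P(Y|X) induced by an input distribution and a channel
channel_joint <- function(input, ch) {
  input <- as_categorical(input)
  stopifnot(inherits(ch, "imotiv_channel"), length(input) == nrow(ch))
  joint_distribution(as.numeric(input) * unclass(ch))
}

#' Shannon entropy of a categorical distribution
#'
#' H(p) = -sum p log p in nats, with 0 log 0 treated as 0 by masking.
#'
#' @param p a [categorical()] or a bare probability vector.
#' @return Entropy in nats (non-negative scalar).
#' @export
#' @examples
#' entropy(categorical(rep(0.25, 4))) # log(4)
entropy <- function(p) {
  p <- as_categorical(p)
  -sum(xlogx(as.numeric(p)))
}

#' Kullback-Leibler divergence between categoricals
#'
#' KL(p || q) = sum p log(p/q) in nats. Requires absolute continuity: every
#' outcome with p > 0 must have q > 0.
#'
#' @param p,q [categorical()] objects (or bare vectors) on the same support.
#' @return Divergence in nats; non-negative, 0 iff p == q.
#' @export
kl_divergence <- function(p, q) {
  p <- as.numeric(as_categorical(p))
  q <- as.numeric(as_categorical(q))
  if (length(p) != length(q)) abort("p and q must have the same support size")
  bad <- which(p > 0 & q == 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "KL divergence undefined: q is zero where p > 0 at index %s",
      paste(bad, collapse = ", ")))
  }
  sum(xlogxy(p, q))
}

#' Mutual information of a joint distribution, by a chosen algebraic route
#'
#' I(X;Y) can be written as the KL divergence from the joint to the product
#' of marginals, as an expected KL divergence of conditionals, or as three
#' different entropy differences. All five routes are implemented
#' independently so their agreement can be checked numerically rather than
#' assumed.
#'
#' @param J a [joint_distribution()].
#' @param form one of `"kl_joint"` (KL from joint to product of marginals),
#'   `"expected_kl"` (E over X of KL from P(Y|X) to P(Y)),
#'   `"entropy_difference_x"` (H(X) - H(X|Y)),
#'   `"entropy_difference_y"` (H(Y) - H(Y|X)),
#'   `"entropy_sum"` (H(X) + H(Y) - H(X,Y)).
#' @return I(X;Y) in nats.
#' @export
mutual_information <- function(J, form = c("kl_joint", "expected_kl",
                                           "entropy_difference_x",
                                           "entropy_difference_y",
                                           "entropy_sum")) {
  form <- match.arg(form)
  stopifnot(inherits(J, "imotiv_joint"))
  m <- unclass(J)
  px <- rowSums(m)
  py <- colSums(m)
  switch(form,
    kl_joint = {
      prod_marg <- outer(px, py)
      sum(xlogxy(as.numeric(m), as.numeric(prod_marg)))
    },
    expected_kl = {
      total <- 0
      for (i in seq_along(px)) {
        if (px[i] > 0) {
          cond <- m[i, ] / px[i]
          total <- total + px[i] * sum(xlogxy(cond, py))
        }
      }
      total
    },
    entropy_difference_x = {
      entropy(categorical(px)) - conditional_entropy(J, given = 2)
    },
    entropy_difference_y = {
      entropy(categorical(py)) - conditional_entropy(J, given = 1)
    },
    entropy_sum = {
      entropy(categorical(px)) + entropy(categorical(py)) +
        sum(xlogx(as.numeric(m)))
    })
}

#' Conditional entropy from a joint distribution
#'
#' @param J a [joint_distribution()] over (X, Y).
#' @param given which variable is conditioned on: 1 returns H(Y|X), 2 returns
#'   H(X|Y).
#' @return Conditional entropy in nats.
#' @export
conditional_entropy <- function(J, given) {
  stopifnot(inherits(J, "imotiv_joint"), given %in% c(1, 2))
  m <- unclass(J)
  if (given == 2) m <- t(m)
  pg <- rowSums(m)
  total <- 0
  for (i in seq_along(pg)) {
    if (pg[i] > 0) total <- total - sum(xlogxy(m[i, ], rep(pg[i], ncol(m))))
  }
  total
}
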