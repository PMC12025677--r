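#' Channel capacity by Blahut-Arimoto iteration
#'
#' Computes C = max over input distributions P(X) of I(X;Y) for a fixed
#' channel P(Y|X), the quantity that defines empowerment when the channel
#' links action sequences to a future observation. Uses the classical
#' alternating fixed-point iteration, which converges from the uniform input
#' distribution for any finite channel. At each iterate the per-row
#' divergences D_x = KL(P(Y|x) || q(Y)) give a lower bound sum_x r_x D_x
#' (the mutual information at the current input distribution r) and an upper
#' bound max_x D_x on capacity; iteration stops when the gap falls below
#' `tol`.
#'
#' Output columns that no input can reach are retained (with zero mass), so
#' column indexing is stable across calls.
#'
#' @param ch a [channel()].
#' @param tol convergence tolerance in nats (gap between the capacity upper
#'   and lower bounds); default 1e-9.
#' @param max_iter iteration cap; default 10000. If reached before the bound
#'   gap closes a warning is issued and `converged` is `FALSE`.
#' @return An object of class `imotiv_capacity` with elements
#'   \describe{
#'     \item{capacity}{the capacity lower bound at termination, in nats}
#'     \item{input_distribution}{the maximising input [categorical()]}
#'     \item{iterations}{number of iterations performed}
#'     \item{converged}{logical; whether the bound gap closed within `tol`}
#'     \item{bound_gap}{final upper-minus-lower bound gap, in nats}
#'     \item{trace}{numeric vector of the lower-bound iterates (monotone
#'       non-decreasing)}
#'   }
#' @export
#' @examples
#' bsc <- channel(rbind(c(0.9, 0.1), c(0.1, 0.9)))
#' channel_capacity(bsc)$capacity # log(2) - H2(0.1)
channel_capacity <- function(ch, tol = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(ch, "imotiv_channel"))
  if (!is.numeric(tol) || tol <= 0) abort("'tol' must be a positive number")
  W <- unclass(ch)
  n_in <- nrow(W)
  r <- rep(1 / n_in, n_in)
  trace <- numeric(max_iter)
  lower <- 0
  gap <- Inf

  # per-row W log W, fixed across iterations; zero entries masked
  wlogw <- rowSums(matrix(xlogx(as.numeric(W)), nrow = n_in))

  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    q <- as.numeric(crossprod(W, r)) # output marginal under r
    # D_x = KL(W[x, ] || q); q[y] == 0 implies W[x, y] == 0 for all x with
    # r_x > 0, handled by masking
    logq <- ifelse(q > 0, log(q), 0)
    D <- wlogw - as.numeric(W %*% logq)
    lower <- sum(r * D)
    upper <- max(D)
    trace[iter] <- lower
    gap <- upper - lower
    if (gap < tol) break
    # multiplicative update r <- r exp(D) / Z, in log space for stability
    logr <- log(r) + D
    r <- exp(logr - logsumexp(logr))
  }

  converged <- gap < tol
  if (!converged) {
    warn(sprintf(
      "Blahut-Arimoto stopped at max_iter = %d with bound gap %.3g nats > tol %.3g",
      max_iter, gap, tol))
  }
  structure(
    list(capacity = lower,
         input_distribution = categorical(r),
         iterations = iter,
         converged = converged,
         bound_gap = gap,
         trace = trace[seq_len(iter)]),
    class = "imotiv_capacity")
}

#' @export
print.imotiv_capacity <- function(x, ...) {
  cat(sprintf("<channel capacity: %.6f nats (%.6f bits), %d iterations, %s>\n",
              x$capacity, nats_to_bits(x$capacity), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Mutual information across a channel for a given input distribution
#'
#' Convenience wrapper: builds the joint P(X)P(Y|X) and evaluates I(X;Y).
#'
#' @param input input [categorical()] (or bare vector) over channel rows.
#' @param ch a [channel()].
#' @param form algebraic route, passed to [mutual_information()].
#' @return I(X;Y) in nats.
#' @export
channel_mutual_information <- function(input, ch, form = "kl_joint") {
  mutual_information(channel_joint(input, ch), form = form)
}

#' Brute-force channel capacity by simplex grid search
#'
#' Enumerates input distributions on a regular simplex grid and returns the
#' best mutual information found. Exponential in the number of channel rows;
#' intended as an independent reference for small channels, not as a solver.
#' With `refine = TRUE` a second pass searches a finer local grid around the
#' coarse optimum, reaching `resolution` locally while keeping the point
#' count manageable for 4-row channels.
#'
#' @param ch a [channel()] with a small number of rows (<= 4 enforced).
#' @param resolution grid spacing on the simplex (default 0.001).
#' @param refine logical; coarse-then-local-fine search (default `TRUE` for
#'   channels with more than 3 rows).
#' @return list with `capacity` (nats) and `input_distribution`.
#' @export
capacity_grid_search <- function(ch, resolution = 0.001,
                                 refine = nrow(ch) > 3) {
  stopifnot(inherits(ch, "imotiv_channel"))
  k <- nrow(ch)
  if (k > 4) abort("grid search supported only for channels with <= 4 rows")
  if (k == 1) {
    return(list(capacity = 0, input_distribution = categorical(1)))
  }
  coarse_res <- if (refine) max(resolution, 0.01) else resolution
  grid <- simplex_grid(k, coarse_res)
  best <- grid_best_mi(grid, ch)
  if (refine && coarse_res > resolution) {
    # local box of width 2 * coarse_res around the coarse optimum
    fine <- simplex_grid_local(best$input, k, resolution,
                               halfwidth = 2 * coarse_res)
    best_fine <- grid_best_mi(fine, ch)
    if (best_fine$capacity > best$capacity) best <- best_fine
  }
  list(capacity = best$capacity,
       input_distribution = categorical(best$input))
}

# all points of the k-simplex with coordinates that are multiples of res
simplex_grid <- function(k, res) {
  n <- round(1 / res)
  if (k == 2) {
    a <- 0:n
    cbind(a, n - a) / n
  } else if (k == 3) {
    a <- unlist(lapply(0:n, function(i) rep(i, n - i + 1)))
    b <- unlist(lapply(0:n, function(i) 0:(n - i)))
    cbind(a, b, n - a - b) / n
  } else {
    out <- list()
    for (i in 0:n) {
      for (j in 0:(n - i)) {
        l <- 0:(n - i - j)
        out[[length(out) + 1L]] <- cbind(i, j, l, n - i - j - l)
      }
    }
    do.call(rbind, out) / n
  }
}

# grid restricted to a box around a centre point, reprojected to the simplex
simplex_grid_local <- function(centre, k, res, halfwidth) {
  n <- round(1 / res)
  lo <- pmax(0, round((centre - halfwidth) * n))
  hi <- pmin(n, round((centre + halfwidth) * n))
  if (k == 2) {
    a <- lo[1]:hi[1]
    g <- cbind(a, n - a)
  } else if (k == 3) {
    ab <- expand.grid(a = lo[1]:hi[1], b = lo[2]:hi[2])
    g <- cbind(ab$a, ab$b, n - ab$a - ab$b)
  } else {
    abc <- expand.grid(a = lo[1]:hi[1], b = lo[2]:hi[2], c = lo[3]:hi[3])
    g <- cbind(abc$a, abc$b, abc$c, n - abc$a - abc$b - abc$c)
  }
  g <- g[g[, k] >= 0 & g[, k] <= n, , drop = FALSE]
  g / n
}

# vectorised evaluation of I(r; W) over many input distributions (rows of R)
grid_best_mi <- function(R, ch) {
  W <- unclass(ch)
  Q <- R %*% W # output marginals, one row per candidate input
  logQ <- ifelse(Q > 0, log(Q), 0)
  mi <- numeric(nrow(R))
  for (x in seq_len(nrow(W))) {
    w <- W[x, ]
    pos <- w > 0
    # D_x(r) = sum_y w_y log(w_y / q_y); rows where r_x = 0 contribute 0
    Dx <- as.numeric(logQ[, pos, drop = FALSE] %*% w[pos])
    Dx <- sum(xlogx(w)) - Dx
    mi <- mi + R[, x] * Dx
  }
  i <- which.max(mi)
  list(capacity = mi[i], input = R[i, ])
}
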