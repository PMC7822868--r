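# Observer internal noise and nonparametric information estimation --------

#' Observer internal-noise model referred to a discrimination threshold
#'
#' Internal noise is additive and isotropic in the uniform colour space,
#' applied independently per coordinate. Both families are parameterised by
#' a nominal width `w` with matched variance `w^2 / 12`: for the uniform
#' family `w` is the width of the support, for the Gaussian family
#' `w = sqrt(12) * sigma`. The width is referred to a hard discrimination
#' threshold `delta_e_thr` through `w = w_per_threshold * delta_e_thr`
#' (default 2: a hard threshold of 0.5 admits displacements up to 0.5 per
#' axis); the constant is exposed so alternative conventions can be swept.
#'
#' @param delta_e_thr hard discrimination threshold in colour-space units
#'   (`> 0`); 0.5 in CIECAM02 space is about one just-perceptible
#'   difference (about 1.0 in CIELAB).
#' @param family `"gaussian"` or `"uniform"`.
#' @param w_per_threshold ratio `w / delta_e_thr` (default 2).
#' @return A `noise_model` with fields `family`, `width_w`, `delta_e_thr`,
#'   `sd`.
#' @export
noise_model <- function(delta_e_thr = 0.5,
                        family = c("gaussian", "uniform"),
                        w_per_threshold = 2) {
  family <- match.arg(family)
  check_number(delta_e_thr, "delta_e_thr", lower = 0, strict_lower = TRUE)
  check_number(w_per_threshold, "w_per_threshold", lower = 0,
               strict_lower = TRUE)
  w <- w_per_threshold * delta_e_thr
  structure(list(family = family, width_w = w, delta_e_thr = delta_e_thr,
                 sd = w / sqrt(12)),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_width_from_threshold <- noise_model

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %s, w = %g (sd %.4g), delta_E_thr = %g\n",
              x$family, x$width_w, x$sd, x$delta_e_thr))
  invisible(x)
}

#' Draw observer-noise displacements
#'
#' i.i.d. per coordinate from the model's family; per-coordinate variance
#' is `w^2 / 12` for both families.
#'
#' @param n number of 3-d displacement triplets.
#' @param model a [noise_model()].
#' @param d dimensionality (default 3).
#' @param seed optional integer seed.
#' @return `n x d` numeric matrix.
#' @export
draw_noise <- function(n, model, d = 3, seed = NULL) {
  stopifnot(inherits(model, "noise_model"), n >= 1)
  with_seed_(seed, {
    if (model$family == "gaussian") {
      matrix(rnorm(n * d, 0, model$sd), n, d)
    } else {
      matrix(runif(n * d, -model$width_w / 2, model$width_w / 2), n, d)
    }
  })
}

# Differential entropy -----------------------------------------------------

log_unit_ball <- function(d) (d / 2) * log(pi) - lgamma(d / 2 + 1)

# deterministic tiny jitter to break exact ties before neighbour search
break_ties <- function(x, rel_scale = 1e-9) {
  dup <- duplicated(asplit(x, 1))
  if (!any(dup)) return(x)
  scale <- mean(apply(x, 2, sd))
  if (scale == 0) scale <- mean(abs(x)) + 1
  jit <- with_seed_(271828L,
                    matrix(rnorm(length(x), 0, rel_scale * scale), nrow(x)))
  x + jit
}

#' Kozachenko-Leonenko k-nearest-neighbour differential entropy
#'
#' Nonparametric estimate of the Shannon differential entropy
#' `h = -integral f log2 f`, in bits, from the distances of each point to
#' its `k`-th nearest neighbour:
#' `h_hat = psi(n) - psi(k) + log2(V_d) + (d/n) sum_i log2(eps_i)`
#' with `V_d` the unit-ball volume in `d` dimensions. Exact ties are broken
#' by a deterministic jitter of 1e-9 times the data scale before the
#' neighbour search.
#'
#' @param points numeric matrix (or data frame) of observations, one row
#'   per point, any dimension.
#' @param k_neighbour neighbour order (`>= 1`, `< n`), default 3.
#' @return Differential entropy in bits.
#' @export
kl_entropy <- function(points, k_neighbour = 3) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (n <= k_neighbour) {
    abort("need more points than `k_neighbour`.",
          class = "surfid_domain_error")
  }
  if (duplicate_fraction(x) >= 0.01) {
    abort("sample is duplicate-heavy; a continuous density cannot be assumed.",
          class = "surfid_degenerate_error")
  }
  x <- break_ties(x)
  eps <- .kth_nn_distance(x, as.integer(k_neighbour))
  eps <- eps[eps > 0]
  h_nats <- digamma(n) - digamma(k_neighbour) + log_unit_ball(d) +
    d * mean(log(eps))
  h_nats / log(2)
}

# Whitening by the sample covariance (Cholesky), mapped back exactly
# through the log-Jacobian: differential entropy transforms additively
# under linear maps, and the kNN estimator's finite-sample bias is much
# smaller on a near-isotropic cloud. Falls back to per-coordinate scaling
# when the covariance is singular; constant coordinates are left unscaled.
whiten_block <- function(x) {
  s <- apply(x, 2, sd)
  s[s <= 0 | !is.finite(s)] <- 1
  xs <- sweep(x, 2, s, `/`)
  ch <- tryCatch(chol(stats::cov(xs)), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-8)) {
    return(list(z = xs, logdet = sum(log2_(s))))
  }
  l <- t(ch)
  list(z = t(forwardsolve(l, t(xs))),
       logdet = sum(log2_(s)) + sum(log2_(diag(l))))
}

std_entropy <- function(x, k_neighbour) {
  w <- whiten_block(x)
  kl_entropy(w$z, k_neighbour) + w$logdet
}

# plug-in discrete mutual information from row keys
discrete_mi <- function(a, b) {
  ka <- apply(a, 1, paste, collapse = "\r")
  kb <- apply(b, 1, paste, collapse = "\r")
  tab <- table(ka, kb) / length(ka)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log2_(tab[nz] / outer(pa, pb)[nz]))
}

group_keys_ <- function(x) apply(x, 1, paste, collapse = "\r")

# I(A;B) = h(B) - sum_m p_m h(B | A = m) for discrete A, continuous B:
# the exact mixed discrete-continuous decomposition
conditional_mi <- function(a_discrete, b, k_neighbour) {
  key <- group_keys_(a_discrete)
  groups <- split(seq_along(key), key)
  sizes <- lengths(groups)
  if (any(sizes <= k_neighbour + 1)) {
    abort("a discrete level has too few observations for the conditional entropy.",
          class = "surfid_degenerate_error")
  }
  # I is invariant under any common linear map of B, and the two entropy
  # terms share their local geometry, so whiten by the pooled WITHIN-group
  # covariance (the noise scale); the Jacobians cancel in the difference
  resid <- b
  for (idx in groups) {
    resid[idx, ] <- sweep(b[idx, , drop = FALSE], 2,
                          colMeans(b[idx, , drop = FALSE]))
  }
  s <- apply(resid, 2, sd)
  s[s <= 0 | !is.finite(s)] <- 1
  zb <- sweep(b, 2, s, `/`)
  ch <- tryCatch(chol(stats::cov(sweep(resid, 2, s, `/`))),
                 error = function(e) NULL)
  if (!is.null(ch) && all(diag(ch) >= 1e-8)) {
    zb <- t(forwardsolve(t(ch), t(zb)))
  }
  h_b <- kl_entropy(zb, k_neighbour)
  h_cond <- sum(vapply(groups, function(idx) {
    (length(idx) / length(key)) *
      kl_entropy(zb[idx, , drop = FALSE], k_neighbour)
  }, numeric(1)))
  h_b - h_cond
}

# Continuous path: Eq.-2 three-entropy combination with the offset shear.
# h(A,B) equals h(A, B - A) exactly (det-1 linear map), and the sheared
# joint is far better conditioned when B is A plus a small change, which
# is this package's regime. Per-coordinate standardisation is corrected
# exactly through the Jacobian terms.
continuous_mi <- function(a, b, k_neighbour) {
  d_ab <- b - a
  if (all(apply(d_ab, 2, sd) == 0)) {
    abort("B is identical to A with zero noise: joint density is singular; add observer noise.",
          class = "surfid_degenerate_error")
  }
  wa <- whiten_block(a)
  wd <- whiten_block(d_ab)
  h_a <- kl_entropy(wa$z, k_neighbour) + wa$logdet
  h_b <- std_entropy(b, k_neighbour)
  # joint assembled from the block-whitened A and D clouds so the shear's
  # cross-structure is preserved; Jacobians corrected exactly
  h_joint <- kl_entropy(cbind(wa$z, wd$z), k_neighbour) +
    wa$logdet + wd$logdet
  h_a + h_b - h_joint
}

mi_once <- function(a, b, k_neighbour, discrete_threshold = 0.1) {
  dup_a <- duplicate_fraction(a)
  dup_b <- duplicate_fraction(b)
  if (dup_a > discrete_threshold && dup_b > discrete_threshold) {
    discrete_mi(a, b)
  } else if (dup_a > discrete_threshold) {
    conditional_mi(a, b, k_neighbour)
  } else if (dup_b > discrete_threshold) {
    conditional_mi(b, a, k_neighbour)
  } else {
    continuous_mi(a, b, k_neighbour)
  }
}

#' Mutual information of paired colour codes
#'
#' Estimates `I(A;B) = h(A) + h(B) - h(A,B)` in bits with
#' Kozachenko-Leonenko entropies, in conjunction with an offset scheme: the
#' joint entropy is evaluated on the offset variables `(A, B - A)` -- a
#' determinant-1 shear that leaves `h(A,B)` unchanged but removes the
#' near-singular diagonal concentration that arises when `B` is `A` plus a
#' small perturbation. When one variable is discrete (a palette), the exact
#' mixed decomposition `I = h(B) - sum_m p_m h(B | A = m)` is used instead;
#' when both are discrete, the plug-in contingency-table estimate.
#'
#' If a [noise_model()] is supplied, `b_points` is taken as the noiseless
#' partner code and the estimate is averaged over `n_noise_reps`
#' independent draws of observer noise added to it. Negative estimates are
#' clamped to zero (with a message).
#'
#' @param a_points,b_points matrices or tibbles of coordinates, row-paired
#'   by pixel.
#' @param k_neighbour neighbour order, default 3.
#' @param n_noise_reps noise draws averaged when `noise` is supplied.
#' @param noise optional [noise_model()] applied to `b_points`.
#' @param seed integer seed for the noise draws.
#' @return An `mi_estimate` with fields `bits`, `k_neighbour`, `n_points`,
#'   `n_noise_reps`, `seed`, `clamped`.
#' @export
mutual_information <- function(a_points, b_points, k_neighbour = 3,
                               n_noise_reps = 1, noise = NULL, seed = NULL) {
  a <- as.matrix(a_points)
  b <- as.matrix(b_points)
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  if (nrow(a) != nrow(b)) {
    abort("`a_points` and `b_points` must be row-paired.",
          class = "surfid_pairing_error")
  }
  if (nrow(a) <= k_neighbour) {
    abort("need more points than `k_neighbour`.",
          class = "surfid_domain_error")
  }
  if (is.null(noise)) {
    bits_reps <- mi_once(a, b, k_neighbour)
    n_reps <- 1L
  } else {
    n_reps <- max(1L, as.integer(n_noise_reps))
    bits_reps <- vapply(seq_len(n_reps), function(r) {
      w <- draw_noise(nrow(b), noise, d = ncol(b),
                      seed = split_seed(seed %||% 0, paste0("noiserep", r)))
      mi_once(a, b + w, k_neighbour)
    }, numeric(1))
  }
  bits <- mean(bits_reps)
  clamped <- bits < 0
  if (clamped) {
    inform(sprintf("negative mutual-information estimate (%.4f bits) clamped to 0.",
                   bits))
    bits <- 0
  }
  structure(list(bits = bits, k_neighbour = as.integer(k_neighbour),
                 n_points = nrow(a), n_noise_reps = n_reps,
                 seed = seed, clamped = clamped),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> %.4f bits (k = %d, n = %d, reps = %d)\n",
              x$bits, x$k_neighbour, x$n_points, x$n_noise_reps))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mi_estimate <- function(x, ...) {
  tibble(bits = x$bits, k_neighbour = x$k_neighbour, n_points = x$n_points,
         n_noise_reps = x$n_noise_reps, clamped = x$clamped)
}
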