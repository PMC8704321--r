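# Interval-valued polypharmacology. The number of targets a ligand is truly
# active against is bracketed by Pmin (known actives only) and Pmax (known
# actives plus all null pairs assumed active). An urn-model estimate of the
# active fraction among a ligand's measured pairs tightens the upper bound to
# the expectation P~max = |S+| + p_hat * |S0|, and a Jeffreys Beta posterior
# on p_hat, mapped affinely through that expression, yields a confidence
# interval. The joint (two-ligand) analogue works on the 3x3 cross-partition
# of the target set.

#' Simple polypharmacology bounds
#'
#' `polypharm_min()` counts a ligand's known active targets (a lower bound on
#' its true polypharmacology). `polypharm_max()` adds all null targets,
#' assuming each is active (the upper bound). The true value always lies in
#' between; the width of the interval equals the number of null pairs, so
#' every new measurement — active *or* inactive — shrinks the maximum error.
#'
#' @param profile An `lt_profile` from [ligand_profile()].
#' @return A non-negative integer.
#' @export
#' @examples
#' p <- ligand_profile(toy_example_relation(), "l1")
#' polypharm_min(p)  # 2
#' polypharm_max(p)  # 4
polypharm_min <- function(profile) {
  stopifnot(inherits(profile, "lt_profile"))
  length(profile$active)
}

#' @rdname polypharm_min
#' @export
polypharm_max <- function(profile) {
  stopifnot(inherits(profile, "lt_profile"))
  length(profile$active) + length(profile$null)
}

#' Urn-model active-rate estimate
#'
#' The fraction of a ligand's measured pairs that are active, used as an
#' estimate of the conditional probability that one of its null pairs is in
#' fact active. When the ligand has no measured pairs the rate is undefined;
#' a `fallback` rate (typically the dataset-wide active fraction among known
#' pairs) may then be substituted, and the source flag records which was
#' used.
#'
#' @param profile An `lt_profile`.
#' @param fallback Optional probability used when the ligand has no measured
#'   pairs.
#' @return List with `p_hat` (number or `NA`) and `source` (one of
#'   `"ligand-specific"`, `"global-fallback"`, `"undefined"`).
#' @export
active_rate <- function(profile, fallback = NULL) {
  stopifnot(inherits(profile, "lt_profile"))
  k <- length(profile$active)
  n <- k + length(profile$inactive)
  if (n > 0) return(list(p_hat = k / n, source = "ligand-specific"))
  if (!is.null(fallback)) {
    stopifnot(is.numeric(fallback), fallback >= 0, fallback <= 1)
    return(list(p_hat = fallback, source = "global-fallback"))
  }
  list(p_hat = NA_real_, source = "undefined")
}

#' Probability-weighted upper bound
#'
#' The expectation-value upper bound `|S+| + p_hat * |S0|`: known actives
#' plus the expected number of active null pairs. Kept real-valued (it is an
#' expectation, not a count). Also returns the corresponding expected error
#' `p_hat * |S0|`.
#'
#' @param profile An `lt_profile`.
#' @param p_hat Probability that a null pair of this ligand is active.
#' @return List with `p_tilde_max` and `delta_e_tilde`.
#' @export
polypharm_max_estimated <- function(profile, p_hat) {
  stopifnot(inherits(profile, "lt_profile"))
  if (length(p_hat) != 1 || is.na(p_hat)) {
    stop("p_hat is undefined; supply a fallback rate via active_rate()")
  }
  stopifnot(p_hat >= 0, p_hat <= 1)
  n0 <- length(profile$null)
  list(p_tilde_max = length(profile$active) + p_hat * n0,
       delta_e_tilde = p_hat * n0)
}

#' Jeffreys interval for a binomial proportion
#'
#' Central interval of the Beta(k + 1/2, n - k + 1/2) posterior (the Jeffreys
#' prior posterior) at levels `alpha/2` and `1 - alpha/2`, with the standard
#' boundary conventions: the lower endpoint is exactly 0 when `k = 0` and the
#' upper exactly 1 when `k = n`. With `n = 0` there is no data and the
#' interval is the whole unit interval, flagged via the `"no_data"`
#' attribute.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials.
#' @param alpha Significance level in `(0, 1)`; default 0.05.
#' @return Numeric `c(low, high)` on the probability scale.
#' @export
#' @examples
#' jeffreys_interval(2, 3)
jeffreys_interval <- function(k, n, alpha = 0.05) {
  stopifnot(length(k) == 1, length(n) == 1, length(alpha) == 1)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (n < 0 || k < 0 || k > n) stop("need 0 <= k <= n")
  if (n == 0) {
    return(structure(c(low = 0, high = 1), no_data = TRUE))
  }
  low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k + 0.5, n - k + 0.5)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 0.5, n - k + 0.5)
  c(low = low, high = high)
}

#' Per-ligand polypharmacology report
#'
#' Computes, for every ligand of a relation, the interval
#' `[Pmin, P~max, Pmax]`, the urn-model active rate with its source flag, the
#' maximum and expected errors, and the Jeffreys confidence interval on
#' `P~max` obtained by mapping the probability-scale interval affinely
#' through `|S+| + q * |S0|`.
#'
#' @param rel An [lt_relation()].
#' @param alpha Significance level for the Jeffreys intervals; default 0.05.
#' @param fallback `"global"` (default) substitutes the dataset-wide active
#'   fraction among known pairs when a ligand has no measured pairs;
#'   `"strict"` leaves such ligands undefined (`NA` estimate and CI).
#' @return A data frame of class `lt_polypharm`, one row per ligand, columns
#'   `ligand`, `n_active`, `n_inactive`, `n_null`, `p_min`, `p_hat`,
#'   `p_hat_source`, `p_tilde_max`, `ci_low`, `ci_high`, `p_max`,
#'   `delta_e_max`, `delta_e_tilde`; attribute `alpha`.
#' @export
#' @examples
#' polypharm(toy_example_relation())
polypharm <- function(rel, alpha = 0.05, fallback = c("global", "strict")) {
  stopifnot(inherits(rel, "lt_relation"))
  fallback <- match.arg(fallback)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  codes <- unclass(rel)
  k <- rowSums(codes == 1L)           # known actives |S+|
  ni <- rowSums(codes == 2L)          # known inactives |S-|
  n0 <- rowSums(codes == 3L)          # nulls |S0|
  nk <- k + ni
  global_known <- sum(nk)
  global_rate <- if (global_known > 0) sum(k) / global_known else NA_real_

  p_hat <- ifelse(nk > 0, k / nk, NA_real_)
  source <- ifelse(nk > 0, "ligand-specific", "undefined")
  if (fallback == "global" && !is.na(global_rate)) {
    fb <- nk == 0
    p_hat[fb] <- global_rate
    source[fb] <- "global-fallback"
  }

  nl <- nrow(codes)
  ci_low <- ci_high <- numeric(nl)
  for (i in seq_len(nl)) {
    if (is.na(p_hat[i])) {
      ci_low[i] <- NA_real_
      ci_high[i] <- NA_real_
    } else {
      # ligands with no measured pairs get the no-data interval (0, 1),
      # which maps to [Pmin, Pmax]
      q <- jeffreys_interval(k[i], nk[i], alpha)
      ci_low[i] <- k[i] + q[["low"]] * n0[i]
      ci_high[i] <- k[i] + q[["high"]] * n0[i]
    }
  }

  out <- data.frame(
    ligand = rownames(codes),
    n_active = as.integer(k), n_inactive = as.integer(ni),
    n_null = as.integer(n0),
    p_min = as.integer(k),
    p_hat = p_hat, p_hat_source = source,
    p_tilde_max = k + p_hat * n0,
    ci_low = ci_low, ci_high = ci_high,
    p_max = as.integer(k + n0),
    delta_e_max = as.integer(n0),
    delta_e_tilde = p_hat * n0,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("lt_polypharm", "data.frame")
  out
}

#' @export
print.lt_polypharm <- function(x, ...) {
  cat("Simple polypharmacology estimates for ", nrow(x),
      " ligands (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' @export
summary.lt_polypharm <- function(object, ...) {
  cat("Simple polypharmacology over ", nrow(object), " ligands (alpha = ",
      attr(object, "alpha"), ")\n", sep = "")
  cat("  Pmin:       median ", stats::median(object$p_min),
      ", max ", max(object$p_min), "\n", sep = "")
  cat("  P~max:      median ",
      formatC(stats::median(object$p_tilde_max), digits = 2, format = "f"),
      "\n", sep = "")
  cat("  Pmax:       median ", stats::median(object$p_max), "\n", sep = "")
  cat("  max error (null pairs): median ", stats::median(object$delta_e_max),
      "\n", sep = "")
  src <- table(object$p_hat_source)
  cat("  p_hat sources: ",
      paste(names(src), src, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(object)
}

#' @export
plot.lt_polypharm <- function(x, order_by = "p_min", ...) {
  o <- order(x[[order_by]], x$p_tilde_max)
  n <- nrow(x)
  plot(NA, xlim = c(1, n), ylim = c(0, max(x$p_max)),
       xlab = "ligand rank", ylab = "polypharmacology",
       main = "Interval-valued simple polypharmacology", ...)
  graphics::segments(seq_len(n), x$p_min[o], seq_len(n), x$p_max[o],
                     col = "grey80")
  graphics::segments(seq_len(n), x$ci_low[o], seq_len(n), x$ci_high[o],
                     col = "black")
  graphics::points(seq_len(n), x$p_tilde_max[o], pch = 20, col = "limegreen")
  graphics::points(seq_len(n), x$p_min[o], pch = 20, col = "darkgreen")
  invisible(x)
}

# ---- joint polypharmacology ------------------------------------------------

#' Joint 3x3 state partition of a ligand pair
#'
#' Cross-tabulates the targets by the activity state each of two ligands
#' assigns them: the nine disjoint cells (active/inactive/null for the first
#' ligand crossed with the same for the second) partition the target set.
#'
#' @param profile_a,profile_b `lt_profile`s over the same target reference
#'   set.
#' @return A 3x3 integer matrix of class `lt_joint_partition` with dimnames
#'   over [lt_states()], attribute `pair` (the two ids).
#' @export
#' @examples
#' rel <- toy_example_relation()
#' joint_partition(ligand_profile(rel, "l1"), ligand_profile(rel, "l2"))
joint_partition <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "lt_profile"),
            inherits(profile_b, "lt_profile"))
  if (!identical(profile_a$active$reference, profile_b$active$reference)) {
    stop("profiles are over different reference sets")
  }
  ref <- profile_a$active$reference
  state_of <- function(p) {
    s <- rep(3L, length(ref))
    s[ref %in% p$active$members] <- 1L
    s[ref %in% p$inactive$members] <- 2L
    s
  }
  sa <- state_of(profile_a)
  sb <- state_of(profile_b)
  counts <- matrix(0L, 3, 3, dimnames = list(lt_states(), lt_states()))
  for (i in 1:3) for (j in 1:3) counts[i, j] <- sum(sa == i & sb == j)
  structure(counts, class = "lt_joint_partition",
            pair = c(profile_a$id, profile_b$id))
}

#' @export
print.lt_joint_partition <- function(x, ...) {
  p <- attr(x, "pair")
  cat("Joint state partition of (", p[1], ", ", p[2], ") over ",
      sum(x), " targets\n", sep = "")
  print(unclass(structure(x, pair = NULL)))
  invisible(x)
}

#' Joint polypharmacology bounds
#'
#' The number of targets two ligands are both truly active against is at
#' least the count of targets both are known active on, and at most that
#' count plus every cell in which one or both states are null (each such
#' target could still turn out jointly active).
#'
#' @param partition An [joint_partition()].
#' @return A non-negative integer.
#' @export
joint_polypharm_min <- function(partition) {
  stopifnot(inherits(partition, "lt_joint_partition"))
  as.integer(partition["active", "active"])
}

#' @rdname joint_polypharm_min
#' @export
joint_polypharm_max <- function(partition) {
  stopifnot(inherits(partition, "lt_joint_partition"))
  as.integer(partition["active", "active"] + partition["active", "null"] +
               partition["null", "active"] + partition["null", "null"])
}

#' Probability estimates for the joint null cells
#'
#' The three conditional probabilities that a target in a mixed or doubly
#' null cell is jointly active, in the order
#' `Pr(+,0+)` (first ligand known active, second null),
#' `Pr(0+,+)` (first null, second known active),
#' `Pr(0+,0+)` (both null).
#'
#' In `"joint"` mode each is estimated from the doubly measured targets:
#' `Pr(+,0+) = |S++| / (|S++| + |S+-|)`,
#' `Pr(0+,+) = |S++| / (|S++| + |S-+|)`,
#' `Pr(0+,0+) = |S++| / (|S++| + |S+-| + |S-+| + |S--|)`.
#' In `"independence"` mode the marginal urn-model rates are used instead:
#' `Pr(+,0+) = p_hat(l')`, `Pr(0+,+) = p_hat(l)`,
#' `Pr(0+,0+) = p_hat(l) * p_hat(l')`.
#'
#' @param partition An [joint_partition()].
#' @param mode `"joint"` or `"independence"`.
#' @param p_hat_a,p_hat_b Marginal active rates of the two ligands
#'   (independence mode).
#' @param fallback Optional probability substituted when a joint-mode
#'   denominator is zero; without it the value is `NA` with source
#'   `"undefined"`.
#' @return Named numeric vector
#'   `c(p_act_null =, p_null_act =, p_null_null =)` with a `source`
#'   attribute (per-component flags).
#' @export
joint_prob_estimates <- function(partition,
                                 mode = c("joint", "independence"),
                                 p_hat_a = NULL, p_hat_b = NULL,
                                 fallback = NULL) {
  stopifnot(inherits(partition, "lt_joint_partition"))
  mode <- match.arg(mode)
  if (mode == "independence") {
    if (is.null(p_hat_a) || is.null(p_hat_b) ||
        is.na(p_hat_a) || is.na(p_hat_b)) {
      stop("independence mode needs marginal p_hat values for both ligands")
    }
    out <- c(p_act_null = p_hat_b, p_null_act = p_hat_a,
             p_null_null = p_hat_a * p_hat_b)
    attr(out, "source") <- rep("independence", 3)
    return(out)
  }
  kpp <- partition["active", "active"]
  den <- c(kpp + partition["active", "inactive"],
           kpp + partition["inactive", "active"],
           kpp + partition["active", "inactive"] +
             partition["inactive", "active"] +
             partition["inactive", "inactive"])
  out <- ifelse(den > 0, kpp / den, NA_real_)
  source <- ifelse(den > 0, "joint", "undefined")
  if (!is.null(fallback)) {
    stopifnot(fallback >= 0, fallback <= 1)
    miss <- is.na(out)
    out[miss] <- fallback
    source[miss] <- "fallback"
  }
  names(out) <- c("p_act_null", "p_null_act", "p_null_null")
  attr(out, "source") <- source
  out
}

#' Probability-weighted joint upper bound
#'
#' The expectation-value upper bound for a ligand pair: the doubly known
#' active count plus each null-involving cell weighted by its probability of
#' being jointly active.
#'
#' @param partition An [joint_partition()].
#' @param probs The three probabilities as returned by
#'   [joint_prob_estimates()].
#' @return A real number in `[joint_polypharm_min, joint_polypharm_max]`.
#' @export
joint_polypharm_max_estimated <- function(partition, probs) {
  stopifnot(inherits(partition, "lt_joint_partition"), length(probs) == 3)
  cells <- c(partition["active", "null"], partition["null", "active"],
             partition["null", "null"])
  used <- probs
  used[cells == 0] <- 0  # empty cells contribute nothing; prob irrelevant
  if (anyNA(used)) {
    stop("undefined probability for a non-empty null cell; ",
         "supply a fallback to joint_prob_estimates()")
  }
  as.numeric(partition["active", "active"] + sum(used * cells))
}

#' Monte Carlo confidence interval for the joint upper bound
#'
#' Propagates Jeffreys Beta posteriors of the underlying probability
#' estimates through the joint upper-bound expression: each probability is
#' drawn from Beta(k + 1/2, n - k + 1/2) with the success/trial counts of its
#' estimator (joint mode) or of the two marginal rates (independence mode),
#' the estimate is evaluated per draw, and the central empirical quantiles
#' are reported. Deterministic given `seed`. When no null-involving cell is
#' populated the interval collapses to the point `|S++|`.
#'
#' @param partition An [joint_partition()].
#' @param mode `"joint"` or `"independence"`.
#' @param alpha Significance level; default 0.05.
#' @param n_draws Number of Monte Carlo draws (>= 1000).
#' @param seed Integer seed (required).
#' @param marginals Independence mode only: list
#'   `list(a = c(k =, n =), b = c(k =, n =))` of the marginal success/trial
#'   counts of the two ligands' urn-model rates.
#' @param fallback Optional fixed probability for joint-mode cells whose
#'   estimator has no data (zero denominator with a populated cell).
#' @return Numeric `c(low, high)`.
#' @export
joint_ci <- function(partition, mode = c("joint", "independence"),
                     alpha = 0.05, n_draws = 2000, seed,
                     marginals = NULL, fallback = NULL) {
  stopifnot(inherits(partition, "lt_joint_partition"))
  mode <- match.arg(mode)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  if (missing(seed)) stop("a seed is required for reproducible intervals")

  cells <- c(partition["active", "null"], partition["null", "active"],
             partition["null", "null"])
  kpp <- as.numeric(partition["active", "active"])
  if (all(cells == 0)) return(c(low = kpp, high = kpp))

  draw <- .with_preserved_seed(seed, {
    if (mode == "joint") {
      kn <- rbind(
        c(kpp, kpp + partition["active", "inactive"]),
        c(kpp, kpp + partition["inactive", "active"]),
        c(kpp, kpp + partition["active", "inactive"] +
            partition["inactive", "active"] +
            partition["inactive", "inactive"]))
      p <- matrix(0, n_draws, 3)
      for (j in 1:3) {
        if (cells[j] == 0) next
        if (kn[j, 2] > 0) {
          p[, j] <- stats::rbeta(n_draws, kn[j, 1] + 0.5,
                                 kn[j, 2] - kn[j, 1] + 0.5)
        } else if (!is.null(fallback)) {
          p[, j] <- fallback
        } else {
          stop("no data for a populated null cell's probability; ",
               "supply a fallback")
        }
      }
      p
    } else {
      if (is.null(marginals)) {
        stop("independence mode needs 'marginals' (k, n for both ligands)")
      }
      draw_rate <- function(kn) {
        if (kn[["n"]] > 0) {
          stats::rbeta(n_draws, kn[["k"]] + 0.5, kn[["n"]] - kn[["k"]] + 0.5)
        } else if (!is.null(fallback)) {
          rep(fallback, n_draws)
        } else {
          stop("no marginal data for a ligand; supply a fallback")
        }
      }
      pa <- draw_rate(marginals$a)
      pb <- draw_rate(marginals$b)
      cbind(pb, pa, pa * pb)
    }
  })
  vals <- kpp + draw %*% cells
  q <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Enumerate unordered ligand pairs
#'
#' All `n * (n - 1) / 2` unordered pairs in reference order, or — with
#' `ligand` given — that ligand against each of the other `n - 1` ligands.
#'
#' @param rel An [lt_relation()] (or a character vector of ligand ids).
#' @param ligand Optional single ligand selector.
#' @return Two-column character matrix (`id1`, `id2`).
#' @export
ligand_pairs <- function(rel, ligand = NULL) {
  ids <- if (inherits(rel, "lt_relation")) rownames(rel) else as.character(rel)
  n <- length(ids)
  if (!is.null(ligand)) {
    i <- match(ligand, ids)
    if (is.na(i)) stop("unknown ligand id: ", sQuote(ligand), call. = FALSE)
    other <- ids[-i]
    return(cbind(id1 = rep(ids[i], n - 1L), id2 = other))
  }
  if (n < 2) return(cbind(id1 = character(), id2 = character()))
  idx <- utils::combn(n, 2L)
  cbind(id1 = ids[idx[1L, ]], id2 = ids[idx[2L, ]])
}

#' Per-pair joint polypharmacology report
#'
#' Computes, for every unordered ligand pair (or one ligand against all
#' others), the nine joint-partition counts, the bounds
#' `[Pmin(l,l'), Pmax(l,l')]`, and both probability-weighted upper-bound
#' estimates: the joint-mode estimate from doubly measured targets and the
#' independence-mode estimate from the marginal urn-model rates. Monte Carlo
#' confidence intervals (see [joint_ci()]) are optional because their cost
#' scales with `pairs * n_draws`.
#'
#' @param rel An [lt_relation()].
#' @param ligand Optional selector: report this ligand against all others
#'   instead of all pairs.
#' @param mode `"independence"` (default) or `"joint"` — which estimate the
#'   confidence interval, if requested, is propagated for.
#' @param alpha Significance level; default 0.05.
#' @param ci Logical; compute Monte Carlo confidence intervals (default
#'   `FALSE`).
#' @param n_draws,seed Monte Carlo controls, used when `ci = TRUE`.
#' @param fallback As in [polypharm()]: `"global"` substitutes the
#'   dataset-wide known-active fraction for undefined probabilities,
#'   `"strict"` leaves them `NA`.
#' @return A data frame of class `lt_joint_polypharm`, one row per pair:
#'   ids, the nine cell counts (`n_pp`, `n_pi`, `n_p0`, `n_ip`, `n_ii`,
#'   `n_i0`, `n_0p`, `n_0i`, `n_00`), `p_min`, `p_tilde_max_joint`,
#'   `p_tilde_max_indep`, `ci_low`, `ci_high`, `p_max`, `delta_e_max`,
#'   `delta_e_tilde`.
#' @export
#' @examples
#' joint_polypharm(toy_example_relation())
joint_polypharm <- function(rel, ligand = NULL,
                            mode = c("independence", "joint"),
                            alpha = 0.05, ci = FALSE, n_draws = 2000,
                            seed = 1L, fallback = c("global", "strict")) {
  stopifnot(inherits(rel, "lt_relation"))
  mode <- match.arg(mode)
  fallback <- match.arg(fallback)
  pairs <- ligand_pairs(rel, ligand)
  codes <- unclass(rel)
  A <- (codes == 1L) + 0
  I <- (codes == 2L) + 0
  N <- (codes == 3L) + 0
  i1 <- match(pairs[, 1L], rownames(codes))
  i2 <- match(pairs[, 2L], rownames(codes))
  cross <- function(X, Y) {
    M <- tcrossprod(X, Y)          # M[l, l'] = #targets with X(l) & Y(l')
    M[cbind(i1, i2)]
  }
  n_pp <- cross(A, A); n_pi <- cross(A, I); n_p0 <- cross(A, N)
  n_ip <- cross(I, A); n_ii <- cross(I, I); n_i0 <- cross(I, N)
  n_0p <- cross(N, A); n_0i <- cross(N, I); n_00 <- cross(N, N)

  p_min <- n_pp
  p_max <- n_pp + n_p0 + n_0p + n_00

  k <- rowSums(A); nk <- k + rowSums(I)
  global_rate <- if (sum(nk) > 0) sum(k) / sum(nk) else NA_real_
  fb <- if (fallback == "global") global_rate else NA_real_

  # joint-mode probabilities, vectorized across pairs
  den1 <- n_pp + n_pi
  den2 <- n_pp + n_ip
  den3 <- n_pp + n_pi + n_ip + n_ii
  pr1 <- ifelse(den1 > 0, n_pp / den1, fb)
  pr2 <- ifelse(den2 > 0, n_pp / den2, fb)
  pr3 <- ifelse(den3 > 0, n_pp / den3, fb)
  term <- function(pr, cell) ifelse(cell == 0, 0, pr * cell)
  p_tilde_joint <- n_pp + term(pr1, n_p0) + term(pr2, n_0p) + term(pr3, n_00)

  # independence-mode probabilities from the marginal rates
  ph <- ifelse(nk > 0, k / nk, fb)
  ph1 <- ph[i1]; ph2 <- ph[i2]
  p_tilde_indep <- n_pp + term(ph2, n_p0) + term(ph1, n_0p) +
    term(ph1 * ph2, n_00)

  ci_low <- ci_high <- rep(NA_real_, nrow(pairs))
  if (ci) {
    for (r in seq_len(nrow(pairs))) {
      part <- matrix(c(n_pp[r], n_pi[r], n_p0[r],
                       n_ip[r], n_ii[r], n_i0[r],
                       n_0p[r], n_0i[r], n_00[r]),
                     3, 3, byrow = TRUE,
                     dimnames = list(lt_states(), lt_states()))
      part <- structure(as.integer(part), dim = c(3L, 3L),
                        dimnames = list(lt_states(), lt_states()),
                        class = "lt_joint_partition",
                        pair = pairs[r, ])
      interval <- joint_ci(
        part, mode = mode, alpha = alpha, n_draws = n_draws,
        seed = seed + r,
        marginals = list(a = c(k = k[[i1[r]]], n = nk[[i1[r]]]),
                         b = c(k = k[[i2[r]]], n = nk[[i2[r]]])),
        fallback = if (fallback == "global" && !is.na(fb)) fb else NULL)
      ci_low[r] <- interval[["low"]]
      ci_high[r] <- interval[["high"]]
    }
  }

  out <- data.frame(
    id1 = pairs[, 1L], id2 = pairs[, 2L],
    n_pp = as.integer(n_pp), n_pi = as.integer(n_pi),
    n_p0 = as.integer(n_p0), n_ip = as.integer(n_ip),
    n_ii = as.integer(n_ii), n_i0 = as.integer(n_i0),
    n_0p = as.integer(n_0p), n_0i = as.integer(n_0i),
    n_00 = as.integer(n_00),
    p_min = as.integer(p_min),
    p_tilde_max_joint = p_tilde_joint,
    p_tilde_max_indep = p_tilde_indep,
    ci_low = ci_low, ci_high = ci_high,
    p_max = as.integer(p_max),
    delta_e_max = as.integer(p_max - p_min),
    delta_e_tilde = (if (mode == "joint") p_tilde_joint else p_tilde_indep) -
      p_min,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "mode") <- mode
  class(out) <- c("lt_joint_polypharm", "data.frame")
  out
}

#' @export
print.lt_joint_polypharm <- function(x, ...) {
  cat("Joint polypharmacology estimates for ", nrow(x), " ligand pair",
      if (nrow(x) != 1) "s", " (mode = ", attr(x, "mode"),
      ", alpha = ", attr(x, "alpha"), ")\n", sep = "")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' @export
summary.lt_joint_polypharm <- function(object, ...) {
  cat("Joint polypharmacology over ", nrow(object), " pairs (mode = ",
      attr(object, "mode"), ")\n", sep = "")
  cat("  Pmin:  median ", stats::median(object$p_min),
      ", max ", max(object$p_min), "\n", sep = "")
  cat("  P~max (joint): median ",
      formatC(stats::median(object$p_tilde_max_joint), digits = 2,
              format = "f"), "\n", sep = "")
  cat("  P~max (indep): median ",
      formatC(stats::median(object$p_tilde_max_indep), digits = 2,
              format = "f"), "\n", sep = "")
  cat("  Pmax:  median ", stats::median(object$p_max), "\n", sep = "")
  invisible(object)
}

# run code under a temporary RNG state; restores the caller's state
.with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
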