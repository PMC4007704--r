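# Lower-middle median: for an even number of values, take the lower of the
# two middle order statistics (keeps medians integral on count data).
median_low <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Pan- and core-genome accumulation curves
#'
#' For each genome ordering and each prefix length N, counts the families
#' with at least one copy in the prefix (pan) and the families present in
#' every prefix genome (core); new(N) = pan(N) - pan(N-1). Orderings are
#' exhaustive (all G! permutations) when G does not exceed
#' \code{exhaustive_max}, otherwise \code{n_permutations} seeded uniform
#' random orderings are drawn. Per-N summaries are lower-middle medians
#' over orderings.
#'
#' @param m copy-count matrix (families x genomes), e.g. from
#'   [presence_matrix()]. Presence = copy count >= 1; paralogues do not
#'   inflate the counts.
#' @param n_permutations number of random orderings when not exhaustive.
#' @param exhaustive_max largest G for which all G! orderings are used.
#' @param seed integer seed for the random orderings.
#' @return object of class \code{pangenome_curve}: per-permutation
#'   \code{pan}, \code{core}, \code{new} matrices (orderings x N) and
#'   \code{median_pan}, \code{median_core}, \code{median_new} vectors.
#' @export
accumulation_curves <- function(m, n_permutations = 1000, exhaustive_max = 8,
                                seed = 1) {
  G <- ncol(m)
  if (G < 2) stop("need at least 2 genomes for accumulation curves")
  if (any(rowSums(m) == 0)) stop("presence matrix has an all-zero family row")
  pres <- m >= 1
  exhaustive <- G <= exhaustive_max
  if (exhaustive) {
    orderings <- all_permutations(G)
  } else {
    set.seed(as.integer(seed))
    orderings <- t(vapply(seq_len(n_permutations), function(i) sample.int(G),
                          integer(G)))
  }
  P <- nrow(orderings)
  pan <- core <- matrix(0L, P, G)
  for (p in seq_len(P)) {
    ord <- orderings[p, ]
    any_in <- pres[, ord[1]]
    all_in <- pres[, ord[1]]
    pan[p, 1] <- sum(any_in)
    core[p, 1] <- sum(all_in)
    for (k in 2:G) {
      col <- pres[, ord[k]]
      any_in <- any_in | col
      all_in <- all_in & col
      pan[p, k] <- sum(any_in)
      core[p, k] <- sum(all_in)
    }
  }
  newg <- cbind(NA_integer_, t(apply(pan, 1, diff)))
  structure(list(
    n_genomes = G,
    pan = pan, core = core, new = newg,
    median_pan = apply(pan, 2, median_low),
    median_core = apply(core, 2, median_low),
    median_new = c(NA_real_, apply(newg[, -1, drop = FALSE], 2, median_low)),
    n_permutations = P, exhaustive = exhaustive, seed = seed
  ), class = "pangenome_curve")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Fit Heaps'-law and decay models to accumulation curves
#'
#' The new-gene curve is fit as \code{new(N) = kappa_new * N^-alpha} by
#' least squares in log-log space over N = 2..G (zero medians skipped); the
#' pan curve as \code{pan(N) = kappa_pan * N^gamma} the same way; the core
#' curve as \code{core(N) = A * exp(-(N-1)/tau) + omega} by nonlinear least
#' squares. Following the standard Heaps'-law criterion the pan-genome is
#' called closed iff \code{alpha > 1}.
#'
#' @param curve a [accumulation_curves()] result.
#' @return object of class \code{heaps_fit} with elements \code{kappa_new},
#'   \code{alpha}, \code{kappa_pan}, \code{gamma}, \code{core_A},
#'   \code{core_tau}, \code{core_omega}, \code{openness_call}.
#' @export
fit_models <- function(curve) {
  G <- curve$n_genomes
  if (G < 4) stop("need at least 4 genomes to fit accumulation models")
  N <- 2:G
  y <- curve$median_new[N]
  keep <- !is.na(y) & y > 0
  if (!any(keep)) stop("all new-gene medians are zero; degenerate panel")
  fit_new <- stats::lm(log(y[keep]) ~ log(N[keep]))
  alpha <- -unname(stats::coef(fit_new)[2])
  kappa_new <- exp(unname(stats::coef(fit_new)[1]))

  Np <- seq_len(G)
  fit_pan <- stats::lm(log(curve$median_pan) ~ log(Np))
  gamma <- unname(stats::coef(fit_pan)[2])
  kappa_pan <- exp(unname(stats::coef(fit_pan)[1]))

  core <- curve$median_core
  omega0 <- core[G]
  A0 <- max(core[1] - omega0, 1e-6)
  core_fit <- tryCatch(
    minpack.lm::nlsLM(core ~ A * exp(-(Np - 1) / tau) + omega,
                      start = list(A = A0, tau = 2, omega = omega0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(core_fit)) {
    warning("core exponential-decay fit did not converge; ",
            "reporting initial estimates")
    core_pars <- c(A = A0, tau = 2, omega = omega0)
  } else {
    core_pars <- stats::coef(core_fit)
  }
  structure(list(
    kappa_new = kappa_new, alpha = alpha,
    kappa_pan = kappa_pan, gamma = gamma,
    core_A = unname(core_pars["A"]), core_tau = unname(core_pars["tau"]),
    core_omega = unname(core_pars["omega"]),
    openness_call = if (alpha > 1) "closed" else "open"
  ), class = "heaps_fit")
}

#' Report on the accumulation curves and model fits
#'
#' @param curve a [accumulation_curves()] result.
#' @param fit a [fit_models()] result.
#' @param k number of leading iterations over which the average new-gene
#'   rate is computed (adding genomes 2..k+1).
#' @return list with final pan/core sizes, per-N medians, rendered fitted
#'   functions, the open/closed call, and the average new-gene rate.
#' @export
curve_report <- function(curve, fit, k = 9) {
  G <- curve$n_genomes
  upto <- min(k + 1, G)
  rate <- mean(curve$median_new[2:upto])
  list(
    pan_final = curve$median_pan[G],
    core_final = curve$median_core[G],
    n_genomes = G,
    median_pan = curve$median_pan,
    median_core = curve$median_core,
    median_new = curve$median_new,
    new_fn = sprintf("new(N) = %.4g * N^-%.4g", fit$kappa_new, fit$alpha),
    pan_fn = sprintf("pan(N) = %.4g * N^%.4g", fit$kappa_pan, fit$gamma),
    core_fn = sprintf("core(N) = %.4g * exp(-(N-1)/%.4g) + %.4g",
                      fit$core_A, fit$core_tau, fit$core_omega),
    openness_call = fit$openness_call,
    avg_new_rate_first_k = rate,
    k = upto - 1,
    n_permutations = curve$n_permutations,
    exhaustive = curve$exhaustive
  )
}
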