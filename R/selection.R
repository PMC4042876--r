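#' Two-component Gaussian mixture threshold
#'
#' Fits a two-component Gaussian mixture to a vector of per-gene (or
#' per-region) mean signal values by EM and derives the significance
#' threshold as the mean of the upper component: the lower component absorbs
#' background, the upper one genuinely bound regions, and a region is called
#' significantly bound when its mean reaches the centre of the bound
#' component.
#'
#' The fit is fully deterministic: components are initialised at the 25th
#' and 75th percentiles with equal weights and standard deviations at half
#' the overall SD, EM iterates to a log-likelihood tolerance of 1e-8
#' (at most 500 iterations).
#'
#' A fit is flagged degenerate when the data do not support two components:
#' either the standardised separation `(mu2 - mu1) / sqrt(pi1 s1^2 + pi2
#' s2^2)` falls below `min_separation`, or the fitted mixture density has no
#' dip between the two component means (i.e. is unimodal, in which case the
#' "upper component mean" is not a meaningful cutoff).
#'
#' @param values Numeric vector of mean signal values (n >= 50, finite).
#' @param min_separation Minimum standardised separation between component
#'   means for a usable threshold. Default 2.
#' @param log_space Fit on `log1p(values)` instead of raw values; the
#'   returned threshold is mapped back to the raw scale.
#' @return A `mixture_fit` list: `mu` (sorted ascending), `sigma`, `lambda`
#'   (weights), `tau` (threshold, `= mu[2]`), `loglik`, `iterations`,
#'   `converged`, `degenerate`, `separation`.
#' @export
fit_two_gaussian_threshold <- function(values, min_separation = 2,
                                       log_space = FALSE) {
  if (length(values) < 50L) stop("need at least 50 values for a mixture fit")
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite values")
  x <- if (log_space) log1p(values) else as.numeric(values)

  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  mu <- c(q[1], q[2])
  s_all <- stats::sd(x)
  sd_floor <- max(s_all, 1e-12) * 1e-4
  sigma <- rep(max(s_all / 2, sd_floor), 2)
  lambda <- c(0.5, 0.5)

  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(500L)) {
    d1 <- lambda[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- lambda[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(loglik) && abs(ll - loglik) < 1e-8) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-10 || n2 < 1e-10) break  # weight collapse
    lambda <- c(n1, n2) / length(x)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sigma <- c(sqrt(sum(r1 * (x - mu[1])^2) / n1),
               sqrt(sum(r2 * (x - mu[2])^2) / n2))
    sigma <- pmax(sigma, sd_floor)
  }

  if (mu[1] > mu[2]) {
    mu <- rev(mu); sigma <- rev(sigma); lambda <- rev(lambda)
  }
  pooled <- sqrt(lambda[1] * sigma[1]^2 + lambda[2] * sigma[2]^2)
  separation <- if (pooled > 0) (mu[2] - mu[1]) / pooled else 0

  degenerate <- separation < min_separation ||
    !mixture_has_dip(mu, sigma, lambda)

  tau <- mu[2]
  if (log_space) tau <- expm1(tau)

  structure(list(mu = mu, sigma = sigma, lambda = lambda, tau = tau,
                 loglik = loglik, iterations = iter, converged = converged,
                 degenerate = degenerate, separation = separation,
                 log_space = log_space),
            class = "mixture_fit")
}

# A two-component threshold is only meaningful if the fitted density is
# bimodal: check for a local minimum strictly between the component means.
mixture_has_dip <- function(mu, sigma, lambda) {
  if (mu[2] - mu[1] <= 0) return(FALSE)
  grid <- seq(mu[1], mu[2], length.out = 512L)
  dens <- lambda[1] * stats::dnorm(grid, mu[1], sigma[1]) +
    lambda[2] * stats::dnorm(grid, mu[2], sigma[2])
  min(dens[-c(1L, 512L)]) < min(dens[1L], dens[512L])
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("two-Gaussian mixture fit: mu = (%.4g, %.4g), ",
                     "sigma = (%.4g, %.4g), weights = (%.3f, %.3f)\n"),
              x$mu[1], x$mu[2], x$sigma[1], x$sigma[2],
              x$lambda[1], x$lambda[2]))
  cat(sprintf("threshold tau = %.4g (separation %.2f SD%s)\n", x$tau,
              x$separation, if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Select significantly bound regions above the mixture threshold
#'
#' @param values Numeric vector the fit was computed on (raw scale).
#' @param fit A `mixture_fit` from [fit_two_gaussian_threshold()], or `NULL`
#'   when `override` is given.
#' @param override Optional explicit threshold replacing the fitted one
#'   (e.g. 0 for a deliberately relaxed selection). Required when the fit is
#'   degenerate.
#' @return Logical mask, `TRUE` where `value >= tau`.
#' @export
select_significant <- function(values, fit = NULL, override = NULL) {
  if (!is.null(override)) {
    tau <- override
  } else {
    if (is.null(fit)) stop("either a fit or an override threshold is required")
    if (fit$degenerate) {
      stop("mixture fit is degenerate; supply an override threshold")
    }
    tau <- fit$tau
  }
  values >= tau
}

#' One-sided interquartile-range outlier filter
#'
#' Keeps a value iff it does not exceed `Q3 + 1.5 * (Q3 - Q1)` (quartiles by
#' linear interpolation, type 7). The rule is upper-sided only: low values
#' are never outliers. This is the outlier definition used before every
#' boxplot-style statistic in the pipeline.
#'
#' @param values Numeric vector, n >= 4.
#' @return Logical keep-mask.
#' @export
iqr_outlier_filter <- function(values) {
  if (length(values) < 4L) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  values <= q[2] + 1.5 * (q[2] - q[1])
}

#' Gene filtering for profile and statistics analyses
#'
#' Applies the pipeline's standing gene filters and reports per-rule counts:
#' \enumerate{
#'   \item proximity: any two gene intervals closer than `min_gap` bp
#'     (including overlapping ones) remove \emph{both} genes;
#'   \item length: only genes strictly longer than `min_length` bp are kept;
#'   \item category: genes in `excluded_categories` are removed;
#'   \item short-ssRNA outliers: genes whose ssRNA mean fails
#'     [iqr_outlier_filter()] are removed (skipped when `ssrna_means` is
#'     `NULL`).
#' }
#' Each rule is evaluated on the full input set, so rule outcomes commute;
#' the retained set is the intersection of the four keep-masks.
#'
#' @param genes Gene table ([read_annotation()]).
#' @param ssrna_means Optional numeric vector aligned with `genes` (short
#'   ssRNA mean at TSS +/- 500, sense plus antisense).
#' @param min_gap Minimum distance between gene intervals (default 2000 bp).
#' @param min_length Minimum gene length, exclusive (default 2000 bp).
#' @param excluded_categories Categories removed outright.
#' @return List with `retained` (gene table subset), `keep` (logical mask on
#'   the input) and `counts` (per-rule removal counts plus totals).
#' @export
filter_genes <- function(genes, ssrna_means = NULL, min_gap = 2000,
                         min_length = 2000,
                         excluded_categories = c("histone", "rRNA", "snomiRNA",
                                                 "snoRNA", "snRNA", "tRNA")) {
  n <- nrow(genes)
  near <- rep(FALSE, n)
  for (chrom in unique(genes$chrom)) {
    idx <- which(genes$chrom == chrom)
    ord <- idx[order(genes$start[idx])]
    for (a in seq_along(ord)) {
      i <- ord[a]
      b <- a + 1L
      while (b <= length(ord)) {
        j <- ord[b]
        if (genes$start[j] >= genes$end[i] + min_gap) break
        gap <- max(genes$start[j] - genes$end[i], 0)
        if (gap < min_gap) near[c(i, j)] <- TRUE
        b <- b + 1L
      }
    }
  }
  short <- (genes$end - genes$start) <= min_length
  bad_cat <- genes$category %in% excluded_categories
  ssrna_out <- rep(FALSE, n)
  if (!is.null(ssrna_means)) {
    stopifnot(length(ssrna_means) == n)
    ssrna_out <- !iqr_outlier_filter(ssrna_means)
  }
  keep <- !(near | short | bad_cat | ssrna_out)
  list(retained = genes[keep, , drop = FALSE],
       keep = keep,
       counts = list(input = n,
                     proximity = sum(near),
                     length = sum(short),
                     category = sum(bad_cat),
                     ssrna_outlier = sum(ssrna_out),
                     removed = sum(!keep),
                     retained = sum(keep)))
}
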