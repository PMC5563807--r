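# run code with a locally-seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a per-stream seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; each context
#' (or simulated assemblage) gets its own deterministic stream, so adding a
#' context never perturbs the deviates of the others.
#'
#' @param master integer master seed.
#' @param index 1-based stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  # multiplier chosen coprime to 2^31 - 1; avoids collisions for small inputs
  as.integer((abs(master) + 1 + 999983 * index) %% 2147483646 + 1)
}

#' Dirichlet deviates for a vector of (fractional) counts
#'
#' Draws `nsim` proportion vectors from the posterior
#' Dirichlet(n_1 + alpha0, ..., n_K + alpha0) given observed class counts
#' `n` and a symmetric prior concentration `alpha0` per class. Counts may be
#' fractional (they are, after proportional tooth splitting). Sampling uses
#' the standard Gamma construction: independent Gamma(shape = n_k + alpha0)
#' draws normalized to sum to 1.
#'
#' @param n nonnegative numeric vector of class counts.
#' @param alpha0 prior concentration added to each class (default 0.5).
#' @param nsim number of deviates (default 2000).
#' @param seed optional integer seed; with a seed the result is reproducible
#'   and global RNG state is left untouched.
#' @return An `nsim` x `length(n)` matrix; every row sums to 1.
#' @export
dirichlet_deviates <- function(n, alpha0 = 0.5, nsim = 2000, seed = NULL) {
  stopifnot(is.numeric(n), length(n) >= 2L)
  if (any(n < 0)) stop("counts must be nonnegative")
  if (alpha0 < 0) stop("alpha0 must be nonnegative")
  if (nsim < 1) stop("nsim must be >= 1")
  shape <- n + alpha0
  if (all(shape == 0))
    stop("all-zero counts with alpha0 = 0: Dirichlet undefined")
  k <- length(n)
  g <- .with_seed(seed,
    matrix(stats::rgamma(nsim * k, shape = rep(shape, each = nsim)),
           nrow = nsim, ncol = k))
  out <- g / rowSums(g)
  colnames(out) <- names(n)
  out
}

#' Equal-tailed credible interval from deviates
#'
#' Empirical quantiles at (1 - level)/2 and (1 + level)/2 per class.
#'
#' @param deviates matrix of proportion vectors (rows = draws).
#' @param level credible level in (0, 1); default 0.95.
#' @return A `K` x 2 matrix with columns `low`, `high`.
#' @export
credible_interval <- function(deviates, level = 0.95) {
  stopifnot(is.matrix(deviates), nrow(deviates) >= 1L)
  # level = 0 is allowed as the degenerate limit (both bounds at the median)
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level >= 1)
    stop("level must lie in [0, 1)")
  probs <- c((1 - level) / 2, (1 + level) / 2)
  out <- t(apply(deviates, 2L, stats::quantile, probs = probs, names = FALSE))
  colnames(out) <- c("low", "high")
  out
}

#' Mortality profiles with Dirichlet credible intervals
#'
#' For each context, the observed proportions p_k = n_k / N together with
#' equal-tailed credible bounds computed from `nsim` Dirichlet deviates
#' (prior concentration `alpha0` per class). Each context uses its own
#' seed stream derived from `seed` (see [derive_seed()]).
#'
#' @param tab a `count_table` from [build_count_table()].
#' @inheritParams dirichlet_deviates
#' @param level credible level (default 0.95, equal-tailed).
#' @param seed master integer seed.
#' @return A list of `mortality_profile` objects (one per context), each a
#'   list with `context_id`, `proportions`, `ci_low`, `ci_high`, `N`,
#'   `nsim`, `alpha0`, `level`. The list carries class
#'   `mortality_profiles`.
#' @export
mortality_profiles <- function(tab, alpha0 = 0.5, nsim = 2000, level = 0.95,
                               seed = 1L) {
  stopifnot(inherits(tab, "count_table"))
  n_teeth <- attr(tab, "N")
  empty <- which(rowSums(tab) <= 0)
  if (length(empty)) {
    warning("excluding context(s) with zero teeth: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[-empty, , drop = FALSE]
    n_teeth <- n_teeth[-empty]
  }
  if (!nrow(tab)) stop("no non-empty contexts")
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    n <- tab[i, ]
    dev <- dirichlet_deviates(n, alpha0, nsim, seed = derive_seed(seed, i))
    ci <- credible_interval(dev, level)
    out[[i]] <- structure(list(
      context_id = rownames(tab)[i],
      proportions = n / sum(n),
      ci_low = stats::setNames(ci[, "low"], colnames(tab)),
      ci_high = stats::setNames(ci[, "high"], colnames(tab)),
      N = unname(n_teeth[i]), nsim = nsim, alpha0 = alpha0, level = level
    ), class = "mortality_profile")
  }
  structure(out, class = "mortality_profiles")
}

#' @export
print.mortality_profile <- function(x, ...) {
  cat(sprintf("Mortality profile '%s' (N = %d teeth, %d deviates, prior %.2g)\n",
              x$context_id, x$N, x$nsim, x$alpha0))
  print(round(rbind(`%` = 100 * x$proportions,
                    lo = 100 * x$ci_low, hi = 100 * x$ci_high), 1))
  invisible(x)
}

#' Tabulate mortality profiles for plotting or export
#'
#' One row per (context, class): percentage of teeth with credible-interval
#' whiskers, plus the context's tooth count for panel annotation. Feeds the
#' per-context barplot panels.
#'
#' @param profiles a `mortality_profiles` list.
#' @return data.frame with columns `context_id`, `class`, `pct`,
#'   `ci_low_pct`, `ci_high_pct`, `N`.
#' @export
profile_report <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(context_id = p$context_id,
               class = factor(names(p$proportions),
                              levels = names(p$proportions)),
               pct = 100 * as.numeric(p$proportions),
               ci_low_pct = 100 * as.numeric(p$ci_low),
               ci_high_pct = 100 * as.numeric(p$ci_high),
               N = p$N, row.names = NULL)
  }))
}

#' Barplot panels of mortality profiles
#'
#' One panel per context: percentage of teeth per age class with credible
#' interval whiskers, N annotated in the panel strip.
#'
#' @param profiles a `mortality_profiles` list.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  df <- profile_report(profiles)
  df$panel <- sprintf("%s (N = %d)", df$context_id, df$N)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low_pct,
                                        ymax = .data$ci_high_pct),
                           width = 0.25, linewidth = 0.3) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "age class", y = "% of teeth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
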