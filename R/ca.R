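#' Correspondence analysis from first principles
#'
#' Given a nonnegative table X (here: stacked Dirichlet deviates, rows
#' summing to 1), CA decomposes the standardized residual matrix
#' \deqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}}
#' by SVD, where P = X / sum(X), r and c are the row and column masses and
#' D_r, D_c the corresponding diagonal matrices. Principal inertias are the
#' squared singular values; their sum is the table's mean-square contingency
#' (phi squared). Row and column principal coordinates are
#' F = D_r^{-1/2} U diag(sigma) and G = D_c^{-1/2} V diag(sigma); standard
#' column coordinates are G / sigma. A column's contribution to axis a is
#' Ctr_ka = 1000 c_k G_ka^2 / lambda_a (per mille).
#'
#' Supplementary profiles are projected into the solution (see
#' [project_supplementary()]) and never contribute to the inertia.
#'
#' Per-axis sign is arbitrary; `orient_anchors` fixes it by flipping each
#' listed axis so the anchored column's coordinate is nonnegative. For the
#' 7-class cattle scheme the reporting convention anchors F1 on the oldest
#' class (>8 years) and F2 on 3--6 years (see [default_orientation()]).
#'
#' @param x nonnegative numeric matrix (active rows). Columns with zero
#'   total are dropped with a warning; rows with zero total are an error.
#' @param supplementary optional named list (or matrix with rownames) of
#'   proportion vectors over the same columns, projected as supplementary
#'   points.
#' @param orient_anchors optional integer vector: for each axis `a` with
#'   `orient_anchors[a] > 0`, flip the axis so column `orient_anchors[a]`
#'   has nonnegative coordinate. `0` leaves an axis untouched.
#' @param keep_row_coords keep the (potentially large) row principal
#'   coordinate matrix in the result (default TRUE).
#' @return An object of class `ca_result`: list with `row_mass`, `col_mass`,
#'   `sv` (singular values), `inertia` (lambda per axis), `total_inertia`,
#'   `pct_inertia`, `row_coords` (I x A), `col_coords` (K x A),
#'   `col_contrib` (K x A, per mille), `std_col_coords` (K x A),
#'   `sup_coords` (named matrix or NULL), `n_axes`, `dropped_cols`.
#' @export
correspondence_analysis <- function(x, supplementary = NULL,
                                    orient_anchors = NULL,
                                    keep_row_coords = TRUE) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("active table must be nonnegative")
  total <- sum(x)
  if (!(total > 0)) stop("active table has zero grand total")
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))

  dropped <- which(colSums(x) == 0)
  if (length(dropped)) {
    warning("dropping zero-mass column(s): ",
            paste(colnames(x)[dropped], collapse = ", "))
    x <- x[, -dropped, drop = FALSE]
  }
  if (any(rowSums(x) == 0)) stop("active table has zero-mass row(s)")

  p <- x / total
  r <- rowSums(p)
  cm <- colSums(p)
  s <- (p - outer(r, cm)) / sqrt(outer(r, cm))
  sv <- svd(s, nu = min(dim(s)), nv = ncol(s))

  n_axes <- min(nrow(x) - 1L, ncol(x) - 1L)
  tol <- 1e-12
  keep <- which(sv$d[seq_len(n_axes)] > tol * max(sv$d[1L], 1))
  n_axes <- length(keep)
  axis_names <- if (n_axes) paste0("F", seq_len(n_axes)) else character(0)

  sigma <- sv$d[keep]
  lambda <- sigma^2
  total_inertia <- sum(s^2)

  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  f <- sweep(u, 2L, sigma, `*`) / sqrt(r)
  g <- sweep(v, 2L, sigma, `*`) / sqrt(cm)
  gamma <- v / sqrt(cm)                      # standard column coordinates

  if (!is.null(orient_anchors) && n_axes) {
    for (a in seq_len(min(n_axes, length(orient_anchors)))) {
      k <- orient_anchors[a]
      if (k > 0 && k <= nrow(g) && g[k, a] < 0) {
        f[, a] <- -f[, a]; g[, a] <- -g[, a]; gamma[, a] <- -gamma[, a]
      }
    }
  }

  ctr <- if (n_axes)
    sweep(sweep(g^2, 1L, cm, `*`), 2L, lambda, `/`) * 1000
  else matrix(0, ncol(x), 0L)

  dimnames(g) <- dimnames(gamma) <- dimnames(ctr) <-
    list(colnames(x), axis_names)
  dimnames(f) <- list(rownames(x), axis_names)
  names(lambda) <- names(sigma) <- axis_names

  res <- structure(list(
    row_mass = r, col_mass = cm, sv = sigma, inertia = lambda,
    total_inertia = total_inertia,
    pct_inertia = if (n_axes) 100 * lambda / total_inertia else numeric(0),
    row_coords = if (keep_row_coords) f else NULL,
    col_coords = g, col_contrib = ctr, std_col_coords = gamma,
    sup_coords = NULL, n_axes = n_axes, dropped_cols = dropped
  ), class = "ca_result")

  if (!is.null(supplementary)) {
    if (is.matrix(supplementary) || is.data.frame(supplementary)) {
      m <- as.matrix(supplementary)
      supplementary <- stats::setNames(
        lapply(seq_len(nrow(m)), function(i) m[i, ]), rownames(m))
    }
    sup <- t(vapply(supplementary, function(pr) project_supplementary(res, pr),
                    numeric(n_axes)))
    dimnames(sup) <- list(names(supplementary), axis_names)
    res$sup_coords <- sup
  }
  res
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("Correspondence analysis: %d axes, total inertia %.4f\n",
              x$n_axes, x$total_inertia))
  if (x$n_axes) {
    show <- seq_len(min(3L, x$n_axes))
    cat("  principal inertias:",
        paste(sprintf("%s = %.4f (%.1f%%)", names(x$inertia)[show],
                      x$inertia[show], x$pct_inertia[show]), collapse = ", "),
        "\n")
  }
  if (!is.null(x$sup_coords))
    cat("  supplementary points:",
        paste(rownames(x$sup_coords), collapse = ", "), "\n")
  invisible(x)
}

#' Default axis-orientation anchors for a scheme
#'
#' Reporting convention for the 7-class cattle scheme: flip F1 so the oldest
#' class (>8 years) has nonnegative coordinate, and F2 so 3--6 years does.
#' Purely presentational; inertias and distances are unaffected.
#'
#' @param scheme an [age_class_scheme()].
#' @return Integer vector of per-axis anchor column indices (0 = no anchor).
#' @export
default_orientation <- function(scheme = legge_classes()) {
  k <- n_classes(scheme)
  anchors <- c(k, if (k == 7L) 5L else 0L)
  anchors
}

#' Stack per-context Dirichlet deviates into a CA input matrix
#'
#' For each context (row of the count table), draws `nsim` Dirichlet
#' deviates from its posterior and stacks them: the active matrix has
#' `nrow(tab) * nsim` rows in context order, each row a proportion vector.
#' Every context uses its own seed stream derived from the master `seed`,
#' so the matrix is byte-identical across runs and adding a context leaves
#' the other blocks unchanged.
#'
#' @param tab a `count_table` from [build_count_table()].
#' @inheritParams dirichlet_deviates
#' @param seed master integer seed.
#' @return Matrix with `nrow(tab) * nsim` rows, rownames
#'   `<context_id>.<sim>`, and attribute `context` (the per-row context id).
#' @export
stack_deviates <- function(tab, alpha0 = 0.5, nsim = 2000, seed = 1L) {
  if (!nrow(tab)) stop("empty context list")
  if (nsim < 1) stop("nsim must be >= 1")
  blocks <- lapply(seq_len(nrow(tab)), function(i)
    dirichlet_deviates(tab[i, ], alpha0, nsim, seed = derive_seed(seed, i)))
  out <- do.call(rbind, blocks)
  ctx <- rep(rownames(tab), each = nsim)
  rownames(out) <- paste(ctx, rep(seq_len(nsim), times = nrow(tab)),
                         sep = ".")
  attr(out, "context") <- ctx
  out
}

#' Project a supplementary profile into a CA solution
#'
#' A supplementary row profile is placed at f_a = sum_k profile_k *
#' gamma_ka, where gamma are the standard column coordinates. Supplementary
#' points never alter the inertias or the active coordinates.
#'
#' @param result a `ca_result`.
#' @param profile numeric proportion vector over the active columns (same
#'   length and, if named, same names).
#' @return Numeric vector of principal-axis coordinates.
#' @export
project_supplementary <- function(result, profile) {
  gamma <- result$std_col_coords
  profile <- .align_profile(profile, rownames(gamma))
  if (abs(sum(profile) - 1) > 1e-6)
    stop("supplementary profile must sum to 1")
  as.numeric(profile %*% gamma)
}

.align_profile <- function(profile, classes) {
  if (!is.null(names(profile))) {
    if (!setequal(names(profile), classes))
      stop("supplementary profile classes do not match the CA columns")
    profile <- profile[classes]
  } else if (length(profile) != length(classes)) {
    stop("supplementary profile has wrong length (", length(profile),
         " vs ", length(classes), " active columns)")
  }
  as.numeric(profile)
}

#' Per-class CA summary table (masses, coordinates, contributions)
#'
#' One row per age class: column mass in per mille of the grand total, then
#' principal coordinate and per-mille contribution on each of the first
#' `axes` axes. Masses and contributions are rounded to integers and
#' coordinates to 3 decimals, matching the conventional presentation.
#'
#' @param result a `ca_result`.
#' @param axes how many leading axes to report (default 3).
#' @param digits_coord decimals for coordinates (default 3).
#' @return data.frame with columns `class`, `mass_permille`, and
#'   `coord_Fa` / `ctr_Fa_permille` per axis.
#' @export
axis_summary <- function(result, axes = 3L, digits_coord = 3L) {
  if (result$n_axes < axes)
    stop("CA result has ", result$n_axes, " axes; ", axes, " requested")
  out <- data.frame(class = rownames(result$col_coords),
                    mass_permille = round(1000 * result$col_mass))
  for (a in seq_len(axes)) {
    out[[sprintf("coord_F%d", a)]] <-
      round(result$col_coords[, a], digits_coord)
    out[[sprintf("ctr_F%d_permille", a)]] <- round(result$col_contrib[, a])
  }
  rownames(out) <- NULL
  out
}

#' Mean deviate profile per context
#'
#' Column means of each context's block of stacked deviates; used to place
#' one summary point per context in the principal plane.
#'
#' @param active the matrix from [stack_deviates()] (needs its `context`
#'   attribute).
#' @return contexts x classes matrix of mean proportions.
#' @export
context_mean_profiles <- function(active) {
  ctx <- attr(active, "context")
  if (is.null(ctx)) stop("active matrix lacks a 'context' attribute")
  m <- rowsum(active, factor(ctx, levels = unique(ctx)))
  m / as.vector(table(factor(ctx, levels = unique(ctx))))
}

#' Nearest-reference classification of contexts in the principal plane
#'
#' Assigns each context (via its mean-profile supplementary coordinates) to
#' the nearest reference husbandry profile by Euclidean distance on the
#' selected axes. Ties go to the first-listed reference with a warning.
#'
#' @param context_coords matrix of context coordinates (rows named by
#'   context).
#' @param reference_coords matrix of reference coordinates (rows named by
#'   reference model).
#' @param axes which axes to use (default 1:2, the principal plane).
#' @return data.frame with `context_id`, `nearest`, and one distance column
#'   per reference.
#' @export
classify_context <- function(context_coords, reference_coords, axes = 1:2) {
  if (max(axes) > ncol(context_coords) || max(axes) > ncol(reference_coords))
    stop("requested axes exceed available coordinates")
  cc <- context_coords[, axes, drop = FALSE]
  rc <- reference_coords[, axes, drop = FALSE]
  d <- sqrt(outer(rowSums(cc^2), rep(1, nrow(rc))) +
            outer(rep(1, nrow(cc)), rowSums(rc^2)) - 2 * cc %*% t(rc))
  d[d < 0] <- 0  # guard tiny negatives from cancellation
  colnames(d) <- rownames(rc)
  nearest <- apply(d, 1L, function(row) {
    hits <- which(row == min(row))
    if (length(hits) > 1L)
      warning("equidistant references; keeping first-listed: ",
              colnames(d)[hits[1L]])
    hits[1L]
  })
  out <- data.frame(context_id = rownames(cc),
                    nearest = rownames(rc)[nearest],
                    stringsAsFactors = FALSE)
  colnames(d) <- paste0("dist_", colnames(d))
  cbind(out, as.data.frame(d, row.names = NULL))
}

#' CA biplot of the principal plane
#'
#' Deviate cloud coloured by context, age-class labels sized by their
#' contribution to the displayed axes, reference profiles as open circles
#' (supplementary points).
#'
#' @param result a `ca_result` (with row coordinates kept).
#' @param axes length-2 integer vector of axes to display.
#' @param context per-row context labels (defaults to the `context`
#'   attribute carried through from [stack_deviates()], if present).
#' @param max_points downsample the cloud to at most this many rows.
#' @return A ggplot object.
#' @export
plot_ca <- function(result, axes = c(1L, 2L), context = NULL,
                    max_points = 5000L) {
  if (is.null(result$row_coords)) stop("row coordinates were not kept")
  f <- result$row_coords[, axes, drop = FALSE]
  if (is.null(context)) context <- attr(result$row_coords, "context")
  if (is.null(context)) context <- "deviates"
  idx <- seq_len(nrow(f))
  if (nrow(f) > max_points) idx <- seq(1L, nrow(f), length.out = max_points)
  cloud <- data.frame(x = f[idx, 1L], y = f[idx, 2L],
                      context = rep_len(context, nrow(f))[idx])
  ctr <- rowMeans(result$col_contrib[, axes, drop = FALSE])
  cols <- data.frame(x = result$col_coords[, axes[1L]],
                     y = result$col_coords[, axes[2L]],
                     label = rownames(result$col_coords), ctr = ctr)
  gg <- ggplot2::ggplot(cloud, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$context),
                        alpha = 0.25, size = 0.4, show.legend = FALSE) +
    ggplot2::geom_text(data = cols,
                       ggplot2::aes(label = .data$label,
                                    size = .data$ctr), colour = "black") +
    ggplot2::scale_size_continuous(range = c(2.5, 6), guide = "none") +
    ggplot2::labs(x = sprintf("F%d (%.1f%%)", axes[1L],
                              result$pct_inertia[axes[1L]]),
                  y = sprintf("F%d (%.1f%%)", axes[2L],
                              result$pct_inertia[axes[2L]])) +
    ggplot2::theme_minimal()
  if (!is.null(result$sup_coords)) {
    sup <- data.frame(x = result$sup_coords[, axes[1L]],
                      y = result$sup_coords[, axes[2L]],
                      label = rownames(result$sup_coords))
    gg <- gg +
      ggplot2::geom_point(data = sup, shape = 1, size = 3, stroke = 1) +
      ggplot2::geom_text(data = sup,
                         ggplot2::aes(label = .data$label),
                         vjust = -1, size = 3)
  }
  gg
}
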