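# shared fixtures: everything is built in code, no stored data files

fix_scheme <- function(...) legge_classes(...)
fix_map <- function(scheme = fix_scheme()) demo_stage_map(scheme)
fix_refs <- function(scheme = fix_scheme()) schematic_reference_set(scheme)

# a tiny hand-written record table covering all teeth and a split stage
fix_records_df <- function() {
  data.frame(
    context_id = c("A", "A", "A", "B", "B"),
    site_id = c("s1", "s1", "s1", "s2", "s2"),
    tooth = c("dP4", "M1", "M3", "M2", "dP4"),
    wear_stage = c("a", "f", "e", "c", "d"),
    crown_height_mm = c(18.2, NA, 12.0, NA, 20.1),
    dap_mm = c(NA, 24.0, NA, 28.5, NA),
    dt_mm = c(NA, 14.0, NA, 16.2, NA),
    stringsAsFactors = FALSE
  )
}

# independent CA oracle: explicit loops + eigendecomposition of t(S) %*% S,
# sharing no code path with correspondence_analysis()
ca_oracle <- function(x) {
  x <- as.matrix(x)
  p <- x / sum(x)
  r <- rowSums(p)
  cm <- colSums(p)
  s <- matrix(0, nrow(p), ncol(p))
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      s[i, j] <- (p[i, j] - r[i] * cm[j]) / sqrt(r[i] * cm[j])
  e <- eigen(t(s) %*% s, symmetric = TRUE)
  n_axes <- min(nrow(x) - 1L, ncol(x) - 1L)
  lambda <- pmax(e$values, 0)[seq_len(n_axes)]
  keep <- lambda > 1e-12
  lambda <- lambda[keep]
  g <- sweep(e$vectors[, seq_len(n_axes), drop = FALSE][, keep, drop = FALSE],
             2L, sqrt(lambda), `*`) / sqrt(cm)
  phi2 <- 0
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      phi2 <- phi2 + (p[i, j] - r[i] * cm[j])^2 / (r[i] * cm[j])
  list(inertia = lambda, total_inertia = phi2, col_coords = g)
}

# random nonnegative table with positive margins
random_table <- function(nr, nc) {
  repeat {
    x <- matrix(stats::rexp(nr * nc), nr, nc)
    if (all(rowSums(x) > 0) && all(colSums(x) > 0)) return(x)
  }
}

# scheme + map pair where classes 2 and 3 are never split across a run
# boundary, so merging them is an exact refinement of the attribution
fix_merge_safe <- function() {
  scheme <- legge_classes()
  labs <- class_labels(scheme)
  entries <- data.frame(
    tooth = "T",
    wear_stage = letters[1:6],
    class_from = labs[c(1, 2, 4, 4, 6, 5)],
    class_to   = labs[c(1, 3, 4, 5, 7, 7)],
    stringsAsFactors = FALSE
  )
  merged <- age_class_scheme(
    labels = c(labs[1], "6-26 months", labs[4:7]),
    start_months = c(0, 6, 26, 36, 72, 96),
    end_months = c(6, 26, 36, 72, 96, Inf),
    nominal_terminal_duration_months = 24)
  mlabs <- class_labels(merged)
  m_entries <- data.frame(
    tooth = "T",
    wear_stage = letters[1:6],
    class_from = mlabs[c(1, 2, 3, 3, 5, 4)],
    class_to   = mlabs[c(1, 2, 3, 4, 6, 6)],
    stringsAsFactors = FALSE
  )
  list(scheme = scheme, map = wear_stage_map(entries, scheme),
       merged_scheme = merged,
       merged_map = wear_stage_map(m_entries, merged))
}
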