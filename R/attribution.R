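#' Fractional attribution of one tooth to age classes
#'
#' A tooth whose wear stage is compatible with a single age class counts 1
#' in that class. A tooth compatible with a run of k classes is divided
#' between them in proportion to the classes' durations in months, so a
#' stage spanning 6--15 and 15--26 months (durations 9 and 11) contributes
#' 9/20 and 11/20 of a tooth. An open-ended terminal class uses the
#' scheme's nominal duration. Weights always sum to exactly 1: splitting
#' never creates or destroys teeth.
#'
#' @param tooth,wear_stage character scalars identifying the stage-map entry.
#' @param map a [wear_stage_map()].
#' @param scheme the [age_class_scheme()] (defaults to the map's scheme).
#' @return Numeric vector of length `n_classes(scheme)` with the tooth's
#'   fractional weights, named by class label.
#' @export
attribute_tooth <- function(tooth, wear_stage, map,
                            scheme = attr(map, "scheme")) {
  run <- admissible_classes(map, tooth, wear_stage)
  w <- numeric(n_classes(scheme))
  names(w) <- class_labels(scheme)
  d <- class_durations(scheme)[run]
  w[run] <- d / sum(d)
  w
}

# weights for each distinct (tooth, stage) entry of a map: rows align with
# the map's entries; used to vectorize attribution over whole record tables
.map_weights <- function(map, scheme = attr(map, "scheme")) {
  labs <- class_labels(scheme)
  dur <- class_durations(scheme)
  from <- match(map$class_from, labs)
  to <- match(map$class_to, labs)
  w <- matrix(0, nrow(map), length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(nrow(map))) {
    run <- seq.int(from[i], to[i])
    w[i, run] <- dur[run] / sum(dur[run])
  }
  w
}

#' Build per-context fractional count tables
#'
#' Sums tooth attribution vectors within each context, giving a contexts x
#' classes table of fractional counts whose row sums equal the numbers of
#' teeth exactly (attribution conserves teeth). Contexts appear in order of
#' first appearance in `records`.
#'
#' @param records a `tooth_records` data.frame (see [read_tooth_records()]).
#' @param map a [wear_stage_map()] covering all (tooth, stage) pairs present.
#' @param scheme the [age_class_scheme()] (defaults to the map's scheme).
#' @return A numeric matrix of class `count_table` (contexts x classes,
#'   rownames = context ids) with attribute `N`, the integer tooth count per
#'   context.
#' @export
build_count_table <- function(records, map, scheme = attr(map, "scheme")) {
  if (!nrow(records)) stop("no tooth records supplied")
  w <- .map_weights(map, scheme)
  key <- paste(map$tooth, map$wear_stage, sep = "\r")
  idx <- match(paste(records$tooth, records$wear_stage, sep = "\r"), key)
  if (anyNA(idx))
    stop("record with no stage-map entry: tooth '",
         records$tooth[which(is.na(idx))[1L]], "', stage '",
         records$wear_stage[which(is.na(idx))[1L]], "'")
  ctx <- factor(records$context_id, levels = unique(records$context_id))
  tab <- rowsum(w[idx, , drop = FALSE], ctx)
  tab <- as.matrix(tab)
  n_teeth <- as.vector(table(ctx))
  names(n_teeth) <- levels(ctx)
  structure(tab, N = n_teeth, class = c("count_table", class(tab)))
}

#' @export
`[.count_table` <- function(x, i, j, ..., drop = TRUE) {
  n <- attr(x, "N")
  out <- unclass(x)
  attr(out, "N") <- NULL
  out <- out[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  structure(out, N = n[rownames(out)],
            class = c("count_table", class(out)))
}

#' Export a count table to CSV
#'
#' Writes contexts x classes fractional counts with a trailing `N` column
#' (teeth per context).
#'
#' @param tab a `count_table` from [build_count_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(tab, path) {
  df <- data.frame(context_id = rownames(tab), as.data.frame(unclass(tab)),
                   N = attr(tab, "N"), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#' @param path path to the CSV file.
#' @return A `count_table` matrix with attribute `N`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  n_col <- match("N", names(df))
  tab <- as.matrix(df[, -c(1L, n_col), drop = FALSE])
  rownames(tab) <- df[[1L]]
  structure(tab, N = stats::setNames(df$N, df[[1L]]),
            class = c("count_table", class(tab)))
}
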