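#' Ordered age-class scheme
#'
#' An age-class scheme is an ordered, contiguous partition of age (in months)
#' into slaughter-age classes. The last class may be open-ended (e.g. "older
#' than 8 years"); proportional division of multi-class teeth then uses a
#' nominal finite duration for that class.
#'
#' @param labels character vector of class labels, youngest first.
#' @param start_months,end_months numeric vectors of class boundaries in
#'   months; classes must be contiguous (`end_months[i] == start_months[i+1]`)
#'   and strictly increasing. The last `end_months` may be `Inf`, marking the
#'   terminal class as open-ended.
#' @param nominal_terminal_duration_months duration (months) assigned to an
#'   open terminal class when splitting multi-class teeth proportionally.
#'   Default 24 (i.e. ">8 years" is treated as 8--10 years for splitting
#'   only). Ignored for closed schemes.
#' @return An object of class `age_class_scheme`: a list with elements
#'   `classes` (data.frame of label, start_months, end_months),
#'   `terminal_open` and `nominal_terminal_duration_months`.
#' @seealso [legge_classes()] for the default cattle scheme,
#'   [class_durations()] for the durations used in proportional splitting.
#' @export
age_class_scheme <- function(labels, start_months, end_months,
                             nominal_terminal_duration_months = 24) {
  stopifnot(is.character(labels), length(labels) >= 1L,
            length(start_months) == length(labels),
            length(end_months) == length(labels))
  if (anyDuplicated(labels))
    stop("age class labels must be unique")
  k <- length(labels)
  if (any(!is.finite(start_months)))
    stop("start_months must all be finite")
  if (any(!is.finite(end_months[-k])))
    stop("only the terminal class may be open-ended")
  if (any(end_months <= start_months))
    stop("each class must have positive duration (end > start)")
  if (k > 1L) {
    gaps <- start_months[-1L] - end_months[-k]
    bad <- which(abs(gaps) > 1e-9)
    if (length(bad))
      stop(sprintf(
        "classes must be contiguous: gap/overlap between '%s' and '%s'",
        labels[bad[1L]], labels[bad[1L] + 1L]))
  }
  terminal_open <- !is.finite(end_months[k])
  if (!is.numeric(nominal_terminal_duration_months) ||
      nominal_terminal_duration_months <= 0)
    stop("nominal_terminal_duration_months must be a positive number")
  structure(
    list(
      classes = data.frame(label = labels,
                           start_months = as.numeric(start_months),
                           end_months = as.numeric(end_months),
                           stringsAsFactors = FALSE),
      terminal_open = terminal_open,
      nominal_terminal_duration_months = nominal_terminal_duration_months
    ),
    class = "age_class_scheme"
  )
}

#' Default 7-class cattle age scheme
#'
#' The standard cattle dental ageing scheme with seven ordinal classes:
#' 0--6, 6--15, 15--26 and 26--36 months, then 3--6 years, 6--8 years and an
#' open terminal class of animals older than 8 years. Class durations (6, 9,
#' 11, 10, 36, 24 months, plus a nominal 24 for the open class) drive the
#' proportional division of teeth compatible with several classes.
#'
#' @inheritParams age_class_scheme
#' @return An [age_class_scheme()].
#' @export
legge_classes <- function(nominal_terminal_duration_months = 24) {
  age_class_scheme(
    labels = c("0-6 months", "6-15 months", "15-26 months", "26-36 months",
               "3-6 years", "6-8 years", ">8 years"),
    start_months = c(0, 6, 15, 26, 36, 72, 96),
    end_months   = c(6, 15, 26, 36, 72, 96, Inf),
    nominal_terminal_duration_months = nominal_terminal_duration_months
  )
}

#' @export
print.age_class_scheme <- function(x, ...) {
  cat(sprintf("Age-class scheme: %d classes%s\n", n_classes(x),
              if (x$terminal_open) " (terminal class open-ended)" else ""))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Number of classes in a scheme
#' @param scheme an [age_class_scheme()].
#' @return integer count of classes.
#' @export
n_classes <- function(scheme) nrow(scheme$classes)

#' Class labels of a scheme
#' @inheritParams n_classes
#' @return character vector of labels, youngest first.
#' @export
class_labels <- function(scheme) scheme$classes$label

#' Class durations used for proportional splitting
#'
#' Durations in months of each class; an open terminal class takes the
#' scheme's nominal terminal duration.
#'
#' @inheritParams n_classes
#' @return numeric vector of durations (months), one per class.
#' @export
class_durations <- function(scheme) {
  d <- scheme$classes$end_months - scheme$classes$start_months
  if (scheme$terminal_open)
    d[length(d)] <- scheme$nominal_terminal_duration_months
  d
}

#' Read an age-class scheme from a CSV config
#'
#' The config is a CSV with columns `label`, `start_months`, `end_months`,
#' one row per class in order. An empty, `Inf` or `NA` terminal
#' `end_months` marks the open-ended class.
#'
#' @param path path to the CSV file.
#' @inheritParams age_class_scheme
#' @return An [age_class_scheme()]; contiguity and ordering are validated.
#' @export
read_age_class_scheme <- function(path, nominal_terminal_duration_months = 24) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_months", "end_months")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("scheme file missing column(s): ", paste(miss, collapse = ", "))
  end <- suppressWarnings(as.numeric(df$end_months))
  end[is.na(end)] <- Inf
  age_class_scheme(as.character(df$label), as.numeric(df$start_months), end,
                   nominal_terminal_duration_months)
}

#' Write an age-class scheme to CSV
#' @param scheme an [age_class_scheme()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_age_class_scheme <- function(scheme, path) {
  df <- scheme$classes
  df$end_months[!is.finite(df$end_months)] <- NA
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
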