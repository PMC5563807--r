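#' Wear-stage to age-class map
#'
#' A wear-stage map records, for every (tooth, wear stage) pair in use, the
#' set of age classes an isolated tooth in that state may belong to. Dental
#' ageing schemes only ever produce *contiguous* runs of classes (wear is
#' monotone in age), so each entry is stored as a first and last class label.
#' The numeric content of the map is data, not code: published stage tables
#' are shipped or supplied by the user as an editable CSV.
#'
#' @param entries data.frame with columns `tooth`, `wear_stage`,
#'   `class_from`, `class_to` (labels in `scheme`; `class_from` must not come
#'   after `class_to` in scheme order).
#' @param scheme the [age_class_scheme()] the map refers to.
#' @return An object of class `wear_stage_map`: the validated entry table
#'   with the scheme attached as attribute `scheme`.
#' @seealso [demo_stage_map()], [read_wear_stage_map()], [attribute_tooth()]
#' @export
wear_stage_map <- function(entries, scheme) {
  stopifnot(is.data.frame(entries), inherits(scheme, "age_class_scheme"))
  need <- c("tooth", "wear_stage", "class_from", "class_to")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("stage map missing column(s): ", paste(miss, collapse = ", "))
  entries <- entries[need]
  entries[] <- lapply(entries, as.character)
  labs <- class_labels(scheme)
  i_from <- match(entries$class_from, labs)
  i_to <- match(entries$class_to, labs)
  bad <- which(is.na(i_from) | is.na(i_to))
  if (length(bad))
    stop(sprintf("stage map row %d: unknown age class '%s'", bad[1L],
                 if (is.na(i_from[bad[1L]])) entries$class_from[bad[1L]]
                 else entries$class_to[bad[1L]]))
  rev_run <- which(i_from > i_to)
  if (length(rev_run))
    stop(sprintf("stage map row %d: class_from after class_to", rev_run[1L]))
  key <- paste(entries$tooth, entries$wear_stage, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (tooth, wear_stage) entry in stage map: ",
         sub("\r", "/", key[duplicated(key)][1L]))
  structure(entries, scheme = scheme, class = c("wear_stage_map",
                                                "data.frame"))
}

#' Look up the admissible class run for a (tooth, stage) pair
#'
#' @param map a [wear_stage_map()].
#' @param tooth,wear_stage character scalars.
#' @return integer vector of class indices (a contiguous run), or an error
#'   if the pair has no entry.
#' @export
admissible_classes <- function(map, tooth, wear_stage) {
  i <- which(map$tooth == tooth & map$wear_stage == wear_stage)
  if (!length(i))
    stop(sprintf("no stage-map entry for tooth '%s', wear stage '%s'",
                 tooth, wear_stage))
  labs <- class_labels(attr(map, "scheme"))
  seq.int(match(map$class_from[i], labs), match(map$class_to[i], labs))
}

#' Tooth codes known to a stage map
#' @param map a [wear_stage_map()].
#' @return character vector of tooth codes.
#' @export
map_teeth <- function(map) unique(map$tooth)

#' Read a wear-stage map from CSV
#'
#' CSV columns: `tooth`, `wear_stage`, `class_from`, `class_to`.
#'
#' @param path path to the CSV file.
#' @param scheme the [age_class_scheme()] whose labels the map uses.
#' @return A validated [wear_stage_map()].
#' @export
read_wear_stage_map <- function(path, scheme) {
  if (!file.exists(path)) stop("stage map file not found: ", path)
  wear_stage_map(utils::read.csv(path, stringsAsFactors = FALSE), scheme)
}

#' Write a wear-stage map to CSV
#' @param map a [wear_stage_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wear_stage_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Demonstration wear-stage map for the 7-class cattle scheme
#'
#' A schematic map used by tests, examples and the synthetic-assemblage
#' generator. It is NOT a published stage table: published stage-to-class
#' lookups should be supplied via [read_wear_stage_map()]. The demo map is
#' constructed so that every class is reachable through at least one
#' single-class stage, roughly a third of stages span two classes
#' (mimicking the isolated-tooth attribution problem), and tooth eruption
#' order is respected (dP4 young classes only, M3 older classes only).
#' Tooth code `M12` denotes a first/second molar that could not be
#' discriminated; its stages span wider runs.
#'
#' @param scheme an [age_class_scheme()] with exactly 7 classes (default
#'   [legge_classes()]).
#' @return A [wear_stage_map()].
#' @export
demo_stage_map <- function(scheme = legge_classes()) {
  if (n_classes(scheme) != 7L)
    stop("demo_stage_map requires a 7-class scheme")
  labs <- class_labels(scheme)
  run <- function(tooth, stage, from, to)
    data.frame(tooth = tooth, wear_stage = stage,
               class_from = labs[from], class_to = labs[to],
               stringsAsFactors = FALSE)
  entries <- rbind(
    # deciduous P4: in wear from birth, shed around 30 months
    run("dP4", "a", 1, 1), run("dP4", "b", 1, 2), run("dP4", "c", 2, 2),
    run("dP4", "d", 2, 3), run("dP4", "e", 3, 3), run("dP4", "f", 4, 4),
    # M1: erupts ~6 months
    run("M1", "a", 2, 2), run("M1", "b", 3, 3), run("M1", "c", 3, 4),
    run("M1", "d", 4, 4), run("M1", "e", 5, 5), run("M1", "f", 5, 6),
    run("M1", "g", 6, 6), run("M1", "h", 7, 7),
    # M2: erupts ~18 months
    run("M2", "a", 3, 3), run("M2", "b", 4, 4), run("M2", "c", 4, 5),
    run("M2", "d", 5, 5), run("M2", "e", 6, 6), run("M2", "f", 6, 7),
    run("M2", "g", 7, 7),
    # M3: erupts ~30 months
    run("M3", "a", 4, 4), run("M3", "b", 5, 5), run("M3", "c", 5, 6),
    run("M3", "d", 6, 6), run("M3", "e", 7, 7),
    # undiscriminated M1/M2: runs are unions of the two possibilities
    run("M12", "a", 2, 3), run("M12", "b", 3, 4), run("M12", "c", 4, 5),
    run("M12", "d", 5, 6), run("M12", "e", 6, 7)
  )
  wear_stage_map(entries, scheme)
}
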