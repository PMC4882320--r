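#' The AAL-90 parcellation shipped with the package
#'
#' Returns the 90-region automated-anatomical-labelling parcellation of the
#' cerebrum (45 regions per hemisphere, cerebellum excluded) in the canonical
#' node order used by every matrix in the pipeline: regions are interleaved
#' left/right, so node `2i - 1` is the left and node `2i` the right homologue
#' of the i-th anatomical structure.
#'
#' Each region carries a functional class after Mesulam's scheme
#' (`association`, `paralimbic`, `subcortical`, `primary`). The `provenance`
#' column records how the class was assigned: `"printed"` entries come
#' verbatim from published FDG-PET hub tables for this parcellation,
#' `"mirrored"` entries copy the printed class of the contralateral
#' homologue, and `"inferred"` entries were completed from the Mesulam
#' scheme by the package authors.
#'
#' @return A data frame with 90 rows and columns `index`, `abbreviation`,
#'   `name`, `hemisphere` (`"L"`/`"R"`), `func_class`, `provenance`.
#' @examples
#' rt <- load_region_table()
#' table(rt$hemisphere)
#' @export
load_region_table <- function() {
  path <- system.file("extdata", "aal90_regions.tsv", package = "metabnet")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged region table 'aal90_regions.tsv' is missing; ",
         "the installation is corrupt", call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("index", "abbreviation", "name", "hemisphere", "func_class",
                "provenance")
  if (!all(required %in% names(tab))) {
    stop("packaged region table is corrupt: missing columns ",
         paste(setdiff(required, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) != 90L || !identical(tab$index, 1:90) ||
      sum(tab$hemisphere == "L") != 45L ||
      anyDuplicated(paste(tab$abbreviation, tab$hemisphere))) {
    stop("packaged region table is corrupt: expected 90 uniquely labelled ",
         "regions, 45 per hemisphere, in canonical order", call. = FALSE)
  }
  if (!all(tab$func_class %in% c("association", "paralimbic", "subcortical",
                                 "primary"))) {
    stop("packaged region table is corrupt: unknown functional class",
         call. = FALSE)
  }
  class(tab) <- c("region_table", "data.frame")
  tab
}

#' Look up a region by abbreviation and hemisphere (or by index)
#'
#' @param region_table A region table from [load_region_table()].
#' @param abbreviation Region abbreviation, e.g. `"REC"`; ignored when
#'   `index` is given.
#' @param hemisphere `"L"` or `"R"`; ignored when `index` is given.
#' @param index Optional canonical node index (1-90).
#' @return A one-row data frame (a single region).
#' @examples
#' rt <- load_region_table()
#' region_lookup(rt, "REC", "R")$name
#' @export
region_lookup <- function(region_table, abbreviation = NULL, hemisphere = NULL,
                          index = NULL) {
  stopifnot(inherits(region_table, "data.frame"))
  if (!is.null(index)) {
    hit <- region_table[region_table$index == index, , drop = FALSE]
  } else {
    if (is.null(abbreviation) || is.null(hemisphere)) {
      stop("supply either `index` or both `abbreviation` and `hemisphere`")
    }
    hit <- region_table[region_table$abbreviation == abbreviation &
                        region_table$hemisphere == hemisphere, , drop = FALSE]
  }
  if (nrow(hit) != 1L) stop("region not found in table")
  hit
}

#' Functional-class composition of a set of regions
#'
#' Counts the regions of each functional class and the corresponding
#' fractions, as used to summarise where network hubs fall (hub regions of
#' metabolic covariance networks concentrate in association and paralimbic
#' cortex).
#'
#' @param regions A data frame of regions with a `func_class` column (any
#'   subset of rows of [load_region_table()], or a loaded hub table).
#' @return A data frame with columns `func_class`, `count`, `fraction`,
#'   covering all four classes (zero rows included), fractions summing to 1.
#' @examples
#' hubs <- load_hub_table("dm")
#' comp <- classify_composition(hubs)
#' sum(comp$fraction[comp$func_class %in% c("association", "paralimbic")])
#' @export
classify_composition <- function(regions) {
  if (!is.data.frame(regions) || !"func_class" %in% names(regions)) {
    stop("`regions` must be a data frame with a `func_class` column")
  }
  if (nrow(regions) == 0L) stop("`regions` must be non-empty")
  classes <- c("association", "paralimbic", "subcortical", "primary")
  if (!all(regions$func_class %in% classes)) {
    stop("unknown functional class in `regions`")
  }
  cnt <- vapply(classes, function(cl) sum(regions$func_class == cl), integer(1))
  data.frame(func_class = classes,
             count = as.integer(cnt),
             fraction = cnt / nrow(regions),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Published hub tables bundled for reference analyses
#'
#' Loads the bundled betweenness-centrality hub table of a published FDG-PET
#' metabolic covariance study of diabetes: the hub regions of the diabetes
#' (`"dm"`) or normal-control (`"nc"`) group network at 10% connection
#' density, with their printed functional class and normalized betweenness
#' `b`.
#'
#' @param group `"dm"` or `"nc"`.
#' @param region_table Region table used to attach canonical node indices.
#' @return A data frame with columns `index`, `abbreviation`, `hemisphere`,
#'   `func_class`, `b`, sorted by descending `b`.
#' @export
load_hub_table <- function(group = c("dm", "nc"),
                           region_table = load_region_table()) {
  group <- match.arg(group)
  path <- system.file("extdata", paste0("hub_table_", group, ".tsv"),
                      package = "metabnet")
  if (!nzchar(path)) stop("bundled hub table missing", call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- paste(region_table$abbreviation, region_table$hemisphere)
  m <- match(paste(tab$abbreviation, tab$hemisphere), key)
  if (anyNA(m)) stop("hub table region not present in region table")
  tab$index <- region_table$index[m]
  tab[order(-tab$b, tab$index), c("index", "abbreviation", "hemisphere",
                                  "func_class", "b")]
}
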