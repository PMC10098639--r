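#' @title Corpus discovery and loading
#' @description Readers for image-sequence corpora laid out like the common
#'   micro-expression (SAMM- and SMIC-style) and macro-expression (CK+-style)
#'   collections: one folder of lexicographically ordered PNG frames per
#'   clip, plus a `labels.csv` table with columns `clip_id`, `subject_id`,
#'   `label` and (optionally) `apex_index`. All layouts are mapped into a
#'   unified 3-class label space and tagged with a domain:
#'   micro-expression (0) or macro-expression (1).
#' @name datasets_io
NULL

.label_maps <- list(
  "samm-like" = c(other = 0L, happiness = 1L, surprise = 2L),
  "smic-like" = c(negative = 0L, positive = 1L, surprise = 2L),
  # Seven-to-three folding for posed macro-expression corpora: everything
  # that is neither happiness nor surprise lands on class 0.
  "ck-like" = c(anger = 0L, contempt = 0L, disgust = 0L, fear = 0L,
                sadness = 0L, happiness = 1L, happy = 1L, surprise = 2L)
)

#' Map a raw corpus label onto the unified 3-class space
#'
#' Classes are `0` = other/negative, `1` = happiness/positive,
#' `2` = surprise. The mapping is case-insensitive and total over the
#' documented vocabulary of each layout.
#'
#' @param raw Label string as found in the corpus table.
#' @param dataset One of `"samm-like"`, `"smic-like"`, `"ck-like"`.
#' @return Integer class index in `0:2`.
#' @export
map_label <- function(raw, dataset) {
  dataset <- match.arg(dataset, names(.label_maps))
  key <- tolower(trimws(raw))
  vocab <- .label_maps[[dataset]]
  if (!key %in% names(vocab)) {
    stop("unknown label '", raw, "' for layout '", dataset, "'")
  }
  unname(vocab[[key]])
}

.new_catalog <- function(df) {
  cat <- tibble::as_tibble(df)
  attr(cat, "class_names") <- .CLASS_NAMES
  class(cat) <- c("me_catalog", class(cat))
  cat
}

#' Class names of the unified label space
#' @param catalog An `me_catalog`.
#' @return Character vector of length 3.
#' @export
class_names <- function(catalog) attr(catalog, "class_names")

#' Scan an on-disk corpus into a catalog
#'
#' Walks `root`, expecting `root/labels.csv` and one sub-folder of PNG
#' frames per `clip_id`. `smic-like` layouts carry no apex annotation, so
#' `apex_index` is left `NA`; `ck-like` layouts are tagged as the macro
#' domain. Frames are loaded lazily via [load_frames()].
#'
#' @param root Corpus root directory.
#' @param layout One of `"samm-like"`, `"smic-like"`, `"ck-like"`.
#' @param fps Frame rate of the recordings, frames/second.
#' @return An `me_catalog`: a tibble with one row per clip (columns
#'   `clip_id`, `subject_id`, `dataset`, `domain`, `emotion`, `apex_index`,
#'   `n_frames`, `fps`, `path`, and a lazy `frames` list-column).
#' @export
scan_dataset <- function(root, layout = c("samm-like", "smic-like", "ck-like"),
                         fps = 30) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop("corpus root '", root, "' does not exist")
  table_path <- file.path(root, "labels.csv")
  if (!file.exists(table_path)) {
    stop("configuration error: label table '", table_path, "' is missing")
  }
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  need <- c("clip_id", "subject_id", "label")
  if (!all(need %in% names(tab))) {
    stop("label table must have columns: ", paste(need, collapse = ", "))
  }
  domain <- if (layout == "ck-like") 1L else 0L
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    clip_dir <- file.path(root, tab$clip_id[i])
    files <- sort(list.files(clip_dir, pattern = "\\.png$", ignore.case = TRUE))
    if (length(files) == 0) {
      warning("skipping clip '", tab$clip_id[i], "': no image frames found")
      return(NULL)
    }
    apex <- NA_integer_
    if (layout == "samm-like" && "apex_index" %in% names(tab) &&
        !is.na(tab$apex_index[i])) {
      apex <- as.integer(tab$apex_index[i])
    }
    tibble::tibble(
      clip_id = tab$clip_id[i], subject_id = as.character(tab$subject_id[i]),
      dataset = layout, domain = domain,
      emotion = map_label(tab$label[i], layout),
      apex_index = apex, n_frames = length(files), fps = fps,
      path = clip_dir, frames = list(NULL))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no clips with frames under '", root, "'")
  .new_catalog(do.call(rbind, rows))
}

#' Extract one sample from a catalog
#'
#' @param catalog An `me_catalog`.
#' @param i Row index.
#' @return An `me_sample` list with the catalog metadata plus `frames`
#'   (still `NULL` if the clip has not been loaded).
#' @export
catalog_sample <- function(catalog, i) {
  stopifnot(i >= 1, i <= nrow(catalog))
  s <- as.list(catalog[i, , drop = FALSE])
  s$frames <- s$frames[[1]]
  s$apex_index <- if (is.na(s$apex_index)) NULL else s$apex_index
  structure(s, class = "me_sample")
}

#' Load the grayscale frame stack of a sample
#'
#' Reads the PNG frames backing `sample` (unless already in memory) into an
#' `H x W x T` array with intensities in `[0, 1]`. Color frames are
#' converted by the BT.601 luma weighting `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param sample An `me_sample`.
#' @return Numeric array of dim `c(H, W, T)`.
#' @export
load_frames <- function(sample) {
  if (!is.null(sample$frames)) return(sample$frames)
  files <- sort(list.files(sample$path, pattern = "\\.png$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no frames under '", sample$path, "'")
  mats <- lapply(files, function(f) {
    img <- tryCatch(png::readPNG(f),
                    error = function(e) stop("I/O error reading '", f, "': ",
                                             conditionMessage(e)))
    if (length(dim(img)) == 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
    img
  })
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1)))) {
    stop("frames under '", sample$path, "' do not share one shape")
  }
  array(unlist(mats), dim = c(d, length(mats)))
}

#' Write / read a catalog manifest
#'
#' The manifest is a plain CSV of the catalog metadata (no pixel data), so a
#' catalog can be reproduced exactly by re-reading it.
#'
#' @param catalog An `me_catalog`.
#' @param path CSV file path.
#' @return `read_catalog_manifest` returns an `me_catalog` with lazy frames.
#' @export
write_catalog_manifest <- function(catalog, path) {
  df <- as.data.frame(catalog[, setdiff(names(catalog), "frames")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_manifest
#' @export
read_catalog_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       clip_id = "character",
                                       path = "character"))
  df$frames <- replicate(nrow(df), NULL, simplify = FALSE)
  .new_catalog(tibble::as_tibble(df))
}
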