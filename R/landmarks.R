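#' Landmark datasets
#'
#' A `landmark_dataset` bundles per-specimen 3D point configurations with
#' specimen metadata (species, sex, optional subspecies) and a map assigning
#' every point to one named anatomical region. All specimens must share the
#' same number of points `k`, in the same order, with no missing coordinates.
#'
#' @param coords numeric array `k x 3 x n` (points x dimensions x specimens)
#'   with specimen identifiers as the third dimnames, or a named list of
#'   `k x 3` matrices.
#' @param specimens data frame with columns `specimen`, `species`, `sex`
#'   (`"male"`/`"female"`) and optionally `subspecies`.
#' @param regions data frame with columns `point_index` (1-based) and
#'   `region`, partitioning the `k` points.
#' @return an object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(coords, specimens, regions = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    ks <- vapply(coords, nrow, integer(1))
    if (length(unique(ks)) != 1L) {
      bad <- names(coords)[which(ks != ks[[1]])[1]]
      abort(sprintf(
        "malformed dataset: specimen '%s' has %d points but the first specimen has %d",
        bad %||% "<unnamed>", ks[ks != ks[1]][1], ks[1]
      ), class = "shaperate_malformed_dataset")
    }
    nm <- names(coords)
    coords <- array(unlist(coords), dim = c(unname(ks[1]), 3, length(coords)),
                    dimnames = list(NULL, c("x", "y", "z"), nm))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (anyNA(coords)) {
    abort("landmark coordinates contain missing values; only complete configurations are supported",
          class = "shaperate_malformed_dataset")
  }
  ids <- dimnames(coords)[[3]]
  if (is.null(ids)) {
    ids <- paste0("specimen_", seq_len(dim(coords)[3]))
    dimnames(coords)[[3]] <- ids
  }
  specimens <- tibble::as_tibble(specimens)
  if (!all(c("specimen", "species", "sex") %in% names(specimens))) {
    abort("metadata must have columns specimen, species, sex", class = "shaperate_validation")
  }
  if (!"subspecies" %in% names(specimens)) specimens$subspecies <- NA_character_
  specimens$sex <- normalize_sex(specimens$sex)
  missing <- setdiff(ids, specimens$specimen)
  if (length(missing)) {
    abort(paste0("metadata does not cover specimens: ", paste(missing, collapse = ", ")),
          class = "shaperate_validation")
  }
  specimens <- specimens[match(ids, specimens$specimen), , drop = FALSE]
  k <- dim(coords)[1]
  if (is.null(regions)) {
    regions <- tibble::tibble(point_index = seq_len(k), region = "whole")
  }
  regions <- tibble::as_tibble(regions)
  if (!all(c("point_index", "region") %in% names(regions))) {
    abort("region map must have columns point_index, region", class = "shaperate_validation")
  }
  if (!setequal(regions$point_index, seq_len(k)) || anyDuplicated(regions$point_index)) {
    abort("region map must assign every point index 1..k exactly once",
          class = "shaperate_validation")
  }
  regions <- regions[order(regions$point_index), ]
  structure(
    list(coords = coords, specimens = specimens, regions = regions),
    class = "landmark_dataset"
  )
}

normalize_sex <- function(x) {
  out <- c(male = "male", m = "male", female = "female", f = "female")[tolower(as.character(x))]
  if (anyNA(out)) {
    abort(paste0("unknown sex codes: ", paste(unique(x[is.na(out)]), collapse = ", ")),
          class = "shaperate_validation")
  }
  unname(out)
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf(
    "<landmark_dataset> %d specimens x %d points, %d species, regions: %s\n",
    dim(x$coords)[3], dim(x$coords)[1],
    length(unique(x$specimens$species)),
    paste(unique(x$regions$region), collapse = ", ")
  ))
  invisible(x)
}

#' Number of points / specimens in a landmark dataset
#' @param x a `landmark_dataset`
#' @return integer count
#' @export
n_points <- function(x) unname(dim(x$coords)[1])

#' @rdname n_points
#' @export
n_specimens <- function(x) unname(dim(x$coords)[3])

#' Read a long-format landmark CSV
#'
#' Expects columns `specimen,point_index,x,y,z` with 0-based `point_index`.
#'
#' @param path file path
#' @return array `k x 3 x n`
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "point_index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(paste0("landmark CSV must have columns ", paste(need, collapse = ",")),
          class = "shaperate_malformed_dataset")
  }
  split_df <- split(df, factor(df$specimen, levels = unique(df$specimen)))
  counts <- vapply(split_df, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    bad <- names(counts)[counts != counts[1]][1]
    abort(sprintf("malformed dataset: specimen '%s' has %d points, expected %d",
                  bad, counts[[bad]], counts[[1]]),
          class = "shaperate_malformed_dataset")
  }
  configs <- lapply(split_df, function(d) {
    d <- d[order(d$point_index), ]
    as.matrix(d[, c("x", "y", "z")])
  })
  array(unlist(configs), dim = c(unname(counts[1]), 3, length(configs)),
        dimnames = list(NULL, c("x", "y", "z"), names(configs)))
}

#' Read a TPS landmark file
#'
#' Supports `LM=`/`LM3=` point-count records (2D rows are padded with z = 0),
#' `ID=` specimen identifiers and `SCALE=` factors (coordinates are multiplied
#' by the scale when present).
#'
#' @param path file path
#' @return array `k x 3 x n`
#' @export
read_landmarks_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines, ignore.case = TRUE)
  if (!length(starts)) abort("no LM=/LM3= records found", class = "shaperate_malformed_dataset")
  bounds <- c(starts, length(lines) + 1L)
  configs <- list()
  for (b in seq_along(starts)) {
    block <- lines[bounds[b]:(bounds[b + 1] - 1L)]
    nlm <- as.integer(sub("^LM3?=", "", block[1], ignore.case = TRUE))
    id_line <- grep("^ID=", block, ignore.case = TRUE, value = TRUE)
    id <- if (length(id_line)) sub("^ID=", "", id_line[1], ignore.case = TRUE) else paste0("specimen_", b)
    scale_line <- grep("^SCALE=", block, ignore.case = TRUE, value = TRUE)
    scale <- if (length(scale_line)) as.numeric(sub("^SCALE=", "", scale_line[1], ignore.case = TRUE)) else 1
    coord_lines <- block[-1]
    coord_lines <- coord_lines[!grepl("^[A-Za-z]", coord_lines)]
    if (length(coord_lines) < nlm) {
      abort(sprintf("malformed dataset: TPS block '%s' declares %d landmarks but has %d coordinate rows",
                    id, nlm, length(coord_lines)),
            class = "shaperate_malformed_dataset")
    }
    xyz <- t(vapply(coord_lines[seq_len(nlm)], function(l) {
      v <- as.numeric(strsplit(l, "[ \t]+")[[1]])
      if (length(v) == 2) v <- c(v, 0)
      if (length(v) != 3 || anyNA(v)) {
        abort("malformed dataset: TPS coordinate row is not 2 or 3 numbers",
              class = "shaperate_malformed_dataset")
      }
      v
    }, numeric(3), USE.NAMES = FALSE))
    configs[[id]] <- xyz * scale
  }
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L) {
    bad <- names(ks)[ks != ks[1]][1]
    abort(sprintf("malformed dataset: specimen '%s' has %d points, expected %d",
                  bad, ks[[bad]], ks[[1]]),
          class = "shaperate_malformed_dataset")
  }
  array(unlist(configs), dim = c(unname(ks[1]), 3, length(configs)),
        dimnames = list(NULL, c("x", "y", "z"), names(configs)))
}

#' Read a region map CSV (`point_index,region`, 0-based indices)
#' @param path file path
#' @return tibble with 1-based `point_index` and `region`
#' @export
read_region_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("point_index", "region") %in% names(df))) {
    abort("region map CSV must have columns point_index,region", class = "shaperate_validation")
  }
  tibble::tibble(point_index = as.integer(df$point_index) + 1L, region = df$region)
}

#' Read a specimen metadata CSV (`specimen,species,sex[,subspecies]`)
#' @param path file path
#' @return tibble
#' @export
read_specimen_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Load a landmark dataset from files
#'
#' @param path landmark file (CSV long format or TPS)
#' @param format `"csv"` or `"tps"`
#' @param metadata_path specimen metadata CSV
#' @param region_path optional region map CSV
#' @return a [landmark_dataset()]
#' @export
load_landmark_dataset <- function(path, format = c("csv", "tps"),
                                  metadata_path, region_path = NULL) {
  format <- match.arg(format)
  coords <- switch(format,
    csv = read_landmarks_csv(path),
    tps = read_landmarks_tps(path)
  )
  regions <- if (!is.null(region_path)) read_region_map(region_path)
  landmark_dataset(coords, read_specimen_metadata(metadata_path), regions)
}

#' Restrict a landmark dataset to one anatomical region
#'
#' The returned dataset contains only the requested region's points, in their
#' original order; downstream Procrustes superimposition is then re-run on
#' the subset, so each region is aligned independently rather than carved out
#' of the whole-configuration alignment.
#'
#' @param dataset a [landmark_dataset()]
#' @param region region name present in the dataset's region map
#' @return a [landmark_dataset()] restricted to `region`
#' @export
region_subset <- function(dataset, region) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (!region %in% dataset$regions$region) {
    abort(sprintf("unknown region '%s' (have: %s)", region,
                  paste(unique(dataset$regions$region), collapse = ", ")),
          class = "shaperate_validation")
  }
  idx <- sort(dataset$regions$point_index[dataset$regions$region == region])
  landmark_dataset(
    dataset$coords[idx, , , drop = FALSE],
    dataset$specimens,
    tibble::tibble(point_index = seq_along(idx), region = region)
  )
}

#' Default region names
#'
#' The four craniofacial regions used throughout: posterior neurocranium,
#' anterior neurocranium, upper face, lower face.
#' @return character vector of length 4
#' @export
default_regions <- function() {
  c("posterior_neurocranium", "anterior_neurocranium", "upper_face", "lower_face")
}

#' Write a landmark dataset to the long CSV dialect
#' @param dataset a [landmark_dataset()]
#' @param path output CSV path (0-based point_index)
#' @param metadata_path optional metadata CSV output
#' @param region_path optional region map CSV output (0-based)
#' @return `path`, invisibly
#' @export
write_landmarks_csv <- function(dataset, path, metadata_path = NULL, region_path = NULL) {
  k <- n_points(dataset); n <- n_specimens(dataset)
  ids <- dimnames(dataset$coords)[[3]]
  df <- data.frame(
    specimen = rep(ids, each = k),
    point_index = rep(0:(k - 1L), n),
    x = as.vector(dataset$coords[, 1, ]),
    y = as.vector(dataset$coords[, 2, ]),
    z = as.vector(dataset$coords[, 3, ])
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.csv(as.data.frame(dataset$specimens), metadata_path, row.names = FALSE)
  }
  if (!is.null(region_path)) {
    rm_df <- data.frame(point_index = dataset$regions$point_index - 1L,
                        region = dataset$regions$region)
    utils::write.csv(rm_df, region_path, row.names = FALSE)
  }
  invisible(path)
}
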