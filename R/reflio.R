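#' Construct an unmerged reflection dataset
#'
#' The central container of the package: one crystal's integrated but
#' unscaled, unmerged observations, together with the header information
#' (unit cell, space-group symbol, image range) needed downstream.
#'
#' @param dataset_id Character identifier (usually the file stem).
#' @param cell A [unit_cell()].
#' @param spacegroup Hermann-Mauguin symbol, e.g. `"P 21 21 21"` or `"P1"`.
#' @param observations `data.frame` with integer columns `h`, `k`, `l`,
#'   numeric `intensity` and `sigma` (> 0) and integer `image` (1-based).
#' @param first_image,last_image Inclusive 1-based image range of the sweep.
#' @param serial Positive integer label used in the dendrogram (assigned by
#'   [gather_inputs()]; may be `NA` for a free-standing dataset).
#' @param source_path Path the data came from, if any.
#' @return An object of class `unmerged_dataset`.
#' @export
unmerged_dataset <- function(dataset_id, cell, spacegroup, observations,
                             first_image = 1L,
                             last_image = max(observations$image),
                             serial = NA_integer_, source_path = "") {
  cell <- as_unit_cell(cell)
  obs <- as.data.frame(observations)
  need <- c("h", "k", "l", "intensity", "sigma", "image")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns ", paste(need, collapse = ", "))
  }
  obs <- obs[need]
  obs$h <- as.integer(obs$h); obs$k <- as.integer(obs$k); obs$l <- as.integer(obs$l)
  obs$image <- as.integer(obs$image)
  first_image <- as.integer(first_image); last_image <- as.integer(last_image)
  if (first_image > last_image) stop("first_image must be <= last_image")
  if (nrow(obs)) {
    if (any(obs$sigma <= 0)) stop("all observation sigmas must be > 0")
    if (any(obs$h == 0L & obs$k == 0L & obs$l == 0L)) {
      stop("observation with Miller index (0,0,0)")
    }
    bad <- obs$image < first_image | obs$image > last_image
    if (any(bad)) {
      stop(sprintf("observation cites image %d outside header range [%d, %d]",
                   obs$image[which(bad)[1]], first_image, last_image))
    }
  }
  structure(list(dataset_id = as.character(dataset_id),
                 serial = as.integer(serial),
                 cell = cell,
                 spacegroup = as.character(spacegroup),
                 first_image = first_image,
                 last_image = last_image,
                 observations = obs,
                 source_path = as.character(source_path)),
            class = "unmerged_dataset")
}

#' @export
print.unmerged_dataset <- function(x, ...) {
  cat(sprintf("unmerged dataset '%s' (serial %s): %d observations, images %d..%d, %s\n",
              x$dataset_id, ifelse(is.na(x$serial), "-", x$serial),
              nrow(x$observations), x$first_image, x$last_image, x$spacegroup))
  print(x$cell)
  invisible(x)
}

#' Read one unmerged reflection dataset
#'
#' Two text dialects are supported. `canonical` is the package's own
#' self-describing format (see [write_dataset()]): a header block with
#' `CELL`, `SPACEGROUP` and `IMAGES` keys followed by a whitespace-separated
#' observation table with columns `H K L I SIGI IMAGE`. `xds_integrate`
#' reads the INTEGRATE-stage HKL dialect of XDS (`!`-prefixed header,
#' `H K L IOBS SIGMA X Y Z ...` records); indices are taken as P1 until
#' symmetry is applied downstream, and a header marker indicating
#' post-CORRECT (already scaled) data triggers a warning, since rescaling
#' scaled intensities is not recommended.
#'
#' @param path File to read.
#' @param dialect One of `"canonical"`, `"xds_integrate"`, `"mtz_unmerged"`.
#'   Binary unmerged MTZ is not supported by this build and errors with a
#'   pointer to the text dialects.
#' @return An [unmerged_dataset()].
#' @export
read_dataset <- function(path, dialect = c("canonical", "xds_integrate", "mtz_unmerged")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
         canonical = read_dataset_canonical(path),
         xds_integrate = read_dataset_xds(path),
         mtz_unmerged = stop("binary unmerged MTZ input is not supported; ",
                             "convert to the canonical text format or XDS INTEGRATE.HKL"))
}

read_dataset_canonical <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^\\s*(CELL|SPACEGROUP|IMAGES|ID)\\b", lines, value = TRUE)
  getval <- function(key) {
    m <- grep(paste0("^\\s*", key, "\\b"), lines, value = TRUE)
    if (!length(m)) stop(sprintf("canonical format error in '%s': missing header field %s", path, key))
    trimws(sub(paste0("^\\s*", key, "\\s*"), "", m[1]))
  }
  cellv <- suppressWarnings(as.numeric(strsplit(getval("CELL"), "\\s+")[[1]]))
  if (length(cellv) != 6 || any(is.na(cellv))) {
    stop(sprintf("canonical format error in '%s': CELL needs six numbers", path))
  }
  sg <- getval("SPACEGROUP")
  img <- suppressWarnings(as.integer(strsplit(getval("IMAGES"), "\\s+")[[1]]))
  if (length(img) != 2 || any(is.na(img))) {
    stop(sprintf("canonical format error in '%s': IMAGES needs two integers", path))
  }
  id <- tryCatch(getval("ID"), error = function(e) tools::file_path_sans_ext(basename(path)))
  body <- setdiff(lines, hdr)
  body <- body[!grepl("^\\s*#", body)]
  colhdr <- grep("^\\s*H\\s+K\\s+L\\b", body)
  if (length(colhdr)) body <- body[-colhdr]
  if (length(body)) {
    obs <- utils::read.table(text = body, col.names = c("h", "k", "l", "intensity", "sigma", "image"))
  } else {
    obs <- data.frame(h = integer(), k = integer(), l = integer(),
                      intensity = numeric(), sigma = numeric(), image = integer())
  }
  unmerged_dataset(id, cellv, sg, obs, img[1], img[2], source_path = path)
}

read_dataset_xds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "!")]
  if (!length(hdr)) stop(sprintf("not an XDS HKL file (no '!' header): %s", path))
  if (any(grepl("XDS_ASCII|CORRECT", hdr))) {
    warning("XDS file ", basename(path), " appears to contain post-CORRECT (scaled) ",
            "intensities; INTEGRATE-stage intensities are recommended as input")
  }
  pick <- function(key) {
    m <- grep(paste0("^!", key, "="), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^!", key, "="), "", m[1]))
  }
  cellstr <- pick("UNIT_CELL_CONSTANTS")
  if (is.null(cellstr)) stop(sprintf("XDS format error in '%s': missing UNIT_CELL_CONSTANTS", path))
  cellv <- as.numeric(strsplit(cellstr, "\\s+")[[1]])
  sgnum <- pick("SPACE_GROUP_NUMBER")
  sg <- if (is.null(sgnum)) "P1" else spacegroup_from_number(as.integer(sgnum))
  rng <- pick("DATA_RANGE")
  dat <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (!length(dat)) stop(sprintf("XDS format error in '%s': no reflection records", path))
  tab <- utils::read.table(text = dat)
  if (ncol(tab) < 8) stop(sprintf("XDS format error in '%s': expected >= 8 columns (H K L IOBS SIGMA X Y Z)", path))
  image <- as.integer(floor(tab[[8]])) + 1L  # Z centroid in frames -> 1-based image
  if (is.null(rng)) {
    first <- min(image); last <- max(image)
  } else {
    r <- as.integer(strsplit(rng, "\\s+")[[1]]); first <- r[1]; last <- r[2]
  }
  image <- pmin(pmax(image, first), last)
  obs <- data.frame(h = tab[[1]], k = tab[[2]], l = tab[[3]],
                    intensity = tab[[4]], sigma = tab[[5]], image = image)
  obs <- obs[obs$sigma > 0, , drop = FALSE]
  unmerged_dataset(tools::file_path_sans_ext(basename(path)), cellv, sg, obs,
                   first, last, source_path = path)
}

spacegroup_from_number <- function(n) {
  map <- c(`1` = "P1", `3` = "P2", `4` = "P21", `16` = "P222",
           `19` = "P212121", `75` = "P4", `168` = "P6")
  out <- map[as.character(n)]
  if (is.na(out)) "P1" else unname(out)
}

#' Write a dataset in the canonical text format
#'
#' @param ds An [unmerged_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "unmerged_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ID", ds$dataset_id),
               paste("CELL", paste(formatC(as.numeric(ds$cell), format = "f", digits = 5), collapse = " ")),
               paste("SPACEGROUP", ds$spacegroup),
               paste("IMAGES", ds$first_image, ds$last_image),
               "H K L I SIGI IMAGE"), con)
  if (nrow(ds$observations)) {
    o <- ds$observations
    writeLines(sprintf("%d %d %d %.9g %.9g %d", o$h, o$k, o$l, o$intensity, o$sigma, o$image), con)
  }
  invisible(path)
}

#' Gather input datasets from a directory or list file
#'
#' Reads every dataset below `target` (a directory, or a text file with one
#' dataset path per line) and assigns dendrogram serial numbers 1..n in
#' lexicographic path order, a deterministic rule so repeated runs over the
#' same inputs always label crystals identically. The resolved absolute
#' paths are written, one per line in serial order, to `mtz_names.dat` in
#' `output_dir` — the bookkeeping file a later run (or a hand-edited copy
#' excluding outliers) can use as its own input.
#'
#' @param target Directory containing dataset files, or path to a list file.
#' @param output_dir Where to write `mtz_names.dat` (default: current dir).
#' @param dialect Dialect for [read_dataset()] applied to files without an
#'   `.hkl` extension (`.hkl` files are always read as `xds_integrate`).
#' @return List of [unmerged_dataset()] objects, serials 1..n.
#' @export
gather_inputs <- function(target, output_dir = ".", dialect = "canonical") {
  if (dir.exists(target)) {
    paths <- list.files(target, pattern = "\\.(refl|dat|txt|hkl|HKL)$", full.names = TRUE)
    paths <- sort(paths, method = "radix")
  } else if (file.exists(target)) {
    first <- trimws(readLines(target, n = 5, warn = FALSE))
    first <- first[nzchar(first)]
    if (length(first) && grepl("^(ID|CELL|SPACEGROUP|IMAGES|!)", first[1])) {
      paths <- target  # a single dataset file, not a list file
    } else {
      paths <- trimws(readLines(target, warn = FALSE))
      paths <- paths[nzchar(paths) & !startsWith(paths, "#")]
    }
  } else {
    stop("input target does not exist: ", target)
  }
  if (!length(paths)) stop("no input datasets found under ", target)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("listed input path does not exist: ", missing[1])
  paths <- normalizePath(paths)
  datasets <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    dial <- if (grepl("\\.hkl$", paths[i], ignore.case = TRUE)) "xds_integrate" else dialect
    ds <- read_dataset(paths[i], dial)
    ds$serial <- i
    datasets[[i]] <- ds
  }
  if (!is.null(output_dir)) {
    writeLines(paths, file.path(output_dir, "mtz_names.dat"))
  }
  datasets
}

#' Write and read the final per-dataset summary list
#'
#' The analysis pass condenses its findings into one six-column row per
#' dataset: source path, dendrogram serial, last accepted image (the
#' radiation-damage cutoff; equal to the last image when no pruning is
#' suggested), first image, last image, and the suggested high-resolution
#' cutoff in Angstrom (3 decimals).
#'
#' @param entries `data.frame` with columns `path`, `serial`, `cutoff_image`
#'   (may be `NA` for "no cutoff"), `first_image`, `last_image`,
#'   `suggested_resolution`.
#' @param path Output file, conventionally `FINAL_list_of_files.dat`.
#' @return `path` invisibly (`write_final_list`); the entries `data.frame`
#'   (`read_final_list`).
#' @export
write_final_list <- function(entries, path) {
  entries <- as.data.frame(entries)
  if (!nrow(entries)) stop("no entries to write")
  entries <- entries[order(entries$serial), , drop = FALSE]
  cut <- ifelse(is.na(entries$cutoff_image), entries$last_image, entries$cutoff_image)
  stopifnot(all(entries$first_image <= cut & cut <= entries$last_image),
            all(entries$suggested_resolution > 0))
  path_col <- ifelse(nzchar(entries$path), entries$path, "<memory>")
  writeLines(sprintf("%s %d %d %d %d %.3f", path_col, entries$serial,
                     as.integer(cut), entries$first_image, entries$last_image,
                     entries$suggested_resolution), path)
  invisible(path)
}

#' @rdname write_final_list
#' @export
read_final_list <- function(path) {
  tab <- utils::read.table(path, col.names = c("path", "serial", "cutoff_image",
                                               "first_image", "last_image",
                                               "suggested_resolution"),
                           colClasses = c("character", "integer", "integer",
                                          "integer", "integer", "numeric"))
  tab
}
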