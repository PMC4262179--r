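#' Landmark dataset container
#'
#' Bundles the digitised 2-D landmark configurations of a sample of
#' specimens. All specimens must share the same landmark scheme (the same
#' number of landmarks, digitised in the same order); the default scheme in
#' this package has 25 landmarks on the left lateral side of the fish.
#'
#' @param coords numeric array of dimension `k x 2 x n` (landmarks,
#'   x/y, specimens), or a list of `k x 2` matrices.
#' @param specimen_ids character vector of unique specimen identifiers.
#' @param groups optional named character vector mapping specimen id to a
#'   group label (e.g. `parentA`, `F1`, `backcrossA`, `F2`, `wild:Liwonde`).
#' @return an object of class `landmark_dataset` with elements `coords`,
#'   `specimen_ids`, `groups`, `k` and `n`.
#' @export
landmark_dataset <- function(coords, specimen_ids = NULL, groups = NULL) {
  if (is.list(coords)) {
    k <- unique(vapply(coords, nrow, 1L))
    if (length(k) != 1L)
      stop("all configurations must share the same landmark count; found ",
           paste(k, collapse = ", "))
    coords <- array(unlist(coords), dim = c(k, 2L, length(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 2L)
    stop("'coords' must be a k x 2 x n array of 2-D landmarks")
  n <- dim(coords)[3]
  if (n < 1L) stop("landmark dataset must contain at least one specimen")
  if (is.null(specimen_ids)) specimen_ids <- as.character(seq_len(n))
  specimen_ids <- as.character(specimen_ids)
  if (length(specimen_ids) != n)
    stop("need one specimen id per configuration")
  if (anyDuplicated(specimen_ids))
    stop("specimen ids must be unique; duplicated: ",
         paste(unique(specimen_ids[duplicated(specimen_ids)]), collapse = ", "))
  if (!all(is.finite(coords)))
    stop("all landmark coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y"), specimen_ids)
  structure(
    list(coords = coords, specimen_ids = specimen_ids,
         groups = groups, k = dim(coords)[1], n = n),
    class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset:", x$n, "specimens,", x$k, "landmarks (2-D)\n")
  if (!is.null(x$groups))
    print(table(x$groups[x$specimen_ids]))
  invisible(x)
}

#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect written by landmark digitisation software:
#' records start with an `LM=k` line (case-insensitive) followed by `k`
#' whitespace-separated x/y coordinate lines, optionally followed by
#' `IMAGE=`, `ID=` and `SCALE=` lines. `SCALE=` is applied multiplicatively
#' to the record's coordinates; `ID=` is used as the specimen identifier,
#' falling back to the record index. The y axis is stored as digitised (no
#' image flip): downstream Procrustes analysis is invariant to any
#' consistent orientation.
#'
#' @param path path to a TPS file.
#' @param group_map optional path to a two-column delimited file (or a named
#'   character vector) mapping specimen id to group label; group labels are
#'   experiment metadata and are not part of the TPS format itself.
#' @return a [landmark_dataset()].
#' @export
read_tps <- function(path, group_map = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^[Ll][Mm]=", lines)
  if (length(starts) == 0L) stop("no LM= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))

  configs <- vector("list", length(starts))
  ids <- character(length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^[Ll][Mm]=", "", block[1L])))
    if (is.na(k) || k < 1L)
      stop("record ", r, ": invalid LM= landmark count")
    body <- block[-1L]
    is_kv <- grepl("^[A-Za-z]+=", body)
    coord_lines <- body[!is_kv]
    if (length(coord_lines) != k)
      stop("record ", r, ": LM=", k, " but ", length(coord_lines),
           " coordinate lines found")
    xy <- lapply(strsplit(coord_lines, "[[:space:],]+"), function(v) {
      v <- suppressWarnings(as.numeric(v[nzchar(v)]))
      if (length(v) != 2L || anyNA(v))
        stop("record ", r, ": malformed coordinate line")
      v
    })
    m <- do.call(rbind, xy)
    kv <- body[is_kv]
    key <- toupper(sub("=.*$", "", kv))
    val <- sub("^[A-Za-z]+=", "", kv)
    if ("SCALE" %in% key) {
      sc <- suppressWarnings(as.numeric(val[match("SCALE", key)]))
      if (is.na(sc) || sc <= 0) stop("record ", r, ": invalid SCALE= value")
      m <- m * sc
    }
    ids[r] <- if ("ID" %in% key) val[match("ID", key)] else as.character(r)
    configs[[r]] <- m
  }
  ks <- vapply(configs, nrow, 1L)
  if (length(unique(ks)) != 1L)
    stop("inconsistent landmark counts across records: ",
         paste(unique(ks), collapse = ", "))

  groups <- NULL
  if (!is.null(group_map)) {
    groups <- if (is.character(group_map) && length(group_map) == 1L &&
                  file.exists(group_map)) read_group_map(group_map) else group_map
  }
  landmark_dataset(configs, specimen_ids = ids, groups = groups)
}

#' Read a specimen-to-group sidecar table
#'
#' @param path two-column delimited text (specimen id, group label); a
#'   header line is detected and skipped if its second field is "group".
#' @return named character vector (names are specimen ids).
#' @export
read_group_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("specimen_id", "group"))
  if (nrow(tab) > 0L && tolower(tab$group[1L]) == "group")
    tab <- tab[-1L, , drop = FALSE]
  stats::setNames(tab$group, tab$specimen_id)
}

#' Write a landmark dataset in TPS format
#'
#' Round-trips through [read_tps()]: coordinates are written at full double
#' precision and each record carries an `ID=` line.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output path.
#' @return invisibly, the path written.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (dataset$n < 1L) stop("refusing to write an empty landmark dataset")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dataset$n)) {
    m <- dataset$coords[, , i]
    writeLines(c(paste0("LM=", dataset$k),
                 paste(format(m[, 1], digits = 17, scientific = FALSE,
                              trim = TRUE),
                       format(m[, 2], digits = 17, scientific = FALSE,
                              trim = TRUE)),
                 paste0("ID=", dataset$specimen_ids[i])), con)
  }
  invisible(path)
}

#' Write a specimen-to-group sidecar table
#'
#' @param groups named character vector (names are specimen ids).
#' @param path output path.
#' @export
write_group_map <- function(groups, path) {
  utils::write.table(
    data.frame(specimen_id = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
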