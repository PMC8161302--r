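#' Read an area table from CSV
#'
#' Expected columns: `area_id`, `population`, `y1`, `y2` (required);
#' `e1`, `e2` (optional expected counts, taken verbatim when present); any
#' further columns are treated as covariates. When `e1`/`e2` are absent,
#' expected counts are computed by internal standardization on population
#' ([compute_expected_counts()]) with each outcome's observed total, so that
#' column sums of E equal those of Y.
#'
#' @param path CSV file path.
#' @return An [area_dataset()].
#' @export
read_area_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  required <- c("area_id", "population", "y1", "y2")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("area table is missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("y1", "y2")) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      stop("negative count in column ", col, " at row(s): ",
           paste(bad, collapse = ", "))
  }
  bad <- which(df$population <= 0)
  if (length(bad))
    stop("non-positive population at row(s): ", paste(bad, collapse = ", "))
  Y <- as.matrix(df[, c("y1", "y2")])
  if (all(c("e1", "e2") %in% names(df))) {
    E <- as.matrix(df[, c("e1", "e2")])
  } else {
    E <- compute_expected_counts(df$population, colSums(Y))
  }
  reserved <- c(required, "e1", "e2")
  xcols <- setdiff(names(df), reserved)
  X <- if (length(xcols)) as.matrix(df[, xcols, drop = FALSE]) else NULL
  area_dataset(df$area_id, df$population, Y, E, X)
}

#' Write an area dataset to CSV
#'
#' Columns `area_id, population, y1, y2, e1, e2` plus one column per
#' covariate; round-trips through [read_area_table()].
#'
#' @param dataset an [area_dataset()].
#' @param path output CSV path.
#' @export
write_area_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "area_dataset"))
  df <- data.frame(area_id = dataset$area_ids,
                   population = dataset$population,
                   y1 = dataset$Y[, 1L], y2 = dataset$Y[, 2L],
                   e1 = dataset$E[, 1L], e2 = dataset$E[, 2L])
  if (!is.null(dataset$X)) df <- cbind(df, as.data.frame(dataset$X))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
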