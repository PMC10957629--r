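#' PCA of concatenated time courses
#'
#' A multivariate view of the raw data.  Rows of the data matrix are
#' built by concatenating time courses according to `arrangement`:
#' \describe{
#'   \item{per-participant-intervention}{one row per participant x
#'     intervention, columns are analyte x time — the typical score
#'     plot separating interventions (36 rows for a 12 x 3 study).}
#'   \item{per-participant}{one row per participant, columns are
#'     intervention x analyte x time.}
#'   \item{per-series}{one row per participant x intervention x
#'     analyte, columns are the sampling times.}
#' }
#' With per-row centering each concatenated time course has its own
#' mean subtracted, largely removing baseline differences before the
#' (column-centered) PCA.  Missing cells are filled with the column
#' mean, with a warning.
#'
#' @param table a [study_table()].
#' @param arrangement row-building scheme, see above.
#' @param centering `"row"` (default) or `"none"`.
#' @return Object of class `study_pca`: `scores` (rows x PCs),
#'   `rowinfo` (keys per row), `sdev`, `rotation`, `arrangement`,
#'   `centering`.  `plot()` draws the PC1/PC2 score plot.
#' @export
pca_scores <- function(table,
                       arrangement = c("per-participant-intervention",
                                       "per-participant",
                                       "per-series"),
                       centering = c("row", "none")) {
  arrangement <- match.arg(arrangement)
  centering <- match.arg(centering)
  df <- as.data.frame(table)
  rowkey <- switch(arrangement,
    "per-participant" = df$Participant,
    "per-participant-intervention" =
      paste(df$Participant, df$Intervention, sep = "\r"),
    "per-series" =
      paste(df$Participant, df$Intervention, df$Analyte, sep = "\r"))
  colkey <- switch(arrangement,
    "per-participant" =
      paste(df$Intervention, df$Analyte, df$Time, sep = "\r"),
    "per-participant-intervention" =
      paste(df$Analyte, df$Time, sep = "\r"),
    "per-series" = as.character(df$Time))
  mat <- tapply(df$Value, list(rowkey, colkey), mean)
  if (nrow(mat) < 3)
    stop("need at least 3 rows for a PCA (got ", nrow(mat), ")")
  if (anyNA(mat)) {
    warning(sum(is.na(mat)), " missing cell(s) filled with the column mean")
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      if (any(nas)) mat[nas, j] <- mean(mat[, j], na.rm = TRUE)
    }
  }
  if (centering == "row") mat <- sweep(mat, 1, rowMeans(mat))
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  keys <- do.call(rbind, strsplit(rownames(mat), "\r", fixed = TRUE))
  rowinfo <- switch(arrangement,
    "per-participant" = data.frame(Participant = keys[, 1]),
    "per-participant-intervention" =
      data.frame(Participant = keys[, 1], Intervention = keys[, 2]),
    "per-series" = data.frame(Participant = keys[, 1],
                              Intervention = keys[, 2],
                              Analyte = keys[, 3]))
  structure(list(scores = pc$x, rowinfo = rowinfo, sdev = pc$sdev,
                 rotation = pc$rotation, arrangement = arrangement,
                 centering = centering),
            class = "study_pca")
}

#' @export
print.study_pca <- function(x, ...) {
  varpc <- 100 * x$sdev^2 / sum(x$sdev^2)
  cat("PCA (", x$arrangement, ", ", x$centering, " centering): ",
      nrow(x$scores), " rows; PC1 ", round(varpc[1], 1), "%, PC2 ",
      round(varpc[2], 1), "% of variance\n", sep = "")
  invisible(x)
}

#' @export
plot.study_pca <- function(x, file = NULL, width = 7, height = 6, ...) {
  varpc <- 100 * x$sdev^2 / sum(x$sdev^2)
  grp <- if ("Intervention" %in% names(x$rowinfo))
    x$rowinfo$Intervention else x$rowinfo$Participant
  obj <- lattice::xyplot(
    x$scores[, 2] ~ x$scores[, 1], groups = grp,
    xlab = sprintf("PC1 (%.1f%%)", varpc[1]),
    ylab = sprintf("PC2 (%.1f%%)", varpc[2]),
    auto.key = list(space = "top", columns = min(4, length(unique(grp)))),
    panel = function(x, y, ...) {
      lattice::panel.abline(h = 0, v = 0, col = "grey80")
      lattice::panel.superpose(x, y, ...)
    }, ...)
  .write_plot(obj, file, width, height)
}
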