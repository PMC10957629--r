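# open a graphics device chosen by file extension, print, close
.write_plot <- function(obj, file, width = 9, height = 7) {
  if (is.null(file)) return(obj)
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = png(file, width = width, height = height, units = "in",
                   res = 120),
         pdf = pdf(file, width = width, height = height),
         svg = svg(file, width = width, height = height),
         stop("unsupported plot format: .", ext))
  on.exit(dev.off())
  print(obj)
  invisible(file)
}

#' Panel plot of raw time courses with optional fitted curves
#'
#' One panel per analyte (rows) and participant (columns), points
#' colored by intervention; when a fit table is supplied, converged
#' Wood curves are overlaid.  Input tables are never modified.
#'
#' @param table a [study_table()].
#' @param participants,analytes subsets to show (default: all
#'   participants / the full roster).
#' @param fits optional `woodfit_table` from [fit_all()].
#' @param file output image (`.png`, `.pdf` or `.svg`); `NULL` returns
#'   the trellis object without writing.
#' @param npoints curve evaluation grid size.
#' @param width,height device size in inches.
#' @return The file path (invisibly) or the trellis object.
#' @export
plot_timecourses <- function(table, participants = NULL,
                             analytes = NULL, fits = NULL, file = NULL,
                             npoints = 100, width = 9, height = 9) {
  df <- as.data.frame(table)
  if (is.null(participants)) participants <- unique(df$Participant)
  if (is.null(analytes)) analytes <- analyte_roster(table)
  if (!all(participants %in% df$Participant))
    stop("unknown participant(s): ",
         paste(setdiff(participants, df$Participant), collapse = ", "))
  if (!all(analytes %in% df$Analyte))
    stop("unknown analyte(s): ",
         paste(setdiff(analytes, df$Analyte), collapse = ", "))
  df <- df[df$Participant %in% participants &
           df$Analyte %in% analytes,
           c("Participant", "Intervention", "Time", "Analyte", "Value")]
  if (!nrow(df)) stop("empty selection")
  df$src <- "obs"
  if (!is.null(fits)) {
    f <- fits[isTRUE_v(fits$converged) &
              fits$Participant %in% participants &
              fits$Analyte %in% analytes, , drop = FALSE]
    if (nrow(f)) {
      grid <- seq(min(df$Time), max(df$Time), length.out = npoints)
      pred <- do.call(rbind, lapply(seq_len(nrow(f)), function(i)
        data.frame(Participant = f$Participant[i],
                   Intervention = f$Intervention[i], Time = grid,
                   Analyte = f$Analyte[i],
                   Value = wood_eval(wood_params(f$a[i], f$m[i],
                                                 f$c[i], f$d[i]),
                                     grid),
                   src = "fit", stringsAsFactors = FALSE)))
      df <- rbind(df, pred)
    }
  }
  df$Participant <- factor(df$Participant, levels = participants)
  df$Analyte <- factor(df$Analyte, levels = analytes)
  src <- df$src
  obj <- lattice::xyplot(
    Value ~ Time | Participant * Analyte, data = df,
    groups = df$Intervention, as.table = TRUE,
    xlab = "Time (min)", ylab = "Concentration",
    scales = list(y = list(relation = "free")),
    auto.key = list(space = "top", columns = 3, points = TRUE),
    panel = function(x, y, subscripts, groups, ...) {
      o <- src[subscripts] == "obs"
      lattice::panel.superpose(x[o], y[o],
                               subscripts = subscripts[o],
                               groups = groups, type = "p", ...)
      if (any(!o))
        lattice::panel.superpose(x[!o], y[!o],
                                 subscripts = subscripts[!o],
                                 groups = groups, type = "l", ...)
    })
  .write_plot(obj, file, width, height)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Dot plot of PoIs before and after curation
#'
#' Side-by-side uncurated/curated panels per PoI and analyte, all
#' participants on the vertical axis, colored by intervention; values
#' removed by curation are simply absent from the curated panel.
#'
#' @param pois uncurated `poi_table`.
#' @param curated curated `poi_table` with the same keys.
#' @param file output image or `NULL`.
#' @param width,height device size in inches.
#' @return The file path (invisibly) or the trellis object.
#' @export
plot_poi_dotplot <- function(pois, curated, file = NULL, width = 10,
                             height = 10) {
  stack_one <- function(tab, stage) {
    do.call(rbind, lapply(c("AUC", "Height", "Time2Max"), function(poi)
      data.frame(tab[c("Participant", "Intervention", "Analyte")],
                 PoI = poi, stage = stage, Value = tab[[poi]],
                 stringsAsFactors = FALSE)))
  }
  df <- rbind(stack_one(as.data.frame(pois), "uncurated"),
              stack_one(as.data.frame(curated), "curated"))
  df <- df[is.finite(df$Value), ]
  if (!nrow(df)) {
    warning("no finite PoI values to plot")
    return(invisible(NULL))
  }
  df$panel <- factor(paste(df$PoI, df$stage),
                     levels = as.vector(outer(c("uncurated", "curated"),
                                              c("AUC", "Height",
                                                "Time2Max"),
                                              function(s, p)
                                                paste(p, s))))
  obj <- lattice::dotplot(
    Participant ~ Value | panel * factor(df$Analyte), data = df,
    groups = df$Intervention, as.table = TRUE,
    scales = list(x = list(relation = "free")),
    auto.key = list(space = "top", columns = 3),
    xlab = "PoI value")
  .write_plot(obj, file, width, height)
}

#' Forest plot of intervention comparisons
#'
#' Per PoI, the contrast estimates and confidence intervals per analyte
#' and test intervention.  The dashed no-effect line sits at 1 for
#' ratio-type and 0 for difference-type contrasts; intervals excluding
#' it are drawn in red.
#'
#' @param results a `poi_comparison` from [compare_pois()].
#' @param file output image or `NULL`.
#' @param width,height device size in inches.
#' @return The file path (invisibly) or the trellis object.
#' @export
plot_forest <- function(results, file = NULL, width = 9, height = 7) {
  df <- as.data.frame(results)
  if (!nrow(df)) stop("empty comparison table")
  df$label <- paste(df$Analyte, df$contrast, sep = " : ")
  df$null <- ifelse(df$type == "ratio", 1, 0)
  df$sig <- df$ci_low > df$null | df$ci_high < df$null
  df$y <- as.numeric(factor(df$label))
  labs <- levels(factor(df$label))
  obj <- lattice::xyplot(
    y ~ estimate | PoI, data = df,
    scales = list(x = list(relation = "free"),
                  y = list(at = seq_along(labs), labels = labs)),
    xlab = "estimate (ratio or difference) with CI",
    ylab = NULL, as.table = TRUE, layout = c(length(unique(df$PoI)), 1),
    panel = function(x, y, subscripts, ...) {
      sub <- df[subscripts, ]
      lattice::panel.abline(v = sub$null[1], lty = 2, col = "grey40")
      col <- ifelse(sub$sig, "red", "black")
      lattice::panel.segments(sub$ci_low, y, sub$ci_high, y, col = col)
      lattice::panel.points(x, y, pch = 16, col = col)
    })
  .write_plot(obj, file, width, height)
}
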