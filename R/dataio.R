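.canon_cols <- c("Participant", "Period", "Intervention", "Time",
                 "Analyte", "Value")

# case-insensitive rename to the canonical spellings; returns the frame
# or stops naming the first missing required column
.match_columns <- function(df, required) {
  nm <- names(df)
  for (want in required) {
    hit <- which(tolower(nm) == tolower(want))
    if (!length(hit))
      stop("required column '", want, "' not found", call. = FALSE)
    names(df)[hit[1]] <- want
  }
  df
}

#' Construct a canonical long-format study table
#'
#' The internal backbone of the package: one row per measured
#' concentration for one participant, period, intervention, analyte and
#' time.  Wide input is an I/O dialect only; all computation uses this
#' long format.  Validates uniqueness of (participant, period, analyte,
#' time), one intervention per participant and period, and presence of
#' the reference intervention.
#'
#' @param data data frame with columns `Participant`, `Period`,
#'   `Intervention`, `Time` (minutes, >= 0), `Analyte`, `Value`
#'   (concentration, `NA` allowed).
#' @param reference label of the reference intervention.
#' @param roster optional ordered character vector of analyte labels;
#'   defaults to the analytes present, in order of appearance.
#' @return A data frame of class `study_table`, sorted by participant,
#'   period, analyte and time, with attributes `reference` and
#'   `roster`.
#' @export
study_table <- function(data, reference, roster = NULL) {
  df <- .match_columns(as.data.frame(data), .canon_cols)[.canon_cols]
  df$Participant <- as.character(df$Participant)
  df$Intervention <- as.character(df$Intervention)
  df$Analyte <- as.character(df$Analyte)
  df$Period <- as.integer(df$Period)
  if (!is.numeric(df$Time)) df$Time <- as.numeric(df$Time)
  if (!is.numeric(df$Value)) {
    v <- suppressWarnings(as.numeric(as.character(df$Value)))
    bad <- !is.na(as.character(df$Value)) & is.na(v)
    if (any(bad))
      warning(sum(bad), " non-numeric value(s) set to NA")
    df$Value <- v
  }
  if (any(!is.finite(df$Time)) || any(df$Time < 0))
    stop("'Time' must be finite and >= 0")
  if (any(is.na(df$Period)) || any(df$Period < 1))
    stop("'Period' must be a positive integer")

  key <- do.call(paste, c(df[c("Participant", "Period", "Analyte",
                               "Time")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (participant, period, analyte, time) records: ",
         paste(utils::head(gsub("\r", "/", dup), 5), collapse = ", "))
  }
  pp <- unique(df[c("Participant", "Period", "Intervention")])
  if (anyDuplicated(pp[c("Participant", "Period")]))
    stop("a participant has more than one intervention in one period")
  if (!reference %in% df$Intervention)
    stop("reference intervention '", reference,
         "' absent from the data")
  if (is.null(roster)) roster <- unique(df$Analyte)
  if (!all(roster %in% df$Analyte))
    stop("analyte roster entries absent from the data: ",
         paste(setdiff(roster, df$Analyte), collapse = ", "))

  df <- df[order(df$Participant, df$Period, df$Analyte, df$Time), ]
  rownames(df) <- NULL
  structure(df, class = c("study_table", "data.frame"),
            reference = reference, roster = roster)
}

#' @export
print.study_table <- function(x, ...) {
  cat("Study table: ", length(unique(x$Participant)), " participants, ",
      length(unique(x$Intervention)), " interventions (reference: ",
      attr(x, "reference"), "), ", length(attr(x, "roster")),
      " analytes, ", nrow(x), " records\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Reference intervention and analyte roster of a study table
#' @param table a [study_table()].
#' @return The reference label / the ordered analyte labels.
#' @export
reference_intervention <- function(table) attr(table, "reference")

#' @rdname reference_intervention
#' @export
analyte_roster <- function(table) attr(table, "roster")

#' Read a crossover time-course table from CSV
#'
#' Accepts the long layout (`Participant`, `Period`, `Intervention`,
#' `Time`, `Analyte`, `Value`) or the wide layout (`Participant`,
#' `Period`, `Intervention`, `Time`, then one column per analyte).
#' Column-name matching is case-insensitive; wide input is melted to the
#' canonical long format.  Non-numeric concentration cells become `NA`
#' with a warning.
#'
#' @param path CSV file (UTF-8, header row).
#' @param format `"long"`, `"wide"`, or `"auto"` (wide when no
#'   `Analyte` column is present).
#' @param reference label of the reference intervention.
#' @param roster optional analyte roster; for wide input it also selects
#'   which columns are analytes (default: all non-key columns).
#' @return A [study_table()].
#' @export
read_study <- function(path, format = c("auto", "long", "wide"),
                       reference, roster = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "auto")
    format <- if (any(tolower(names(df)) == "analyte")) "long" else "wide"
  if (format == "long")
    return(study_table(df, reference = reference, roster = roster))

  df <- .match_columns(df, c("Participant", "Period", "Intervention",
                             "Time"))
  keys <- c("Participant", "Period", "Intervention", "Time")
  analytes <- if (is.null(roster)) setdiff(names(df), keys)
              else { miss <- setdiff(roster, names(df))
                     if (length(miss))
                       stop("analyte column(s) not found: ",
                            paste(miss, collapse = ", "))
                     roster }
  if (!length(analytes)) stop("wide input has no analyte columns")
  long <- do.call(rbind, lapply(analytes, function(an)
    data.frame(df[keys], Analyte = an, Value = df[[an]],
               stringsAsFactors = FALSE)))
  study_table(long, reference = reference, roster = analytes)
}

#' Write a study table to CSV
#'
#' @param table a [study_table()].
#' @param path output file.
#' @param format `"long"` (canonical) or `"wide"` (one column per
#'   analyte).
#' @return `path`, invisibly.
#' @export
write_study <- function(table, path, format = c("long", "wide")) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  if (format == "wide") {
    keys <- c("Participant", "Period", "Intervention", "Time")
    wide <- unique(df[keys])
    wkey <- do.call(paste, c(wide[keys], sep = "\r"))
    for (an in analyte_roster(table)) {
      sub <- df[df$Analyte == an, ]
      i <- match(wkey, do.call(paste, c(sub[keys], sep = "\r")))
      wide[[an]] <- sub$Value[i]
    }
    df <- wide
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-series fit-readiness report
#'
#' Counts non-missing points per (participant, intervention, analyte)
#' series and checks them against the minimum needed to fit the
#' four-parameter curve (five points) and the recommended count for a
#' reliable fit (eight).  Purely a report; nothing is modified.
#'
#' @param table a [study_table()].
#' @param min_timepoints minimum usable points for a fit (default 5).
#' @param recommended recommended count (default 8).
#' @return Data frame with one row per series: keys, `n_obs`,
#'   `fittable`, `meets_recommended`.
#' @export
validate_study <- function(table, min_timepoints = 5, recommended = 8) {
  df <- as.data.frame(table)
  if (!nrow(df))
    return(data.frame(Participant = character(),
                      Intervention = character(),
                      Analyte = character(), n_obs = integer(),
                      fittable = logical(),
                      meets_recommended = logical()))
  agg <- aggregate(list(n_obs = is.finite(df$Value)),
                   df[c("Participant", "Intervention", "Analyte")], sum)
  agg$n_obs <- as.integer(agg$n_obs)
  agg$fittable <- agg$n_obs >= min_timepoints
  agg$meets_recommended <- agg$n_obs >= recommended
  agg[order(agg$Participant, agg$Intervention, agg$Analyte), ,
      drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg
}

#' Append aggregated analyte totals
#'
#' For each named group, appends a new analyte whose value at every
#' sampled time is the sum of the member analytes; a sum with any
#' missing member is missing.  Existing records are never altered.
#'
#' @param table a [study_table()].
#' @param groups named list mapping each new total's label to a
#'   character vector of member analytes.
#' @return A [study_table()] with the totals appended to the roster.
#' @export
aggregate_analytes <- function(table, groups) {
  if (!length(groups)) return(table)
  df <- as.data.frame(table)
  unknown <- setdiff(unique(unlist(groups)), unique(df$Analyte))
  if (length(unknown))
    stop("unknown analyte(s) in group definition: ",
         paste(unknown, collapse = ", "))
  keys <- c("Participant", "Period", "Intervention", "Time")
  new <- lapply(names(groups), function(g) {
    sub <- df[df$Analyte %in% groups[[g]], ]
    agg <- aggregate(list(Value = sub$Value), sub[keys],
                     function(v) if (length(v) < length(groups[[g]]) ||
                                     anyNA(v)) NA_real_ else sum(v))
    data.frame(agg[keys], Analyte = g, Value = agg$Value,
               stringsAsFactors = FALSE)
  })
  study_table(rbind(df, do.call(rbind, new)),
              reference = reference_intervention(table),
              roster = c(analyte_roster(table), names(groups)))
}
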