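# Tidy assay tables: the canonical in-memory container for every tabular input
# the pipeline consumes (plate-reader FP time courses, saturation titrations,
# BLI sensorgrams, emission scans, melt curves and microscopy line profiles).
# One measurement per row; concentrations in molar, times in seconds.

ASSAY_KINDS <- list(
  fp_timecourse = list(cols = c("series", "conc", "time", "fp"),
                       x = "time", value = "fp", conc = "conc"),
  saturation    = list(cols = c("series", "conc", "fp"),
                       x = "conc", value = "fp", conc = "conc"),
  sensorgram    = list(cols = c("series", "conc", "time", "response", "phase"),
                       x = "time", value = "response", conc = "conc"),
  emission_scan = list(cols = c("series", "wavelength", "intensity"),
                       x = "wavelength", value = "intensity", conc = NULL),
  melt_curve    = list(cols = c("series", "temp", "ratio"),
                       x = "temp", value = "ratio", conc = NULL),
  line_profile  = list(cols = c("series", "position", "intensity"),
                       x = "position", value = "intensity", conc = NULL)
)

#' Construct a validated assay table
#'
#' An assay table is a tidy data frame (one measurement per row) tagged with an
#' assay kind and free-form metadata. Internal units are molar for
#' concentrations and seconds for times; readers convert from the declared
#' input units. Kinds and their canonical columns:
#'
#' * `fp_timecourse`: `series`, `conc` (M), `time` (s), `fp` (mP)
#' * `saturation`: `series`, `conc` (M), `fp` (mP)
#' * `sensorgram`: `series`, `conc` (M), `time` (s), `response` (nm), `phase`
#'   (`baseline`/`association`/`dissociation`)
#' * `emission_scan`: `series`, `wavelength` (nm), `intensity`
#' * `melt_curve`: `series`, `temp` (deg C), `ratio`
#' * `line_profile`: `series`, `position` (nm), `intensity`
#'
#' Extra columns (e.g. `replicate`) are carried through untouched. Validation
#' enforces: strictly increasing abscissa within each series (within phase for
#' sensorgrams), non-negative concentrations, and at least three points per
#' series.
#'
#' @param data data frame with the canonical columns for `kind`.
#' @param kind one of `names(ASSAY_KINDS)` above.
#' @param meta named list of metadata (reagent concentrations, ground truth of
#'   a simulation, ...).
#' @return an object of class `assay_table` (a data frame).
#' @export
assay_table <- function(data, kind, meta = list()) {
  kind <- match.arg(kind, names(ASSAY_KINDS))
  spec <- ASSAY_KINDS[[kind]]
  missing <- setdiff(spec$cols, names(data))
  if (length(missing) > 0) {
    stop_badarg("missing required column(s) for kind '", kind, "': ",
                paste(missing, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  out <- structure(data, kind = kind, meta = meta,
                   class = c("assay_table", "data.frame"))
  validate_assay_table(out)
  out
}

#' @rdname assay_table
#' @param x an `assay_table`.
#' @export
validate_assay_table <- function(x) {
  kind <- attr(x, "kind")
  spec <- ASSAY_KINDS[[kind]]
  if (!is.null(spec$conc) && any(x[[spec$conc]] < 0, na.rm = TRUE)) {
    stop_badarg("negative concentration values in assay table")
  }
  key <- if (kind == "sensorgram") {
    interaction(x$series, x$phase, drop = TRUE)
  } else {
    factor(x$series)
  }
  xs <- split(x[[spec$x]], factor(x$series))
  n <- vapply(xs, length, integer(1))
  if (any(n < 3)) {
    stop_badarg("series with fewer than 3 points: ",
                paste(names(xs)[n < 3], collapse = ", "))
  }
  for (g in split(x[[spec$x]], key)) {
    if (any(diff(g) <= 0)) {
      bad <- levels(key)[vapply(split(x[[spec$x]], key),
                                function(v) any(diff(v) <= 0), logical(1))]
      stop_badarg("non-monotonic or duplicated ", spec$x,
                  " within series: ", paste(unique(bad), collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.assay_table <- function(x, ...) {
  cat(sprintf("<assay_table kind=%s: %d rows, %d series>\n",
              attr(x, "kind"), nrow(x), length(unique(x$series))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

assay_kind <- function(x) attr(x, "kind")
assay_meta <- function(x) attr(x, "meta")

unit_factor <- function(unit, what) {
  tab <- switch(what,
    conc = c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12),
    time = c(s = 1, min = 60, h = 3600)
  )
  if (!unit %in% names(tab)) {
    stop_badarg("unknown ", what, " unit '", unit, "'")
  }
  unname(tab[unit])
}

#' Read a tidy assay table from CSV
#'
#' Reads a long-format delimited file (one measurement per row) and returns a
#' validated [assay_table] in internal SI units (molar, seconds). The dialect
#' declares the input units and, optionally, a column mapping from the file's
#' headers to the canonical names; by default concentration columns are in nM
#' (the convention in which these assays are reported) and times in seconds.
#' Unit-suffixed headers such as `conc_nM`, `conc_uM` or `time_s` are
#' recognised automatically.
#'
#' @param path path of the CSV file.
#' @param kind assay kind, see [assay_table].
#' @param dialect list with any of `conc_unit` (`"M"`, `"mM"`, `"uM"`, `"nM"`,
#'   `"pM"`), `time_unit` (`"s"`, `"min"`, `"h"`), `columns` (named character
#'   vector mapping canonical name -> file header), `sep`.
#' @return an [assay_table].
#' @export
read_assay_table <- function(path, kind, dialect = list()) {
  if (!file.exists(path)) stop_badarg("file not found: ", path)
  kind <- match.arg(kind, names(ASSAY_KINDS))
  spec <- ASSAY_KINDS[[kind]]
  raw <- utils::read.csv(path, sep = dialect$sep %||% ",",
                         stringsAsFactors = FALSE, check.names = FALSE)
  conc_unit <- dialect$conc_unit %||% "nM"
  time_unit <- dialect$time_unit %||% "s"
  colmap <- dialect$columns %||% character(0)

  find_col <- function(canon) {
    if (canon %in% names(colmap)) {
      hit <- colmap[[canon]]
      if (!hit %in% names(raw)) {
        stop_badarg("schema error: mapped column '", hit, "' (for '", canon,
                    "') not present in ", path)
      }
      return(hit)
    }
    if (canon %in% names(raw)) return(canon)
    # accept unit-suffixed headers, e.g. conc_nM, time_s, and case variants
    suffixed <- grep(paste0("^", canon, "_"), names(raw), value = TRUE)
    if (length(suffixed) == 1) return(suffixed)
    lc <- which(tolower(names(raw)) == tolower(canon))
    if (length(lc) == 1) return(names(raw)[lc])
    stop_badarg("schema error: required column '", canon,
                "' missing for kind '", kind, "' in ", path)
  }

  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in spec$cols) {
    hdr <- find_col(canon)
    v <- raw[[hdr]]
    if (canon == "conc") {
      unit <- sub("^conc_", "", hdr)
      if (hdr == canon || !is.null(dialect$columns)) unit <- conc_unit
      v <- as.numeric(v) * unit_factor(unit, "conc")
    } else if (canon == "time") {
      unit <- sub("^time_", "", hdr)
      if (hdr == canon || !is.null(dialect$columns)) unit <- time_unit
      v <- as.numeric(v) * unit_factor(unit, "time")
    }
    out[[canon]] <- v
  }
  extra <- setdiff(names(raw), vapply(spec$cols, find_col, character(1)))
  for (e in extra) out[[e]] <- raw[[e]]
  assay_table(out, kind, meta = list(source = path))
}

#' Write an assay table to CSV
#'
#' Writes the tidy long format read back by [read_assay_table]. Concentrations
#' are written in nM (header `conc_nM`) and times in seconds (`time_s`) at
#' full precision, so a write/read round trip reproduces values to better than
#' 1e-9 relative.
#'
#' @param x an [assay_table].
#' @param path output file path.
#' @export
write_assay_table <- function(x, path) {
  stopifnot(inherits(x, "assay_table"))
  out <- as.data.frame(x)
  if ("conc" %in% names(out)) {
    out$conc <- out$conc / 1e-9
    names(out)[names(out) == "conc"] <- "conc_nM"
  }
  if ("time" %in% names(out)) names(out)[names(out) == "time"] <- "time_s"
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first non-blank character (`>` FASTA,
#' `@` FASTQ). Sequences are uppercased; record order is preserved.
#'
#' @param path input file.
#' @return data frame with columns `id`, `seq` and (FASTQ only) `qual`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop_badarg("file not found: ", path)
  first <- ""
  con <- file(path, "r")
  on.exit(close(con))
  while (TRUE) {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop_badarg("empty reads file: ", path)
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1, 1); break }
  }
  if (first == ">") {
    ss <- Biostrings::readDNAStringSet(path, format = "fasta")
    data.frame(id = names(ss), seq = toupper(as.character(ss)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else if (first == "@") {
    # Biostrings warns about dropping (empty) metadata columns on FASTQ input
    ss <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    data.frame(id = names(ss), seq = toupper(as.character(ss)),
               qual = as.character(Biostrings::quality(ss)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    stop_badarg("unrecognised reads format (first character '", first,
                "') in ", path)
  }
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads data frame with `id`, `seq` and optionally `qual` columns.
#' @param path output path.
#' @param format `"fastq"` (default when a `qual` column is present) or
#'   `"fasta"`.
#' @export
write_reads <- function(reads, path, format = NULL) {
  format <- format %||% if ("qual" %in% names(reads)) "fastq" else "fasta"
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  if (format == "fastq") {
    qual <- reads$qual %||% strrep("I", nchar(reads$seq))
    qss <- Biostrings::QualityScaledDNAStringSet(
      ss, Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(qss, path)
  } else {
    Biostrings::writeXStringSet(ss, path, format = "fasta")
  }
  invisible(path)
}

#' Serialize a fit object to JSON or CSV
#'
#' All fitted parameters, confidence intervals and diagnostics of a fit object
#' (kinetic, dose-response, saturation, BLI, melt or profile fit) are written
#' at full precision. JSON is a single object keyed by parameter name; CSV is
#' a two-column `parameter,value` table (list-valued diagnostics are flattened
#' with `.` separators).
#'
#' @param fit a fit object produced by this package.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(fit, path, format = c("json", "csv")) {
  format <- match.arg(format)
  rec <- as_report(fit)
  if (format == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    flat <- unlist(rec)
    utils::write.csv(
      data.frame(parameter = names(flat),
                 value = vapply(flat, format, character(1), digits = 17)),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
as_report <- function(fit) UseMethod("as_report")

#' @export
as_report.default <- function(fit) {
  lapply(unclass(fit), function(v) if (is.function(v)) NULL else v)
}
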