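## File formats: the CSV peak-table dialect, NMR-STAR chemical-shift
## loops, anisotropy tables, and schema-versioned JSON reports.
## CSV dialect: comma-separated, UTF-8, mandatory header, lower_snake_case
## column names.  Residue indexing is 1-based inclusive everywhere
## user-facing.

.PEAK_REQUIRED <- c("assignment", "intensity", "condition")

#' Read a peak table
#'
#' Reads a CSV/TSV peak table with columns \code{assignment},
#' \code{residue}, \code{h_ppm}, \code{n_ppm}, \code{intensity},
#' \code{condition}.  \code{assignment}, \code{intensity} and
#' \code{condition} are required; \code{residue} is parsed from the
#' assignment label (its digits) when absent; extra columns are
#' preserved.  Duplicate (assignment, condition) pairs are an error
#' naming the offending rows.
#'
#' @param path file path
#' @param sep field separator (\code{","} default; use \code{"\t"} for TSV)
#' @return data.frame of validated records
#' @export
readPeakTable <- function(path, sep = ",") {
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = TRUE)
  missing <- setdiff(.PEAK_REQUIRED, names(tab))
  if (length(missing))
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(tab$intensity < 0, na.rm = TRUE))
    stop("negative intensities in peak table")
  if (!"residue" %in% names(tab)) {
    tab$residue <- suppressWarnings(
      as.integer(gsub("[^0-9]", "", tab$assignment)))
    if (anyNA(tab$residue))
      stop("column 'residue' absent and not parseable from assignment ",
           "labels: ",
           paste(tab$assignment[is.na(tab$residue)], collapse = ", "))
  }
  key <- paste(tab$assignment, tab$condition, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (assignment, condition) pairs at row(s) ",
         paste(dup, collapse = ", "), ": ",
         paste(unique(tab$assignment[dup]), collapse = ", "))
  }
  if (!"h_ppm" %in% names(tab)) tab$h_ppm <- NA_real_
  if (!"n_ppm" %in% names(tab)) tab$n_ppm <- NA_real_
  tab
}

#' @param records data.frame of peak records
#' @param path output file path
#' @rdname readPeakTable
#' @export
writePeakTable <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an anisotropy titration table
#'
#' CSV with columns \code{concentration} and \code{anisotropy}, plus an
#' optional \code{sd} column of replicate standard deviations.
#'
#' @param path file path
#' @param labeledConc fixed labeled-species concentration
#' @param unit concentration unit tag
#' @return an \linkS4class{AnisotropyTitration}
#' @export
readAnisotropyTable <- function(path, labeledConc, unit = "mol%") {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("concentration", "anisotropy"), names(tab))
  if (length(missing))
    stop("anisotropy table is missing required column(s): ",
         paste(missing, collapse = ", "))
  anisotropyTitration(labeledConc, tab$concentration, tab$anisotropy,
                      replicateSd = if ("sd" %in% names(tab)) tab$sd
                                    else numeric(),
                      unit = unit)
}

#' Build a TitrationSeries from a long-format peak table
#'
#' The peak table must contain one row per (assignment, condition) with
#' \code{condition} holding the numeric titrant concentration of each
#' titration point.  For slow exchange the observable is the raw peak
#' intensity.  For fast exchange the observable is the hybrid 1H/15N
#' shift change of each peak relative to its position at the zero-titrant
#' condition, computed with \code{\link{hybridShift}} from the
#' \code{h_ppm}/\code{n_ppm} columns.
#'
#' @param records peak records as returned by \code{\link{readPeakTable}}
#' @param u0 fixed observed-subunit concentration
#' @param regime exchange regime of the titration
#' @param unit concentration unit tag
#' @return a \linkS4class{TitrationSeries}
#' @export
titrationSeriesFromPeaks <- function(records, u0,
                                     regime = c("slow_exchange_intensity",
                                                "fast_exchange_shift"),
                                     unit = "mol%") {
  regime <- match.arg(regime)
  conc <- suppressWarnings(as.numeric(as.character(records$condition)))
  if (anyNA(conc))
    stop("condition column must hold numeric titrant concentrations")
  concs <- sort(unique(conc))
  if (!any(concs == 0)) stop("a zero-titrant condition is required")
  peaks <- unique(records$assignment)
  full <- vapply(peaks, function(a) {
    all(concs %in% conc[records$assignment == a])
  }, logical(1))
  if (!all(full))
    stop("peak(s) missing titration points: ",
         paste(peaks[!full], collapse = ", "))
  idx <- function(a, cc) which(records$assignment == a & conc == cc)
  Y <- matrix(0, length(peaks), length(concs))
  for (i in seq_along(peaks)) {
    rows <- vapply(concs, function(cc) idx(peaks[i], cc), integer(1))
    if (regime == "slow_exchange_intensity") {
      Y[i, ] <- records$intensity[rows]
    } else {
      ref <- rows[concs == 0]
      Y[i, ] <- hybridShift(shiftPerturbation(
        records$h_ppm[rows] - records$h_ppm[ref],
        records$n_ppm[rows] - records$n_ppm[ref]))
    }
  }
  residues <- records$residue[match(peaks, records$assignment)]
  titrationSeries(Y, conc = concs, u0 = u0, regime = regime, unit = unit,
                  residues = residues, assignments = peaks)
}

#' Write a TitrationSeries as a long-format peak table
#'
#' Emits the same CSV dialect \code{\link{readPeakTable}} consumes, with
#' \code{condition} holding the titrant concentration.  Slow-exchange
#' observables are written as peak intensities.  Fast-exchange hybrid
#' shift changes are encoded in the 1H dimension
#' (\code{h_ppm = 8 + sqrt(2) * delta} around a fixed 15N position), from
#' which \code{\link{titrationSeriesFromPeaks}} recovers them exactly.
#'
#' @param series a \linkS4class{TitrationSeries}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeTitrationSeries <- function(series, path) {
  Y <- SummarizedExperiment::assay(series, "observables")
  rd <- SummarizedExperiment::rowData(series)
  conc <- titrantConcentrations(series)
  slow <- exchangeRegime(series) == "slow_exchange_intensity"
  rows <- expand.grid(p = seq_len(nrow(Y)), j = seq_along(conc))
  tab <- data.frame(
    assignment = rd$assignment[rows$p],
    residue = rd$residue[rows$p],
    h_ppm = if (slow) 8 else 8 + sqrt(2) * Y[cbind(rows$p, rows$j)],
    n_ppm = 120,
    intensity = if (slow) Y[cbind(rows$p, rows$j)] else 1,
    condition = conc[rows$j])
  writePeakTable(tab, path)
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## minimal NMR-STAR chemical-shift-loop reader.  Handles the assigned
## chemical shift loop of both STAR 3.x (_Atom_chem_shift.* tags) and
## 2.1 (_Residue_seq_code / _Atom_name / _Chem_shift_value) files; only
## CA, CB and C(O) rows are retained.
.readNmrStarShifts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  tagIdx <- grep("^_", lines)
  v3 <- grepl("^_Atom_chem_shift\\.", lines[tagIdx])
  v2 <- lines[tagIdx] %in% c("_Residue_seq_code", "_Residue_label",
                             "_Atom_name", "_Chem_shift_value")
  use3 <- any(v3)
  sel <- tagIdx[if (use3) v3 else v2]
  if (!length(sel))
    stop("no chemical-shift loop found in NMR-STAR file")
  tags <- sub("^_Atom_chem_shift\\.", "", lines[sel])
  want <- if (use3)
    c(res = "Comp_index_ID", aa = "Comp_ID", atom = "Atom_ID", val = "Val")
  else
    c(res = "_Residue_seq_code", aa = "_Residue_label",
      atom = "_Atom_name", val = "_Chem_shift_value")
  cols <- match(want, tags)
  if (anyNA(cols))
    stop("chemical-shift loop lacks tag(s): ",
         paste(want[is.na(cols)], collapse = ", "))
  ## data rows: after the last tag of the loop, until stop_/blank tag line
  start <- max(sel) + 1L
  rows <- character()
  for (i in start:length(lines)) {
    ln <- lines[i]
    if (ln == "stop_" || grepl("^(loop_|save_|_)", ln)) break
    if (nzchar(ln) && !startsWith(ln, "#")) rows <- c(rows, ln)
  }
  if (!length(rows)) stop("chemical-shift loop contains no data rows")
  fields <- strsplit(rows, "[[:space:]]+")
  rec <- vapply(fields, function(f) f[cols], character(4))
  data.frame(residue = as.integer(rec[1, ]),
             aa = unname(.AA3TO1[toupper(rec[2, ])]),
             atom = toupper(rec[3, ]),
             val = as.numeric(rec[4, ]), stringsAsFactors = FALSE)
}

#' Read a backbone chemical-shift table
#'
#' Accepts either the package CSV dialect (columns \code{residue},
#' \code{aa}, \code{ca}, \code{cb}, \code{co}) or an NMR-STAR file with
#' an assigned-chemical-shift loop, from which CA, CB and CO shifts are
#' extracted.
#'
#' @param path file path
#' @param format \code{"auto"} (by extension), \code{"csv"} or
#'   \code{"nmr-star"}
#' @return a \linkS4class{ShiftTable}
#' @export
readShiftTable <- function(path, format = c("auto", "csv", "nmr-star")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(str|star|bmrb)$", path, ignore.case = TRUE))
      "nmr-star" else "csv"
  if (format == "csv") {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(c("residue", "aa"), names(tab))
    if (length(missing))
      stop("shift table is missing required column(s): ",
           paste(missing, collapse = ", "))
    pick <- function(nm) if (nm %in% names(tab)) tab[[nm]] else NA_real_
    return(shiftTable(tab$residue, tab$aa, ca = pick("ca"),
                      cb = pick("cb"), co = pick("co"), source = "csv"))
  }
  long <- .readNmrStarShifts(path)
  long <- long[long$atom %in% c("CA", "CB", "C", "CO"), ]
  long$atom[long$atom == "C"] <- "CO"
  residues <- sort(unique(long$residue))
  get <- function(atom) {
    sub <- long[long$atom == atom, ]
    sub$val[match(residues, sub$residue)]
  }
  aa <- long$aa[match(residues, long$residue)]
  shiftTable(residues, aa, ca = get("CA"), cb = get("CB"), co = get("CO"),
             source = "nmr-star")
}

## ---------------------------------------------------------------------------
## JSON reports
## ---------------------------------------------------------------------------

.reportList <- function(result) {
  if (is(result, "BindingFitResult")) {
    list(type = "binding_fit", regime = result@regime,
         kd = result@kd, kd_se = result@kdSe, unit = result@unit,
         bound_flag = result@boundFlag,
         lower_bound_value = if (length(result@lowerBoundValue))
           result@lowerBoundValue else NULL,
         saturation_fraction = result@saturationFraction,
         per_peak = result@perPeak,
         excluded_peaks = as.list(result@excludedPeaks),
         deviance = result@fitInfo$deviance, df = result@fitInfo$df)
  } else if (is(result, "TopologyCall")) {
    seg <- function(r) data.frame(start = IRanges::start(r),
                                  end = IRanges::end(r))
    list(type = "topology_call", no_span = result@noSpan,
         tm_start = if (result@noSpan) NULL else result@tmStart,
         tm_end = if (result@noSpan) NULL else result@tmEnd,
         protected_segments = seg(result@protectedSegments),
         exposed_segments = seg(result@exposedSegments),
         evidence = result@evidence)
  } else if (is(result, "ProfileComparison")) {
    list(type = "profile_comparison", verdict = result@verdict,
         n_significant = result@nSignificant, allowed = result@allowed,
         k = result@k,
         per_residue = data.frame(residue = result@residues,
                                  delta = result@delta,
                                  combined_error = result@combinedError))
  } else {
    stop("no report serialization for class ", class(result))
  }
}

#' Write an analysis result as a schema-versioned JSON report
#'
#' Serializes a \linkS4class{BindingFitResult},
#' \linkS4class{TopologyCall} or \linkS4class{ProfileComparison} to JSON
#' with all floats at full precision.
#'
#' @param result the result object
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeReport <- function(result, path) {
  payload <- c(list(schema_version = "1.0", package = "BicelleNMR"),
               .reportList(result))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}
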