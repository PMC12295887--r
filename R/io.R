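.scheduleLabel <- function(s) {
    if (s@mode == "continuous") "continuous"
    else sprintf("intermittent:%g:%g", s@window, s@period)
}

.scheduleFromLabel <- function(lab) {
    if (identical(lab, "continuous")) return(IlluminationSchedule())
    parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3 || parts[1] != "intermittent")
        stop("unrecognized schedule label: ", lab)
    IlluminationSchedule("intermittent", window = as.numeric(parts[2]),
                         period = as.numeric(parts[3]))
}

#' Write fluorescence traces to tabular text
#'
#' Long-format CSV with header \code{time_s,intensity_au,condition,schedule}.
#'
#' @param traces a \code{FluorescenceTrace} or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(traces, path) {
    if (is(traces, "FluorescenceTrace")) traces <- list(traces)
    rows <- do.call(rbind, lapply(traces, function(tr) {
        data.frame(time_s = tr@time, intensity_au = tr@intensity,
                   condition = tr@condition,
                   schedule = .scheduleLabel(tr@schedule))
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read fluorescence traces from tabular text
#'
#' Reads the CSV dialect written by \code{\link{writeTraces}}; one trace
#' per distinct condition label.
#'
#' @param path input file path.
#' @return named list of \code{\link{FluorescenceTrace-class}} objects.
#' @export
readTraces <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("time_s", "intensity_au", "condition", "schedule")
    if (!all(need %in% names(d)))
        stop("trace file must have columns ", paste(need, collapse = ","))
    out <- lapply(split(d, d$condition), function(g) {
        g <- g[order(g$time_s), , drop = FALSE]
        FluorescenceTrace(g$time_s, g$intensity_au, g$condition[1],
                          .scheduleFromLabel(g$schedule[1]))
    })
    out[unique(d$condition)]
}

#' Write or read steady-state series
#'
#' CSV with header \code{actin_uM,intensity_au,condition}; multiple
#' conditions may share a file.
#'
#' @param series a \code{SteadyStateSeries} or list of them.
#' @param path file path.
#' @return \code{writeSteadyStateSeries} returns \code{path} invisibly;
#'   \code{readSteadyStateSeries} returns a named list of
#'   \code{\link{SteadyStateSeries-class}} objects.
#' @export
writeSteadyStateSeries <- function(series, path) {
    if (is(series, "SteadyStateSeries")) series <- list(series)
    rows <- do.call(rbind, lapply(series, function(s) {
        data.frame(actin_uM = s@actinConc, intensity_au = s@intensity,
                   condition = s@condition)
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeSteadyStateSeries
#' @export
readSteadyStateSeries <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("actin_uM", "intensity_au", "condition")
    if (!all(need %in% names(d)))
        stop("series file must have columns ", paste(need, collapse = ","))
    out <- lapply(split(d, d$condition), function(g)
        SteadyStateSeries(g$actin_uM, g$intensity_au, g$condition[1]))
    out[unique(d$condition)]
}

#' Write a height image as TIFF with a JSON sidecar
#'
#' Heights are min-max normalized into [0, 1] for 32-bit TIFF storage; the
#' sidecar \code{<path>.json} records the pixel size and the height range
#' needed to restore nm values.
#'
#' @param image a \code{\link{HeightImage-class}} object.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeHeightImage <- function(image, path) {
    stopifnot(is(image, "HeightImage"))
    h <- image@heights
    lo <- min(h); hi <- max(h)
    norm <- if (hi > lo) (h - lo) / (hi - lo) else h * 0
    tiff::writeTIFF(norm, path, bits.per.sample = 32L)
    jsonlite::write_json(
        list(pixel_size_nm = image@pixelSize, height_min_nm = lo,
             height_max_nm = hi),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a height image written by \code{writeHeightImage}
#'
#' @param path TIFF path; the sidecar \code{<path>.json} must exist.
#' @return a \code{\link{HeightImage-class}} object.
#' @export
readHeightImage <- function(path) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    norm <- tiff::readTIFF(path)
    h <- norm * (meta$height_max_nm - meta$height_min_nm) +
        meta$height_min_nm
    new("HeightImage", heights = h, pixelSize = meta$pixel_size_nm)
}
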