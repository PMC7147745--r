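#' Load a configuration file
#'
#' Reads a flat `key = value` text file into a validated parameter bundle.
#' Missing keys take the published defaults; unknown keys are rejected.
#' Logical fields accept `TRUE`/`FALSE`; everything else is numeric.
#'
#' @param path file path, or `NULL` for pure defaults.
#' @return a [neuron_params()] bundle.
#' @export
load_config <- function(path = NULL) {
  defaults <- neuron_params()
  if (is.null(path)) return(defaults)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults))
      stop("unknown config key: '", key, "'", call. = FALSE)
    if (key %in% c("ip_inhibitory", "normalize")) {
      vals[[key]] <- as.logical(val)
    } else {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v))
        stop("config key '", key, "' has non-numeric value '", val, "'",
             call. = FALSE)
      vals[[key]] <- v
    }
  }
  p <- utils::modifyList(unclass(defaults), vals)
  class(p) <- "neuron_params"
  validate_params(p)
  p
}

#' Save a configuration file
#'
#' @param params a [neuron_params()] bundle.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  validate_params(params)
  lines <- vapply(names(params), function(k)
    paste(k, "=", format(params[[k]], digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export / read a spike raster
#'
#' TSV format has a header and columns `time_ms` (fixed-point, 0.1 ms
#' resolution) and `neuron_id` (0-based); the binary format is an RDS
#' container. Round-trips are lossless at the stated time resolution.
#'
#' @param spikes data frame with `time_ms` and `neuron` (1-based).
#' @param path output path.
#' @param format `"tsv"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
export_rasters <- function(spikes, path, format = c("tsv", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    saveRDS(spikes[, c("time_ms", "neuron")], path)
  } else {
    df <- data.frame(time_ms = sprintf("%.1f", spikes$time_ms),
                     neuron_id = spikes$neuron - 1L)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_rasters
#' @export
read_rasters <- function(path, format = c("tsv", "binary")) {
  format <- match.arg(format)
  if (format == "binary") return(readRDS(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  data.frame(time_ms = as.numeric(df$time_ms), neuron = df$neuron_id + 1L)
}

#' Export / read a weight matrix as sparse coordinate triplets
#'
#' TSV columns `pre`, `post` (0-based) and `weight_nS` (full precision);
#' only nonzero entries are stored. The matrix dimension is recorded on a
#' comment-free first data read via the `n` attribute argument.
#'
#' @param W weight matrix `[post, pre]` (nS).
#' @param path output path.
#' @param format `"tsv"` or `"binary"` (RDS).
#' @return `path`, invisibly.
#' @export
export_weights <- function(W, path, format = c("tsv", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    saveRDS(W, path)
    return(invisible(path))
  }
  nz <- which(W != 0, arr.ind = TRUE)
  df <- data.frame(pre = nz[, "col"] - 1L, post = nz[, "row"] - 1L,
                   weight_nS = format(W[nz], digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_weights
#' @param n matrix dimension for TSV reads (square).
#' @export
read_weights <- function(path, n, format = c("tsv", "binary")) {
  format <- match.arg(format)
  if (format == "binary") return(readRDS(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  W <- matrix(0, n, n)
  W[cbind(df$post + 1L, df$pre + 1L)] <- as.numeric(df$weight_nS)
  W
}

#' Export a stimulus schedule as a tabular event file
#'
#' @param schedule a `"stimulus_schedule"`.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
export_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Basic raster diagnostic plot
#'
#' @param spikes data frame with `time_ms` and `neuron`.
#' @param topology optional topology; trained groups get distinct colours.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_raster <- function(spikes, topology = NULL, ...) {
  col <- "grey30"
  if (!is.null(topology)) {
    ga <- topology$group_assignment
    col <- rep("grey70", max(spikes$neuron))
    pal <- c("#D55E00", "#E69F00", "#009E73", "#0072B2", "#CC79A7", "#555555")
    for (g in 1:6) col[which(ga == g)] <- pal[g]
    col <- col[spikes$neuron]
  }
  graphics::plot(spikes$time_ms, spikes$neuron, pch = ".", cex = 2,
                 col = col, xlab = "time (ms)", ylab = "neuron", ...)
  invisible(NULL)
}
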