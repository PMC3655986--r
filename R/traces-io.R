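#' Write and read simulated trace families
#'
#' Traces are stored as a single long-format tab-separated file (columns
#' `sweep`, `sweep_value`, `segment`, `time`, `voltage`, `current`, then one
#' occupancy column per state) plus a YAML metadata sidecar (`<path>.meta.yml`)
#' holding the protocol definition, simulator configuration, state names and
#' any generating-truth annotations. The round trip is lossless to full
#' double precision.
#'
#' @param traces A `nav_trace_set`.
#' @param path Output file path (the sidecar gets `.meta.yml` appended).
#' @param truth Optional named list recorded in the sidecar (e.g. generating
#'   parameters of a synthetic family).
#' @return `write_traces()` returns `path` invisibly; `read_traces()` returns
#'   a `nav_trace_set`.
#' @export
write_traces <- function(traces, path, truth = NULL) {
  stopifnot(length(traces) > 0L)
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    df <- data.frame(sweep = i, sweep_value = tr$sweep_value,
                     segment = tr$segment, time = tr$time,
                     voltage = tr$voltage, current = tr$current)
    occ <- as.data.frame(tr$occ)
    names(occ) <- paste0("occ.", tr$states)
    cbind(df, occ)
  })
  long <- do.call(rbind, rows)
  num <- vapply(long, is.double, TRUE)
  long[num] <- lapply(long[num], function(x) sprintf("%.17g", x))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  proto <- attr(traces, "protocol")
  meta <- list(
    protocol = if (!is.null(proto)) {
      tmp <- tempfile(fileext = ".yml"); on.exit(unlink(tmp), add = TRUE)
      write_protocol(proto, tmp)
      yaml::read_yaml(tmp)
    },
    config = unclass(attr(traces, "config")),
    scheme = attr(traces, "scheme"),
    states = traces[[1]]$states, open = traces[[1]]$open,
    truth = truth)
  yaml::write_yaml(meta, paste0(path, ".meta.yml"), precision = 12L)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  metapath <- paste0(path, ".meta.yml")
  meta <- if (file.exists(metapath)) yaml::read_yaml(metapath) else list()
  states <- if (!is.null(meta$states)) unlist(meta$states) else
    sub("^occ\\.", "", grep("^occ\\.", names(long), value = TRUE))
  occcols <- paste0("occ.", states)
  proto <- if (!is.null(meta$protocol)) {
    tmp <- tempfile(fileext = ".yml"); on.exit(unlink(tmp), add = TRUE)
    yaml::write_yaml(meta$protocol, tmp, precision = 12L)
    read_protocol(tmp)
  }
  traces <- lapply(split(long, long$sweep), function(df) {
    df <- df[order(df$time), ]
    structure(list(time = df$time, segment = df$segment,
                   voltage = df$voltage,
                   occ = as.matrix(stats::setNames(df[occcols], states)),
                   current = df$current,
                   sweep_value = df$sweep_value[1], states = states,
                   open = meta$open,
                   protocol = if (!is.null(proto)) proto$name else NA),
              class = "nav_trace")
  })
  names(traces) <- NULL
  structure(traces, class = "nav_trace_set", protocol = proto,
            config = meta$config, scheme = meta$scheme,
            truth = meta$truth)
}

#' Serialize a fit result to structured text
#'
#' @param fit A `boltzmann_fit`, `monoexp_fit` or `biexp_fit`.
#' @param path Output path (YAML).
#' @return `write_fit()` returns `path` invisibly; `read_fit()` returns the
#'   fit as a named list with a `class` field.
#' @export
write_fit <- function(fit, path) {
  yaml::write_yaml(c(list(class = class(fit)[1]), unclass(fit)), path,
                   precision = 12L)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) yaml::read_yaml(path)
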