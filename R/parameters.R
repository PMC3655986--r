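#' Model parameter sets
#'
#' A parameter set is a named list: each exponential rate entry (`alpha1`,
#' `alpha2`, `alpha3`, `beta1`, `beta2`, `phi1`, `phi2`, `phi3`, `rho2`,
#' `rho3`) is a `c(k, n)` pair (pre-exponential factor in 1/ms, exponential
#' voltage factor in mV); `rho1` is the sigmoid triple `c(g, a, f)` (maximal
#' rate 1/ms, half-activation offset mV, slope factor mV); `c` is the
#' dimensionless row-to-row scaling factor.
#'
#' `nav_params()` returns the packaged best-fit defaults for the Nav1.5
#' models, shared by the 8-state and 12-state schemes. Individual entries can
#' be overridden by name, e.g. `nav_params(alpha1 = c(k = 10, n = 40))`.
#'
#' @param ... Named overrides of default entries.
#' @return A named list of class `nav_params`.
#' @examples
#' p <- nav_params()
#' p$alpha1                     # k = 9.435, n = 39.70
#' nav_params(c = 1)$c
#' @export
nav_params <- function(...) {
  p <- list(
    alpha1 = c(k = 9.435,    n = 39.70),
    alpha2 = c(k = 441.1,    n = 6.593),
    alpha3 = c(k = 11.17,    n = 11.64),
    beta1  = c(k = 0.000037, n = -7.770),
    beta2  = c(k = 0.2241,   n = -21.13),
    phi1   = c(k = 0.000020, n = -13.07),
    phi2   = c(k = 0.000302, n = -47.08),
    phi3   = c(k = 0.000230, n = -57.21),
    rho1   = c(g = 0.01296,  a = 85.62, f = 15.64),
    rho2   = c(k = 1.823,    n = 92.78),
    rho3   = c(k = 0.000315, n = 965.2),
    c      = c(c = 2.146)
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("parameter overrides must be named")
    for (nm in names(ov)) {
      val <- ov[[nm]]
      if (!nm %in% names(p)) {
        p[nm] <- list(val)  # allow extra user-defined entries
        next
      }
      tmpl <- p[[nm]]
      if (is.null(names(val))) {
        if (length(val) != length(tmpl))
          stop("override for '", nm, "' must have ", length(tmpl), " value(s)")
        names(val) <- names(tmpl)
      }
      tmpl[names(val)] <- val
      p[[nm]] <- tmpl
    }
  }
  validate_params(p)
  structure(p, class = "nav_params")
}

validate_params <- function(p) {
  for (nm in c("alpha1", "alpha2", "alpha3", "beta1", "beta2",
               "phi1", "phi2", "phi3", "rho2", "rho3")) {
    if (is.null(p[[nm]])) stop("missing parameter entry '", nm, "'")
    v <- p[[nm]]
    if (!is.finite(v[["k"]]) || v[["k"]] <= 0)
      stop("parameter '", nm, "': k must be positive")
    if (is.na(v[["n"]]) || v[["n"]] == 0)
      stop("parameter '", nm, "': n must be nonzero (Inf = constant)")
  }
  r1 <- p[["rho1"]]
  if (is.null(r1) || r1[["g"]] <= 0 || r1[["f"]] <= 0)
    stop("parameter 'rho1': need g > 0, f > 0")
  if (p[["c"]][["c"]] <= 0) stop("parameter 'c' must be positive")
  invisible(p)
}

#' @export
print.nav_params <- function(x, ...) {
  cat("<nav_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-7s %s\n", nm,
                paste(sprintf("%s=%g", names(v), v), collapse = "  ")))
  }
  invisible(x)
}

#' Read and write parameter files
#'
#' Parameters live in a flat whitespace-separated key-value text format, one
#' `name value` pair per line (`alpha1.k 9.435`), `#` comments allowed.
#'
#' @param path File path.
#' @param params A `nav_params` object.
#' @return `read_params()` returns a `nav_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "[[:space:]]+")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed parameter line: ", ln[which(bad)[1]])
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  vals[keys == "rho3.n" & vapply(kv, `[[`, "", 2L) %in% c("Inf", "inf")] <- Inf
  if (any(is.na(vals))) stop("non-numeric parameter value for: ",
                             keys[which(is.na(vals))[1]])
  parts <- strsplit(keys, ".", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("parameter keys must be of the form entry.field (got '",
         keys[which(lengths(parts) != 2L)[1]], "')")
  p <- list()
  for (i in seq_along(parts)) {
    ent <- parts[[i]][1]; fld <- parts[[i]][2]
    p[[ent]][fld] <- vals[i]
  }
  do.call(nav_params, p)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "nav_params"))
  out <- character(0)
  for (nm in names(params))
    out <- c(out, sprintf("%s.%s %.17g", nm, names(params[[nm]]), params[[nm]]))
  writeLines(out, path)
  invisible(path)
}

#' Resolve one named parameter entry into a rate_law object
#'
#' Builds the concrete [rate_laws] object for a scheme transition: an
#' exponential law from a `c(k, n)` entry or a sigmoid law from a
#' `c(g, a, f)` entry, optionally scaled by a (power of a) dimensionless
#' parameter.
#'
#' @param params A `nav_params` list.
#' @param name Entry name, e.g. `"alpha1"`.
#' @param scale Optional name of a dimensionless scaling entry (e.g. `"c"`).
#' @param power Integer power applied to the scale factor (may be negative).
#' @return A `rate_law`.
#' @keywords internal
#' @export
param_law <- function(params, name, scale = NULL, power = 1L) {
  v <- params[[name]]
  if (is.null(v)) stop("parameter entry '", name, "' not found")
  law <- if (all(c("g", "a", "f") %in% names(v)))
    rate_sigmoid(v[["g"]], v[["a"]], v[["f"]])
  else
    rate_exp(v[["k"]], v[["n"]])
  if (!is.null(scale)) {
    s <- params[[scale]]
    if (is.null(s)) stop("scale parameter '", scale, "' not found")
    law <- rate_scaled(law, unname(s[1])^power)
  }
  law
}
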